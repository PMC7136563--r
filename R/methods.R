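#' Construct a PairedExpressionSet
#'
#' Builds a [PairedExpressionSet-class] from a count matrix and a pairing
#' sheet. Samples present in `counts` but not referenced by the pairing
#' are dropped with a warning; a pairing row that names a sample missing
#' from the matrix is an error.
#'
#' @param counts non-negative numeric matrix, features x samples, with
#'   unique rownames (feature identifiers) and colnames (sample
#'   identifiers).
#' @param pairing data.frame with columns `tumor_sample`, `normal_sample`
#'   and `patient`, one row per patient.
#' @return a validated [PairedExpressionSet-class].
#' @examples
#' cts <- matrix(rpois(24, 50), 4, 6,
#'   dimnames = list(paste0("f", 1:4), paste0("s", 1:6)))
#' prs <- data.frame(tumor_sample = c("s1", "s2", "s3"),
#'                   normal_sample = c("s4", "s5", "s6"),
#'                   patient = c("P1", "P2", "P3"))
#' pes <- PairedExpressionSet(cts, prs)
#' pairing(pes)
#' @export
PairedExpressionSet <- function(counts, pairing) {
  counts <- as.matrix(counts)
  need <- c("tumor_sample", "normal_sample", "patient")
  if (!all(need %in% colnames(pairing)))
    stop("pairing needs columns: ", paste(need, collapse = ", "))
  pairing <- as.data.frame(pairing)[need]
  for (cn in need) pairing[[cn]] <- as.character(pairing[[cn]])
  ref <- c(pairing$tumor_sample, pairing$normal_sample)
  if (anyDuplicated(ref))
    stop("a sample occurs more than once in the pairing sheet: ",
         paste(unique(ref[duplicated(ref)]), collapse = ", "))
  missing <- setdiff(ref, colnames(counts))
  if (length(missing))
    stop("pairing references samples absent from the count matrix: ",
         paste(missing, collapse = ", "))
  extra <- setdiff(colnames(counts), ref)
  if (length(extra)) {
    warning("dropping ", length(extra), " unpaired sample(s): ",
            paste(extra, collapse = ", "))
    counts <- counts[, ref, drop = FALSE]
  } else {
    counts <- counts[, ref, drop = FALSE]
  }
  cd <- S4Vectors::DataFrame(
    patient = c(pairing$patient, pairing$patient),
    condition = rep(c("tumor", "normal"), each = nrow(pairing)),
    row.names = ref)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("PairedExpressionSet", se)
}

#' Tumor/normal pairing triples
#'
#' @param x a [PairedExpressionSet-class].
#' @return data.frame with columns `tumor_sample`, `normal_sample`,
#'   `patient`, one row per patient, in patient order of first
#'   appearance.
#' @rdname pairing
#' @export
setMethod("pairing", "PairedExpressionSet", function(x) {
  cd <- SummarizedExperiment::colData(x)
  pts <- unique(cd$patient)
  smp <- rownames(cd)
  data.frame(
    tumor_sample = vapply(pts, function(p)
      smp[cd$patient == p & cd$condition == "tumor"], ""),
    normal_sample = vapply(pts, function(p)
      smp[cd$patient == p & cd$condition == "normal"], ""),
    patient = pts, row.names = NULL)
})

#' @describeIn PairedExpressionSet-class raw count matrix accessor.
#' @param object a `PairedExpressionSet`.
#' @export
setMethod("counts", "PairedExpressionSet", function(object)
  SummarizedExperiment::assay(object, "counts"))

setMethod("show", "PairedExpressionSet", function(object) {
  cat("PairedExpressionSet with", nrow(object), "features,",
      length(unique(SummarizedExperiment::colData(object)$patient)),
      "tumor/normal patient pairs\n")
  callNextMethod()
})

#' Construct a TargetMap
#'
#' @param mirna,gene character vectors of equal length giving interaction
#'   pairs, or `mirna` may be a data.frame with columns `mirna`, `gene`.
#'   Duplicate pairs are collapsed.
#' @return a [TargetMap-class].
#' @examples
#' tm <- TargetMap(c("mir-a", "mir-a", "mir-b"), c("g1", "g2", "g1"))
#' targetsOf(tm, "mir-a")
#' regulatorsOf(tm, "g1")
#' @export
TargetMap <- function(mirna, gene = NULL) {
  if (is.data.frame(mirna)) {
    df <- mirna
    if (!all(c("mirna", "gene") %in% colnames(df)))
      stop("data.frame input needs columns 'mirna' and 'gene'")
    df <- df[c("mirna", "gene")]
  } else {
    df <- data.frame(mirna = as.character(mirna),
                     gene = as.character(gene))
  }
  df$mirna <- as.character(df$mirna)
  df$gene <- as.character(df$gene)
  df <- unique(df)
  rownames(df) <- NULL
  new("TargetMap", edges = df)
}

#' Target genes of a miRNA / regulators of a gene
#'
#' Both index sets are derived from the same stored edge set of the
#' [TargetMap-class], so `g %in% targetsOf(x, m)` exactly when
#' `m %in% regulatorsOf(x, g)`.
#'
#' @param x a [TargetMap-class].
#' @param mirna,gene single identifier.
#' @return character vector (possibly empty), sorted.
#' @rdname targetsOf
#' @export
setMethod("targetsOf", "TargetMap", function(x, mirna)
  sort(x@edges$gene[x@edges$mirna == mirna]))

#' @rdname targetsOf
#' @export
setMethod("regulatorsOf", "TargetMap", function(x, gene)
  sort(x@edges$mirna[x@edges$gene == gene]))

#' @describeIn TargetMap-class edge table accessor.
#' @param x a `TargetMap`.
#' @export
targetEdges <- function(x) x@edges

setMethod("show", "TargetMap", function(object) {
  cat("TargetMap:", nrow(object@edges), "interactions,",
      length(unique(object@edges$mirna)), "miRNAs,",
      length(unique(object@edges$gene)), "genes\n")
})

#' Construct a PPIDegrees table
#'
#' @param degree named non-negative numeric vector of gene degrees.
#' @return a [PPIDegrees-class]; `dmax` is set to the maximum degree.
#' @export
PPIDegrees <- function(degree) {
  new("PPIDegrees", degree = degree, dmax = max(degree))
}

#' @describeIn PPIDegrees-class degree lookup; genes absent from the
#'   network return 0.
#' @param x a `PPIDegrees`.
#' @param genes character vector of gene identifiers.
#' @export
ppiDegree <- function(x, genes) {
  d <- x@degree[genes]
  d[is.na(d)] <- 0
  names(d) <- genes
  d
}

#' @describeIn PPIDegrees-class the maximum degree in the network.
#' @export
ppiMaxDegree <- function(x) x@dmax

setMethod("show", "PPIDegrees", function(object) {
  cat("PPIDegrees:", length(object@degree), "genes, max degree",
      object@dmax, "\n")
})

setMethod("show", "ApportionedDeltas", function(object) {
  cat("ApportionedDeltas:", length(object@mirna), "edges over",
      length(object@patients), "patients\n")
})

#' @describeIn InfluenceReport-class regulation edge table accessor.
#' @param x an `InfluenceReport`.
#' @export
regulationEdges <- function(x) x@edges

#' @describeIn InfluenceReport-class ranked global influence table
#'   accessor.
#' @export
globalRanking <- function(x) x@global

#' @describeIn InfluenceReport-class per-edge intervention call accessor.
#' @export
interventionCallTable <- function(x) x@calls

setMethod("show", "InfluenceReport", function(object) {
  cat("InfluenceReport:", nrow(object@edges), "regulation edges,",
      nrow(object@global), "ranked miRNAs\n")
  if (nrow(object@global)) {
    cat("top miRNAs by global influence:\n")
    print(head(object@global, 5))
  }
})
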