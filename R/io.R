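# Readers and writers for the three TSV input formats and the result
# tables. All inputs are tab-separated with a header row; outputs use a
# fixed, documented column order so repeated runs are byte-identical.

#' Read a paired expression dataset
#'
#' Reads a features x samples count matrix (TSV, first column feature
#' identifiers, header row of sample identifiers) together with a
#' pairing sheet (TSV, columns `tumor_sample`, `normal_sample`,
#' `patient`). Samples in the matrix not referenced by the pairing are
#' dropped with a warning.
#'
#' @param counts_path path to the count matrix TSV.
#' @param pairing_path path to the pairing sheet TSV.
#' @return a [PairedExpressionSet-class].
#' @export
readExpression <- function(counts_path, pairing_path) {
  tab <- read.delim(counts_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L)
    stop("count matrix needs a feature column plus at least one sample")
  feats <- as.character(tab[[1L]])
  if (anyDuplicated(feats))
    stop("duplicate feature identifiers in ", counts_path, ": ",
         paste(unique(feats[duplicated(feats)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(m) || anyNA(m))
    stop("non-numeric count value in ", counts_path)
  if (any(m < 0))
    stop("negative count value in ", counts_path)
  rownames(m) <- feats
  prs <- read.delim(pairing_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  need <- c("tumor_sample", "normal_sample", "patient")
  if (!all(need %in% colnames(prs)))
    stop("pairing sheet needs columns: ", paste(need, collapse = ", "))
  PairedExpressionSet(m, prs)
}

#' Read a miRNA-target interaction table
#'
#' Reads a miRTarbase-style TSV with (at least) a miRNA column and a
#' gene column; extra columns are ignored and duplicate rows collapsed.
#'
#' @param path path to the TSV.
#' @param mirna_col,gene_col column names to use (defaults `mirna`,
#'   `gene`), so exports with other headers can be mapped.
#' @return a [TargetMap-class].
#' @export
readTargetMap <- function(path, mirna_col = "mirna", gene_col = "gene") {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(tab) == 0L)
    stop("target map ", path, " is empty")
  if (!all(c(mirna_col, gene_col) %in% colnames(tab)))
    stop("target map ", path, " needs columns '", mirna_col, "' and '",
         gene_col, "'")
  TargetMap(as.character(tab[[mirna_col]]), as.character(tab[[gene_col]]))
}

#' Read a PPI edge list and compute gene degrees
#'
#' Reads a STRING-style TSV with columns `protein1`, `protein2`,
#' `combined_score`, keeps edges with `combined_score` strictly greater
#' than `min_score`, drops self-loops and counts each undirected edge
#' once. The degree of a gene is its number of distinct retained
#' neighbors; genes never seen in a retained edge have implicit degree 0.
#'
#' @param path path to the TSV.
#' @param min_score score threshold; edges must exceed it (default 150).
#' @return a [PPIDegrees-class].
#' @export
readPPI <- function(path, min_score = 150) {
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% colnames(tab)))
    stop("PPI file ", path, " needs columns: ",
         paste(need, collapse = ", "))
  ppiDegreesFromEdges(tab, min_score = min_score)
}

#' Compute score-filtered PPI degrees from an edge data.frame
#'
#' @param edges data.frame with columns `protein1`, `protein2`,
#'   `combined_score`.
#' @param min_score strict score threshold (default 150).
#' @return a [PPIDegrees-class].
#' @export
ppiDegreesFromEdges <- function(edges, min_score = 150) {
  keep <- edges$combined_score > min_score
  e <- edges[keep & edges$protein1 != edges$protein2, , drop = FALSE]
  if (nrow(e) == 0L)
    stop("no PPI edge survives the score filter (> ", min_score,
         "); maximum degree undefined")
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(e$protein1),
               to = as.character(e$protein2)),
    directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  deg <- igraph::degree(g)
  PPIDegrees(deg[order(names(deg))])
}

.writeTSV <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write all result tables of an influence analysis
#'
#' Writes, into `out_dir`:
#' \describe{
#'   \item{global_influence.tsv}{rank, mirna, score, n_targets_used;
#'     descending score, ties broken by miRNA identifier.}
#'   \item{top_mirnas.tsv}{the top-k rows of the same table
#'     (plot-ready).}
#'   \item{edges.tsv}{mirna, gene, rho, mean_abs_apportioned_delta,
#'     local_influence, n_patients; sorted by mirna then gene.}
#'   \item{intervention_calls.tsv}{mirna, gene, effect,
#'     abs_local_influence, bin; sorted by mirna then gene.}
#'   \item{intervention_table.tsv}{bin, positive, negative with a Total
#'     row.}
#'   \item{de_mirna.tsv / de_gene.tsv}{feature, log2fc, p, q, direction,
#'     flagged; sorted by feature.}
#' }
#' All orderings are deterministic, so two runs on identical inputs
#' produce byte-identical files.
#'
#' @param report an [InfluenceReport-class].
#' @param out_dir output directory (created if needed).
#' @param top_k rows kept in `top_mirnas.tsv` (default 20).
#' @return invisibly, the character vector of written paths.
#' @rdname writeReport
#' @export
setMethod("writeReport", "InfluenceReport",
  function(report, out_dir, top_k = 20) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE)
    if (!dir.exists(out_dir))
      stop("cannot create output directory ", out_dir)
    paths <- c(
      .writeTSV(report@global, file.path(out_dir, "global_influence.tsv")),
      .writeTSV(head(report@global, top_k),
                file.path(out_dir, "top_mirnas.tsv")),
      .writeTSV(report@edges, file.path(out_dir, "edges.tsv")),
      .writeTSV(report@calls, file.path(out_dir, "intervention_calls.tsv")),
      .writeTSV(report@binTable,
                file.path(out_dir, "intervention_table.tsv")),
      .writeTSV(report@deMirna, file.path(out_dir, "de_mirna.tsv")),
      .writeTSV(report@deGene, file.path(out_dir, "de_gene.tsv")))
    invisible(paths)
  })
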