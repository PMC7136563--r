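#' @import methods
#' @importFrom stats cor pnorm p.adjust rnorm rnbinom runif sd t.test var setNames
#'   wilcox.test quantile
#' @importFrom utils read.delim write.table head
#' @importFrom BiocGenerics counts
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' PairedExpressionSet: raw counts with an explicit tumor/normal pairing
#'
#' A [SummarizedExperiment::SummarizedExperiment] holding a non-negative
#' `counts` assay (features x samples) whose `colData` records, for every
#' sample, the patient it came from and its condition (`"tumor"` or
#' `"normal"`). Each patient contributes exactly one tumor and one matched
#' normal sample, so per-patient expression changes are well defined.
#'
#' Validity requires: unique feature and sample identifiers, non-negative
#' finite counts, `colData` columns `patient` and `condition`, exactly one
#' tumor and one normal sample per patient, and at least 3 patients (a
#' Pearson correlation over patients is undefined below that).
#'
#' @seealso [PairedExpressionSet()], [pairing()], [rpmNormalize()]
#' @export
setClass("PairedExpressionSet", contains = "SummarizedExperiment")

.validPairedExpressionSet <- function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    if (!is.numeric(cts) || anyNA(cts) || any(!is.finite(cts)))
      msg <- c(msg, "counts must be finite numeric values")
    else if (any(cts < 0))
      msg <- c(msg, "counts must be non-negative")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "feature identifiers must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be unique")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("patient", "condition") %in% colnames(cd))) {
    msg <- c(msg, "colData must contain 'patient' and 'condition'")
  } else {
    if (!all(cd$condition %in% c("tumor", "normal")))
      msg <- c(msg, "condition must be 'tumor' or 'normal'")
    tab <- table(cd$patient, cd$condition)
    if (!all(tab == 1L) || ncol(tab) != 2L)
      msg <- c(msg, "each patient needs exactly one tumor and one normal sample")
    if (nrow(tab) < 3L)
      msg <- c(msg, "at least 3 patients are required")
  }
  if (length(msg)) msg else TRUE
}
setValidity("PairedExpressionSet", .validPairedExpressionSet)

#' TargetMap: a bipartite miRNA-to-gene target relation
#'
#' Stores the set of (miRNA, gene) interaction pairs, e.g. an
#' experimentally validated target table. The target set of miRNA i
#' and the regulator set of gene j are both derived from the same edge
#' set, so they are mutually consistent by construction.
#'
#' @slot edges data.frame with character columns `mirna` and `gene`;
#'   no duplicated pairs.
#' @seealso [TargetMap()], [targetsOf()], [regulatorsOf()]
#' @export
setClass("TargetMap", representation(edges = "data.frame"))

setValidity("TargetMap", function(object) {
  e <- object@edges
  if (!all(c("mirna", "gene") %in% colnames(e)))
    return("edges must have columns 'mirna' and 'gene'")
  if (!is.character(e$mirna) || !is.character(e$gene))
    return("edge columns must be character")
  if (anyDuplicated(e[c("mirna", "gene")]))
    return("duplicate (mirna, gene) pairs are not allowed")
  TRUE
})

#' PPIDegrees: gene degrees in a score-filtered PPI network
#'
#' Degrees of genes in an undirected protein-protein interaction network
#' after filtering edges by combined score, with self-loops and duplicate
#' edges removed. Genes absent from the network have implicit degree 0.
#' `dmax` is the maximum degree and normalizes gene importance to unit range.
#'
#' @slot degree named non-negative numeric vector of gene degrees.
#' @slot dmax positive number, the maximum degree in the network.
#' @seealso [readPPI()], [geneImportance()]
#' @export
setClass("PPIDegrees", representation(degree = "numeric", dmax = "numeric"))

setValidity("PPIDegrees", function(object) {
  d <- object@degree
  if (length(d) == 0L) return("degree table is empty")
  if (is.null(names(d)) || anyDuplicated(names(d)))
    return("degrees must be uniquely named by gene")
  if (any(d < 0)) return("degrees must be non-negative")
  if (length(object@dmax) != 1L || object@dmax <= 0)
    return("dmax must be a single positive number")
  if (abs(object@dmax - max(d)) > 1e-9)
    return("dmax must equal the maximum stored degree")
  TRUE
})

#' ApportionedDeltas: per-patient apportioned miRNA expression changes
#'
#' For each (miRNA, gene) edge under analysis, the per-patient share of
#' the miRNA's tumor-minus-normal RPM change assigned to that target
#' gene, weighted by the gene's fraction of the total absolute change
#' over the miRNA's effective target set.
#'
#' @slot mirna,gene character vectors, one entry per edge.
#' @slot delta numeric matrix, edges x patients.
#' @slot patients character vector of patient identifiers (columns of
#'   `delta`).
#' @seealso [apportionDelta()], [regulationRho()]
#' @export
setClass("ApportionedDeltas",
  representation(mirna = "character", gene = "character",
                 delta = "matrix", patients = "character"))

setValidity("ApportionedDeltas", function(object) {
  n <- length(object@mirna)
  if (length(object@gene) != n) return("mirna and gene lengths differ")
  if (nrow(object@delta) != n) return("delta must have one row per edge")
  if (ncol(object@delta) != length(object@patients))
    return("delta must have one column per patient")
  TRUE
})

#' InfluenceReport: the full result set of an influence analysis
#'
#' Bundles the regulation edge table (Pearson rho, mean absolute
#' apportioned delta, per-gene-normalized local influence), the ranked
#' global influence table, per-edge intervention-effect calls, the
#' binned intervention summary, and both differential-expression tables.
#'
#' @slot edges data.frame: mirna, gene, rho, mean_abs_apportioned_delta,
#'   local_influence, n_patients.
#' @slot global data.frame: rank, mirna, score, n_targets_used.
#' @slot calls data.frame: mirna, gene, effect, abs_local_influence, bin.
#' @slot binTable data.frame: bin, positive, negative (Total row last).
#' @slot deMirna,deGene data.frame: feature, log2fc, p, q, direction,
#'   flagged.
#' @slot meta list of run metadata (configuration echo, stage counts).
#' @seealso [runPipeline()], [writeReport()]
#' @export
setClass("InfluenceReport",
  representation(edges = "data.frame", global = "data.frame",
                 calls = "data.frame", binTable = "data.frame",
                 deMirna = "data.frame", deGene = "data.frame",
                 meta = "list"))
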