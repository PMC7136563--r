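# Global influence: each miRNA's absolute local influences are weighted
# by the PPI-degree importance of the target genes and summed,
#   I_i = sum_{j in G_i} | I_ij * d_j / d_max |,
# so a miRNA gains global influence both from regulating many genes and
# from regulating well-connected ones. The sum is over absolute values,
# making the score non-negative and sign-blind.

#' Gene importance from PPI degree
#'
#' `d_j / d_max`; genes absent from the network return 0.
#'
#' @param ppi a [PPIDegrees-class].
#' @param genes character vector of gene identifiers.
#' @return numeric vector in \[0, 1\], named by gene.
#' @export
geneImportance <- function(ppi, genes) {
  ppiDegree(ppi, genes) / ppiMaxDegree(ppi)
}

#' Global influence scores
#'
#' Sums, per miRNA, the absolute local influences times the PPI
#' importance of the target genes. miRNAs with no edge in the table are
#' omitted; miRNAs whose every target lies outside the PPI keep score 0
#' and still appear (so "no PPI data" is distinguishable from "not
#' analyzed").
#'
#' @param edges regulation edge table from [computeRegulationEdges()].
#' @param ppi a [PPIDegrees-class].
#' @return data.frame with columns `mirna`, `score`, `n_targets_used`,
#'   sorted by miRNA identifier.
#' @export
globalInfluence <- function(edges, ppi) {
  if (nrow(edges) == 0L)
    return(data.frame(mirna = character(), score = numeric(),
                      n_targets_used = integer()))
  contrib <- abs(edges$local_influence) *
    geneImportance(ppi, edges$gene)
  score <- tapply(contrib, edges$mirna, sum)
  ntar <- tapply(edges$gene, edges$mirna, length)
  out <- data.frame(mirna = names(score),
                    score = as.numeric(score),
                    n_targets_used = as.integer(ntar),
                    row.names = NULL)
  out[order(out$mirna), , drop = FALSE]
}

#' Rank miRNAs by global influence
#'
#' Descending by score; ties broken lexicographically by miRNA
#' identifier; truncated to the top `top_k`.
#'
#' @param scores data.frame from [globalInfluence()].
#' @param top_k number of rows kept (default 20); must be positive.
#' @return data.frame with columns `rank`, `mirna`, `score`,
#'   `n_targets_used`.
#' @export
rankMirnas <- function(scores, top_k = 20) {
  if (!is.numeric(top_k) || length(top_k) != 1L || top_k <= 0)
    stop("top_k must be a positive integer")
  ord <- order(-scores$score, scores$mirna)
  out <- scores[ord, , drop = FALSE]
  out <- head(out, top_k)
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}
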