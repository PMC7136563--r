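# Intervention-effect logic. "Intervention" means restoring a miRNA
# toward its normal level. For an edge with regulation sign rho and the
# two differential-expression directions, the effect on the target gene
# is:
#   positive (alleviates the gene's abnormal expression) when the miRNA
#   promotes the gene and both are abnormal in the same direction, or
#   when it represses the gene and they are abnormal in opposite
#   directions;
#   negative (deteriorates it) in the remaining two sign patterns.
# The classification is purely qualitative; no dosage model is implied.

.BIN_LABELS <- c("[0.0,0.1)", "[0.1,0.2)", "[0.2,0.3)", "[0.3,0.4)",
                 "[0.4,0.5)", "[0.5,0.6)", "[0.6,0.7)", "[0.7,0.8)",
                 "[0.8,0.9)", "[0.9,1.0]")

.influenceBin <- function(abs_influence) {
  idx <- pmin(pmax(floor(abs_influence * 10) + 1L, 1L), 10L)
  .BIN_LABELS[idx]
}

#' Classify the intervention effect of a regulation edge
#'
#' @param rho_sign `"+"` or `"-"`: the sign of the edge's regulation
#'   correlation.
#' @param mirna_dir,gene_dir `"over"` or `"under"`: the
#'   differential-expression directions of the miRNA and the gene.
#' @return `"positive"` or `"negative"`; vectorized over all arguments.
#'   The function is total over the 8 sign patterns, symmetric under
#'   flipping both directions and antisymmetric under flipping
#'   `rho_sign`.
#' @examples
#' classifyIntervention("+", "over", "over")   # positive
#' classifyIntervention("-", "over", "under")  # positive
#' classifyIntervention("+", "over", "under")  # negative
#' @export
classifyIntervention <- function(rho_sign, mirna_dir, gene_dir) {
  if (!all(rho_sign %in% c("+", "-")))
    stop("rho_sign must be '+' or '-'")
  if (!all(c(mirna_dir, gene_dir) %in% c("over", "under")))
    stop("directions must be 'over' or 'under'")
  same <- mirna_dir == gene_dir
  ifelse((rho_sign == "+") == same, "positive", "negative")
}

#' Per-edge intervention calls
#'
#' Joins the regulation edge table with the two differential-expression
#' tables and classifies every edge. An edge is `undefined` when its
#' correlation is 0 or when either endpoint is not a flagged
#' differentially expressed feature (its abnormal direction is then not
#' established).
#'
#' @param edges regulation edge table from [computeRegulationEdges()].
#' @param de_mirna,de_gene data.frames from [callDifferential()].
#' @return data.frame with columns `mirna`, `gene`, `effect`
#'   (`positive`/`negative`/`undefined`), `abs_local_influence`, `bin`;
#'   sorted by mirna then gene.
#' @export
interventionCalls <- function(edges, de_mirna, de_gene) {
  if (nrow(edges) == 0L)
    return(data.frame(mirna = character(), gene = character(),
                      effect = character(),
                      abs_local_influence = numeric(),
                      bin = character()))
  mdir <- de_mirna$direction[match(edges$mirna, de_mirna$feature)]
  mflag <- de_mirna$flagged[match(edges$mirna, de_mirna$feature)]
  gdir <- de_gene$direction[match(edges$gene, de_gene$feature)]
  gflag <- de_gene$flagged[match(edges$gene, de_gene$feature)]
  defined <- edges$rho != 0 &
    !is.na(mflag) & mflag & !is.na(gflag) & gflag
  effect <- rep("undefined", nrow(edges))
  if (any(defined))
    effect[defined] <- classifyIntervention(
      ifelse(edges$rho[defined] > 0, "+", "-"),
      mdir[defined], gdir[defined])
  absI <- abs(edges$local_influence)
  out <- data.frame(mirna = edges$mirna, gene = edges$gene,
                    effect = effect, abs_local_influence = absI,
                    bin = .influenceBin(absI))
  out <- out[order(out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Binned intervention summary for the top miRNAs
#'
#' Counts positive and negative intervention calls per absolute local
#' influence bin (width 0.1; left-closed, the last bin closed), for
#' edges whose miRNA is among the top `n_top` of the ranking. Undefined
#' calls are excluded with a message reporting their count. Bins are
#' listed from strongest (\[0.9, 1.0\]) to weakest, followed by a
#' `Total` row.
#'
#' @param calls data.frame from [interventionCalls()].
#' @param top_mirnas character vector of miRNAs in rank order (e.g.
#'   `rankMirnas(...)$mirna`).
#' @param n_top number of top miRNAs summarized (default 5).
#' @return data.frame with columns `bin`, `positive`, `negative`.
#' @export
interventionTable <- function(calls, top_mirnas, n_top = 5) {
  top <- head(top_mirnas, n_top)
  sub <- calls[calls$mirna %in% top, , drop = FALSE]
  n_undef <- sum(sub$effect == "undefined")
  if (n_undef > 0L)
    message(n_undef, " undefined call(s) excluded from the summary")
  sub <- sub[sub$effect != "undefined", , drop = FALSE]
  lev <- rev(.BIN_LABELS)
  pos <- table(factor(sub$bin[sub$effect == "positive"], levels = lev))
  neg <- table(factor(sub$bin[sub$effect == "negative"], levels = lev))
  out <- data.frame(bin = lev, positive = as.integer(pos),
                    negative = as.integer(neg))
  rbind(out, data.frame(bin = "Total",
                        positive = sum(out$positive),
                        negative = sum(out$negative)))
}
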