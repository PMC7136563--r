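# Core of the method: per-patient tumor-minus-normal deltas, the
# apportionment of each miRNA's delta over its target genes, the Pearson
# correlation giving each regulation's sign, and the per-gene-normalized
# local influence strength.
#
# For miRNA i with effective target set G_i and gene j in G_i, patient p:
#   w_ij(p)     = |dg_j(p)| / sum_{j' in G_i} |dg_j'(p)|   (0 if the sum is 0)
#   dr_ij(p)    = w_ij(p) * dr_i(p)
#   rho_ij      = Pearson( dr_ij(.), dg_j(.) ) over patients
#   I_ij        = rho_ij*|mean_p dr_ij(p)| / sum_{i' in R_j} |rho_i'j * mean_p dr_i'j(p)|
# so for every gene with an informative regulator set, sum_i |I_ij| = 1,
# and sign(I_ij) = sign(rho_ij). The proportionality constant linking the
# correlation to the underlying regulatory slope is the same for all
# pairs and cancels in the per-gene normalization, so it is never exposed.

#' Per-patient tumor-minus-normal expression changes
#'
#' `delta[f, p] = rpm[f, tumor_p] - rpm[f, normal_p]` for every pairing
#' triple p.
#'
#' @param x a normalized expression matrix (features x samples) or a
#'   [PairedExpressionSet-class] (its RPM assay is used, computed on the
#'   fly if absent).
#' @param pairing data.frame with columns `tumor_sample`,
#'   `normal_sample`, `patient` (taken from the object when `x` is a
#'   `PairedExpressionSet`).
#' @param ... unused.
#' @return numeric matrix, features x patients, columns named by
#'   patient.
#' @rdname pairedDeltas
#' @export
setMethod("pairedDeltas", "matrix", function(x, pairing, ...) {
  miss <- setdiff(c(pairing$tumor_sample, pairing$normal_sample),
                  colnames(x))
  if (length(miss))
    stop("pairing references samples missing from the matrix: ",
         paste(miss, collapse = ", "))
  d <- x[, pairing$tumor_sample, drop = FALSE] -
    x[, pairing$normal_sample, drop = FALSE]
  colnames(d) <- pairing$patient
  d
})

#' @rdname pairedDeltas
#' @export
setMethod("pairedDeltas", "PairedExpressionSet", function(x, ...) {
  pairedDeltas(rpm(x), pairing(x))
})

#' Apportion each miRNA's delta over its target genes
#'
#' For every target-map edge whose miRNA is a row of `delta_mirna` and
#' whose gene is a row of `delta_gene` (other pairs are skipped with a
#' message), assigns to gene j the share of the miRNA's change equal to
#' the gene's fraction of the total absolute change over the miRNA's
#' effective target set. With `mode = "per_patient"` (default) the
#' weights are recomputed in every patient; with `"cohort_mean"` one
#' weight per gene is computed from the patient-mean absolute gene
#' deltas, in which case the weight is a positive constant over patients
#' and the downstream correlation reduces to the plain Pearson
#' correlation of miRNA and gene deltas. A patient (or cohort) in which
#' all of a miRNA's targets are unchanged gets weight 0.
#'
#' Both matrices are first restricted to their shared patients.
#'
#' @param delta_mirna,delta_gene matrices from [pairedDeltas()].
#' @param targets a [TargetMap-class] (already restricted to the edges
#'   under analysis, e.g. differentially expressed features when
#'   gating).
#' @param mode `"per_patient"` or `"cohort_mean"`.
#' @return an [ApportionedDeltas-class].
#' @export
apportionDelta <- function(delta_mirna, delta_gene, targets,
                           mode = c("per_patient", "cohort_mean")) {
  mode <- match.arg(mode)
  pts <- intersect(colnames(delta_mirna), colnames(delta_gene))
  if (length(pts) == 0L)
    stop("the miRNA and gene delta matrices share no patients")
  dm <- delta_mirna[, pts, drop = FALSE]
  dg <- delta_gene[, pts, drop = FALSE]
  ed <- targetEdges(targets)
  present <- ed$mirna %in% rownames(dm) & ed$gene %in% rownames(dg)
  if (any(!present))
    message("skipping ", sum(!present),
            " target-map edge(s) with features absent from the ",
            "expression data")
  ed <- ed[present, , drop = FALSE]
  ed <- ed[order(ed$mirna, ed$gene), , drop = FALSE]
  delta <- matrix(0, nrow(ed), length(pts),
                  dimnames = list(NULL, pts))
  if (nrow(ed)) {
    for (m in unique(ed$mirna)) {
      idx <- which(ed$mirna == m)
      gi <- ed$gene[idx]
      A <- abs(dg[gi, , drop = FALSE])
      if (mode == "per_patient") {
        den <- colSums(A)
        W <- sweep(A, 2L, ifelse(den > 0, den, 1), "/")
        W[, den == 0] <- 0
      } else {
        wbar <- rowMeans(A)
        s <- sum(wbar)
        W <- matrix(if (s > 0) wbar / s else 0,
                    length(gi), length(pts))
      }
      delta[idx, ] <- W * matrix(dm[m, ], length(gi), length(pts),
                                 byrow = TRUE)
    }
  }
  new("ApportionedDeltas", mirna = ed$mirna, gene = ed$gene,
      delta = delta, patients = pts)
}

#' @describeIn apportionDelta patient-mean absolute apportioned delta
#'   per edge, `|mean_p dr_ij(p)|`.
#' @param app an [ApportionedDeltas-class].
#' @export
meanAbsDelta <- function(app) {
  if (nrow(app@delta) == 0L) return(numeric())
  abs(rowMeans(app@delta))
}

#' Regulation sign: Pearson correlation of apportioned deltas
#'
#' For every edge, the Pearson correlation across patients between the
#' apportioned miRNA delta and the target gene's delta. A positive
#' correlation is read as up-regulation, negative as repression. An edge
#' where either vector has zero variance gets rho = 0 (uninformative),
#' with a message reporting the count.
#'
#' @param app an [ApportionedDeltas-class].
#' @param delta_gene the gene delta matrix used to build `app`.
#' @return numeric vector of correlations in \[-1, 1\], one per edge.
#' @export
regulationRho <- function(app, delta_gene) {
  n <- length(app@mirna)
  if (n == 0L) return(numeric())
  if (length(app@patients) < 3L)
    stop("at least 3 patients are required for the correlation")
  dg <- delta_gene[, app@patients, drop = FALSE]
  rho <- numeric(n)
  degenerate <- 0L
  for (e in seq_len(n)) {
    xv <- app@delta[e, ]
    yv <- dg[app@gene[e], ]
    if (sd(xv) == 0 || sd(yv) == 0) {
      rho[e] <- 0
      degenerate <- degenerate + 1L
    } else {
      rho[e] <- cor(xv, yv)
    }
  }
  if (degenerate > 0L)
    message(degenerate, " zero-variance edge(s) set to rho = 0")
  rho
}

#' Per-gene-normalized local influence strengths
#'
#' For each gene j, `I_ij = rho_ij * |mean dr_ij| / sum_i' |rho_i'j *
#' mean dr_i'j|` over the gene's regulators, so the absolute local
#' influences on every informative gene sum to 1 and each influence
#' carries the sign of its correlation. A gene whose denominator is 0
#' (no informative regulator) has all its influences set to 0.
#'
#' @param edges data.frame with columns `mirna`, `gene`, `rho`,
#'   `mean_abs_apportioned_delta` (and optionally `n_patients`).
#' @return the same data.frame with a `local_influence` column added,
#'   sorted by mirna then gene.
#' @export
localInfluence <- function(edges) {
  edges <- edges[order(edges$mirna, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  if (nrow(edges) == 0L) {
    edges$local_influence <- numeric()
    return(edges)
  }
  s <- edges$rho * edges$mean_abs_apportioned_delta
  den <- stats::ave(abs(s), edges$gene, FUN = sum)
  edges$local_influence <- ifelse(den > 0, s / den, 0)
  edges
}

#' Full regulation edge table
#'
#' Runs apportionment, correlation and local-influence normalization in
#' one call.
#'
#' @inheritParams apportionDelta
#' @return data.frame with columns `mirna`, `gene`, `rho`,
#'   `mean_abs_apportioned_delta`, `local_influence`, `n_patients`.
#' @export
computeRegulationEdges <- function(delta_mirna, delta_gene, targets,
                                   mode = c("per_patient",
                                            "cohort_mean")) {
  app <- apportionDelta(delta_mirna, delta_gene, targets, mode)
  ed <- data.frame(mirna = app@mirna, gene = app@gene,
                   rho = regulationRho(app, delta_gene),
                   mean_abs_apportioned_delta = meanAbsDelta(app),
                   n_patients = rep(length(app@patients),
                                    length(app@mirna)))
  ed <- localInfluence(ed)
  ed[c("mirna", "gene", "rho", "mean_abs_apportioned_delta",
       "local_influence", "n_patients")]
}

#' Distribution of regulation-sign correlations
#'
#' Bins the edge correlations into width-0.1 bins over \[-1, 1\] and
#' counts edges above `threshold` and below `-threshold`.
#'
#' @param rho numeric vector of edge correlations (or a data.frame with
#'   a `rho` column).
#' @param threshold default 0.3.
#' @return list with `bins` (data.frame `lower`, `upper`, `count`; 20
#'   left-closed bins, last bin closed), `n_positive` (rho > threshold)
#'   and `n_negative` (rho < -threshold).
#' @export
rhoDistribution <- function(rho, threshold = 0.3) {
  if (is.data.frame(rho)) rho <- rho$rho
  breaks <- round(seq(-1, 1, by = 0.1), 1)
  idx <- pmin(pmax(floor((rho + 1) * 10) + 1L, 1L), 20L)
  counts <- tabulate(idx, nbins = 20L)
  list(
    bins = data.frame(lower = breaks[-21L], upper = breaks[-1L],
                      count = counts),
    n_positive = sum(rho > threshold),
    n_negative = sum(rho < -threshold))
}
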