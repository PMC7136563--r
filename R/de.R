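# Differential expression between tumor and matched normal samples.
# The default test is a negative-binomial Wald test on raw counts with a
# log library-size offset and a per-feature method-of-moments dispersion
# (floored at 1e-8); paired Wilcoxon and paired t alternatives operate
# on per-patient RPM differences. p-values are Benjamini-Hochberg
# adjusted and features with q below alpha are flagged.

.rowVars <- function(m) {
  n <- ncol(m)
  if (n < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1L)
}

# Method-of-moments NB dispersion per feature, estimated within each
# group on size-factor-normalized counts and averaged; alpha such that
# var = mu + alpha * mu^2. Floored at 1e-8 (near-Poisson), capped at 100.
.momDispersion <- function(counts, grp) {
  libs <- colSums(counts)
  sf <- libs / mean(libs)
  sf[sf == 0] <- 1
  yn <- sweep(counts, 2L, sf, "/")
  est <- sapply(c(0, 1), function(g) {
    sub <- yn[, grp == g, drop = FALSE]
    m <- rowMeans(sub)
    v <- .rowVars(sub)
    a <- (v - m) / m^2
    a[!is.finite(a)] <- NA_real_
    a
  })
  alpha <- rowMeans(est, na.rm = TRUE)
  alpha[!is.finite(alpha)] <- 1e-8
  pmin(pmax(alpha, 1e-8), 100)
}

# Vectorized IRLS fit of log(mu) = b0 + b1*group + log(libsize) for all
# features at once (NB with fixed per-feature dispersion), returning the
# two-sided Wald p-value for the group coefficient.
.nbWald <- function(counts, grp) {
  nf <- nrow(counts)
  ns <- ncol(counts)
  libs <- colSums(counts)
  off <- log(pmax(libs, 1))
  offm <- matrix(off, nf, ns, byrow = TRUE)
  alpha <- .momDispersion(counts, grp)
  b0 <- log(pmax(rowSums(counts), 0.5) / sum(exp(off)))
  b1 <- numeric(nf)
  gm <- matrix(grp, nf, ns, byrow = TRUE)
  for (it in seq_len(60L)) {
    eta <- b0 + b1 * gm + offm
    mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
    W <- mu / (1 + alpha * mu)
    Z <- (eta - offm) + (counts - mu) / mu
    s11 <- rowSums(W)
    s12 <- as.vector(W %*% grp)
    t1 <- rowSums(W * Z)
    t2 <- as.vector((W * Z) %*% grp)
    det <- s12 * (s11 - s12)
    ok <- is.finite(det) & det > 1e-12
    nb0 <- ifelse(ok, (t1 - t2) / (s11 - s12), b0)
    nb1 <- ifelse(ok, (s11 * t2 - s12 * t1) / det, 0)
    nb0 <- pmin(pmax(nb0, -50), 50)
    nb1 <- pmin(pmax(nb1, -50), 50)
    delta <- max(abs(nb0 - b0), abs(nb1 - b1))
    b0 <- nb0
    b1 <- nb1
    if (delta < 1e-10) break
  }
  eta <- b0 + b1 * gm + offm
  mu <- pmin(pmax(exp(eta), 1e-10), 1e12)
  W <- mu / (1 + alpha * mu)
  s11 <- rowSums(W)
  s12 <- as.vector(W %*% grp)
  det <- s12 * (s11 - s12)
  se <- sqrt(ifelse(det > 1e-12, s11 / det, Inf))
  z <- b1 / se
  p <- 2 * pnorm(-abs(z))
  p[!is.finite(p)] <- 1
  p[rowSums(counts) == 0] <- 1
  p
}

.pairedTestP <- function(diffs, test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  apply(diffs, 1L, function(d) {
    if (all(d == 0) || sd(d) == 0) return(1)
    p <- tryCatch(
      if (test == "wilcoxon")
        suppressWarnings(wilcox.test(d, exact = FALSE)$p.value)
      else t.test(d)$p.value,
      error = function(e) 1)
    if (is.finite(p)) p else 1
  })
}

#' Call differential expression between tumor and matched normal
#'
#' Per feature, tests tumor vs normal with the chosen method, adjusts
#' p-values by Benjamini-Hochberg and flags features with `q < alpha`.
#' The fold-change direction is taken from the sign of the mean
#' tumor-minus-normal RPM difference for every method (`over` when the
#' pseudocounted log2 fold change is positive, `under` otherwise, so a
#' tie resolves to `under`). A feature with zero variance under the
#' paired tests gets p = 1.
#'
#' @param x a [PairedExpressionSet-class].
#' @param alpha FDR threshold in \[0, 1\] (default 0.05).
#' @param method `"nb_wald"` (default; negative-binomial Wald test on
#'   counts with library-size offsets), `"paired_wilcoxon"` or
#'   `"paired_t"` (on per-patient RPM differences).
#' @return data.frame with columns `feature`, `log2fc`, `p`, `q`,
#'   `direction`, `flagged`, in the feature order of `x`.
#' @export
callDifferential <- function(x, alpha = 0.05,
                             method = c("nb_wald", "paired_wilcoxon",
                                        "paired_t")) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must be a single value in [0, 1]")
  prs <- pairing(x)
  cts <- counts(x)
  rpmm <- rpm(x)
  mt <- rowMeans(rpmm[, prs$tumor_sample, drop = FALSE])
  mn <- rowMeans(rpmm[, prs$normal_sample, drop = FALSE])
  log2fc <- log2((mt + 0.5) / (mn + 0.5))
  p <- switch(method,
    nb_wald = {
      ord <- c(prs$tumor_sample, prs$normal_sample)
      grp <- rep(c(1, 0), each = nrow(prs))
      .nbWald(cts[, ord, drop = FALSE], grp)
    },
    paired_wilcoxon = .pairedTestP(
      rpmm[, prs$tumor_sample, drop = FALSE] -
        rpmm[, prs$normal_sample, drop = FALSE], "wilcoxon"),
    paired_t = .pairedTestP(
      rpmm[, prs$tumor_sample, drop = FALSE] -
        rpmm[, prs$normal_sample, drop = FALSE], "t"))
  q <- p.adjust(p, method = "BH")
  data.frame(
    feature = rownames(cts),
    log2fc = log2fc,
    p = p,
    q = q,
    direction = ifelse(log2fc > 0, "over", "under"),
    flagged = q < alpha,
    row.names = NULL)
}

#' Count flagged differentially expressed miRNAs and genes
#'
#' @param results_mirna,results_gene data.frames from
#'   [callDifferential()].
#' @return named integer vector `c(n_demir, n_deg)`.
#' @export
deCounts <- function(results_mirna, results_gene) {
  c(n_demir = sum(results_mirna$flagged),
    n_deg = sum(results_gene$flagged))
}
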