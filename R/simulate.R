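# Seeded generator of paired tumor/normal miRNA + gene count datasets
# with a planted signed regulation network, a matching target map, a
# STRING-style PPI edge list and full ground truth.
#
# Generative model (per patient): every miRNA has a standard-normal
# latent z; its tumor-minus-normal latent delta is d = shift + a*z,
# where the shift is nonzero for planted (differentially expressed)
# miRNAs. Each planted gene responds to exactly one regulator with the
# planted sign; its latent is built from the regulator's z with a target
# latent correlation, plus independent noise, plus its own DE shift.
# The delta is injected symmetrically into the negative-binomial count
# means (tumor b + d/2, normal b - d/2), which keeps both means well
# away from zero even for strongly down-shifted features, so the
# tumor-minus-normal count difference is an unbiased, untruncated
# realization of d. Counting noise with variance
#   nu = 2b + alpha*(2b^2 + s^2/2 + a^2/2)
# (both sides together, evaluated at the planted shift magnitude s)
# attenuates the delta correlation by lambda = a / sqrt(a^2 + nu), so
# the latent correlation is pre-compensated by 1/lambda^2 to make the
# observed delta correlation land on effect_rho; the residual
# discretization error is small relative to the +-0.05 calibration
# tolerance. Restricting planted genes to a single regulator is what
# makes a per-edge population correlation as high as 0.8 attainable (a
# gene driven by k independent regulators can correlate with each at
# most 1/sqrt(k) of the shared slope). Non-planted ("decoy") target-map
# edges are statistically independent pairs, giving the null background
# and multi-regulator genes.

#' Simulation configuration
#'
#' Validates and returns the parameter list for
#' [simulateRegulation()]. Defaults describe a cohort of the scale the
#' method is meant for: 50 tumor/normal pairs, 100 miRNAs, 400 genes, 80
#' planted signed regulations plus as many null target-map edges,
#' per-edge population correlation 0.8, balanced positive/negative
#' signs, NB counts around 1000 with dispersion 0.02.
#'
#' @param n_patients number of tumor/normal pairs (>= 3).
#' @param n_mirnas,n_genes numbers of features.
#' @param n_edges planted signed regulations; at most `n_genes` (each
#'   planted gene has exactly one planted regulator).
#' @param effect_rho target population correlation of tumor-minus-normal
#'   deltas per planted edge, in (-1, 1) and nonzero when edges are
#'   planted.
#' @param frac_positive fraction of planted edges with positive sign.
#' @param baseline_mean NB mean of every feature in normal samples.
#' @param dispersion NB dispersion alpha (var = mu + alpha mu^2).
#' @param n_decoy_edges extra target-map edges with no planted effect
#'   (default `n_edges`).
#' @param shift_frac DE shift of planted features, as a fraction of
#'   `baseline_mean` (default 0.6; random sign per feature).
#' @param delta_sd_frac SD of the latent per-patient delta as a fraction
#'   of `baseline_mean` (default 0.5).
#' @param hub_spec optional list describing a planted hub miRNA:
#'   `n_hub_targets` strong-effect targets for miRNA 1 whose genes get
#'   `degree_boost` extra PPI neighbors, while every background miRNA
#'   gets `background_targets` (default 2) targets with population
#'   correlation `background_rho` (default 0.4) on low-degree genes.
#' @param seed integer seed; the simulation is fully reproducible from
#'   it.
#' @return a validated list of class `mirinf_simconfig`.
#' @export
simulationConfig <- function(n_patients = 50, n_mirnas = 100,
                             n_genes = 400, n_edges = 80,
                             effect_rho = 0.8, frac_positive = 0.5,
                             baseline_mean = 1000, dispersion = 0.02,
                             n_decoy_edges = n_edges, shift_frac = 0.6,
                             delta_sd_frac = 0.5, hub_spec = NULL,
                             seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (n_patients < 3) stop("n_patients must be at least 3")
  if (n_edges > n_genes)
    stop("n_edges must not exceed n_genes (one planted regulator per gene)")
  if (n_edges > n_mirnas * n_genes)
    stop("n_edges exceeds the number of possible pairs")
  if (abs(effect_rho) >= 1) stop("effect_rho must lie in (-1, 1)")
  if (effect_rho == 0 && n_edges > 0)
    stop("effect_rho = 0 is infeasible when edges are planted")
  if (frac_positive < 0 || frac_positive > 1)
    stop("frac_positive must lie in [0, 1]")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (!is.null(hub_spec)) {
    hub_spec <- utils::modifyList(
      list(n_hub_targets = 20, degree_boost = 30,
           background_targets = 2, background_rho = 0.4), hub_spec)
    if (hub_spec$n_hub_targets +
        (n_mirnas - 1) * hub_spec$background_targets > n_genes)
      stop("hub configuration needs more genes than available")
  }
  cfg <- list(n_patients = n_patients, n_mirnas = n_mirnas,
              n_genes = n_genes, n_edges = n_edges,
              effect_rho = effect_rho, frac_positive = frac_positive,
              baseline_mean = baseline_mean, dispersion = dispersion,
              n_decoy_edges = n_decoy_edges, shift_frac = shift_frac,
              delta_sd_frac = delta_sd_frac, hub_spec = hub_spec,
              seed = as.integer(seed))
  class(cfg) <- "mirinf_simconfig"
  cfg
}

# attenuation of the delta correlation by NB counting noise on both
# sides of a planted (DE-shifted) feature; a = latent delta SD, b =
# baseline mean, s = DE shift magnitude, alpha = NB dispersion
.nbAttenuation <- function(a, b, s, alpha) {
  nu <- 2 * b + alpha * (2 * b^2 + s^2 / 2 + a^2 / 2)
  a / sqrt(a^2 + nu)
}

.latentRho <- function(target, lambda2) {
  need <- abs(target) / lambda2
  if (need > 0.995)
    stop("effect_rho = ", target, " is unattainable at this ",
         "baseline_mean/dispersion (required latent correlation ",
         round(need, 3), " > 0.995)")
  sign(target) * need
}

#' Simulate a paired cohort with a planted regulation network
#'
#' @param config a list from [simulationConfig()].
#' @return list with elements `mirna` and `gene`
#'   ([PairedExpressionSet-class]s sharing the same patients), `targets`
#'   (a [TargetMap-class] of planted plus decoy edges), `ppi`
#'   (data.frame `protein1`, `protein2`, `combined_score`) and `truth`
#'   (list: `edge_signs` data.frame `mirna`, `gene`, `sign`;
#'   `de_mirnas`; `de_genes`; `mirna_dir`; `gene_dir`; `hub_mirna`).
#' @export
simulateRegulation <- function(config) {
  stopifnot(inherits(config, "mirinf_simconfig"))
  set.seed(config$seed)
  P <- config$n_patients
  M <- config$n_mirnas
  G <- config$n_genes
  b <- config$baseline_mean
  disp <- config$dispersion
  a <- config$delta_sd_frac * b
  lam2 <- .nbAttenuation(a, b, config$shift_frac * b, disp)^2
  mirnas <- sprintf("mir-%03d", seq_len(M))
  genes <- sprintf("gene-%04d", seq_len(G))
  patients <- sprintf("P%03d", seq_len(P))

  # planted edges: each planted gene has exactly one planted regulator
  if (is.null(config$hub_spec)) {
    n_edges <- config$n_edges
    e_gene <- if (n_edges) sample(G, n_edges) else integer()
    e_mirna <- if (n_edges) sample(M, n_edges, replace = TRUE) else integer()
    e_rho <- rep(abs(config$effect_rho), n_edges)
    hub <- NA_character_
  } else {
    hs <- config$hub_spec
    hub_gene <- seq_len(hs$n_hub_targets)
    bg_gene <- hs$n_hub_targets +
      seq_len((M - 1) * hs$background_targets)
    e_gene <- c(hub_gene, bg_gene)
    e_mirna <- c(rep(1L, hs$n_hub_targets),
                 rep(2:M, each = hs$background_targets))
    e_rho <- c(rep(abs(config$effect_rho), hs$n_hub_targets),
               rep(abs(hs$background_rho), length(bg_gene)))
    n_edges <- length(e_gene)
    hub <- mirnas[1L]
  }
  e_sign <- if (n_edges)
    ifelse(runif(n_edges) < config$frac_positive, 1, -1) else numeric()

  de_mir_idx <- sort(unique(e_mirna))
  de_gene_idx <- sort(e_gene)
  shift_m <- numeric(M)
  shift_m[de_mir_idx] <- sample(c(-1, 1), length(de_mir_idx),
                                replace = TRUE) * config$shift_frac * b
  shift_g <- numeric(G)
  shift_g[de_gene_idx] <- sample(c(-1, 1), length(de_gene_idx),
                                 replace = TRUE) * config$shift_frac * b

  # latent deltas
  Z <- matrix(rnorm(M * P), M, P)
  dM <- shift_m + a * Z
  EG <- matrix(rnorm(G * P), G, P)        # independent gene noise
  if (n_edges) {
    for (k in seq_len(n_edges)) {
      rl <- .latentRho(e_rho[k], lam2)
      j <- e_gene[k]
      EG[j, ] <- e_sign[k] *
        (rl * Z[e_mirna[k], ] + sqrt(1 - rl^2) * EG[j, ])
    }
  }
  dG <- shift_g + a * EG

  drawCounts <- function(d, n) {
    tum <- matrix(rnbinom(n * P, mu = pmax(as.vector(b + d / 2), 1),
                          size = 1 / disp), n, P)
    nor <- matrix(rnbinom(n * P, mu = pmax(as.vector(b - d / 2), 1),
                          size = 1 / disp), n, P)
    cbind(tum, nor)
  }
  ctsM <- drawCounts(dM, M)
  ctsG <- drawCounts(dG, G)
  tum <- paste0("T_", patients)
  nor <- paste0("N_", patients)
  dimnames(ctsM) <- list(mirnas, c(tum, nor))
  dimnames(ctsG) <- list(genes, c(tum, nor))
  prs <- data.frame(tumor_sample = tum, normal_sample = nor,
                    patient = patients)

  # target map: planted edges plus independent decoys
  edge_df <- data.frame(mirna = mirnas[e_mirna], gene = genes[e_gene],
                        stringsAsFactors = FALSE)
  n_decoy <- config$n_decoy_edges
  if (n_decoy > 0) {
    key <- paste(edge_df$mirna, edge_df$gene)
    decoys <- data.frame(mirna = character(), gene = character())
    guard <- 0L
    while (nrow(decoys) < n_decoy && guard < 50L) {
      cand <- data.frame(
        mirna = mirnas[sample(M, n_decoy, replace = TRUE)],
        gene = genes[sample(G, n_decoy, replace = TRUE)])
      cand <- cand[!paste(cand$mirna, cand$gene) %in%
                     c(key, paste(decoys$mirna, decoys$gene)), ,
                   drop = FALSE]
      decoys <- unique(rbind(decoys, cand))
      guard <- guard + 1L
    }
    edge_df <- rbind(edge_df, head(decoys, n_decoy))
  }
  targets <- TargetMap(edge_df)

  ppi <- .simulatePPI(genes, config)

  truth <- list(
    edge_signs = data.frame(mirna = mirnas[e_mirna],
                            gene = genes[e_gene],
                            sign = ifelse(e_sign > 0, "+", "-"),
                            stringsAsFactors = FALSE),
    de_mirnas = mirnas[de_mir_idx],
    de_genes = genes[de_gene_idx],
    mirna_dir = setNames(ifelse(shift_m[de_mir_idx] > 0, "over", "under"),
                         mirnas[de_mir_idx]),
    gene_dir = setNames(ifelse(shift_g[de_gene_idx] > 0, "over", "under"),
                        genes[de_gene_idx]),
    hub_mirna = hub)

  list(mirna = PairedExpressionSet(ctsM, prs),
       gene = PairedExpressionSet(ctsG, prs),
       targets = targets, ppi = ppi, truth = truth)
}

# Erdos-Renyi background (mean degree ~4) with scores above the default
# filter, a sprinkling of low-score edges that the filter removes, and
# optional extra neighbors for hub-target genes.
.simulatePPI <- function(genes, config) {
  G <- length(genes)
  n_bg <- max(G, 8L)
  p1 <- sample(G, 3L * n_bg, replace = TRUE)
  p2 <- sample(G, 3L * n_bg, replace = TRUE)
  ok <- p1 != p2
  bg <- unique(data.frame(a = pmin(p1[ok], p2[ok]),
                          b = pmax(p1[ok], p2[ok])))
  bg <- head(bg, 2L * n_bg)
  score <- sample(151:999, nrow(bg), replace = TRUE)
  low_n <- max(2L, n_bg %/% 4L)
  lp1 <- sample(G, low_n, replace = TRUE)
  lp2 <- sample(G, low_n, replace = TRUE)
  lok <- lp1 != lp2
  edges <- data.frame(
    protein1 = genes[c(bg$a, lp1[lok])],
    protein2 = genes[c(bg$b, lp2[lok])],
    combined_score = c(score, sample(10:150, sum(lok), replace = TRUE)))
  if (!is.null(config$hub_spec)) {
    hub_genes <- seq_len(config$hub_spec$n_hub_targets)
    boost <- config$hub_spec$degree_boost
    for (j in hub_genes) {
      partners <- sample(setdiff(seq_len(G), j), boost)
      edges <- rbind(edges, data.frame(
        protein1 = genes[j], protein2 = genes[partners],
        combined_score = 900L))
    }
  }
  rownames(edges) <- NULL
  edges
}

#' Simulate a simple two-group count dataset for DE testing
#'
#' Negative-binomial counts with per-feature multiplicative tumor fold
#' changes and no regulation structure; used to exercise the
#' differential-expression stage on its own.
#'
#' @param n_features,n_patients dataset shape.
#' @param fold per-feature tumor/normal fold change (recycled; default
#'   all 1, the global null).
#' @param baseline_mean,dispersion NB parameters as in
#'   [simulationConfig()].
#' @param seed integer seed.
#' @return a [PairedExpressionSet-class].
#' @export
simulateDECounts <- function(n_features = 100, n_patients = 20,
                             fold = 1, baseline_mean = 1000,
                             dispersion = 0.02, seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  set.seed(as.integer(seed))
  fold <- rep_len(fold, n_features)
  feats <- sprintf("feat-%04d", seq_len(n_features))
  patients <- sprintf("P%03d", seq_len(n_patients))
  tum <- matrix(rnbinom(n_features * n_patients,
                        mu = baseline_mean * fold,
                        size = 1 / dispersion),
                n_features, n_patients)
  nor <- matrix(rnbinom(n_features * n_patients, mu = baseline_mean,
                        size = 1 / dispersion),
                n_features, n_patients)
  cts <- cbind(tum, nor)
  dimnames(cts) <- list(feats, c(paste0("T_", patients),
                                 paste0("N_", patients)))
  PairedExpressionSet(cts, data.frame(
    tumor_sample = paste0("T_", patients),
    normal_sample = paste0("N_", patients),
    patient = patients))
}

#' Write the canonical small fixture
#'
#' Simulates a 3-miRNA, 8-gene, 10-patient cohort (seed 1 by default)
#' and writes the six input files used across the test suite:
#' `mirna_counts.tsv`, `gene_counts.tsv`, `pairing.tsv`,
#' `target_map.tsv`, `ppi.tsv` and `ground_truth.tsv`. Re-running with
#' the same seed reproduces the files byte for byte.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed (default 1).
#' @return invisibly, the named character vector of written paths.
#' @export
makeFixture <- function(out_dir, seed = 1) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- simulationConfig(n_patients = 10, n_mirnas = 3, n_genes = 8,
                          n_edges = 3, n_decoy_edges = 2,
                          effect_rho = 0.8, seed = seed)
  sim <- simulateRegulation(cfg)
  writeCounts <- function(x, path) {
    df <- data.frame(feature = rownames(counts(x)), counts(x),
                     check.names = FALSE)
    .writeTSV(df, path)
  }
  gt <- sim$truth$edge_signs
  gt$mirna_dir <- unname(sim$truth$mirna_dir[gt$mirna])
  gt$gene_dir <- unname(sim$truth$gene_dir[gt$gene])
  paths <- c(
    mirna_counts = writeCounts(sim$mirna,
                               file.path(out_dir, "mirna_counts.tsv")),
    gene_counts = writeCounts(sim$gene,
                              file.path(out_dir, "gene_counts.tsv")),
    pairing = .writeTSV(pairing(sim$mirna),
                        file.path(out_dir, "pairing.tsv")),
    target_map = .writeTSV(targetEdges(sim$targets),
                           file.path(out_dir, "target_map.tsv")),
    ppi = .writeTSV(sim$ppi, file.path(out_dir, "ppi.tsv")),
    ground_truth = .writeTSV(gt, file.path(out_dir, "ground_truth.tsv")))
  invisible(paths)
}
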