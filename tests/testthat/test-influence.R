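test_that("paired deltas are tumor minus normal per patient", {
  cts <- tinyCounts()
  prs <- tinyPairing()
  # direct numeric example on an unnormalized matrix
  m <- matrix(c(10, 4), 1, 2, dimnames = list("f", c("t", "n")))
  d <- pairedDeltas(m, data.frame(tumor_sample = "t",
                                  normal_sample = "n", patient = "P1"))
  expect_equal(d["f", "P1"], 6)

  # identical tumor/normal columns give an all-zero delta column
  m2 <- cbind(t1 = c(1, 2), n1 = c(1, 2), t2 = c(3, 4), n2 = c(5, 6))
  rownames(m2) <- c("a", "b")
  prs2 <- data.frame(tumor_sample = c("t1", "t2"),
                     normal_sample = c("n1", "n2"),
                     patient = c("P1", "P2"))
  d2 <- pairedDeltas(m2, prs2)
  expect_equal(unname(d2[, "P1"]), c(0, 0))
  expect_equal(unname(d2[, "P2"]), c(-2, -2))

  # hand-computed 3-feature, 2-patient case
  m3 <- cbind(T1 = c(10, 0, 5), N1 = c(4, 1, 5),
              T2 = c(2, 8, 1), N2 = c(6, 2, 0))
  rownames(m3) <- c("x", "y", "z")
  prs3 <- data.frame(tumor_sample = c("T1", "T2"),
                     normal_sample = c("N1", "N2"),
                     patient = c("p1", "p2"))
  expect_equal(pairedDeltas(m3, prs3),
               cbind(p1 = c(6, -1, 0), p2 = c(-4, 6, 1)),
               ignore_attr = "dimnames")
  expect_error(pairedDeltas(m3, data.frame(tumor_sample = "T9",
                                           normal_sample = "N1",
                                           patient = "p")),
               "missing")
})

test_that("apportionment splits a miRNA's delta by target-gene change", {
  # single target: the full delta goes to the one gene
  dM <- matrix(c(8, -3, 1), 1, 3,
               dimnames = list("m1", paste0("P", 1:3)))
  dG <- matrix(rnorm(3), 1, 3,
               dimnames = list("g1", paste0("P", 1:3)))
  app <- apportionDelta(dM, dG, TargetMap("m1", "g1"))
  expect_equal(unname(app@delta[1, ]), c(8, -3, 1))

  # two targets with |dg| 3 and 1, miRNA delta 8 -> 6 and 2
  dG2 <- matrix(c(3, -1), 2, 1, dimnames = list(c("gA", "gB"), "P1"))
  dM2 <- matrix(8, 1, 1, dimnames = list("m1", "P1"))
  # per-patient mode needs >=1 patient here; weights are per patient
  app2 <- apportionDelta(dM2, dG2, TargetMap(c("m1", "m1"),
                                             c("gA", "gB")))
  expect_equal(unname(app2@delta[match("gA", app2@gene), 1]), 6)
  expect_equal(unname(app2@delta[match("gB", app2@gene), 1]), 2)

  # a patient where all targets are unchanged gets weight 0
  dG3 <- cbind(P1 = c(3, -1), P2 = c(0, 0))
  rownames(dG3) <- c("gA", "gB")
  dM3 <- cbind(P1 = 8, P2 = 5)
  rownames(dM3) <- "m1"
  app3 <- apportionDelta(dM3, dG3, TargetMap(c("m1", "m1"),
                                             c("gA", "gB")))
  expect_equal(unname(app3@delta[, "P2"]), c(0, 0))

  # matches the nested-loop oracle on a random 4-patient instance
  inst <- randomInstance(3, 5, 4, seed = 21)
  for (mode in c("per_patient", "cohort_mean")) {
    app4 <- suppressMessages(
      apportionDelta(inst$dM, inst$dG, TargetMap(inst$edges), mode))
    want <- oracleApportion(inst$dM, inst$dG,
                            inst$edges[order(inst$edges$mirna,
                                             inst$edges$gene), ],
                            mode)
    expect_equal(unname(app4@delta), unname(want), tolerance = 1e-12)
  }
})

test_that("regulation rho is the Pearson correlation of delta vectors", {
  dG <- matrix(c(2, 4, 6), 1, 3,
               dimnames = list("g", paste0("P", 1:3)))
  app <- new("ApportionedDeltas", mirna = "m", gene = "g",
             delta = matrix(c(1, 2, 3), 1, 3,
                            dimnames = list(NULL, paste0("P", 1:3))),
             patients = paste0("P", 1:3))
  expect_equal(regulationRho(app, dG), 1)
  expect_equal(regulationRho(app, -dG), -1)

  set.seed(4)
  x <- rnorm(10)
  y <- rnorm(10)
  app2 <- new("ApportionedDeltas", mirna = "m", gene = "g",
              delta = matrix(x, 1, dimnames = list(NULL, paste0("P", 1:10))),
              patients = paste0("P", 1:10))
  dG2 <- matrix(y, 1, dimnames = list("g", paste0("P", 1:10)))
  expect_equal(regulationRho(app2, dG2), oraclePearson(x, y),
               tolerance = 1e-12)

  # zero variance on either side is rho = 0, not NaN
  flat <- matrix(1, 1, 10, dimnames = list("g", paste0("P", 1:10)))
  expect_message(r0 <- regulationRho(app2, flat), "zero-variance")
  expect_identical(r0, 0)
})

test_that("local influences are per-gene normalized and sign-coherent", {
  # single regulator reduces to the sign of rho
  e1 <- data.frame(mirna = "m1", gene = "g1", rho = 0.4,
                   mean_abs_apportioned_delta = 7)
  expect_equal(localInfluence(e1)$local_influence, 1)
  e1$rho <- -0.4
  expect_equal(localInfluence(e1)$local_influence, -1)

  # symmetric two-regulator split
  e2 <- data.frame(mirna = c("m1", "m2"), gene = "g",
                   rho = c(0.5, -0.5),
                   mean_abs_apportioned_delta = c(2, 2))
  expect_equal(localInfluence(e2)$local_influence, c(0.5, -0.5))

  # all-zero denominator flags the gene uninformative (all I = 0)
  e3 <- data.frame(mirna = c("m1", "m2"), gene = "g", rho = 0,
                   mean_abs_apportioned_delta = c(1, 2))
  expect_equal(localInfluence(e3)$local_influence, c(0, 0))

  # random 5-regulator instance: conservation and the direct formula
  set.seed(9)
  e4 <- data.frame(mirna = paste0("m", 1:5), gene = "g",
                   rho = runif(5, -1, 1),
                   mean_abs_apportioned_delta = rexp(5))
  out <- localInfluence(e4)
  expect_equal(sum(abs(out$local_influence)), 1, tolerance = 1e-12)
  den <- sum(abs(e4$rho * e4$mean_abs_apportioned_delta))
  expect_equal(out$local_influence,
               (e4$rho * e4$mean_abs_apportioned_delta / den)[
                 order(e4$mirna)],
               tolerance = 1e-12)
  nz <- out$local_influence != 0
  expect_equal(sign(out$local_influence[nz]), sign(out$rho[nz]))
})

test_that("cohort-mean apportionment reduces rho to the plain delta correlation", {
  inst <- randomInstance(4, 6, 8, seed = 31)
  edges <- suppressMessages(computeRegulationEdges(
    inst$dM, inst$dG, TargetMap(inst$edges), mode = "cohort_mean"))
  for (e in seq_len(nrow(edges))) {
    expect_equal(edges$rho[e],
                 cor(inst$dM[edges$mirna[e], ],
                     inst$dG[edges$gene[e], ]),
                 tolerance = 1e-12)
  }
})

test_that("rho and local influence are invariant under the transformations that preserve them", {
  inst <- randomInstance(4, 6, 9, seed = 41)
  tm <- TargetMap(inst$edges)
  base <- suppressMessages(computeRegulationEdges(inst$dM, inst$dG, tm))

  # relabeling (permuting) patients changes nothing
  perm <- sample(colnames(inst$dM))
  permuted <- suppressMessages(computeRegulationEdges(
    inst$dM[, perm], inst$dG[, perm], tm))
  expect_equal(permuted, base, tolerance = 1e-12)

  # rescaling ALL miRNAs by one positive constant changes nothing but
  # the apportioned-delta magnitudes
  for (mode in c("per_patient", "cohort_mean")) {
    b2 <- suppressMessages(computeRegulationEdges(inst$dM, inst$dG, tm,
                                                  mode))
    s2 <- suppressMessages(computeRegulationEdges(3.7 * inst$dM,
                                                  inst$dG, tm, mode))
    expect_equal(s2$rho, b2$rho, tolerance = 1e-12)
    expect_equal(s2$local_influence, b2$local_influence,
                 tolerance = 1e-12)
  }

  # rescaling ONE miRNA leaves every rho unchanged, and leaves the
  # influences of single-regulator genes unchanged
  m1 <- rownames(inst$dM)[1]
  dM2 <- inst$dM
  dM2[m1, ] <- 5 * dM2[m1, ]
  s1 <- suppressMessages(computeRegulationEdges(dM2, inst$dG, tm))
  expect_equal(s1$rho, base$rho, tolerance = 1e-12)
  solo <- names(which(table(base$gene) == 1))
  idx <- base$gene %in% solo
  expect_equal(s1$local_influence[idx], base$local_influence[idx],
               tolerance = 1e-12)
})

test_that("rho distribution bins and threshold counts are correct", {
  d <- rhoDistribution(c(0.35, -0.35), threshold = 0.3)
  expect_identical(d$n_positive, 1L)
  expect_identical(d$n_negative, 1L)
  expect_identical(sum(d$bins$count), 2L)
  expect_identical(d$bins$count[d$bins$lower == 0.3], 1L)

  e <- rhoDistribution(numeric())
  expect_identical(sum(e$bins$count), 0L)
  expect_identical(e$n_positive + e$n_negative, 0L)

  # boundary values fall in the left-closed bin; 1 stays in the last
  b <- rhoDistribution(c(-1, -0.3, 0, 0.3, 1))
  expect_identical(b$bins$count[b$bins$lower == -1], 1L)
  expect_identical(b$bins$count[b$bins$lower == 0.9], 1L)
  expect_identical(b$n_positive, 1L)  # only rho = 1 exceeds 0.3
})

test_that("planted balanced effects give balanced positive and negative rho", {
  pos <- 0
  neg <- 0
  for (s in 1:20) {
    sim <- simulateRegulation(simulationConfig(
      n_patients = 30, n_mirnas = 40, n_genes = 120, n_edges = 30,
      n_decoy_edges = 0, seed = 500 + s))
    dM <- pairedDeltas(rpmNormalize(sim$mirna))
    dG <- pairedDeltas(rpmNormalize(sim$gene))
    edges <- suppressMessages(
      computeRegulationEdges(dM, dG, sim$targets))
    d <- rhoDistribution(edges)
    pos <- pos + d$n_positive
    neg <- neg + d$n_negative
  }
  n <- pos + neg
  expect_lt(abs(pos - neg), 2 * sqrt(n))
})
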