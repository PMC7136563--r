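test_that("intervention classification follows the two qualitative rules", {
  # exhaustive truth table: promote (+) with matching abnormal
  # directions alleviates; repress (-) with opposite directions
  # alleviates; the other four patterns deteriorate
  tt <- expand.grid(rho = c("+", "-"),
                    mdir = c("over", "under"),
                    gdir = c("over", "under"),
                    stringsAsFactors = FALSE)
  want <- ifelse((tt$rho == "+") == (tt$mdir == tt$gdir),
                 "positive", "negative")
  got <- classifyIntervention(tt$rho, tt$mdir, tt$gdir)
  expect_identical(got, want)
  # the three anchor cases spelled out
  expect_identical(classifyIntervention("+", "over", "over"), "positive")
  expect_identical(classifyIntervention("-", "over", "under"), "positive")
  expect_identical(classifyIntervention("+", "over", "under"), "negative")

  # symmetric under flipping both directions
  flip <- function(d) ifelse(d == "over", "under", "over")
  expect_identical(classifyIntervention(tt$rho, flip(tt$mdir),
                                        flip(tt$gdir)), got)
  # antisymmetric under flipping the regulation sign
  expect_identical(classifyIntervention(ifelse(tt$rho == "+", "-", "+"),
                                        tt$mdir, tt$gdir),
                   ifelse(got == "positive", "negative", "positive"))
  expect_error(classifyIntervention("0", "over", "over"), "rho_sign")
})

test_that("per-edge calls handle undefined endpoints and bin correctly", {
  edges <- data.frame(
    mirna = c("m1", "m1", "m2", "m3"),
    gene = c("g1", "g2", "g1", "g3"),
    rho = c(0.8, -0.5, 0, 0.9),
    mean_abs_apportioned_delta = 1,
    local_influence = c(0.95, -0.55, 0, 1))
  de_m <- data.frame(feature = c("m1", "m2", "m3"),
                     log2fc = c(1, 1, -1), p = 0, q = 0,
                     direction = c("over", "over", "under"),
                     flagged = c(TRUE, TRUE, FALSE))
  de_g <- data.frame(feature = c("g1", "g2", "g3"),
                     log2fc = c(1, -1, 1), p = 0, q = 0,
                     direction = c("over", "under", "over"),
                     flagged = TRUE)
  calls <- interventionCalls(edges, de_m, de_g)
  get <- function(m, g) calls$effect[calls$mirna == m & calls$gene == g]
  expect_identical(get("m1", "g1"), "positive")   # + over over
  expect_identical(get("m1", "g2"), "positive")   # - over under
  expect_identical(get("m2", "g1"), "undefined")  # rho 0
  expect_identical(get("m3", "g3"), "undefined")  # miRNA not flagged
  expect_identical(calls$bin[calls$mirna == "m1" & calls$gene == "g1"],
                   "[0.9,1.0]")
})

test_that("the binned summary counts top-miRNA calls per influence bin", {
  calls <- data.frame(
    mirna = c("m1", "m1", "m2", "m2", "m9"),
    gene = paste0("g", 1:5),
    effect = c("positive", "positive", "negative", "positive",
               "positive"),
    abs_local_influence = c(0.95, 0.95, 0.55, 0.15, 0.5),
    bin = c("[0.9,1.0]", "[0.9,1.0]", "[0.5,0.6)", "[0.1,0.2)",
            "[0.5,0.6)"))
  tab <- interventionTable(calls, top_mirnas = c("m1", "m2"), n_top = 2)
  row <- function(b) tab[tab$bin == b, ]
  expect_identical(row("[0.9,1.0]")$positive, 2L)
  expect_identical(row("[0.5,0.6)")$negative, 1L)
  expect_identical(row("[0.1,0.2)")$positive, 1L)
  expect_identical(row("Total")$positive, 3L)
  expect_identical(row("Total")$negative, 1L)
  # m9 is outside the top list and must not be counted
  expect_identical(sum(tab$positive[tab$bin != "Total"]) +
                     sum(tab$negative[tab$bin != "Total"]),
                   4L)

  empty <- interventionTable(calls[0, ], character())
  expect_identical(empty$positive, rep(0L, 11))
  expect_identical(empty$bin[11], "Total")
})

test_that("bin counts match an independent recount on simulated calls", {
  sim <- simulateRegulation(simulationConfig(
    n_patients = 20, n_mirnas = 10, n_genes = 40, n_edges = 15,
    n_decoy_edges = 5, seed = 61))
  mir <- rpmNormalize(sim$mirna)
  gen <- rpmNormalize(sim$gene)
  deM <- callDifferential(mir)
  deG <- callDifferential(gen)
  edges <- suppressMessages(computeRegulationEdges(
    pairedDeltas(mir), pairedDeltas(gen), sim$targets))
  calls <- interventionCalls(edges, deM, deG)
  gi <- globalInfluence(edges, ppiDegreesFromEdges(sim$ppi))
  top <- rankMirnas(gi, 5)$mirna
  tab <- suppressMessages(interventionTable(calls, top, n_top = 5))
  # brute-force recount
  sub <- calls[calls$mirna %in% top & calls$effect != "undefined", ]
  for (r in seq_len(nrow(tab) - 1L)) {
    b <- tab$bin[r]
    expect_identical(tab$positive[r],
                     sum(sub$bin == b & sub$effect == "positive"))
    expect_identical(tab$negative[r],
                     sum(sub$bin == b & sub$effect == "negative"))
  }
  # conservation: bins sum to the number of defined top calls
  expect_identical(tab$positive[11] + tab$negative[11], nrow(sub))
})
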