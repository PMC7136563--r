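# Independent brute-force oracles, written as plain nested loops over
# the defining formulas. They share no code with the package internals
# and are deliberately unvectorized.

# Pearson correlation from the textbook sum formula.
oraclePearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Apportioned deltas: straight loop over edges and patients.
# edges: data.frame(mirna, gene). Returns matrix edges x patients.
oracleApportion <- function(dM, dG, edges, mode = "per_patient") {
  pts <- intersect(colnames(dM), colnames(dG))
  out <- matrix(0, nrow(edges), length(pts))
  for (e in seq_len(nrow(edges))) {
    m <- edges$mirna[e]
    g <- edges$gene[e]
    gi <- sort(edges$gene[edges$mirna == m])
    for (pi in seq_along(pts)) {
      p <- pts[pi]
      if (mode == "per_patient") {
        den <- 0
        for (g2 in gi) den <- den + abs(dG[g2, p])
        w <- if (den > 0) abs(dG[g, p]) / den else 0
      } else {
        den <- 0
        num <- 0
        for (g2 in gi) den <- den + mean(abs(dG[g2, pts]))
        num <- mean(abs(dG[g, pts]))
        w <- if (den > 0) num / den else 0
      }
      out[e, pi] <- w * dM[m, p]
    }
  }
  colnames(out) <- pts
  out
}

# Full edge table by the defining formulas (per-gene normalization).
oracleEdgeTable <- function(dM, dG, edges, mode = "per_patient") {
  pts <- intersect(colnames(dM), colnames(dG))
  app <- oracleApportion(dM, dG, edges, mode)
  rho <- numeric(nrow(edges))
  mad <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    x <- app[e, ]
    y <- dG[edges$gene[e], pts]
    rho[e] <- if (sd(x) == 0 || sd(y) == 0) 0 else oraclePearson(x, y)
    mad[e] <- abs(mean(x))
  }
  I <- numeric(nrow(edges))
  for (e in seq_len(nrow(edges))) {
    den <- 0
    for (e2 in which(edges$gene == edges$gene[e]))
      den <- den + abs(rho[e2] * mad[e2])
    I[e] <- if (den > 0) rho[e] * mad[e] / den else 0
  }
  data.frame(mirna = edges$mirna, gene = edges$gene, rho = rho,
             mean_abs_apportioned_delta = mad, local_influence = I)
}

# Global influence by nested loops.
oracleGlobal <- function(edge_table, degree, dmax) {
  mirnas <- sort(unique(edge_table$mirna))
  score <- numeric(length(mirnas))
  for (k in seq_along(mirnas)) {
    for (e in which(edge_table$mirna == mirnas[k])) {
      d <- degree[edge_table$gene[e]]
      if (is.na(d)) d <- 0
      score[k] <- score[k] +
        abs(edge_table$local_influence[e] * d / dmax)
    }
  }
  data.frame(mirna = mirnas, score = score)
}

# Benjamini-Hochberg step-up by the definition.
oracleBH <- function(p) {
  n <- length(p)
  ord <- order(p)
  q <- numeric(n)
  prev <- 1
  for (k in n:1) {
    val <- min(prev, p[ord[k]] * n / k)
    q[ord[k]] <- val
    prev <- val
  }
  q
}

# PPI degrees by counting distinct neighbors per node.
oracleDegrees <- function(ppi, min_score) {
  keep <- ppi$combined_score > min_score & ppi$protein1 != ppi$protein2
  e <- ppi[keep, , drop = FALSE]
  nodes <- sort(unique(c(e$protein1, e$protein2)))
  deg <- setNames(integer(length(nodes)), nodes)
  for (v in nodes) {
    nb <- unique(c(e$protein2[e$protein1 == v], e$protein1[e$protein2 == v]))
    deg[v] <- length(setdiff(nb, v))
  }
  deg
}

# Random delta matrices plus a random target map, for oracle-equivalence
# and conservation checks.
randomInstance <- function(n_mirnas, n_genes, n_patients, seed,
                           edge_prob = 0.5) {
  set.seed(seed)
  mirnas <- paste0("m", seq_len(n_mirnas))
  genes <- paste0("g", seq_len(n_genes))
  pts <- paste0("P", seq_len(n_patients))
  dM <- matrix(rnorm(n_mirnas * n_patients, sd = 5), n_mirnas,
               dimnames = list(mirnas, pts))
  dG <- matrix(rnorm(n_genes * n_patients, sd = 5), n_genes,
               dimnames = list(genes, pts))
  grid <- expand.grid(mirna = mirnas, gene = genes,
                      stringsAsFactors = FALSE)
  keep <- runif(nrow(grid)) < edge_prob
  if (!any(keep)) keep[sample(nrow(grid), 1)] <- TRUE
  list(dM = dM, dG = dG, edges = grid[keep, , drop = FALSE])
}

# Small expression fixture built in code: 2 features x 6 samples,
# 3 tumor/normal pairs.
tinyCounts <- function() {
  matrix(c(10, 20, 30, 40, 50, 60,
           5, 15, 25, 35, 45, 55), 2, 6, byrow = TRUE,
         dimnames = list(c("f1", "f2"),
                         c("t1", "t2", "t3", "n1", "n2", "n3")))
}

tinyPairing <- function() {
  data.frame(tumor_sample = c("t1", "t2", "t3"),
             normal_sample = c("n1", "n2", "n3"),
             patient = c("P1", "P2", "P3"))
}
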