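# Independent brute-force oracles used across the suite. These deliberately
# re-derive each statistic from its definition by direct loops/enumeration,
# sharing no code with the package implementation.

# Running-sum enrichment score: walk every rank position explicitly and
# keep the whole trajectory.
oracle_es_walk <- function(scores, is_hit, weight_exponent) {
  n <- length(scores)
  nh <- sum(is_hit)
  w <- abs(scores)^weight_exponent
  tot <- sum(w[is_hit])
  run <- numeric(n)
  acc <- 0
  for (i in seq_len(n)) {
    acc <- acc + if (is_hit[i]) {
      if (tot > 0) w[i] / tot else 1 / nh
    } else {
      -1 / (n - nh)
    }
    run[i] <- acc
  }
  run
}

# Compare an enrichment score against the oracle walk. The magnitude must
# match the walk's maximal absolute deviation to 1e-12; the sign must match
# the extremum's sign except when the positive and negative deviations tie
# to within float noise (the positive-preference tie-break is then allowed
# to differ between summation orders).
expect_es_matches_walk <- function(es, run) {
  hi <- max(run)
  lo <- min(run)
  want <- if (hi >= -lo) hi else lo
  expect_equal(abs(es), abs(want), tolerance = 1e-12)
  if (abs(hi + lo) > 1e-9) expect_equal(sign(es), sign(want))
}

# Step-up BH from the definition: padj_(i) = min_{j >= i} p_(j) * n / j.
oracle_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  padj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    padj_sorted[i] <- min(1, min(p[ord][i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- padj_sorted
  out
}

# Upper-tail hypergeometric by complete enumeration of all draws.
oracle_hyper_p <- function(universe, annotation, draws, observed_overlap) {
  all_draws <- utils::combn(universe, draws, simplify = FALSE)
  hits <- vapply(all_draws, function(d) {
    length(intersect(d, annotation)) >= observed_overlap
  }, logical(1))
  mean(hits)
}

# Exact two-sided Mann-Whitney by enumeration over rank assignments,
# written against the midrank formulation (independent of the package's
# pairwise-count exact branch).
oracle_mw_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_from <- function(i) sum(r[i]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  obs <- abs(u_from(seq_len(n1)) - mu)
  assigns <- utils::combn(n1 + n2, n1, simplify = FALSE)
  mean(vapply(assigns, function(i) abs(u_from(i) - mu) >= obs - 1e-9,
              logical(1)))
}

# Random ranked signature over n genes with continuous scores.
random_ranked <- function(n, seed) {
  set.seed(seed)
  rank_signature(data.frame(gene = sprintf("g%04d", seq_len(n)),
                            log2fc = stats::rnorm(n)))
}

# Default 18-marker two-population IMC scene, the study-scale panel.
imc_two_pops <- function(n1 = 120, n2 = 80, seed_means = 7) {
  set.seed(seed_means)
  mk <- c("aSMA", "CD45", "HLA-DR", "CD44", "CD8", "vimentin", "collagen1",
          "CD16", "CD163", "CD68", "CD74", "CD276", "Ki67", "VEGF",
          "arginase1", "histoneH3", "bactin", "CD8a")
  mu1 <- stats::setNames(stats::runif(length(mk), 3, 6), mk)
  mu2 <- stats::setNames(stats::runif(length(mk), 0.2, 1.5), mk)
  list(list(n_cells = n1, entity = "PVR", sample = "pvr1", means = mu1),
       list(n_cells = n2, entity = "ERM", sample = "erm1", means = mu2))
}
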