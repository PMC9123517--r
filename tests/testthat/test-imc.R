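# IMC phenotyping: percentile normalization, graph clustering, cluster
# profiles/composition and gating.

test_that("percentile normalization scales, clips and is scale-invariant", {
  m <- matrix(1:100, 100, 1, dimnames = list(NULL, "mk"))
  nm <- normalize_percentile(m)
  q99 <- quantile(1:100, 0.99, names = FALSE)
  expect_equal(unname(nm[which(m == round(q99)), 1]), round(q99) / q99,
               tolerance = 0.01)
  expect_equal(max(nm), 1)              # 100 clips to 1
  expect_true(all(nm >= 0 & nm <= 1))

  expect_equal(normalize_percentile(m * 10), nm)  # scale invariance

  z <- cbind(m, zero = 0)
  expect_warning(nz <- normalize_percentile(z), "all-zero")
  expect_true(all(nz[, "zero"] == 0))
  expect_error(normalize_percentile(m, q = 0), "q")

  # idempotent up to clipping
  expect_equal(normalize_percentile(nm), pmin(nm / quantile(nm, 0.99), 1))
})

test_that("clustering recovers planted populations deterministically", {
  sim <- simulate_cell_matrix(imc_two_pops(), noise_sd = 0.3, seed = 31)
  nm <- normalize_percentile(sim$cells)
  ca <- cluster_cells(nm, k = 15, seed = 32)
  expect_identical(max(ca$cluster), 2L)
  expect_identical(sort(unique(ca$cluster)), 1:2)
  skip_if_not_installed("mclust")
  expect_gte(mclust::adjustedRandIndex(ca$cluster, sim$truth$cell_labels),
             0.95)

  again <- cluster_cells(nm, k = 15, seed = 32)
  expect_identical(ca, again)

  expect_error(cluster_cells(nm$intensities[1:10, ], k = 15, seed = 1),
               "n > k")
})

test_that("duplicated cells are co-assigned", {
  sim <- simulate_cell_matrix(imc_two_pops(60, 60), noise_sd = 0.2,
                              seed = 33)
  nm <- normalize_percentile(sim$cells)
  dup <- rbind(nm$intensities, nm$intensities)
  ca <- cluster_cells(dup, k = 15, seed = 34)
  n <- nrow(nm$intensities)
  expect_identical(ca$cluster[seq_len(n)], ca$cluster[n + seq_len(n)])
})

test_that("cluster profiles give standardized per-marker z-scores", {
  sim <- simulate_cell_matrix(imc_two_pops(), noise_sd = 0.3, seed = 35)
  nm <- normalize_percentile(sim$cells)
  ca <- cluster_cells(nm, k = 15, seed = 36)
  prof <- cluster_profile(nm, ca)
  expect_equal(unname(colMeans(prof$z)), rep(0, ncol(prof$z)),
               tolerance = 1e-9)
  # the defining high markers of population 1 have positive z in cluster 1
  strongest <- names(which.max(prof$mean[1, ] - prof$mean[2, ]))
  expect_gt(prof$z[1, strongest], 0)

  one <- structure(list(cluster = rep(1L, nrow(nm$intensities)), k = 15,
                        seed = 1), class = "cluster_assignment")
  expect_true(all(cluster_profile(nm, one)$z == 0))
})

test_that("cluster composition counts, averages and attributes entities", {
  sim <- simulate_cell_matrix(imc_two_pops(120, 80), noise_sd = 0.3,
                              seed = 37)
  ca <- cluster_cells(normalize_percentile(sim$cells), k = 15, seed = 38)
  comp <- cluster_composition(sim$cells, ca)
  # conservation: entity column sums equal total cells per entity
  expect_equal(unname(colSums(comp$counts)[c("PVR", "ERM")]), c(120, 80))
  # pure clusters are attributed to their entity
  expect_setequal(unname(comp$attribution), c("PVR", "ERM"))

  mixed <- structure(list(cluster = rep(1L, 200), k = 15, seed = 1),
                     class = "cluster_assignment")
  m <- cluster_composition(sim$cells, mixed)
  expect_identical(unname(m$attribution), "shared")  # 60/40 at fraction 0.8
  pure <- cluster_composition(sim$cells,
                              structure(list(cluster = sim$truth$cell_labels,
                                             k = 15, seed = 1),
                                        class = "cluster_assignment"))
  expect_identical(unname(pure$attribution), c("PVR", "ERM"))
})

test_that("gating counts positives within the gate and partitions to 100%", {
  m <- cbind(aSMA = c(0.9, 0.8, 0.1, 0.95), CD45 = c(0.9, 0.1, 0.9, 0.6))
  g <- gate_coexpression(m, "aSMA", "CD45", threshold = 0.5)
  expect_identical(g$n_gated, 3L)
  expect_equal(unname(g$percent["CD45"]), 100 * 2 / 3)

  self <- gate_coexpression(m, "aSMA", "aSMA")
  expect_equal(unname(self$percent), 100)

  set.seed(39)
  rnd <- matrix(runif(300), 100, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  g <- gate_coexpression(rnd, "a", c("b", "c"))
  expect_true(all(g$percent >= 0 & g$percent <= 100))
  # positive% + negative% = 100 by construction of the partition
  neg_b <- 100 * sum(rnd[rnd[, "a"] > 0.5, "b"] <= 0.5) / g$n_gated
  expect_equal(unname(g$percent["b"]) + neg_b, 100)

  expect_error(gate_coexpression(m, "nope", "CD45"), "unknown gate")
  expect_error(gate_coexpression(m, "aSMA", "CD45", threshold = 1.2),
               "threshold")
  low <- matrix(0.1, 5, 2, dimnames = list(NULL, c("aSMA", "CD45")))
  expect_warning(e <- gate_coexpression(low, "aSMA", "CD45"), "no cell")
  expect_true(e$empty)
})

test_that("boolean co-marker combinations follow AND/OR semantics", {
  m <- cbind(aSMA = c(0.9, 0.9, 0.9, 0.9),
             CD45 = c(0.9, 0.9, 0.1, 0.1),
             `HLA-DR` = c(0.9, 0.1, 0.9, 0.1))
  g <- gate_coexpression(m, "aSMA", c("CD45&HLA-DR", "CD45|HLA-DR"))
  expect_equal(unname(g$percent["CD45&HLA-DR"]), 25)
  expect_equal(unname(g$percent["CD45|HLA-DR"]), 75)
})

test_that("zero-noise gating recovers planted population fractions exactly", {
  pops <- list(
    list(n_cells = 72, means = c(aSMA = 1, CD45 = 1)),   # aSMA+CD45+
    list(n_cells = 28, means = c(aSMA = 1, CD45 = 0)),   # aSMA+CD45-
    list(n_cells = 50, means = c(aSMA = 0, CD45 = 1)))   # aSMA-
  sim <- simulate_cell_matrix(pops, noise_sd = 0, seed = 40)
  nm <- normalize_percentile(sim$cells)
  g <- gate_coexpression(nm, "aSMA", "CD45", threshold = 0.5)
  expect_identical(g$n_gated, 100L)
  expect_equal(unname(g$percent["CD45"]), 72)
})
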