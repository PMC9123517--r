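# The weighted running-sum enrichment statistic, its permutation
# calibration, and drug ranking.

test_that("enrichment score reproduces hand-computed walks", {
  rs <- rank_signature(data.frame(gene = c("g1", "g2", "g3", "g4"),
                                  log2fc = c(4, 3, 2, 1)))
  expect_equal(enrichment_score(rs, "g1", weight_exponent = 0)$es, 1)
  expect_equal(enrichment_score(rs, "g4", weight_exponent = 0)$es, -1)
  es <- enrichment_score(rs, c("g1", "g3"), weight_exponent = 1)
  expect_equal(es$es, 2 / 3, tolerance = 1e-12)
  expect_identical(es$leading_edge, "g1")

  expect_error(enrichment_score(rs, "nope"), "no member")
  expect_error(enrichment_score(rs, rs$gene), "entire ranking")
})

test_that("enrichment score matches the brute-force oracle", {
  set.seed(10)
  for (i in 1:200) {
    n <- sample(5:50, 1)
    rs <- random_ranked(n, seed = 1000 + i)
    members <- sample(rs$gene, sample(seq_len(n - 1), 1))
    p <- sample(c(0, 1), 1)
    got <- enrichment_score(rs, members, weight_exponent = p)
    expect_es_matches_walk(got$es, oracle_es_walk(rs$score,
                                                  rs$gene %in% members, p))
  }
})

test_that("running sum is consistent with the extremum and ends at zero", {
  set.seed(11)
  rs <- random_ranked(40, seed = 12)
  members <- sample(rs$gene, 8)
  got <- enrichment_score(rs, members, keep_running_sum = TRUE)
  expect_equal(max(abs(got$running_sum)), abs(got$es), tolerance = 1e-12)
  expect_equal(got$running_sum[40], 0, tolerance = 1e-12)
})

test_that("unweighted statistic equals the two-sample KS distance", {
  set.seed(12)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    rs <- random_ranked(n, seed = 2000 + i)
    members <- sample(rs$gene, sample(2:(n - 2), 1))
    hits <- which(rs$gene %in% members)
    ks <- suppressWarnings(
      stats::ks.test(hits, setdiff(seq_len(n), hits))$statistic)
    es <- enrichment_score(rs, members, weight_exponent = 0)$es
    expect_equal(abs(es), unname(ks), tolerance = 1e-10)
  }
})

test_that("weighted scores agree with an independent GSEA implementation", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  for (i in 1:20) {
    n <- sample(20:60, 1)
    rs <- random_ranked(n, seed = 3000 + i)
    members <- sample(rs$gene, sample(3:10, 1))
    mine <- enrichment_score(rs, members, weight_exponent = 1)$es
    ref <- fgsea::calcGseaStat(setNames(rs$score, rs$gene),
                               selectedStats = which(rs$gene %in% members),
                               gseaParam = 1)
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("the score depends only on ordering and membership pattern", {
  rs <- random_ranked(30, seed = 14)
  members <- rs$gene[c(2, 9, 15)]
  base <- enrichment_score(rs, members)$es
  # uniform rescaling cancels in the normalized hit weights (p = 1) and is
  # irrelevant when p = 0
  rs2 <- rank_signature(data.frame(gene = rs$gene, log2fc = rs$score * 5))
  expect_equal(enrichment_score(rs2, members)$es, base, tolerance = 1e-12)
  expect_equal(enrichment_score(rs2, members, weight_exponent = 0)$es,
               enrichment_score(rs, members, weight_exponent = 0)$es,
               tolerance = 1e-12)
  # renaming genes while preserving order and membership leaves es unchanged
  rs3 <- data.frame(gene = sprintf("x%04d", seq_len(30)),
                    log2fc = sort(rs$score, decreasing = TRUE))
  rs3 <- rank_signature(rs3)
  members3 <- rs3$gene[which(rs$gene %in% members)]
  expect_equal(enrichment_score(rs3, members3)$es, base, tolerance = 1e-12)
})

test_that("permutation null is seeded and symmetric on random rankings", {
  rs <- random_ranked(100, seed = 15)
  expect_length(permutation_null(rs, 10, n_perm = 1, seed = 1), 1)
  expect_identical(permutation_null(rs, 10, n_perm = 50, seed = 2),
                   permutation_null(rs, 10, n_perm = 50, seed = 2))
  expect_error(permutation_null(rs, 0, seed = 1), "set_size")
  expect_error(permutation_null(rs, 100, seed = 1), "set_size")

  big <- random_ranked(2000, seed = 16)
  null <- permutation_null(big, 30, n_perm = 2000, seed = 3)
  expect_gt(mean(null > 0), 0.4)
  expect_lt(mean(null > 0), 0.6)
})

test_that("drug scoring honors sign convention, p floor and set handling", {
  rs <- random_ranked(200, seed = 17)
  bottom <- drug_profile("bottom",
                         down_genes = gene_set("bottom", tail(rs$gene, 15)))
  res <- score_drug(rs, bottom, n_perm = 200, seed = 4)
  expect_lt(res$es, 0)
  expect_gte(res$p, 1 / 201)

  top <- drug_profile("top", down_genes = gene_set("top", head(rs$gene, 15)))
  res <- score_drug(rs, top, n_perm = 200, seed = 4)
  expect_gt(res$nes, 1)
  expect_lt(res$p, 0.05)
  # genes absent from the ranking are dropped; set_size records intersection
  padded <- drug_profile("pad", down_genes = gene_set("pad",
                           c(head(rs$gene, 15), "absent1", "absent2")))
  expect_identical(score_drug(rs, padded, n_perm = 50, seed = 5)$set_size,
                   15L)

  alien <- drug_profile("alien", down_genes = gene_set("alien", "nowhere"))
  expect_warning(res <- score_drug(rs, alien, n_perm = 50, seed = 6),
                 "unscorable")
  expect_false(res$scorable)
})

test_that("batch scoring with shared nulls matches single-drug scoring", {
  rs <- random_ranked(300, seed = 18)
  drugs <- lapply(1:4, function(i) {
    set.seed(40 + i)
    drug_profile(paste0("d", i),
                 down_genes = gene_set(paste0("d", i), sample(rs$gene, 20)))
  })
  batch <- score_drugs(rs, drugs, n_perm = 300, seed = 7)
  shared_null <- permutation_null(rs, 20, n_perm = 300, seed = 7)
  for (i in seq_along(drugs)) {
    single <- score_drug(rs, drugs[[i]], seed = 7, null_es = shared_null)
    expect_equal(batch[[i]]$es, single$es)
    expect_equal(batch[[i]]$nes, single$nes)
    expect_equal(batch[[i]]$p, single$p)
  }
})

test_that("drug ranking reproduces the published candidate order", {
  # NES values reported for the four best-fitting agents; ranking by NES
  # descending must reproduce their order
  mk <- function(name, nes, p) {
    structure(list(set_name = name, es = nes / 2, nes = nes, p = p,
                   padj = NA_real_, set_size = 30,
                   leading_edge = character(0), scorable = TRUE),
              class = "enrichment_result")
  }
  res <- list(mk("doxorubicin", 1.31, 0.002), mk("aminocaproic acid", 1.58,
                                                 1e-4),
              mk("etoposide", 1.27, 0.003), mk("mitoxantrone", 1.37, 0.001))
  tab <- rank_drugs(res)
  expect_identical(tab$drug, c("aminocaproic acid", "mitoxantrone",
                               "doxorubicin", "etoposide"))
  expect_true(all(diff(tab$nes) <= 0))
  expect_true(all(tab$padj >= tab$p))

  single <- rank_drugs(res[2])
  expect_equal(single$padj, single$p)

  tied <- list(mk("zeta", 1.5, 0.02), mk("alpha", 1.5, 0.02),
               mk("beta", 1.5, 0.001))
  expect_identical(rank_drugs(tied)$drug, c("beta", "alpha", "zeta"))
  expect_error(rank_drugs(list()), "no scorable")
})
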