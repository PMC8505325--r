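test_that("cosine similarity is exact, symmetric and scale invariant", {
  u <- c(1, 2, 3); v <- c(0, 0, 0, 1)
  expect_equal(cosine_similarity(u, u), 1.0)
  expect_equal(cosine_similarity(c(1, 0, 0), c(0, 1, 1)), 0.0)
  expect_equal(cosine_similarity(u, rev(u)), cosine_similarity(rev(u), u))
  expect_equal(cosine_similarity(u, 100 * u), 1.0)
  expect_error(cosine_similarity(u, c(0, 0, 0)), "zero vector")
})

test_that("rank-1 KL-NMF lands on its analytic fixed point", {
  set.seed(5)
  mat <- matrix(rpois(96 * 6, 8), 96, 6,
                dimnames = list(sbs96_channels(), sprintf("S%d", 1:6)))
  res <- extract_signatures_nmf(mat, rank_range = 1, n_restarts = 3,
                                seed = 1)
  expect_equal(res$rank, 1)
  expect_equal(unname(res$signatures[, 1]),
               unname(rowSums(mat) / sum(mat)), tolerance = 1e-4)
  expect_equal(unname(res$exposures[, 1]), unname(colSums(mat)),
               tolerance = 1e-3)
})

test_that("NNLS attribution recovers pure and mixed loadings", {
  sigs <- fixture_signature_catalog()[, 1:3]
  pure <- attribute_exposures_nnls(sigs[, 1] * 100, sigs)
  expect_equal(unname(pure$exposures), c(100, 0, 0), tolerance = 1e-8)
  expect_gt(pure$reconstruction_cosine, 0.999999)

  set.seed(8)
  w <- c(4000, 3000, 3000)
  mixed <- attribute_exposures_nnls(as.numeric(sigs %*% w), sigs)
  expect_lt(sum(abs(mixed$exposures - w)) / sum(w), 1e-8)

  zero <- attribute_exposures_nnls(rep(0, 96), sigs)
  expect_equal(unname(zero$exposures), c(0, 0, 0))
})

test_that("reference matching is greedy one-to-one and label-strict", {
  ref <- fixture_signature_catalog()
  m <- match_to_reference(ref, ref)
  expect_equal(m$reference, colnames(ref))
  expect_equal(m$cosine, rep(1, 4), tolerance = 1e-12)

  shuffled <- ref[sample(96), ]
  expect_error(match_to_reference(ref, shuffled), "ordered differently")
  unlabeled <- ref; rownames(unlabeled) <- NULL
  expect_error(match_to_reference(ref, unlabeled), "rownames")

  # below-threshold similarity stays unassigned but reports its best cosine
  far <- matrix(c(rep(0, 95), 1), ncol = 1,
                dimnames = list(rownames(ref), "spike"))
  m2 <- match_to_reference(far, ref[, "deamination", drop = FALSE],
                           min_cosine = 0.99)
  expect_true(is.na(m2$reference))
  expect_false(is.na(m2$cosine))
})

test_that("planted three-signature cohorts are recovered with the right rank", {
  catalog <- fixture_signature_catalog()[, c("UV", "clock_flat",
                                             "deamination")]
  set.seed(21)
  # sparse mixing, as in the acceptance-scale planted cohorts
  expo <- t(sapply(1:40, function(i) {
    g <- rgamma(3, c(0.8, 0.5, 0.4)); g / sum(g)
  }))
  counts <- sapply(1:40, function(i) {
    n <- sample(200:500, 1)
    tabulate(sample(96, n, TRUE, prob = as.vector(catalog %*% expo[i, ])), 96)
  })
  rownames(counts) <- rownames(catalog)
  colnames(counts) <- sprintf("S%02d", 1:40)
  res <- extract_signatures_nmf(counts, rank_range = 2:4, n_restarts = 12,
                                seed = 5)
  expect_equal(res$rank, 3)
  m <- match_to_reference(res$signatures, catalog, min_cosine = 0.8)
  expect_setequal(m$reference, colnames(catalog))
  expect_true(all(m$cosine >= 0.9))

  # duplicating every sample changes neither rank nor signatures materially
  dup <- cbind(counts, counts)
  colnames(dup) <- sprintf("S%02d", 1:80)
  res2 <- extract_signatures_nmf(dup, rank_range = 2:4, n_restarts = 12,
                                 seed = 5)
  expect_equal(res2$rank, res$rank)
  m12 <- match_to_reference(res2$signatures, res$signatures,
                            min_cosine = 0.5)
  expect_true(all(m12$cosine >= 0.98))

  # reconstruction: signatures x exposures approximates the input
  recon <- res$signatures %*% t(res$exposures)
  expect_lt(sum(abs(recon - counts)) / sum(counts), 0.35)
  expect_error(extract_signatures_nmf(counts[, 1:3], rank_range = 5),
               "rank exceeds")
})

test_that("contribution comparisons and Bonferroni behave", {
  set.seed(9)
  expos <- matrix(rexp(40 * 3, 1 / 100), 40, 3,
                  dimnames = list(sprintf("S%02d", 1:40),
                                  c("sigA", "sigB", "sigC")))
  g <- rep(c("high", "low"), each = 20)
  # identical groups: all adjusted p = 1
  same <- rbind(expos[1:20, ], expos[1:20, ])
  res0 <- compare_signature_contributions(same, g)
  expect_true(all(res0$p_adj == 1))

  # one signature strongly shifted: flagged alone at alpha 0.05
  shifted <- expos
  shifted[g == "high", "sigB"] <- shifted[g == "high", "sigB"] + 2000
  res1 <- compare_signature_contributions(shifted, g)
  expect_lt(res1$p_adj[res1$feature == "sigB"], 0.05)
  expect_true(all(res1$p_adj >= res1$p))

  # summed-signature mode
  res2 <- compare_signature_contributions(
    shifted, g, sum_signatures = list("sigB/C" = c("sigB", "sigC")))
  expect_true("sigB/C" %in% res2$feature)
})

test_that("exposure co-occurrence matches the hypergeometric oracle", {
  # perfectly exclusive presence across 20 samples
  expos <- matrix(0, 20, 2, dimnames = list(sprintf("S%02d", 1:20),
                                            c("uv", "clock")))
  expos[1:10, "uv"] <- 100
  expos[11:20, "clock"] <- 100
  res <- exposure_cooccurrence(expos, "uv", "clock")
  expect_lt(res$odds_ratio, 1)
  # oracle: P(no overlap) enumerated from the hypergeometric tail
  expect_equal(res$p, fisher.test(matrix(c(0, 10, 10, 0), 2))$p.value)
  expect_false(res$degenerate)

  both <- matrix(100, 20, 2, dimnames = dimnames(expos))
  res2 <- exposure_cooccurrence(both, "uv", "clock")
  expect_true(res2$degenerate)
  expect_true(is.finite(res2$odds_ratio))
})
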