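make_expr <- function(gzma, prf1, extra = NULL) {
  m <- rbind(GZMA = gzma, PRF1 = prf1)
  if (!is.null(extra)) m <- rbind(m, extra)
  colnames(m) <- sprintf("S%02d", seq_len(ncol(m)))
  m
}

test_that("CYT is the geometric mean of GZMA and PRF1", {
  m <- make_expr(c(4, 7, 7), c(9, 7, 7))
  cyt <- compute_cyt(m, pseudocount = 0)
  expect_equal(cyt$CYT[1], 6.0)            # sqrt(4 * 9)
  expect_equal(cyt$CYT[2:3], c(7, 7))      # geometric mean idempotence
  # frozen value from direct arithmetic: sqrt((12.3+0.01)*(45.6+0.01))
  m2 <- make_expr(c(12.3, 1), c(45.6, 1))
  expect_equal(compute_cyt(m2, pseudocount = 0.01)$CYT[1],
               23.69512819, tolerance = 1e-8)
  expect_error(compute_cyt(m[-1, , drop = FALSE]), "GZMA")
})

test_that("CYT is scale-equivariant and AM-GM bounded", {
  set.seed(42)
  g <- rexp(30, 1 / 20); p <- rexp(30, 1 / 15)
  m <- make_expr(g, p)
  base <- compute_cyt(m, pseudocount = 0)$CYT
  scaled <- compute_cyt(m * 3.7, pseudocount = 0)$CYT
  expect_equal(scaled, base * 3.7)
  expect_true(all(base <= (g + p) / 2 + 1e-12))
})

test_that("quartile stratification matches the stated extreme-group rule", {
  cyt <- data.frame(sample = sprintf("S%02d", 1:8), CYT = 1:8)
  out <- stratify_quartiles(cyt)
  expect_equal(out$group[7:8], c("high", "high"))
  expect_equal(out$group[1:2], c("low", "low"))
  expect_equal(out$group[3:6], rep("mid", 4))

  # all ties: everything lands mid
  tie <- data.frame(sample = sprintf("S%02d", 1:8), CYT = rep(5, 8))
  expect_equal(unique(stratify_quartiles(tie)$group), "mid")

  # tiny stratum skipped with warning
  expect_warning(
    out2 <- stratify_quartiles(
      data.frame(sample = sprintf("S%02d", 1:10), CYT = 1:10),
      strata = c(rep("a", 8), "b", "b")),
    "fewer than 4")
  expect_true(all(is.na(out2$group[9:10])))
})

test_that("stratification partitions every cohort and ignores sample order", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(c(20, 100, 101), 1)
    cyt <- data.frame(sample = sprintf("S%03d", 1:n),
                      CYT = rexp(n, 1 / 10))
    out <- stratify_quartiles(cyt)
    expect_equal(sum(table(out$group)), n)
    expect_false(any(is.na(out$group)))
    perm <- sample.int(n)
    out_p <- stratify_quartiles(cyt[perm, ])
    expect_equal(out_p$group, out$group[perm])
    if (n %% 4 == 0) {   # tie-free: extreme groups are exactly n/4 each
      expect_equal(as.integer(table(out$group)[c("high", "low")]),
                   c(n / 4, n / 4))
    }
  }
})

test_that("coexpression_rho hits the exact extremes", {
  m <- make_expr(1:10, (1:10)^2)   # monotone transform: rho 1
  expect_equal(coexpression_rho(m)$rho, 1)
  m2 <- make_expr(1:10, 10:1)
  expect_equal(coexpression_rho(m2)$rho, -1)
})

test_that("signature scores are mean per-gene z-scores", {
  m <- matrix(5, nrow = 3, ncol = 4,
              dimnames = list(c("A", "B", "C"), sprintf("S%d", 1:4)))
  expect_warning(sc <- signature_score(m, c("A", "B")), "zero-variance")
  expect_equal(unname(sc), rep(0, 4), ignore_attr = TRUE)

  set.seed(7)
  m2 <- matrix(rexp(40), nrow = 4,
               dimnames = list(c("A", "B", "C", "D"), sprintf("S%d", 1:10)))
  one <- signature_score(m2, "B")
  expect_equal(unname(one),
               unname((m2["B", ] - mean(m2["B", ])) / sd(m2["B", ])),
               ignore_attr = TRUE)
  # direct recomputation oracle for a multi-gene set
  z <- t(apply(m2[c("A", "C"), ], 1, function(x) (x - mean(x)) / sd(x)))
  expect_equal(unname(signature_score(m2, c("A", "C"))),
               unname(colMeans(z)), ignore_attr = TRUE)
  expect_equal(attr(signature_score(m2, c("A", "C", "ZZZ")) |>
                      suppressWarnings(), "n_genes"), 2)
})

test_that("group comparison reproduces exact Mann-Whitney and adjustment fixtures", {
  # U = 0 separation: exact two-sided p = 2/20
  res <- compare_groups(c(1, 2, 3, 4, 5, 6),
                        c("a", "a", "a", "b", "b", "b"))
  expect_equal(res$p, 0.1)
  expect_equal(unname(res$statistic), 0)

  # identical groups: p = 1
  res2 <- compare_groups(rep(c(5, 7, 9), 2), rep(c("a", "b"), each = 3))
  expect_equal(res2$p, 1)

  # BH on (0.01, 0.02, 0.03) -> all 0.03; Bonferroni caps at 1
  vals <- matrix(rnorm(30), nrow = 3)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  g <- rep(c("a", "b"), c(5, 5))
  res3 <- compare_groups(vals, g, correction = "bonferroni")
  expect_true(all(res3$p_adj >= res3$p))
  expect_true(all(res3$p_adj <= 1))
})

test_that("the two published immune gene panels are intact", {
  expect_length(ifng_signature_genes(), 6)
  expect_length(expanded_immune_genes(), 18)
  expect_true(all(c("IFNG", "STAT1") %in% ifng_signature_genes()))
})
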