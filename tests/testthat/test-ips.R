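test_that("sample-wise z-scores follow the documented sd convention", {
  m <- matrix(c(1, 3), nrow = 1, dimnames = list("G", c("s1", "s2")))
  # sample sd of (1,3) is sqrt(2): z = -/+ 1/sqrt(2)
  z <- samplewise_zscores(m)
  expect_equal(unname(z[1, ]), c(-1, 1) / sqrt(2))
  zp <- samplewise_zscores(m, sd_type = "population")
  expect_equal(unname(zp[1, ]), c(-1, 1))

  const <- matrix(5, 1, 4, dimnames = list("G", sprintf("s%d", 1:4)))
  expect_warning(zc <- samplewise_zscores(const), "zero-variance")
  expect_true(all(zc == 0))

  set.seed(2)
  m2 <- matrix(rexp(20), 2, 10,
               dimnames = list(c("A", "B"), sprintf("s%d", 1:10)))
  expect_equal(samplewise_zscores(m2 + 100), samplewise_zscores(m2))
})

test_that("category scores are weighted factor means", {
  w <- default_ips_weights()
  genes <- unique(w$gene)
  z <- matrix(0, length(genes), 3, dimnames = list(genes, c("a", "b", "c")))
  cs0 <- category_scores(z, w)
  expect_true(all(cs0 == 0))

  # single-gene single-factor category equals that gene's z
  w1 <- data.frame(gene = "X", factor = "fx", category = "MHC", weight = 1)
  z1 <- matrix(c(-1, 0, 2), 1, dimnames = list("X", c("a", "b", "c")))
  expect_equal(unname(category_scores(z1, w1)[, "MHC"]), c(-1, 0, 2))

  # direct recomputation oracle on a random fixture
  set.seed(6)
  zr <- matrix(rnorm(length(genes) * 5), length(genes), 5,
               dimnames = list(genes, sprintf("s%d", 1:5)))
  got <- category_scores(zr, w)
  for (cat in c("MHC", "CP", "EC", "SC")) {
    wc <- w[w$category == cat, ]
    fs <- sapply(unique(wc$factor), function(f) {
      wf <- wc[wc$factor == f, ]
      colSums(zr[wf$gene, , drop = FALSE] * wf$weight) / sum(abs(wf$weight))
    })
    expect_equal(unname(got[, cat]), unname(rowMeans(fs)))
  }
})

test_that("IPS scaling saturates at 0 and 10 and is linear between", {
  cs <- matrix(0, 5, 4, dimnames = list(sprintf("s%d", 1:5),
                                        c("MHC", "CP", "EC", "SC")))
  cs[1, ] <- c(0, 0, 0, 0)        # AZ = 0   -> 0
  cs[2, ] <- c(2, 1, 0.5, -0.5)   # AZ = 3   -> 10
  cs[3, ] <- c(1, 0.25, 0.25, 0)  # AZ = 1.5 -> 5
  cs[4, ] <- c(-1, 0, 0, 0)       # AZ < 0   -> 0
  cs[5, ] <- c(4, 1, 1, 0)        # AZ > 3   -> 10
  ips <- ips_score(cs)
  expect_equal(ips$IPS, c(0L, 10L, 5L, 0L, 10L))
  expect_equal(ips$AZ, unname(rowSums(cs)))
})

test_that("cohort IPS stays in 0..10 and responds to suppressor load", {
  cfg <- cohort_config(n_samples = 60, seed = 19)
  expr <- generate_expression(cfg)
  ips <- compute_ips(expr)
  expect_true(all(ips$IPS %in% 0:10))

  # raising suppressor-cell genes lowers the score (negative SC weights)
  w <- default_ips_weights()
  sc_genes <- w$gene[w$category == "SC"]
  tpm2 <- expr$tpm
  tpm2[sc_genes, 1:30] <- tpm2[sc_genes, 1:30] * 50
  ips2 <- compute_ips(tpm2)
  expect_lt(mean(ips2$AZ[1:30]), mean(ips2$AZ[31:60]))

  # planted AZ shift separates groups
  groups <- setNames(rep(c("high", "low"), each = 30), ips$sample)
  shifted <- ips
  shifted$IPS <- pmin(10L, shifted$IPS + ifelse(groups == "high", 3L, 0L))
  cmp <- compare_ips(shifted, groups)
  expect_equal(cmp$direction, "high")
  expect_lt(cmp$comparison$p, 0.01)
})

test_that("the shipped weight fixture round-trips and validates", {
  path <- system.file("extdata", "ips_weights_synthetic.tsv",
                      package = "melanomics")
  expect_true(nzchar(path))
  w <- read_ips_weights(path)
  expect_equal(w, default_ips_weights(), ignore_attr = TRUE)
  bad <- w
  bad$category[1] <- "XX"
  tf <- tempfile(fileext = ".tsv")
  write.table(bad, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_ips_weights(tf), "unknown IPS categories")
})
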