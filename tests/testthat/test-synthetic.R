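test_that("fixed seed gives byte-identical cohorts", {
  cfg <- cohort_config(n_samples = 10, mean_mutations = 40, seed = 11)
  a <- suppressWarnings(generate_cohort(cfg))
  b <- suppressWarnings(generate_cohort(cfg))
  expect_identical(a$expression$tpm, b$expression$tpm)
  expect_identical(a$mutations, b$mutations)
  expect_identical(a$segments, b$segments)
  expect_identical(a$clinical, b$clinical)
})

test_that("expression generator hits the target GZMA/PRF1 rank correlation", {
  # perfect dependence: identical ranks
  cfg1 <- cohort_config(n_samples = 50, cyt_rho = 1, seed = 3)
  e1 <- generate_expression(cfg1)
  expect_equal(rank(e1$tpm["GZMA", ]), rank(e1$tpm["PRF1", ]))
  expect_equal(coexpression_rho(e1)$rho, 1.0)

  # the study's rho ~ 0.9 at n = 200
  cfg2 <- cohort_config(n_samples = 200, cyt_rho = 0.9, seed = 1)
  rho <- coexpression_rho(generate_expression(cfg2))$rho
  expect_gt(rho, 0.85)
  expect_lt(rho, 0.95)

  cfg3 <- cohort_config(n_samples = 4, seed = 5)
  expect_equal(ncol(generate_expression(cfg3)$tpm), 4)
  expect_true(all(c("GZMA", "PRF1", ifng_signature_genes()) %in%
                    rownames(generate_expression(cfg3)$tpm)))
})

test_that("mutation generator reproduces a pure signature's channel mixture", {
  catalog <- fixture_signature_catalog()
  expo <- matrix(0, nrow = 4, ncol = 4,
                 dimnames = list(NULL, colnames(catalog)))
  expo[, "UV"] <- 1
  cfg <- cohort_config(n_samples = 4, mean_mutations = 5000,
                       exposure_matrix = expo, mean_dbs = 0, seed = 9)
  muts <- generate_mutations(cfg, catalog)
  m <- build_sbs96_matrix(muts)
  freq <- rowSums(m) / sum(m)
  expect_lt(sum(abs(freq - catalog[, "UV"])), 0.05)
})

test_that("kataegis injection is verbatim and background spacing is respected", {
  ks <- data.frame(sample = "S0001", chrom = "chr1", start = 1e6,
                   n_mutations = 8, spacing = 500)
  cfg <- cohort_config(n_samples = 4, mean_mutations = 50,
                       kataegis_spec = ks, mean_dbs = 0, seed = 2)
  muts <- generate_mutations(cfg)
  inj <- muts[muts$kataegis, ]
  expect_equal(sort(inj$Start_Position), 1e6 + (0:7) * 500)
  bg <- muts[!muts$kataegis, ]
  for (k in unique(paste(bg$Tumor_Sample_Barcode, bg$Chromosome))) {
    idx <- paste(bg$Tumor_Sample_Barcode, bg$Chromosome) == k
    p <- sort(bg$Start_Position[idx])
    if (length(p) > 1) expect_true(all(diff(p) > 1e4))
  }
  expect_error(cohort_config(n_samples = 4,
                             kataegis_spec = data.frame(
                               sample = "S0001", chrom = "chr1", start = 1,
                               n_mutations = 5, spacing = 100)),
               ">= 6")
})

test_that("doublets can be disabled and zero-exposure rows error", {
  cfg <- cohort_config(n_samples = 4, mean_mutations = 200, mean_dbs = 0,
                       seed = 4)
  muts <- generate_mutations(cfg)
  expect_equal(sum(build_dbs78_matrix(muts)), 0)

  expo <- matrix(0, 4, 4, dimnames = list(sprintf("S%04d", 1:4),
                                          colnames(fixture_signature_catalog())))
  expo[1:3, "UV"] <- 1
  cfg2 <- cohort_config(n_samples = 4, exposure_matrix = expo, seed = 4)
  expect_error(generate_mutations(cfg2), "summing to 0")
})

test_that("segment generator plants oscillations and quiet backgrounds", {
  ct <- data.frame(sample = "S0002", chrom = "chr9", n_oscillations = 25,
                   amplitude = 0.5)
  cfg <- cohort_config(n_samples = 4, chromothripsis_spec = ct, seed = 6)
  segs <- generate_segments(cfg)
  osc <- segs[segs$ID == "S0002" & segs$chrom == "chr9", ]
  steps <- abs(diff(osc$seg.mean))
  expect_gte(sum(steps >= 0.5), 25)
  expect_true(all(osc$loc.end - osc$loc.start + 1 >= 1e4))

  bg <- segs[!(segs$ID == "S0002" & segs$chrom == "chr9"), ]
  expect_true(all(abs(bg$seg.mean) < 0.3))
  counts <- table(paste(bg$ID, bg$chrom))
  expect_true(all(counts <= 4))  # at most 3 change points

  expect_error(cohort_config(n_samples = 4,
                             chromothripsis_spec = data.frame(
                               sample = "S0001", chrom = "chr1",
                               n_oscillations = 25, amplitude = 0.2)),
               ">= 0.3")
})

test_that("survival generator respects group hazards and censoring", {
  cfg <- cohort_config(n_samples = 400, seed = 8,
                       survival_hazards = c(high = 1 / 3000, low = 1 / 1000),
                       censor_hazard = 0)
  groups <- rep(c("high", "low"), each = 200)
  surv <- generate_survival(cfg, groups)
  expect_true(all(surv$event == 1))
  expect_gt(median(surv$time[surv$group == "high"]),
            median(surv$time[surv$group == "low"]))
  expect_error(generate_survival(cfg, rep("unknown", 400)), "absent")
})
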