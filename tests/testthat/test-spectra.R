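test_that("SBS-96 matrix counts, conserves and strand-collapses", {
  empty <- make_muts("S1", "chr1", numeric(0))
  m0 <- build_sbs96_matrix(empty)
  expect_equal(sum(m0), 0)

  one <- make_muts("S1", "chr1", 100, ref = "C", alt = "T", context = "ACG")
  m1 <- build_sbs96_matrix(one)
  expect_equal(m1["A[C>T]G", "S1"], 1L)
  expect_equal(sum(m1), 1)

  # reverse-complementing every record leaves the matrix bit-identical
  set.seed(3)
  ch <- sample(sbs96_channels(), 60, replace = TRUE)
  muts <- make_muts("S1", "chr1", seq(1e5, by = 2e4, length.out = 60),
                    ref = substr(ch, 3, 3), alt = substr(ch, 5, 5),
                    context = paste0(substr(ch, 1, 1), substr(ch, 3, 3),
                                     substr(ch, 7, 7)))
  rc <- muts
  comp <- function(x) chartr("ACGT", "TGCA", x)
  rc$Reference_Allele <- comp(muts$Reference_Allele)
  rc$Tumor_Seq_Allele2 <- comp(muts$Tumor_Seq_Allele2)
  rc$trinucleotide_context <- vapply(strsplit(comp(muts$trinucleotide_context),
                                              ""),
                                     function(x) paste(rev(x), collapse = ""),
                                     character(1))
  expect_identical(build_sbs96_matrix(muts), build_sbs96_matrix(rc))
  # column sums conserve the SNV count
  expect_equal(sum(build_sbs96_matrix(muts)), nrow(muts))
})

test_that("adjacent substitutions become doublets, triplets are excluded", {
  muts <- rbind(
    make_muts("S1", "chr1", c(100, 101), ref = c("C", "C"),
              alt = c("T", "T"), context = c("ACC", "CCA")),
    make_muts("S1", "chr1", c(5000, 20000)),                # isolated SNVs
    make_muts("S1", "chr2", c(300, 301, 302))               # triplet run
  )
  parts <- extract_doublets(muts)
  expect_equal(nrow(parts$dbs), 1)
  expect_equal(parts$dbs$ref2, "CC")
  expect_equal(parts$dbs$alt2, "TT")
  expect_equal(nrow(parts$snv), 2)
  expect_equal(unname(parts$excluded["excluded_multi"]), 3)

  sbs <- build_sbs96_matrix(muts)
  dbs <- build_dbs78_matrix(muts)
  expect_equal(sum(sbs), 2)                  # doublet not double-counted
  expect_equal(dbs["CC>TT", "S1"], 1L)
  # SNVs + 2 x DBS + excluded = raw records
  expect_equal(sum(sbs) + 2 * sum(dbs) +
                 unname(parts$excluded["excluded_multi"]), nrow(muts))
})

test_that("substitution spectrum fractions are well formed", {
  ch <- c("A[C>T]G", "T[C>T]C", "A[T>A]T", "C[C>G]G")
  muts <- make_muts("S1", "chr1", c(1e5, 2e5, 3e5, 4e5),
                    ref = substr(ch, 3, 3), alt = substr(ch, 5, 5),
                    context = paste0(substr(ch, 1, 1), substr(ch, 3, 3),
                                     substr(ch, 7, 7)))
  spec <- substitution_spectrum(muts)
  expect_equal(sum(spec$fractions[, "S1"]), 1)
  expect_equal(spec$fractions["C>T", "S1"], 0.5)

  all_ct <- make_muts("S2", "chr1", seq(1e5, by = 2e4, length.out = 10))
  s2 <- substitution_spectrum(all_ct)
  expect_equal(unname(s2$fractions[, "S2"]), c(0, 0, 1, 0, 0, 0))
})

test_that("a planted 89% C>T mixture is recovered at depth", {
  cfg <- cohort_config(n_samples = 4, mean_mutations = 2500, mean_dbs = 0,
                       seed = 12)
  muts <- generate_mutations(cfg)
  spec <- substitution_spectrum(muts)
  ct <- mean(spec$fractions["C>T", ])
  planted <- sum(as.vector(
    fixture_signature_catalog() %*%
      colMeans(cfg$exposure_matrix))[substr(sbs96_channels(), 3, 5) == "C>T"])
  expect_lt(abs(ct - planted), 0.02)
})

test_that("simplified SMG test behaves like its binomial oracle", {
  genes <- data.frame(gene = c("G1", "G2", "G3"),
                      length_bp = c(1e4, 1e4, 1e4))
  # 50 samples, each with 1 mutation; G1 hit by all, G2/G3 never
  muts <- make_muts(sprintf("S%02d", 1:50), "chr1",
                    seq(1e5, by = 2e4, length.out = 50))
  muts$Hugo_Symbol <- "G1"
  res <- smg_frequency_test(muts, genes)
  expect_equal(attr(res, "method"), "simplified_frequency_test")
  g1 <- res[res$gene == "G1", ]
  # oracle: rate = 1 mutation / 0.03 Mb territory; p0 = 1 - exp(-rate * L)
  p0 <- 1 - exp(-(1 / 0.03) * 0.01)
  expect_equal(g1$expected_p0, p0, tolerance = 1e-12)
  expect_equal(g1$p, binom.test(50, 50, p0, "greater")$p.value)
  expect_true(g1$significant)
  expect_equal(res$p[res$gene %in% c("G2", "G3")], c(1, 1))
  # BH q non-decreasing in p rank
  expect_true(all(diff(res$q) >= -1e-12))
})
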