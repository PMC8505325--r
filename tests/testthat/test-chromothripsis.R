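test_that("profile simplification drops short segments and merges close ones", {
  segs <- make_segs("S1", "chr1", c(1, 1e6 + 1), c(1e6, 2e6), c(0.1, 0.25))
  m <- merge_segments(segs)
  expect_equal(nrow(m), 1)
  # length-weighted mean
  expect_equal(m$seg.mean, (0.1 + 0.25) / 2)

  short <- make_segs("S1", "chr1", c(1, 1e6 + 1), c(1e6, 1e6 + 5000),
                     c(0.1, 0.9))
  expect_equal(nrow(merge_segments(short)), 1)

  # idempotence on random profiles
  for (seed in 1:10) {
    set.seed(seed)
    n <- 30
    bounds <- sort(sample.int(1e8, n + 1))
    p <- make_segs("S1", "chr1", bounds[-(n + 1)] + 1, bounds[-1],
                   rnorm(n, 0, 0.4))
    once <- merge_segments(p)
    twice <- merge_segments(once)
    expect_equal(twice$seg.mean, once$seg.mean)
    expect_equal(twice$loc.start, once$loc.start)
    if (nrow(once) > 1) {
      expect_true(all(abs(diff(once$seg.mean)) >= 0.3))
    }
  }
})

test_that("switch counting matches the literal recount oracle", {
  flat <- make_segs("S1", "chr1", 1, 1e8, 0)
  expect_equal(count_cn_switches(merge_segments(flat))$n_switches, 0)

  n_seg <- 21
  alt <- make_segs("S1", "chr1", seq(1, by = 5e4, length.out = n_seg),
                   seq(5e4, by = 5e4, length.out = n_seg),
                   rep(c(0.5, -0.5), length.out = n_seg))
  expect_equal(count_cn_switches(merge_segments(alt))$n_switches, 20)

  for (seed in 1:10) {
    set.seed(seed)
    n <- 40
    bounds <- sort(sample.int(1e8, n + 1))
    p <- make_segs("S1", "chr1", bounds[-(n + 1)] + 1, bounds[-1],
                   rnorm(n, 0, 0.4))
    got <- count_cn_switches(merge_segments(p))
    want <- oracle_switch_count(p$loc.start, p$loc.end, p$seg.mean)
    expect_equal(if (nrow(got)) got$n_switches else 0, want)
  }
})

test_that("the Poisson likelihood ratio follows its closed form", {
  expect_equal(chromothripsis_lr(10, 1e7, 3000, 3e9), 0)  # lambda1 == lambda0
  # direct arithmetic oracle
  k <- 25; W <- 5e7; K <- 30; G <- 3e9
  l1 <- k / W; l0 <- K / G
  want <- (k * log(l1 / l0) - W * (l1 - l0)) / log(10)
  expect_equal(chromothripsis_lr(k, W, K, G), want)
  # strictly increasing in k above the background
  lrs <- sapply(20:40, chromothripsis_lr, W = W, K = K, G = G)
  expect_true(all(diff(lrs) > 0))
  expect_true(is.infinite(chromothripsis_lr(5, W, 0, G)))
  expect_equal(chromothripsis_lr(0, W, 0, G), 0)
})

test_that("planted oscillating chromosomes are called, background is not", {
  ct <- data.frame(sample = c("S0002", "S0002"), chrom = c("chr3", "chr7"),
                   n_oscillations = 25, amplitude = 0.5)
  cfg <- cohort_config(n_samples = 4, chromothripsis_spec = ct, seed = 13)
  segs <- generate_segments(cfg)
  calls <- call_chromothripsis(segs, genome = synthetic_genome())
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$chrom, c("chr3", "chr7"))
  expect_true(all(calls$sample == "S0002"))
  expect_true(all(calls$n_switches >= 20))
  expect_true(all(calls$log10_lr >= 8 | calls$lr_infinite))
  expect_true(all(calls$n_gains > 0) && all(calls$n_losses > 0))

  # record order within a sample does not matter
  calls2 <- call_chromothripsis(segs[sample(nrow(segs)), ],
                                genome = synthetic_genome())
  o <- order(calls2$chrom)
  expect_equal(calls2[o, ], calls[order(calls$chrom), ],
               ignore_attr = TRUE)

  quiet <- generate_segments(cohort_config(n_samples = 4, seed = 14))
  expect_equal(nrow(call_chromothripsis(quiet,
                                        genome = synthetic_genome())), 0)
})

test_that("gene annotation and group summaries aggregate correctly", {
  ct <- data.frame(sample = "S0001", chrom = "chr2", n_oscillations = 30,
                   amplitude = 0.6)
  cfg <- cohort_config(n_samples = 4, chromothripsis_spec = ct, seed = 15)
  segs <- generate_segments(cfg)
  genes <- data.frame(chrom = c("chr2", "chr2", "chr5"),
                      start = c(2.05e7, 2.09e7, 1e6),
                      end = c(2.06e7, 2.10e7, 2e6),
                      gene = c("ONC1", "TSG1", "FAR1"),
                      stringsAsFactors = FALSE)
  calls <- call_chromothripsis(segs, genome = synthetic_genome(),
                               gene_table = genes)
  expect_equal(nrow(calls), 1)
  hit_genes <- unlist(strsplit(c(calls$genes_gain, calls$genes_loss), ","))
  expect_true(all(c("ONC1", "TSG1") %in% hit_genes))
  expect_false("FAR1" %in% hit_genes)

  summ <- chromothripsis_group_summary(
    data.frame(sample = c("A", "B"), chrom = "chr1", start = 1, end = 2,
               n_switches = c(20, 30), log10_lr = 9, lr_infinite = FALSE,
               n_gains = 1, n_losses = 1, genes_gain = "", genes_loss = "",
               stringsAsFactors = FALSE),
    groups = c(A = "low", B = "low"))
  expect_equal(summ$mean_switches, 25)
  expect_equal(summ$sd_switches, 7.0710678, tolerance = 1e-6)
  expect_equal(nrow(chromothripsis_group_summary(
    call_chromothripsis(make_segs("S1", "chr1", 1, 1e8, 0)))), 0)
})
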