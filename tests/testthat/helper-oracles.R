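# Independent brute-force oracles and small fixture builders used across
# the suite. These deliberately re-derive results by the slowest, most
# literal route so they stay independent of the package's implementations.

# All qualifying kataegis windows by exhaustive O(n^2) enumeration, then
# leftmost-longest greedy selection. Returns a data.frame(start_idx,
# end_idx) over the sorted position vector.
oracle_kataegis <- function(pos, min_mutations = 6, max_imd = 1000) {
  pos <- sort(pos)
  n <- length(pos)
  wins <- NULL
  if (n >= min_mutations) {
    for (i in seq_len(n - min_mutations + 1)) {
      for (j in seq(i + min_mutations - 1, n)) {
        if ((pos[j] - pos[i]) / (j - i) <= max_imd) {
          wins <- rbind(wins, c(i, j))
        }
      }
    }
  }
  sel <- NULL
  while (!is.null(wins) && nrow(wins) > 0) {
    i0 <- min(wins[, 1])
    j0 <- max(wins[wins[, 1] == i0, 2])
    sel <- rbind(sel, c(i0, j0))
    keep <- wins[, 1] > j0 | wins[, 2] < i0
    wins <- wins[keep, , drop = FALSE]
  }
  if (is.null(sel)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0)))
  }
  data.frame(start_idx = sel[, 1], end_idx = sel[, 2])
}

# Literal re-implementation of the profile simplification + switch count:
# drop short segments, merge adjacent pairs below the signal distance
# (length-weighted), count remaining boundaries. One sample-chromosome.
oracle_switch_count <- function(starts, ends, means, signal_distance = 0.3,
                                min_size = 1e4) {
  keep <- (ends - starts + 1) >= min_size
  starts <- starts[keep]; ends <- ends[keep]; means <- means[keep]
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]; means <- means[o]
  repeat {
    if (length(means) < 2) break
    d <- abs(diff(means))
    i <- which(d < signal_distance)[1]
    if (is.na(i)) break
    l1 <- ends[i] - starts[i] + 1
    l2 <- ends[i + 1] - starts[i + 1] + 1
    means[i] <- (means[i] * l1 + means[i + 1] * l2) / (l1 + l2)
    ends[i] <- ends[i + 1]
    starts <- starts[-(i + 1)]; ends <- ends[-(i + 1)]
    means <- means[-(i + 1)]
  }
  max(0, length(means) - 1)
}

# Two-group log-rank O/E table computed literally from the risk sets.
oracle_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O - E)^2 / V
  list(observed = O, expected = E, chisq = chisq,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# A small fully-formed mutation table from explicit positions.
make_muts <- function(sample, chrom, pos, ref = "C", alt = "T",
                      context = "ACA", alt_count = 30, ref_count = 70) {
  n <- length(pos)
  data.frame(Tumor_Sample_Barcode = rep_len(sample, n),
             Chromosome = rep_len(chrom, n), Start_Position = pos,
             Reference_Allele = rep_len(ref, n),
             Tumor_Seq_Allele2 = rep_len(alt, n),
             ref_count = rep_len(ref_count, n),
             alt_count = rep_len(alt_count, n),
             trinucleotide_context = rep_len(context, n),
             Hugo_Symbol = rep_len("SYNG001", n),
             stringsAsFactors = FALSE)
}

make_segs <- function(id, chrom, start, end, mean, nm = 10) {
  data.frame(ID = id, chrom = chrom, loc.start = start, loc.end = end,
             num.mark = nm, seg.mean = mean, stringsAsFactors = FALSE)
}

# Random mutation table on the synthetic genome for oracle-equivalence runs;
# positions are unconstrained (no spacing guarantee) so the caller is
# exercised on arbitrary geometry.
random_muts <- function(n, n_samples = 3, n_chroms = 4, span = 5e6,
                        seed = 1) {
  set.seed(seed)
  make_muts(sample = sprintf("R%02d", sample.int(n_samples, n, TRUE)),
            chrom = paste0("chr", sample.int(n_chroms, n, TRUE)),
            pos = sort(sample.int(span, n, replace = TRUE)))
}
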