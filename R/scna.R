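# Somatic copy-number aberrations: per-segment amplification/deletion
# thresholding, per-sample burden with group comparison, and a simplified
# GISTIC-like recurrence G-score with a circular-permutation FDR.

required_seg_cols <- c("ID", "chrom", "loc.start", "loc.end", "seg.mean")

validate_seg <- function(segments) {
  missing <- setdiff(required_seg_cols, names(segments))
  if (length(missing) > 0) {
    stop("segment table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (any(segments$loc.start > segments$loc.end)) {
    stop("segment with loc.start > loc.end")
  }
  segments
}

#' Threshold segments into amplifications and deletions
#'
#' `seg.mean >= amp_cut` (default 0.6) labels an amplification,
#' `seg.mean <= del_cut` (default -0.4) a deletion, anything else neutral.
#' The asymmetric defaults are the conventional log-ratio cutoffs for
#' somatic-vs-normal segment mean changes.
#'
#' @param segments SEG-style data.frame (`ID`, `chrom`, `loc.start`,
#'   `loc.end`, `num.mark`, `seg.mean`).
#' @param amp_cut,del_cut Amplification / deletion log-ratio cutoffs.
#' @return The input with a `status` column
#'   (`amplification`/`deletion`/`neutral`).
#' @export
threshold_scna <- function(segments, amp_cut = 0.6, del_cut = -0.4) {
  validate_seg(segments)
  stopifnot(amp_cut > 0, del_cut < 0)
  segments$status <- ifelse(segments$seg.mean >= amp_cut, "amplification",
                     ifelse(segments$seg.mean <= del_cut, "deletion",
                            "neutral"))
  segments
}

#' Per-sample SCNA burden, with optional group comparison
#'
#' Counts labeled segments per sample (see [threshold_scna()]); when
#' two-level group labels are supplied, amplification, deletion and total
#' counts are each compared between groups by Mann-Whitney (BH adjusted).
#'
#' @param segments Labeled segment table (from [threshold_scna()], or raw —
#'   thresholds are applied with defaults when the `status` column is
#'   absent).
#' @param groups Optional named per-sample group labels.
#' @return List with `per_sample` (data.frame `sample`, `n_amp`, `n_del`,
#'   `n_scna`), `totals`, and optionally `comparison`.
#' @export
scna_burden <- function(segments, groups = NULL) {
  if (!"status" %in% names(segments)) segments <- threshold_scna(segments)
  samples <- sort(unique(segments$ID))
  n_amp <- table(factor(segments$ID[segments$status == "amplification"],
                        levels = samples))
  n_del <- table(factor(segments$ID[segments$status == "deletion"],
                        levels = samples))
  per_sample <- data.frame(sample = samples,
                           n_amp = as.integer(n_amp),
                           n_del = as.integer(n_del),
                           stringsAsFactors = FALSE)
  per_sample$n_scna <- per_sample$n_amp + per_sample$n_del
  res <- list(per_sample = per_sample,
              totals = c(amplifications = sum(per_sample$n_amp),
                         deletions = sum(per_sample$n_del)))
  if (!is.null(groups)) {
    g <- groups[per_sample$sample]
    keep <- !is.na(g)
    vals <- t(as.matrix(per_sample[keep, c("n_amp", "n_del", "n_scna")]))
    colnames(vals) <- per_sample$sample[keep]
    res$comparison <- compare_groups(vals, g[keep], correction = "BH")
  }
  res
}

# overlap-weighted |seg.mean| contribution of segments to fixed bins;
# bins are a data.frame(chrom, start, end) with a global index
bin_gscore <- function(segments, bins, bin_size) {
  g <- numeric(nrow(bins))
  if (nrow(segments) == 0) return(g)
  first_bin <- setNames(match(unique(bins$chrom), bins$chrom),
                        unique(bins$chrom))
  for (i in seq_len(nrow(segments))) {
    cc <- as.character(segments$chrom[i])
    fb <- first_bin[[cc]]
    if (is.null(fb) || is.na(fb)) next
    s <- segments$loc.start[i]; e <- segments$loc.end[i]
    b1 <- floor((s - 1) / bin_size); b2 <- floor((e - 1) / bin_size)
    w <- abs(segments$seg.mean[i])
    for (b in b1:b2) {
      idx <- fb + b
      if (idx > nrow(bins) || bins$chrom[idx] != cc) next
      ov <- (min(e, (b + 1) * bin_size) - max(s, b * bin_size + 1) + 1) /
        bin_size
      g[idx] <- g[idx] + w * ov
    }
  }
  g
}

# circular shift of segment coordinates within each chromosome, wrapping
# segments that cross the end
shift_segments <- function(segments, genome, offsets) {
  if (nrow(segments) == 0) return(segments)
  L <- genome[as.character(segments$chrom)]
  off <- offsets[as.character(segments$chrom)]
  s <- ((segments$loc.start - 1 + off) %% L) + 1
  e <- s + (segments$loc.end - segments$loc.start)
  wrap <- e > L
  out <- segments
  out$loc.start <- s
  out$loc.end <- pmin(e, L)
  if (any(wrap)) {
    extra <- segments[wrap, , drop = FALSE]
    extra$loc.start <- 1
    extra$loc.end <- e[wrap] - L[wrap]
    out <- rbind(out, extra)
  }
  out
}

#' Simplified recurrence G-score with permutation FDR
#'
#' The genome is tiled into fixed-width bins; for each sign, a bin's G-score
#' is the sum over samples of `|seg.mean|` of aberrant segments overlapping
#' the bin, weighted by overlap fraction — amplitude times frequency, a
#' GISTIC-like recurrence score (not GISTIC2). The null distribution comes
#' from within-sample circular permutation of segment placements along each
#' chromosome, which preserves each sample's segment-length and amplitude
#' multiset; empirical p-values use the `(1 + b) / (n + 1)` convention and
#' are BH-adjusted.
#'
#' @param segments Labeled segment table (thresholded with defaults if the
#'   `status` column is absent).
#' @param genome Named chromosome lengths (default [synthetic_genome()]).
#' @param bin_size Bin width in bp.
#' @param n_permutations Circular permutations for the null.
#' @param seed Integer seed for the permutation offsets.
#' @param q_threshold Significance threshold on the BH-adjusted empirical p.
#' @return data.frame with one row per bin: `chrom`, `start`, `end`,
#'   `G_amp`, `p_amp`, `q_amp`, `G_del`, `p_del`, `q_del`,
#'   `significant_amp`, `significant_del`.
#' @export
recurrence_gscore <- function(segments, genome = synthetic_genome(),
                              bin_size = 1e6, n_permutations = 199,
                              seed = 1L, q_threshold = 0.1) {
  if (!"status" %in% names(segments)) segments <- threshold_scna(segments)
  validate_seg(segments)
  set.seed(as.integer(seed))
  bins <- do.call(rbind, lapply(names(genome), function(cc) {
    starts <- seq(1, genome[[cc]], by = bin_size)
    data.frame(chrom = cc, start = starts,
               end = pmin(starts + bin_size - 1, genome[[cc]]),
               stringsAsFactors = FALSE)
  }))

  res <- bins
  for (sign in c("amp", "del")) {
    lab <- if (sign == "amp") "amplification" else "deletion"
    ab <- segments[segments$status == lab, , drop = FALSE]
    obs <- bin_gscore(ab, bins, bin_size)
    exceed <- integer(nrow(bins))
    samples <- unique(segments$ID)
    for (p in seq_len(n_permutations)) {
      shifted <- do.call(rbind, lapply(samples, function(s) {
        sub <- ab[ab$ID == s, , drop = FALSE]
        offs <- setNames(floor(stats::runif(length(genome)) * genome),
                         names(genome))
        shift_segments(sub, genome, offs)
      }))
      if (is.null(shifted)) shifted <- ab[0, , drop = FALSE]
      exceed <- exceed + (bin_gscore(shifted, bins, bin_size) >= obs)
    }
    pvals <- (1 + exceed) / (n_permutations + 1)
    qvals <- stats::p.adjust(pvals, method = "BH")
    res[[paste0("G_", sign)]] <- obs
    res[[paste0("p_", sign)]] <- pvals
    res[[paste0("q_", sign)]] <- qvals
    res[[paste0("significant_", sign)]] <- qvals < q_threshold
  }
  res
}
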