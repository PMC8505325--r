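# Chromothripsis-like region detection from segmented copy-number profiles:
# profile simplification (short-segment dropping, signal-distance merging),
# oscillation (copy-number status switch) counting, a Poisson
# likelihood-ratio statistic for local breakpoint clustering, and a sliding
# window caller with gain/loss and gene annotation.

#' Simplify a segmented profile
#'
#' Segments shorter than `min_segment_size` (default 10 kb) are dropped;
#' adjacent segments whose seg.mean values differ by less than
#' `signal_distance` (default 0.3) are merged with a length-weighted mean,
#' iterated to a fixed point (so merging is idempotent). Every boundary left
#' in the simplified profile is a copy-number status change of at least
#' `signal_distance`.
#'
#' @param segments SEG-style data.frame.
#' @param signal_distance Minimum |seg.mean| difference kept between
#'   adjacent segments.
#' @param min_segment_size Minimum segment length in bp.
#' @return Simplified segment data.frame, ordered by sample, chromosome,
#'   position.
#' @export
merge_segments <- function(segments, signal_distance = 0.3,
                           min_segment_size = 1e4) {
  validate_seg(segments)
  segments <- segments[segments$loc.end - segments$loc.start + 1 >=
                         min_segment_size, , drop = FALSE]
  if (nrow(segments) == 0) return(segments)
  segments <- segments[order(segments$ID, segments$chrom,
                             segments$loc.start), , drop = FALSE]
  key <- paste(segments$ID, segments$chrom, sep = "\r")
  out <- lapply(unique(key), function(k) {
    sub <- segments[key == k, , drop = FALSE]
    repeat {
      if (nrow(sub) < 2) break
      d <- abs(diff(sub$seg.mean))
      idx <- which(d < signal_distance)
      if (length(idx) == 0) break
      i <- idx[1]                      # leftmost mergeable pair first
      l1 <- sub$loc.end[i] - sub$loc.start[i] + 1
      l2 <- sub$loc.end[i + 1] - sub$loc.start[i + 1] + 1
      sub$seg.mean[i] <- (sub$seg.mean[i] * l1 + sub$seg.mean[i + 1] * l2) /
        (l1 + l2)
      sub$loc.end[i] <- sub$loc.end[i + 1]
      if ("num.mark" %in% names(sub)) {
        sub$num.mark[i] <- sub$num.mark[i] + sub$num.mark[i + 1]
      }
      sub <- sub[-(i + 1), , drop = FALSE]
    }
    sub
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count copy-number status switches in a simplified profile
#'
#' Each adjacent-segment boundary of the merged profile is one switch (by
#' construction its |seg.mean| step is at least the merge signal distance).
#'
#' @param profile Simplified segment table from [merge_segments()].
#' @param sample,chrom Optional filters.
#' @return data.frame with `sample`, `chrom`, `n_switches`; the breakpoint
#'   positions (start of the right-hand segment at each boundary) are in
#'   attribute `breakpoints` (data.frame `sample`, `chrom`, `pos`).
#' @export
count_cn_switches <- function(profile, sample = NULL, chrom = NULL) {
  if (!is.null(sample)) profile <- profile[profile$ID %in% sample, ,
                                           drop = FALSE]
  if (!is.null(chrom)) profile <- profile[profile$chrom %in% chrom, ,
                                          drop = FALSE]
  if (nrow(profile) == 0) {
    out <- data.frame(sample = character(0), chrom = character(0),
                      n_switches = integer(0), stringsAsFactors = FALSE)
    attr(out, "breakpoints") <- data.frame(sample = character(0),
                                           chrom = character(0),
                                           pos = numeric(0))
    return(out)
  }
  profile <- profile[order(profile$ID, profile$chrom, profile$loc.start), ,
                     drop = FALSE]
  key <- paste(profile$ID, profile$chrom, sep = "\r")
  counts <- lapply(unique(key), function(k) {
    sub <- profile[key == k, , drop = FALSE]
    bp <- if (nrow(sub) >= 2) sub$loc.start[-1] else numeric(0)
    list(row = data.frame(sample = sub$ID[1], chrom = sub$chrom[1],
                          n_switches = length(bp),
                          stringsAsFactors = FALSE),
         bp = data.frame(sample = rep(sub$ID[1], length(bp)),
                         chrom = rep(sub$chrom[1], length(bp)), pos = bp,
                         stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(counts, `[[`, "row"))
  attr(out, "breakpoints") <- do.call(rbind, lapply(counts, `[[`, "bp"))
  out
}

#' Poisson likelihood-ratio statistic for local breakpoint clustering
#'
#' Compares the local breakpoint rate `lambda1 = k / W` in a window of width
#' `W` against the sample's genome-wide background rate `lambda0 = K / G`:
#' `log10 LR = (k * ln(lambda1/lambda0) - W * (lambda1 - lambda0)) / ln(10)`.
#' With no genome-wide background (`K = 0`) but local breakpoints, the
#' statistic is `+Inf` (flagged by the caller).
#'
#' @param k Breakpoints in the window.
#' @param W Window width (bp).
#' @param K Genome-wide breakpoints of the sample.
#' @param G Genome length (bp).
#' @return log10 likelihood ratio (0 when `k = 0` matches `lambda0 = 0`, or
#'   when `lambda1 = lambda0`).
#' @export
chromothripsis_lr <- function(k, W, K, G) {
  stopifnot(W > 0, G > 0, k >= 0, K >= 0)
  lambda1 <- k / W
  lambda0 <- K / G
  if (lambda0 == 0) {
    if (k == 0) return(0)
    return(Inf)
  }
  if (k == 0) return((W * lambda0) / log(10))
  (k * log(lambda1 / lambda0) - W * (lambda1 - lambda0)) / log(10)
}

#' Call chromothripsis-like regions
#'
#' The profile is simplified by [merge_segments()]; switch counts and
#' breakpoints come from [count_cn_switches()]. A sliding window (default
#' 50 Mb, step 10 Mb) over each sample-chromosome qualifies when it holds at
#' least `min_switches` breakpoints and its [chromothripsis_lr()] is at
#' least `min_lr`; overlapping qualifying windows are merged into one
#' maximal region whose statistics are recomputed on the merged extent.
#' Sub-regions with merged seg.mean at or above `gain_cut` (default 0.15) /
#' at or below `loss_cut` (default -0.15) are annotated as gains / losses,
#' and genes from an optional BED-like table are attached by interval
#' overlap.
#'
#' @param segments SEG-style data.frame.
#' @param genome Named chromosome lengths.
#' @param min_switches,min_lr Calling thresholds (defaults 20 switches,
#'   log10 LR 8).
#' @param signal_distance,min_segment_size Profile simplification
#'   parameters.
#' @param window,step Sliding-window width and step in bp.
#' @param gain_cut,loss_cut Display thresholds for gain/loss annotation.
#' @param gene_table Optional data.frame (`chrom`, `start`, `end`, `gene`).
#' @return data.frame of calls: `sample`, `chrom`, `start`, `end`,
#'   `n_switches`, `log10_lr`, `lr_infinite`, `n_gains`, `n_losses`,
#'   `genes_gain`, `genes_loss`.
#' @export
call_chromothripsis <- function(segments, genome = synthetic_genome(),
                                min_switches = 20, min_lr = 8,
                                signal_distance = 0.3,
                                min_segment_size = 1e4,
                                window = 5e7, step = 1e7,
                                gain_cut = 0.15, loss_cut = -0.15,
                                gene_table = NULL) {
  profile <- merge_segments(segments, signal_distance, min_segment_size)
  sw <- count_cn_switches(profile)
  bps <- attr(sw, "breakpoints")
  G <- sum(genome)
  calls <- list()
  for (s in unique(profile$ID)) {
    K <- sum(bps$pos[bps$sample == s] > 0)
    for (cc in unique(profile$chrom[profile$ID == s])) {
      pos <- sort(bps$pos[bps$sample == s & bps$chrom == cc])
      if (length(pos) < min_switches) next
      L <- genome[[cc]]
      if (is.null(L) || is.na(L)) L <- max(profile$loc.end[
        profile$ID == s & profile$chrom == cc])
      starts <- seq(1, max(1, L - window + 1), by = step)
      qual <- NULL
      for (w0 in starts) {
        w1 <- min(w0 + window - 1, L)
        k <- sum(pos >= w0 & pos <= w1)
        if (k < min_switches) next
        lr <- chromothripsis_lr(k, w1 - w0 + 1, K, G)
        if (lr >= min_lr) qual <- rbind(qual, c(w0, w1))
      }
      if (is.null(qual)) next
      # merge overlapping qualifying windows into maximal regions
      qual <- qual[order(qual[, 1]), , drop = FALSE]
      reg_start <- qual[1, 1]; reg_end <- qual[1, 2]
      regions <- list()
      if (nrow(qual) > 1) {
        for (i in 2:nrow(qual)) {
          if (qual[i, 1] <= reg_end + 1) {
            reg_end <- max(reg_end, qual[i, 2])
          } else {
            regions[[length(regions) + 1]] <- c(reg_start, reg_end)
            reg_start <- qual[i, 1]; reg_end <- qual[i, 2]
          }
        }
      }
      regions[[length(regions) + 1]] <- c(reg_start, reg_end)
      for (r in regions) {
        k <- sum(pos >= r[1] & pos <= r[2])
        lr <- chromothripsis_lr(k, r[2] - r[1] + 1, K, G)
        segs <- profile[profile$ID == s & profile$chrom == cc &
                          profile$loc.end >= r[1] &
                          profile$loc.start <= r[2], , drop = FALSE]
        gains <- segs[segs$seg.mean >= gain_cut, , drop = FALSE]
        losses <- segs[segs$seg.mean <= loss_cut, , drop = FALSE]
        gg <- ll <- character(0)
        if (!is.null(gene_table)) {
          ann <- function(sub) {
            hits <- gene_table$chrom == cc &
              outer(gene_table$start, sub$loc.end, "<=") &
              outer(gene_table$end, sub$loc.start, ">=")
            sort(unique(gene_table$gene[rowSums(hits) > 0]))
          }
          if (nrow(gains) > 0) gg <- ann(gains)
          if (nrow(losses) > 0) ll <- ann(losses)
        }
        calls[[length(calls) + 1]] <- data.frame(
          sample = s, chrom = cc, start = r[1], end = min(r[2], L),
          n_switches = k, log10_lr = lr, lr_infinite = is.infinite(lr),
          n_gains = nrow(gains), n_losses = nrow(losses),
          genes_gain = paste(gg, collapse = ","),
          genes_loss = paste(ll, collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(calls) == 0) {
    return(data.frame(sample = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_switches = integer(0), log10_lr = numeric(0),
                      lr_infinite = logical(0), n_gains = integer(0),
                      n_losses = integer(0), genes_gain = character(0),
                      genes_loss = character(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, calls)
  rownames(res) <- NULL
  res
}

#' Summarize chromothripsis calls per group
#'
#' @param calls data.frame from [call_chromothripsis()].
#' @param groups Optional named per-sample group labels.
#' @return data.frame with per-group call counts, tumors and chromosomes
#'   affected, mean and SD of switch counts, and gain/loss gene tallies.
#' @export
chromothripsis_group_summary <- function(calls, groups = NULL) {
  if (nrow(calls) == 0) {
    return(data.frame(group = character(0), n_calls = integer(0),
                      n_tumors = integer(0), n_chromosomes = integer(0),
                      mean_switches = numeric(0), sd_switches = numeric(0),
                      n_gene_gains = integer(0), n_gene_losses = integer(0),
                      stringsAsFactors = FALSE))
  }
  g <- if (is.null(groups)) rep("all", nrow(calls))
       else as.character(groups[calls$sample])
  by <- lapply(split(seq_len(nrow(calls)), g), function(idx) {
    e <- calls[idx, , drop = FALSE]
    count_genes <- function(x) length(unlist(strsplit(x[nzchar(x)], ",")))
    data.frame(n_calls = nrow(e),
               n_tumors = length(unique(e$sample)),
               n_chromosomes = length(unique(paste(e$sample, e$chrom))),
               mean_switches = mean(e$n_switches),
               sd_switches = stats::sd(e$n_switches),
               n_gene_gains = count_genes(e$genes_gain),
               n_gene_losses = count_genes(e$genes_loss),
               stringsAsFactors = FALSE)
  })
  out <- cbind(group = names(by), do.call(rbind, by))
  rownames(out) <- NULL
  out
}
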