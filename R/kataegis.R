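# Kataegis: localized hypermutation showers called from inter-mutation
# distances. An event is a run of >= 6 consecutive same-sample,
# same-chromosome mutations whose mean successive distance is <= 1000 bp.
# Events are emitted left to right: from the current scan point the
# qualifying window with the smallest start and the largest end is taken,
# then scanning resumes past it, so events never overlap and each satisfies
# both thresholds.

#' Ordered positions and successive inter-mutation distances
#'
#' @param muts MAF-like data.frame.
#' @param sample,chrom Sample barcode and chromosome to extract.
#' @return List with sorted `positions` and `distances`
#'   (`distance[i] = pos[i+1] - pos[i]`; empty for < 2 mutations).
#' @export
intermutation_distances <- function(muts, sample, chrom) {
  validate_maf(muts)
  pos <- muts$Start_Position[muts$Tumor_Sample_Barcode == sample &
                               muts$Chromosome == chrom]
  pos <- sort(as.numeric(pos))
  list(positions = pos,
       distances = if (length(pos) >= 2) diff(pos) else numeric(0))
}

# leftmost-longest qualifying windows over one sorted position vector;
# returns index pairs (i, j)
kataegis_runs <- function(pos, min_mutations, max_imd) {
  n <- length(pos)
  runs <- list()
  i <- 1L
  while (i + min_mutations - 1L <= n) {
    js <- seq.int(i + min_mutations - 1L, n)
    qual <- (pos[js] - pos[i]) <= max_imd * (js - i)
    if (any(qual)) {
      j <- max(js[qual])
      runs[[length(runs) + 1L]] <- c(i, j)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  runs
}

#' Call kataegis events
#'
#' @param muts MAF-like data.frame.
#' @param min_mutations Minimum mutations per event (default 6).
#' @param max_imd Maximum mean inter-mutation distance in bp (default 1000).
#' @return data.frame with one row per event: `sample`, `chrom`, `start`,
#'   `end`, `n_mutations`, `mean_imd`, and the count of member mutations in
#'   each of the six substitution classes (`C>A` ... `T>G`).
#' @export
call_kataegis <- function(muts, min_mutations = 6, max_imd = 1000) {
  validate_maf(muts)
  out <- list()
  if (nrow(muts) > 0) {
    muts <- muts[order(muts$Tumor_Sample_Barcode, muts$Chromosome,
                       muts$Start_Position), , drop = FALSE]
    key <- paste(muts$Tumor_Sample_Barcode, muts$Chromosome, sep = "\r")
    for (k in unique(key)) {
      sub <- muts[key == k, , drop = FALSE]
      pos <- as.numeric(sub$Start_Position)
      runs <- kataegis_runs(pos, min_mutations, max_imd)
      for (r in runs) {
        idx <- seq.int(r[1], r[2])
        cls <- substitution_class(sub$Reference_Allele[idx],
                                  sub$Tumor_Seq_Allele2[idx])
        comp <- table(factor(cls, levels = SBS_CLASSES))
        row <- data.frame(sample = sub$Tumor_Sample_Barcode[1],
                          chrom = sub$Chromosome[1],
                          start = pos[r[1]], end = pos[r[2]],
                          n_mutations = length(idx),
                          mean_imd = (pos[r[2]] - pos[r[1]]) / (length(idx) - 1),
                          stringsAsFactors = FALSE, check.names = FALSE)
        row[SBS_CLASSES] <- as.list(as.integer(comp))
        out[[length(out) + 1L]] <- row
      }
    }
  }
  if (length(out) == 0) {
    ev <- data.frame(sample = character(0), chrom = character(0),
                     start = numeric(0), end = numeric(0),
                     n_mutations = integer(0), mean_imd = numeric(0),
                     stringsAsFactors = FALSE, check.names = FALSE)
    ev[SBS_CLASSES] <- lapply(SBS_CLASSES, function(x) integer(0))
    return(ev)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize kataegis events, optionally per CYT group
#'
#' @param events data.frame from [call_kataegis()].
#' @param groups Optional named per-sample group labels.
#' @return List with `n_events`, `n_tumors`, `n_mutations`,
#'   `ct_fraction` (fraction of event mutations that are C>T) and, when
#'   groups are given, a per-group data.frame `by_group`.
#' @export
kataegis_summary <- function(events, groups = NULL) {
  n_mut <- sum(events$n_mutations)
  ct <- if (n_mut > 0) sum(events[["C>T"]]) / n_mut else 0
  res <- list(n_events = nrow(events),
              n_tumors = length(unique(events$sample)),
              n_mutations = n_mut, ct_fraction = ct)
  if (!is.null(groups) && nrow(events) > 0) {
    g <- groups[events$sample]
    by <- lapply(split(seq_len(nrow(events)), g), function(idx) {
      e <- events[idx, , drop = FALSE]
      data.frame(n_events = nrow(e),
                 n_tumors = length(unique(e$sample)),
                 n_mutations = sum(e$n_mutations),
                 stringsAsFactors = FALSE)
    })
    res$by_group <- cbind(group = names(by), do.call(rbind, by))
    rownames(res$by_group) <- NULL
  }
  res
}

#' Rainfall-plot data
#'
#' Per-mutation log10 distance to the previous mutation on the same
#' sample-chromosome, with its substitution class — the standard rainfall
#' representation for spotting kataegis.
#'
#' @param muts MAF-like data.frame.
#' @return data.frame with `sample`, `chrom`, `pos`, `log10_imd` (`NA` for
#'   the first mutation of each sample-chromosome) and `class`.
#' @export
rainfall_data <- function(muts) {
  validate_maf(muts)
  muts <- muts[order(muts$Tumor_Sample_Barcode, muts$Chromosome,
                     muts$Start_Position), , drop = FALSE]
  key <- paste(muts$Tumor_Sample_Barcode, muts$Chromosome, sep = "\r")
  imd <- ave(as.numeric(muts$Start_Position), key,
             FUN = function(p) c(NA, diff(p)))
  data.frame(sample = muts$Tumor_Sample_Barcode, chrom = muts$Chromosome,
             pos = muts$Start_Position,
             log10_imd = ifelse(imd > 0, log10(imd), 0),
             class = substitution_class(muts$Reference_Allele,
                                        muts$Tumor_Seq_Allele2),
             stringsAsFactors = FALSE)
}
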