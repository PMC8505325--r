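# Intra-tumor heterogeneity from variant allele frequencies: the MATH score
# (scaled MAD over median, percent scale) and BIC-selected Gaussian-mixture
# clustering of each sample's VAF distribution.

#' Variant allele frequencies per mutation
#'
#' VAF = alt_count / (alt_count + ref_count). Records without usable counts
#' (missing, or zero total depth) are excluded and tallied in the
#' `n_excluded` attribute.
#'
#' @param muts MAF-like data.frame with `ref_count` and `alt_count`.
#' @return data.frame with `sample` and `vaf`.
#' @export
compute_vaf <- function(muts) {
  validate_maf(muts)
  if (!all(c("ref_count", "alt_count") %in% names(muts))) {
    stop("mutation table needs ref_count and alt_count columns")
  }
  tot <- muts$ref_count + muts$alt_count
  ok <- !is.na(tot) & tot > 0
  out <- data.frame(sample = muts$Tumor_Sample_Barcode[ok],
                    vaf = muts$alt_count[ok] / tot[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' MATH score (mutant-allele tumor heterogeneity)
#'
#' `MATH = 100 * (1.4826 * median(|VAF - median(VAF)|)) / median(VAF)` —
#' the Gaussian-consistent scaled median absolute deviation of the VAF
#' distribution as a percentage of its median. Invariant to positive
#' rescaling of the VAFs.
#'
#' @param vafs Numeric VAF vector (at least 2 values; median must be > 0).
#' @return Scalar MATH score (percent scale).
#' @export
math_score <- function(vafs) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < 2) stop("MATH needs at least 2 VAF values")
  med <- stats::median(vafs)
  if (med <= 0) stop("MATH undefined: median VAF is 0")
  100 * (1.4826 * stats::median(abs(vafs - med))) / med
}

#' Cluster a sample's VAF distribution
#'
#' One-dimensional Gaussian mixtures for k = 1..`max_clusters` fitted by EM
#' (mclust), with the number of modes selected by BIC. Fewer than 5
#' mutations force a single cluster, flagged low-confidence. mclust's
#' hierarchical initialization makes the fit deterministic for a given VAF
#' vector.
#'
#' @param vafs Numeric VAF vector.
#' @param max_clusters Largest mixture size considered (default 4).
#' @return List with `n_clusters`, `means`, `weights`, `low_confidence`.
#' @importFrom mclust Mclust mclustBIC
#' @export
cluster_vaf <- function(vafs, max_clusters = 4) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < 5) {
    return(list(n_clusters = 1L,
                means = if (length(vafs)) mean(vafs) else NA_real_,
                weights = 1, low_confidence = TRUE))
  }
  fit <- suppressWarnings(
    Mclust(vafs, G = seq_len(max_clusters), verbose = FALSE))
  if (is.null(fit)) {
    return(list(n_clusters = 1L, means = mean(vafs), weights = 1,
                low_confidence = TRUE))
  }
  ord <- order(fit$parameters$mean)
  list(n_clusters = as.integer(fit$G),
       means = unname(fit$parameters$mean[ord]),
       weights = unname(fit$parameters$pro[ord]),
       low_confidence = FALSE)
}

#' Per-sample heterogeneity profile
#'
#' Combines [compute_vaf()], [math_score()] and [cluster_vaf()] over a
#' cohort. Samples whose MATH is undefined (fewer than 2 usable VAFs or
#' zero median) get `NA` with no error.
#'
#' @param muts MAF-like data.frame.
#' @param max_clusters Passed to [cluster_vaf()].
#' @return data.frame with `sample`, `n_mutations`, `MATH`, `n_clusters`,
#'   `cluster_means` (comma string), `low_confidence`.
#' @export
vaf_profile <- function(muts, max_clusters = 4) {
  v <- compute_vaf(muts)
  out <- lapply(split(v$vaf, v$sample), function(x) {
    m <- tryCatch(math_score(x), error = function(e) NA_real_)
    cl <- cluster_vaf(x, max_clusters)
    data.frame(n_mutations = length(x), MATH = m,
               n_clusters = cl$n_clusters,
               cluster_means = paste(round(cl$means, 4), collapse = ","),
               low_confidence = cl$low_confidence,
               stringsAsFactors = FALSE)
  })
  res <- cbind(sample = names(out), do.call(rbind, out))
  rownames(res) <- NULL
  res
}
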