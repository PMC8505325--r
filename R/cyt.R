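# Immune cytolytic activity: CYT = geometric mean of GZMA and PRF1 TPM,
# quartile stratification within tumor-type strata, expression-signature
# scoring, and the shared two-group Mann-Whitney comparison helper.

#' IFN-gamma signature gene set
#'
#' Six IFN-gamma-responsive genes related to antigen presentation, chemokine
#' expression and cytotoxic activity, proposed as a predictor of response to
#' PD-1 blockade.
#'
#' @return Character vector of gene symbols.
#' @export
ifng_signature_genes <- function() {
  c("IFNG", "IDO1", "CXCL9", "CXCL10", "HLA-DRA", "STAT1")
}

#' Expanded-immune signature gene set
#'
#' The 18-gene expanded immune signature companion to
#' [ifng_signature_genes()].
#'
#' @return Character vector of 18 gene symbols.
#' @export
expanded_immune_genes <- function() {
  c("CD30", "IDO1", "CIITA", "CD3E", "CCL5", "GZMK", "CD2", "HLA-DRA",
    "CXCL13", "IL2RG", "NKG7", "HLA-E", "CXCR6", "LAG3", "TAGAP", "CXCL10",
    "STAT1", "GZMB")
}

as_tpm_matrix <- function(expr) {
  if (inherits(expr, "melan_expression")) expr$tpm
  else if (is.matrix(expr)) expr
  else stop("expr must be a TPM matrix or a melan_expression object")
}

#' Compute per-sample cytolytic activity (CYT)
#'
#' CYT is the geometric mean of GZMA and PRF1 expression on the TPM scale:
#' `sqrt((GZMA + pseudocount) * (PRF1 + pseudocount))`. The pseudocount
#' (default 0.01 TPM) keeps a single zero transcript from annihilating the
#' score.
#'
#' @param expr TPM matrix (genes x samples) or a `melan_expression` object.
#' @param pseudocount TPM added to both genes before the geometric mean.
#' @return data.frame with `sample`, `CYT` and `cyt_log2`.
#' @export
compute_cyt <- function(expr, pseudocount = 0.01) {
  tpm <- as_tpm_matrix(expr)
  for (g in c("GZMA", "PRF1")) {
    if (!g %in% rownames(tpm)) {
      stop("expression matrix is missing required gene row: ", g)
    }
  }
  if (any(tpm[c("GZMA", "PRF1"), ] < 0)) stop("TPM values must be >= 0")
  cyt <- sqrt((tpm["GZMA", ] + pseudocount) * (tpm["PRF1", ] + pseudocount))
  data.frame(sample = colnames(tpm), CYT = unname(cyt),
             cyt_log2 = unname(log2(cyt)), stringsAsFactors = FALSE)
}

#' Stratify samples into CYT-high / CYT-low quartiles
#'
#' Within each stratum (by default the whole cohort), samples at or above
#' the 75th percentile of CYT are labeled `high`, those at or below the 25th
#' percentile `low`, the rest `mid`. Percentiles use linear interpolation
#' (quantile type 7). Ties spanning both boundaries (e.g. all values equal)
#' fall to `mid`, keeping the extreme groups conservative. Strata with fewer
#' than 4 samples are skipped with a warning (group `NA`).
#'
#' @param cyt data.frame from [compute_cyt()], or any data.frame with
#'   `sample` and `CYT` columns.
#' @param strata Optional per-sample stratum labels (e.g. tumor type);
#'   `NULL` pools the cohort.
#' @return The input with `tumor_type` (if strata supplied) and `group`
#'   (`high`/`mid`/`low`/`NA`) columns appended.
#' @export
stratify_quartiles <- function(cyt, strata = NULL) {
  stopifnot(is.data.frame(cyt), all(c("sample", "CYT") %in% names(cyt)))
  n <- nrow(cyt)
  if (is.null(strata)) strata <- rep("all", n)
  stopifnot(length(strata) == n)
  group <- rep(NA_character_, n)
  for (st in unique(strata)) {
    idx <- which(strata == st)
    if (length(idx) < 4) {
      warning("stratum '", st, "' has fewer than 4 samples; skipped")
      next
    }
    x <- cyt$CYT[idx]
    q <- stats::quantile(x, probs = c(0.25, 0.75), type = 7, names = FALSE)
    hi <- x >= q[2] & x > q[1]
    lo <- x <= q[1] & x < q[2]
    group[idx] <- ifelse(hi, "high", ifelse(lo, "low", "mid"))
  }
  out <- cyt
  if (!identical(unique(strata), "all")) out$tumor_type <- strata
  out$group <- group
  out
}

#' Spearman co-expression of two genes
#'
#' @param expr TPM matrix or `melan_expression`.
#' @param geneA,geneB Gene row names.
#' @return List with `rho`, `p`, and `n`.
#' @export
coexpression_rho <- function(expr, geneA = "GZMA", geneB = "PRF1") {
  tpm <- as_tpm_matrix(expr)
  for (g in c(geneA, geneB)) {
    if (!g %in% rownames(tpm)) stop("missing gene row: ", g)
  }
  x <- tpm[geneA, ]; y <- tpm[geneB, ]
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Mean z-score signature scoring
#'
#' Score = mean across the set's genes (those present in the matrix) of the
#' per-gene z-score, where z is taken across samples with the sample
#' standard deviation. Zero-variance genes contribute z = 0.
#'
#' @param expr TPM matrix or `melan_expression`.
#' @param gene_set Character vector of gene symbols.
#' @return Numeric per-sample score vector with attribute `n_genes` (number
#'   of set genes found in the matrix).
#' @export
signature_score <- function(expr, gene_set) {
  tpm <- as_tpm_matrix(expr)
  present <- intersect(gene_set, rownames(tpm))
  if (length(present) == 0) stop("no genes of the set are in the matrix")
  if (length(present) < length(gene_set)) {
    warning(length(gene_set) - length(present),
            " gene(s) of the set absent from the matrix")
  }
  z <- samplewise_zscores(tpm, present)
  score <- colMeans(z)
  attr(score, "n_genes") <- length(present)
  score
}

#' Two-group Mann-Whitney comparison with multiplicity adjustment
#'
#' Runs a two-sided Mann-Whitney U test (midrank ties) per feature between
#' two groups and adjusts p-values by Benjamini-Hochberg or Bonferroni.
#'
#' @param values Numeric vector (one feature) or features x samples matrix /
#'   data.frame.
#' @param groups Two-level per-sample group labels; samples with other or
#'   missing labels are dropped.
#' @param correction `"BH"` (default) or `"bonferroni"`.
#' @param levels Optional explicit pair of group labels to compare (first vs
#'   second); default the two labels present.
#' @return data.frame with `feature`, `statistic` (U for the first group),
#'   `p`, `p_adj`, and the two group medians.
#' @export
compare_groups <- function(values, groups,
                           correction = c("BH", "bonferroni"),
                           levels = NULL) {
  correction <- match.arg(correction)
  if (is.null(dim(values))) {
    values <- matrix(values, nrow = 1,
                     dimnames = list("value", names(values)))
  }
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("feature%d", seq_len(nrow(values)))
  }
  stopifnot(ncol(values) == length(groups))
  if (is.null(levels)) {
    levels <- unique(stats::na.omit(as.character(groups)))
    if (length(levels) != 2) {
      stop("groups must have exactly two levels; got: ",
           paste(levels, collapse = ", "))
    }
  }
  ia <- which(groups == levels[1]); ib <- which(groups == levels[2])
  if (length(ia) == 0 || length(ib) == 0) stop("empty comparison group")
  res <- t(apply(values, 1, function(v) {
    wt <- suppressWarnings(stats::wilcox.test(v[ia], v[ib],
                                              alternative = "two.sided"))
    c(statistic = unname(wt$statistic), p = wt$p.value,
      median_a = stats::median(v[ia]), median_b = stats::median(v[ib]))
  }))
  out <- data.frame(feature = rownames(values), res,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[names(out) == "median_a"] <- paste0("median_", levels[1])
  names(out)[names(out) == "median_b"] <- paste0("median_", levels[2])
  out$p_adj <- stats::p.adjust(out$p, method = correction)
  out
}
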