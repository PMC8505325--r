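# Kaplan-Meier estimation, log-rank (Mantel-Cox) testing and the two-gene
# survival synergy analysis (both-high / both-low versus the rest).

validate_clinical <- function(clinical) {
  stopifnot(is.data.frame(clinical),
            all(c("sample", "time", "event") %in% names(clinical)))
  if (any(clinical$time < 0)) stop("negative survival times")
  if (!all(clinical$event %in% c(0, 1))) stop("event must be 0/1")
  clinical
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator per group with Greenwood standard errors and
#' log-transformed confidence intervals (survival::survfit).
#'
#' @param clinical data.frame with `sample`, `time` (days), `event`
#'   (1 death / 0 censored) and optionally a `group` column.
#' @param group Optional per-sample labels overriding the `group` column;
#'   `NULL` with no group column estimates a single curve.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   `std_err` (Greenwood SE of the survival probability), `lower`,
#'   `upper`.
#' @export
km_estimate <- function(clinical, group = NULL) {
  validate_clinical(clinical)
  if (is.null(group)) {
    group <- if ("group" %in% names(clinical)) clinical$group
             else rep("all", nrow(clinical))
  }
  df <- data.frame(time = clinical$time, event = clinical$event,
                   group = as.character(group), stringsAsFactors = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df,
                           conf.type = "log")
  sm <- summary(fit, censored = TRUE)
  grp <- if (is.null(sm$strata)) rep(unique(df$group)[1], length(sm$time))
         else sub("^group=", "", as.character(sm$strata))
  data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
             n_event = sm$n.event, surv = sm$surv,
             std_err = sm$std.err, lower = sm$lower, upper = sm$upper,
             stringsAsFactors = FALSE)
}

#' Two-group log-rank (Mantel-Cox) test
#'
#' @param clinical data.frame with `sample`, `time`, `event` and a `group`
#'   column (or labels via `groups`).
#' @param groupA,groupB The two labels to compare.
#' @param groups Optional per-sample labels overriding the `group` column.
#' @return List with `chisq` (1 df), `p`, `n` (per-group sizes),
#'   `observed`, `expected`.
#' @export
logrank_test <- function(clinical, groupA, groupB, groups = NULL) {
  validate_clinical(clinical)
  g <- if (!is.null(groups)) as.character(groups) else clinical$group
  keep <- g %in% c(groupA, groupB)
  if (sum(clinical$event[keep]) == 0) {
    stop("log-rank undefined: no events in the compared groups")
  }
  df <- data.frame(time = clinical$time[keep], event = clinical$event[keep],
                   group = factor(g[keep], levels = c(groupA, groupB)))
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  list(chisq = unname(sd_$chisq), p = p,
       n = setNames(as.integer(sd_$n), c(groupA, groupB)),
       observed = unname(sd_$obs), expected = unname(sd_$exp))
}

#' Two-gene survival synergy analysis
#'
#' Samples are dichotomized per gene at `cutpoint` (default the median) and
#' four log-rank contrasts are run: each gene high-vs-low alone, both-high
#' versus all other samples, and both-low versus all other samples. A
#' both-low contrast that is more extreme than either single-gene contrast
#' is the signature of synergistic loss.
#'
#' @param expr TPM matrix or `melan_expression`.
#' @param clinical data.frame with `sample`, `time`, `event`.
#' @param geneA,geneB Gene row names (defaults GZMA and PRF1).
#' @param cutpoint `"median"` or a quantile in (0, 1).
#' @return data.frame with one row per contrast: `contrast`, `n_in`,
#'   `n_out`, `chisq`, `p`.
#' @export
synergy_analysis <- function(expr, clinical, geneA = "GZMA", geneB = "PRF1",
                             cutpoint = "median") {
  tpm <- as_tpm_matrix(expr)
  validate_clinical(clinical)
  common <- intersect(colnames(tpm), clinical$sample)
  if (length(common) < 4) stop("need >= 4 samples shared by inputs")
  tpm <- tpm[, common, drop = FALSE]
  clinical <- clinical[match(common, clinical$sample), ]
  q <- if (identical(cutpoint, "median")) 0.5 else as.numeric(cutpoint)
  hiA <- tpm[geneA, ] > stats::quantile(tpm[geneA, ], q, names = FALSE)
  hiB <- tpm[geneB, ] > stats::quantile(tpm[geneB, ], q, names = FALSE)
  contrasts <- list(
    A_high_vs_low = hiA,
    B_high_vs_low = hiB,
    both_high_vs_other = hiA & hiB,
    both_low_vs_other = !hiA & !hiB
  )
  out <- lapply(names(contrasts), function(nm) {
    memb <- contrasts[[nm]]
    lr <- logrank_test(clinical, "in", "out",
                       groups = ifelse(memb, "in", "out"))
    data.frame(contrast = nm, n_in = sum(memb), n_out = sum(!memb),
               chisq = lr$chisq, p = lr$p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
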