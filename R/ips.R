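# Immunophenoscore: sample-wise gene z-scores, weighted factor and category
# scores (MHC molecules, immunomodulators/checkpoints, effector cells,
# suppressor cells), and the 0-10 integer IPS scaling.

#' Sample-wise z-scores of expression
#'
#' `(x - mean) / sd` per gene row, across samples. The sample standard
#' deviation (n - 1) is the default convention; zero-variance genes get
#' z = 0 with a warning.
#'
#' @param expr TPM matrix or `melan_expression`.
#' @param genes Gene rows to score (default all).
#' @param sd_type `"sample"` (n - 1) or `"population"` (n).
#' @return genes x samples matrix of z-scores.
#' @export
samplewise_zscores <- function(expr, genes = NULL, sd_type = "sample") {
  tpm <- as_tpm_matrix(expr)
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(tpm))
    if (length(missing) > 0) {
      stop("missing gene row(s): ", paste(missing, collapse = ", "))
    }
    tpm <- tpm[genes, , drop = FALSE]
  }
  n <- ncol(tpm)
  mu <- rowMeans(tpm)
  sds <- apply(tpm, 1, stats::sd)
  if (sd_type == "population") sds <- sds * sqrt((n - 1) / n)
  zero <- sds == 0 | is.na(sds)
  if (any(zero)) {
    warning(sum(zero), " zero-variance gene(s); z set to 0")
    sds[zero] <- 1
  }
  z <- sweep(sweep(tpm, 1, mu, "-"), 1, sds, "/")
  z[zero, ] <- 0
  z
}

#' Example immunophenogram weight table
#'
#' A synthetic, editable gene/factor/category/weight table in the
#' immunophenogram layout: MHC molecules (MHC, positive weights),
#' immunomodulators (CP, checkpoint genes with negative weights and
#' costimulators positive), effector cells (EC, positive) and suppressor
#' cells (SC, negative). It is a working example for tests and synthetic
#' cohorts — not the published weight set, which users can supply as a TSV
#' with the same columns via [read_ips_weights()].
#'
#' @return data.frame with `gene`, `factor`, `category`, `weight`.
#' @export
default_ips_weights <- function() {
  w <- rbind(
    data.frame(gene = c("HLA-A", "HLA-B", "HLA-C", "HLA-DPA1", "HLA-DPB1",
                        "HLA-DRA", "HLA-E", "HLA-F", "B2M", "TAP1", "TAP2"),
               factor = c("HLA-A", "HLA-B", "HLA-C", "HLA-DPA1", "HLA-DPB1",
                          "HLA-DRA", "HLA-E", "HLA-F", "B2M", "TAP1", "TAP2"),
               category = "MHC", weight = 1),
    data.frame(gene = c("PDCD1", "CTLA4", "LAG3", "TIGIT", "CD274",
                        "PDCD1LG2", "IDO1", "CD27", "ICOS", "CD28"),
               factor = c("PD1", "CTLA4", "LAG3", "TIGIT", "PDL1",
                          "PDL2", "IDO1", "CD27", "ICOS", "CD28"),
               category = "CP",
               weight = c(-1, -1, -1, -1, -1, -1, -1, 1, 1, 1)),
    data.frame(gene = c("CD8A", "GZMA", "GZMB", "PRF1", "CD4", "IL2RG",
                        "EOMES", "CXCR6"),
               factor = c("Act_CD8", "Act_CD8", "Act_CD8", "Act_CD8",
                          "Act_CD4", "Act_CD4", "Tem_CD8", "Tem_CD8"),
               category = "EC", weight = 1),
    data.frame(gene = c("FOXP3", "CCR8", "ITGAM", "ARG1", "NOS2"),
               factor = c("Treg", "Treg", "MDSC", "MDSC", "MDSC"),
               category = "SC", weight = -1)
  )
  w$gene <- as.character(w$gene)
  w$factor <- as.character(w$factor)
  w$category <- as.character(w$category)
  w
}

validate_ips_weights <- function(weights) {
  stopifnot(all(c("gene", "factor", "category", "weight") %in%
                  names(weights)))
  bad <- setdiff(unique(weights$category), c("MHC", "CP", "EC", "SC"))
  if (length(bad) > 0) {
    stop("unknown IPS categories: ", paste(bad, collapse = ", "))
  }
  weights
}

#' Immunophenogram category scores
#'
#' Each factor's score is the weighted mean of its member genes' z-scores;
#' each category's score is the unweighted mean of its factor scores.
#' Checkpoint (CP) and suppressor (SC) genes carry negative weights in the
#' weight table, so an immunosuppressive profile lowers the aggregate.
#'
#' @param z genes x samples z-score matrix from [samplewise_zscores()].
#' @param weights Weight table (see [default_ips_weights()]).
#' @return samples x 4 matrix with columns MHC, CP, EC, SC.
#' @export
category_scores <- function(z, weights = default_ips_weights()) {
  validate_ips_weights(weights)
  weights <- weights[weights$gene %in% rownames(z), , drop = FALSE]
  if (nrow(weights) == 0) stop("no weight-table genes found in the matrix")
  cats <- c("MHC", "CP", "EC", "SC")
  out <- matrix(0, ncol(z), 4, dimnames = list(colnames(z), cats))
  for (cat in cats) {
    wc <- weights[weights$category == cat, , drop = FALSE]
    if (nrow(wc) == 0) next
    fscores <- vapply(unique(wc$factor), function(f) {
      wf <- wc[wc$factor == f, , drop = FALSE]
      colSums(z[wf$gene, , drop = FALSE] * wf$weight) / sum(abs(wf$weight))
    }, numeric(ncol(z)))
    out[, cat] <- rowMeans(as.matrix(fscores))
  }
  out
}

#' Immunophenoscore (IPS) from category scores
#'
#' The aggregate AZ is the sum of the four category scores (MHC + CP + EC +
#' SC, the negative weights already encoded in the table). IPS = 0 when
#' AZ <= 0, 10 when AZ >= 3, otherwise AZ * 10/3 rounded half-up to an
#' integer.
#'
#' @param cat_scores samples x 4 matrix from [category_scores()].
#' @return data.frame with `sample`, `MHC`, `CP`, `EC`, `SC`, `AZ`, `IPS`.
#' @export
ips_score <- function(cat_scores) {
  az <- rowSums(cat_scores)
  ips <- as.integer(pmin(10, pmax(0, floor(az * 10 / 3 + 0.5))))
  ips[az <= 0] <- 0L
  ips[az >= 3] <- 10L
  data.frame(sample = rownames(cat_scores),
             MHC = cat_scores[, "MHC"], CP = cat_scores[, "CP"],
             EC = cat_scores[, "EC"], SC = cat_scores[, "SC"],
             AZ = az, IPS = ips, row.names = NULL, stringsAsFactors = FALSE)
}

#' Compute IPS for a cohort in one call
#'
#' @param expr TPM matrix or `melan_expression`.
#' @param weights Weight table.
#' @param sd_type z-score convention, see [samplewise_zscores()].
#' @return data.frame from [ips_score()].
#' @export
compute_ips <- function(expr, weights = default_ips_weights(),
                        sd_type = "sample") {
  validate_ips_weights(weights)
  tpm <- as_tpm_matrix(expr)
  genes <- intersect(unique(weights$gene), rownames(tpm))
  z <- samplewise_zscores(tpm, genes, sd_type)
  ips_score(category_scores(z, weights))
}

#' Compare IPS between groups
#'
#' @param ips data.frame from [ips_score()] / [compute_ips()].
#' @param groups Named per-sample group labels.
#' @return List with the Mann-Whitney `comparison` row and `direction`
#'   (which group has the higher median IPS).
#' @export
compare_ips <- function(ips, groups) {
  g <- groups[ips$sample]
  keep <- !is.na(g)
  cmp <- compare_groups(setNames(ips$IPS[keep], ips$sample[keep]), g[keep])
  meds <- tapply(ips$IPS[keep], g[keep], stats::median)
  list(comparison = cmp,
       direction = names(meds)[which.max(meds)])
}
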