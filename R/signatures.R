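# De novo mutational-signature extraction by KL-divergence NMF with
# multiplicative updates, restart-clustering stability for rank selection,
# cosine matching to a reference catalog, NNLS exposure attribution, and
# subgroup contribution statistics.

#' Cosine similarity of two channel vectors
#'
#' `u . v / (|u| |v|)`; in `[0, 1]` for non-negative inputs. Symmetric and
#' scale-invariant. Errors on a zero vector.
#'
#' @param u,v Numeric vectors of equal length.
#' @return Scalar similarity.
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine similarity undefined for zero vector")
  sum(u * v) / (nu * nv)
}

kl_divergence <- function(V, WH) {
  eps <- 1e-12
  sum(ifelse(V > 0, V * log(V / pmax(WH, eps)), 0) - V + WH)
}

nmf_kl_single <- function(V, k, max_iter = 1000, tol = 1e-6) {
  eps <- 1e-12
  n <- nrow(V); m <- ncol(V)
  W <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  H <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  H <- H * (sum(V) / sum(W %*% H))
  last <- Inf
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H))
    W <- sweep(W, 2, pmax(rowSums(H), eps), "/")
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (V / WH))
    H <- sweep(H, 1, pmax(colSums(W), eps), "/")
    if (it %% 10 == 0) {
      d <- kl_divergence(V, pmax(W %*% H, eps))
      if (is.finite(last) && abs(last - d) < tol * (abs(last) + eps)) break
      last <- d
    }
  }
  # scale signatures to L1 = 1, exposures absorb the scale
  s <- pmax(colSums(W), eps)
  W <- sweep(W, 2, s, "/")
  H <- sweep(H, 1, s, "*")
  list(W = W, H = H, kl = kl_divergence(V, pmax(W %*% H, eps)))
}

# continue multiplicative updates from a fixed W initialization (H refit
# from scratch), used to polish cluster-consensus signatures
nmf_kl_polish <- function(V, W0, max_iter = 200, tol = 1e-6) {
  eps <- 1e-12
  k <- ncol(W0)
  W <- pmax(W0, eps)
  H <- matrix(stats::runif(k * ncol(V), 0.1, 1), k, ncol(V))
  H <- H * (sum(V) / sum(W %*% H))
  for (it in seq_len(max_iter)) {
    WH <- pmax(W %*% H, eps)
    H <- H * (t(W) %*% (V / WH))
    H <- sweep(H, 1, pmax(colSums(W), eps), "/")
    WH <- pmax(W %*% H, eps)
    W <- W * ((V / WH) %*% t(H))
    W <- sweep(W, 2, pmax(rowSums(H), eps), "/")
  }
  sweep(W, 2, pmax(colSums(W), eps), "/")
}

#' De novo signature extraction by KL-NMF with stability-based rank selection
#'
#' For each rank in `rank_range`, `n_restarts` KL-divergence NMF fits
#' (multiplicative updates) are run from random starts. The restart
#' signatures are clustered into `rank` groups by partitioning around
#' medoids on cosine dissimilarity. Stability is the silhouette width of the
#' *weakest* cluster (one irreproducible signature disqualifies a rank; the
#' overall mean silhouette is also reported); the consensus signatures are
#' the cluster medoids polished by a short additional run of multiplicative
#' updates. The selected rank is the largest rank with stability at least
#' `stability_threshold` (rank 1 is defined perfectly stable). Exposures
#' are non-negative least-squares fits of each sample onto the consensus
#' signatures, rescaled to the sample's mutation count.
#'
#' @param mat Channels x samples count matrix (e.g. from
#'   [build_sbs96_matrix()]).
#' @param rank_range Integer ranks to explore.
#' @param n_restarts Random restarts per rank.
#' @param seed Integer seed controlling all restarts.
#' @param max_iter,tol Multiplicative-update iteration cap and relative
#'   KL-change convergence tolerance.
#' @param stability_threshold Minimum mean silhouette for an acceptable rank.
#' @return List with `signatures` (channels x rank, L1-normalized),
#'   `exposures` (samples x rank counts), `rank`, and `diagnostics`
#'   (per-rank stability and best-restart KL).
#' @export
extract_signatures_nmf <- function(mat, rank_range = 2:5, n_restarts = 20,
                                   seed = 1L, max_iter = 1000, tol = 1e-6,
                                   stability_threshold = 0.8) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  if (sum(mat) <= 0) stop("total mutation count must be positive")
  if (max(rank_range) > min(dim(mat))) {
    stop("rank exceeds matrix dimensions")
  }
  set.seed(seed)
  diag_rows <- list()
  per_rank <- list()
  for (k in rank_range) {
    fits <- lapply(seq_len(n_restarts), function(r)
      nmf_kl_single(mat, k, max_iter, tol))
    sigs <- do.call(cbind, lapply(fits, `[[`, "W"))
    if (k == 1) {
      stability <- mean_sil <- 1
      consensus <- matrix(rowMeans(sigs), ncol = 1)
    } else {
      # cosine dissimilarity between restart signatures
      norms <- sqrt(pmax(colSums(sigs^2), 1e-12))
      cos_mat <- crossprod(sweep(sigs, 2, norms, "/"))
      d <- stats::as.dist(pmax(1 - cos_mat, 0))
      pm <- cluster::pam(d, k = k, diss = TRUE)
      sil <- cluster::silhouette(pm$clustering, d)
      mean_sil <- mean(sil[, "sil_width"])
      # stability of the *weakest* signature decides the rank: one
      # irreproducible cluster means the rank over-fits
      stability <- min(tapply(sil[, "sil_width"], pm$clustering, mean))
      consensus <- sigs[, pm$medoids, drop = FALSE]
      # polish: short seeded KL refinement from the medoid consensus
      consensus <- nmf_kl_polish(mat, consensus, max_iter = 200, tol = tol)
    }
    kl_best <- min(vapply(fits, `[[`, numeric(1), "kl"))
    diag_rows[[as.character(k)]] <- data.frame(rank = k,
                                               stability = stability,
                                               mean_silhouette = mean_sil,
                                               kl_best = kl_best)
    per_rank[[as.character(k)]] <- consensus
  }
  diagnostics <- do.call(rbind, diag_rows)
  rownames(diagnostics) <- NULL
  ok <- diagnostics$rank[diagnostics$stability >= stability_threshold]
  if (length(ok) == 0) {
    warning("no rank reached the stability threshold; using the most stable")
    sel <- diagnostics$rank[which.max(diagnostics$stability)]
  } else {
    sel <- max(ok)
  }
  signatures <- per_rank[[as.character(sel)]]
  rownames(signatures) <- rownames(mat)
  colnames(signatures) <- sprintf("DN%d", seq_len(ncol(signatures)))

  exposures <- vapply(seq_len(ncol(mat)), function(j) {
    attribute_exposures_nnls(mat[, j], signatures)$exposures
  }, numeric(ncol(signatures)))
  exposures <- t(matrix(exposures, nrow = ncol(signatures)))
  # rescale each sample's exposures to its observed mutation count
  tot <- colSums(mat)
  es <- rowSums(exposures)
  scale <- ifelse(es > 0, tot / es, 0)
  exposures <- exposures * scale
  rownames(exposures) <- colnames(mat)
  colnames(exposures) <- colnames(signatures)

  list(signatures = signatures, exposures = exposures, rank = sel,
       diagnostics = diagnostics)
}

#' Match de novo signatures to a reference catalog by cosine similarity
#'
#' Greedy one-to-one assignment on similarity sorted descending; de novo
#' signatures whose best remaining reference falls below `min_cosine` stay
#' unassigned. Channel labels must be present and in the same order on both
#' catalogs; mismatched labels are a hard error rather than a silent
#' misalignment.
#'
#' @param denovo Channels x signatures matrix with channel rownames.
#' @param reference Channels x signatures reference matrix (e.g. from
#'   [read_signature_catalog()]).
#' @param min_cosine Minimum similarity for an assignment.
#' @return data.frame with `denovo`, `reference` (`NA` if unassigned) and
#'   `cosine`.
#' @export
match_to_reference <- function(denovo, reference, min_cosine = 0.8) {
  if (is.null(rownames(denovo)) || is.null(rownames(reference))) {
    stop("both catalogs need channel rownames")
  }
  if (!identical(rownames(denovo), rownames(reference))) {
    stop("channel labels differ or are ordered differently between catalogs")
  }
  sim <- outer(seq_len(ncol(denovo)), seq_len(ncol(reference)),
               Vectorize(function(i, j)
                 cosine_similarity(denovo[, i], reference[, j])))
  dimnames(sim) <- list(colnames(denovo), colnames(reference))
  assign <- data.frame(denovo = colnames(denovo),
                       reference = NA_character_, cosine = NA_real_,
                       stringsAsFactors = FALSE)
  s <- sim
  repeat {
    if (all(is.na(s)) || max(s, na.rm = TRUE) < min_cosine) break
    ij <- which(s == max(s, na.rm = TRUE), arr.ind = TRUE)[1, ]
    assign$reference[ij[1]] <- colnames(s)[ij[2]]
    assign$cosine[ij[1]] <- s[ij[1], ij[2]]
    s[ij[1], ] <- NA
    s[, ij[2]] <- NA
  }
  # report the best similarity even for unassigned signatures
  un <- is.na(assign$reference)
  if (any(un)) assign$cosine[un] <- apply(sim[un, , drop = FALSE], 1, max)
  attr(assign, "similarity") <- sim
  assign
}

#' Non-negative least-squares exposure attribution for one sample
#'
#' @param sample_vector Channel count vector.
#' @param signatures Channels x signatures matrix.
#' @return List with `exposures` (non-negative, named), `residual` (L2) and
#'   `reconstruction_cosine` (0 when the fit is the zero vector).
#' @export
attribute_exposures_nnls <- function(sample_vector, signatures) {
  signatures <- as.matrix(signatures)
  stopifnot(length(sample_vector) == nrow(signatures))
  if (all(sample_vector == 0)) {
    expos <- setNames(rep(0, ncol(signatures)), colnames(signatures))
    return(list(exposures = expos, residual = 0, reconstruction_cosine = NA))
  }
  fit <- pracma::lsqnonneg(signatures, as.numeric(sample_vector))
  expos <- setNames(pmax(fit$x, 0), colnames(signatures))
  recon <- as.numeric(signatures %*% expos)
  rc <- if (sum(recon) == 0) 0
        else cosine_similarity(recon, as.numeric(sample_vector))
  list(exposures = expos, residual = sqrt(sum((sample_vector - recon)^2)),
       reconstruction_cosine = rc)
}

#' Relative signature contributions per sample
#'
#' @param exposures Samples x signatures count matrix.
#' @return Samples x signatures matrix of per-sample fractions (rows sum to
#'   1 for samples with any mutations).
#' @export
relative_contributions <- function(exposures) {
  exposures <- as.matrix(exposures)
  tot <- rowSums(exposures)
  sweep(exposures, 1, pmax(tot, 1e-12), "/")
}

#' Compare per-signature contributions between two groups
#'
#' Mann-Whitney on each signature's relative contribution, Bonferroni
#' adjusted (`p_adj = min(1, m * p)`).
#'
#' @param exposures Samples x signatures count matrix.
#' @param groups Per-sample two-level labels (in row order of `exposures`).
#' @param sum_signatures Optional named list of signature groups to sum
#'   before testing (e.g. `list("SBS7a/b" = c("SBS7a","SBS7b"))`).
#' @return data.frame from [compare_groups()] with Bonferroni adjustment.
#' @export
compare_signature_contributions <- function(exposures, groups,
                                            sum_signatures = NULL) {
  rel <- relative_contributions(exposures)
  if (!is.null(sum_signatures)) {
    for (nm in names(sum_signatures)) {
      cols <- sum_signatures[[nm]]
      rel <- cbind(rel, rowSums(rel[, cols, drop = FALSE]))
      colnames(rel)[ncol(rel)] <- nm
      rel <- rel[, setdiff(colnames(rel), cols), drop = FALSE]
    }
  }
  compare_groups(t(rel), groups, correction = "bonferroni")
}

#' Presence/absence co-occurrence of two signatures
#'
#' A sample is positive for a signature when its relative contribution
#' exceeds `threshold`. Association is a 2x2 Fisher exact test; the odds
#' ratio uses the Haldane 0.5 correction when any cell is zero, and the
#' result is flagged degenerate when a table margin is empty.
#'
#' @param exposures Samples x signatures count matrix.
#' @param sigA,sigB Signature column names.
#' @param threshold Relative-contribution presence cutoff.
#' @return List with `table`, `odds_ratio`, `p`, `degenerate`.
#' @export
exposure_cooccurrence <- function(exposures, sigA, sigB, threshold = 0.05) {
  rel <- relative_contributions(exposures)
  stopifnot(sigA %in% colnames(rel), sigB %in% colnames(rel))
  a <- factor(rel[, sigA] > threshold, levels = c(FALSE, TRUE))
  b <- factor(rel[, sigB] > threshold, levels = c(FALSE, TRUE))
  tab <- table(A = a, B = b)
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  ft <- stats::fisher.test(tab)
  or <- if (any(tab == 0)) {
    (tab[2, 2] + 0.5) * (tab[1, 1] + 0.5) /
      ((tab[1, 2] + 0.5) * (tab[2, 1] + 0.5))
  } else {
    unname(ft$estimate)
  }
  list(table = tab, odds_ratio = or, p = ft$p.value, degenerate = degenerate)
}
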