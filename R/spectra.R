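# SBS-96 / DBS-78 context matrices from a MAF-like mutation table, 6-class
# substitution spectra, and the simplified recurrently-mutated-gene test.

required_maf_cols <- c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
                       "Reference_Allele", "Tumor_Seq_Allele2")

validate_maf <- function(muts) {
  missing <- setdiff(required_maf_cols, names(muts))
  if (length(missing) > 0) {
    stop("mutation table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  muts
}

#' Split a mutation table into SNVs and doublet events
#'
#' Two single-base substitutions of the same sample at adjacent positions are
#' one doublet (DBS) event and are removed from the SNV set. Runs of three or
#' more adjacent substituted positions are excluded from both sets and
#' tallied (`excluded_multi`), as are records with ambiguous bases
#' (`excluded_ambiguous`) and non-single-base alleles (`excluded_nonsnv`).
#'
#' @param muts MAF-like data.frame (see [generate_mutations()] for columns).
#' @return List with `snv` (data.frame), `dbs` (data.frame with `ref2`,
#'   `alt2`) and `excluded` (named counts).
#' @export
extract_doublets <- function(muts) {
  muts <- validate_maf(muts)
  ref <- toupper(muts$Reference_Allele)
  alt <- toupper(muts$Tumor_Seq_Allele2)
  is_single <- nchar(ref) == 1 & nchar(alt) == 1
  is_clean <- is_single & ref %in% BASES & alt %in% BASES & ref != alt
  n_nonsnv <- sum(!is_single)
  n_ambig <- sum(is_single & !is_clean)
  snv <- muts[is_clean, , drop = FALSE]

  if (nrow(snv) == 0) {
    return(list(snv = snv, dbs = data.frame(), excluded = c(
      excluded_nonsnv = n_nonsnv, excluded_ambiguous = n_ambig,
      excluded_multi = 0L)))
  }
  o <- order(snv$Tumor_Sample_Barcode, snv$Chromosome, snv$Start_Position)
  snv <- snv[o, , drop = FALSE]
  same_run <- with(snv, c(FALSE,
    Tumor_Sample_Barcode[-1] == Tumor_Sample_Barcode[-nrow(snv)] &
    Chromosome[-1] == Chromosome[-nrow(snv)] &
    diff(Start_Position) == 1))
  run_id <- cumsum(!same_run)
  run_len <- ave(run_id, run_id, FUN = length)

  multi <- run_len >= 3
  pair_first <- run_len == 2 & !duplicated(run_id)
  pair_second <- run_len == 2 & duplicated(run_id)
  dbs <- data.frame()
  if (any(pair_first)) {
    a <- snv[pair_first, , drop = FALSE]
    b <- snv[pair_second, , drop = FALSE]
    dbs <- data.frame(
      Tumor_Sample_Barcode = a$Tumor_Sample_Barcode,
      Chromosome = a$Chromosome, Start_Position = a$Start_Position,
      ref2 = paste0(toupper(a$Reference_Allele), toupper(b$Reference_Allele)),
      alt2 = paste0(toupper(a$Tumor_Seq_Allele2), toupper(b$Tumor_Seq_Allele2)),
      stringsAsFactors = FALSE)
  }
  list(snv = snv[run_len == 1, , drop = FALSE], dbs = dbs,
       excluded = c(excluded_nonsnv = n_nonsnv, excluded_ambiguous = n_ambig,
                    excluded_multi = sum(multi)))
}

maf_context <- function(snv, fasta = NULL) {
  if ("trinucleotide_context" %in% names(snv) &&
      !all(is.na(snv$trinucleotide_context))) {
    ctx <- toupper(snv$trinucleotide_context)
  } else if (!is.null(fasta)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("FASTA context lookup requires the Biostrings package")
    }
    genome <- Biostrings::readDNAStringSet(fasta)
    names(genome) <- sub("\\s.*$", "", names(genome))
    ctx <- vapply(seq_len(nrow(snv)), function(i) {
      chr <- as.character(snv$Chromosome[i])
      p <- snv$Start_Position[i]
      as.character(Biostrings::subseq(genome[[chr]], p - 1, p + 1))
    }, character(1))
    ctx <- toupper(ctx)
  } else {
    stop("no trinucleotide_context column and no reference FASTA supplied")
  }
  ctx
}

#' Build the SBS-96 count matrix
#'
#' Doublets are extracted first (see [extract_doublets()]) so adjacent
#' substitutions are not double-counted as two SNVs; remaining SNVs are
#' classified by [classify_sbs96()] with pyrimidine strand collapse. The
#' trinucleotide context comes from the `trinucleotide_context` column if
#' present, else from a reference FASTA (1-based MAF coordinates).
#'
#' @param muts MAF-like data.frame.
#' @param fasta Optional path to a reference FASTA.
#' @param samples Optional sample universe for the columns (defaults to the
#'   samples present).
#' @return 96 x samples integer matrix with attributes `excluded` (exclusion
#'   tallies) and `n_dbs` (doublet events removed per sample).
#' @export
build_sbs96_matrix <- function(muts, fasta = NULL, samples = NULL) {
  parts <- extract_doublets(muts)
  snv <- parts$snv
  if (is.null(samples)) samples <- sort(unique(muts$Tumor_Sample_Barcode))
  ch <- sbs96_channels()
  mat <- matrix(0L, nrow = 96, ncol = length(samples),
                dimnames = list(ch, samples))
  excluded <- parts$excluded
  if (nrow(snv) > 0) {
    ctx <- maf_context(snv, fasta)
    ok_ctx <- grepl("^[ACGT]{3}$", ctx) &
      substr(ctx, 2, 2) == toupper(snv$Reference_Allele)
    if (any(!ok_ctx)) {
      excluded["excluded_context"] <- sum(!ok_ctx)
      snv <- snv[ok_ctx, , drop = FALSE]
      ctx <- ctx[ok_ctx]
    }
    lab <- classify_sbs96(snv$Reference_Allele, snv$Tumor_Seq_Allele2,
                          substr(ctx, 1, 1), substr(ctx, 3, 3))
    tab <- table(factor(lab, levels = ch),
                 factor(snv$Tumor_Sample_Barcode, levels = samples))
    mat <- mat + matrix(as.integer(tab), nrow = 96,
                        dimnames = list(ch, samples))
  }
  attr(mat, "excluded") <- excluded
  if (nrow(parts$dbs) > 0) {
    attr(mat, "n_dbs") <- table(factor(parts$dbs$Tumor_Sample_Barcode,
                                       levels = samples))
  }
  mat
}

#' Build the DBS-78 count matrix
#'
#' Doublet events are the adjacent-position substitution pairs found by
#' [extract_doublets()], mapped to the canonical 78 channels by
#' [classify_dbs()].
#'
#' @inheritParams build_sbs96_matrix
#' @return 78 x samples integer matrix.
#' @export
build_dbs78_matrix <- function(muts, samples = NULL) {
  parts <- extract_doublets(muts)
  if (is.null(samples)) samples <- sort(unique(muts$Tumor_Sample_Barcode))
  ch <- dbs78_channels()
  mat <- matrix(0L, nrow = 78, ncol = length(samples),
                dimnames = list(ch, samples))
  if (nrow(parts$dbs) > 0) {
    lab <- classify_dbs(parts$dbs$ref2, parts$dbs$alt2)
    tab <- table(factor(lab, levels = ch),
                 factor(parts$dbs$Tumor_Sample_Barcode, levels = samples))
    mat <- mat + matrix(as.integer(tab), nrow = 78,
                        dimnames = list(ch, samples))
  }
  mat
}

#' Collapse a substitution to one of the six pyrimidine classes
#'
#' @param ref,alt Single reference/alternate bases.
#' @return Factor-free character vector over `C>A`, `C>G`, `C>T`, `T>A`,
#'   `T>C`, `T>G`; `NA` for ambiguous input.
#' @export
substitution_class <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  ok <- ref %in% BASES & alt %in% BASES & ref != alt
  flip <- ok & ref %in% c("A", "G")
  r <- ref; a <- alt
  r[flip] <- comp_base(ref[flip]); a[flip] <- comp_base(alt[flip])
  out <- rep(NA_character_, length(ref))
  out[ok] <- paste0(r[ok], ">", a[ok])
  out
}

#' Per-sample 6-class substitution spectrum, with optional group comparison
#'
#' Fractions of each sample's SNVs (after doublet extraction) in the six
#' substitution classes; each sample's fractions sum to 1. When two-level
#' group labels are supplied, each class is compared between groups by
#' Mann-Whitney with BH adjustment.
#'
#' @param muts MAF-like data.frame.
#' @param groups Optional named per-sample group labels (names = samples).
#' @return List with `fractions` (6 x samples), `counts` (6 x samples) and,
#'   if groups were given, `comparison` (data.frame from [compare_groups()]).
#' @export
substitution_spectrum <- function(muts, groups = NULL) {
  snv <- extract_doublets(muts)$snv
  samples <- sort(unique(muts$Tumor_Sample_Barcode))
  cls <- substitution_class(snv$Reference_Allele, snv$Tumor_Seq_Allele2)
  counts <- table(factor(cls, levels = SBS_CLASSES),
                  factor(snv$Tumor_Sample_Barcode, levels = samples))
  counts <- matrix(as.integer(counts), nrow = 6,
                   dimnames = list(SBS_CLASSES, samples))
  tot <- colSums(counts)
  fractions <- sweep(counts, 2, pmax(tot, 1), "/")
  res <- list(fractions = fractions, counts = counts)
  if (!is.null(groups)) {
    g <- groups[samples]
    keep <- !is.na(g) & g %in% names(which(table(g) > 0))
    res$comparison <- compare_groups(fractions[, keep, drop = FALSE],
                                     g[keep], correction = "BH")
  }
  res
}

#' Simplified recurrently-mutated-gene frequency test
#'
#' For each gene, the number of samples carrying at least one mutation is
#' compared to a background expectation by a one-sided binomial test. The
#' background probability that a sample hits the gene is
#' `1 - exp(-r * L)` where `r` is the cohort-median per-Mb mutation rate
#' over the surveyed territory (the summed gene lengths) and `L` the gene
#' length in Mb. P-values are BH-adjusted; genes with `q < q_threshold` are
#' flagged. This is a frequency-only stand-in for covariate-aware driver
#' tests and is labeled as such in the `method` attribute.
#'
#' @param muts MAF-like data.frame with a `Hugo_Symbol` column.
#' @param gene_lengths data.frame with `gene` and `length_bp`.
#' @param q_threshold FDR threshold for the `significant` flag.
#' @return data.frame with `gene`, `n_mutated_samples`, `expected_p0`, `p`,
#'   `q`, `significant`, sorted by `p`; attribute
#'   `method = "simplified_frequency_test"`.
#' @export
smg_frequency_test <- function(muts, gene_lengths, q_threshold = 0.1) {
  validate_maf(muts)
  if (!"Hugo_Symbol" %in% names(muts)) {
    stop("smg_frequency_test requires a Hugo_Symbol column")
  }
  stopifnot(all(c("gene", "length_bp") %in% names(gene_lengths)))
  samples <- unique(muts$Tumor_Sample_Barcode)
  n_samp <- length(samples)
  territory_mb <- sum(gene_lengths$length_bp) / 1e6
  per_sample <- table(factor(muts$Tumor_Sample_Barcode, levels = samples))
  rate_mb <- stats::median(as.numeric(per_sample)) / territory_mb

  hit <- unique(muts[, c("Tumor_Sample_Barcode", "Hugo_Symbol")])
  k <- table(factor(hit$Hugo_Symbol, levels = gene_lengths$gene))
  len_mb <- gene_lengths$length_bp / 1e6
  p0 <- pmin(1 - exp(-rate_mb * len_mb), 1 - 1e-12)
  p <- vapply(seq_along(p0), function(i) {
    ki <- as.integer(k[i])
    if (ki == 0) return(1)
    stats::binom.test(ki, n_samp, p0[i], alternative = "greater")$p.value
  }, numeric(1))
  out <- data.frame(gene = gene_lengths$gene,
                    n_mutated_samples = as.integer(k),
                    expected_p0 = p0, p = p,
                    q = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  out$significant <- out$q < q_threshold
  out <- out[order(out$p, out$gene), ]
  rownames(out) <- NULL
  attr(out, "method") <- "simplified_frequency_test"
  attr(out, "background_rate_per_mb") <- rate_mb
  out
}
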