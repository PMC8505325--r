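# Plain-text readers and writers for the formats the pipeline exchanges:
# expression TSV (genes x samples), MAF-like mutation TSV, SEG segment
# tables, clinical TSV, COSMIC-layout signature catalogs and IPS weight
# tables.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a TPM expression matrix
#'
#' TSV with gene identifiers in the first column and one column per sample.
#'
#' @param path File path.
#' @return Numeric matrix, genes x samples.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' @rdname read_expression_tsv
#' @param tpm Genes x samples matrix.
#' @export
write_expression_tsv <- function(tpm, path) {
  df <- data.frame(gene = rownames(tpm), tpm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read / write a MAF-like mutation table
#'
#' Tab-separated with at least `Tumor_Sample_Barcode`, `Chromosome`,
#' `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`; optional
#' `ref_count`, `alt_count`, `trinucleotide_context`, `Hugo_Symbol`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_maf <- function(path) {
  validate_maf(utils::read.delim(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
}

#' @rdname read_maf
#' @param muts MAF-like data.frame.
#' @export
write_maf <- function(muts, path) write_tsv(validate_maf(muts), path)

#' Read / write a SEG segment table
#'
#' Tab-separated `ID`, `chrom`, `loc.start`, `loc.end`, `num.mark`,
#' `seg.mean`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_seg <- function(path) {
  validate_seg(utils::read.delim(path, stringsAsFactors = FALSE,
                                 check.names = FALSE))
}

#' @rdname read_seg
#' @param segments Segment data.frame.
#' @export
write_seg <- function(segments, path) write_tsv(validate_seg(segments), path)

#' Read / write a clinical table
#'
#' Tab-separated `sample`, `time` (days), `event` (0/1), plus any
#' annotation columns (e.g. `tumor_type`, `group`).
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  validate_clinical(utils::read.delim(path, stringsAsFactors = FALSE,
                                      check.names = FALSE))
}

#' @rdname read_clinical
#' @param clinical Clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  write_tsv(validate_clinical(clinical), path)
}

#' Read a signature catalog in COSMIC layout
#'
#' First column (`Type`) holds channel labels such as `A[C>A]A` (SBS-96) or
#' `AC>CA` (DBS-78); each further column is one signature's channel
#' probabilities. Rows are reordered to the package's canonical channel
#' order; unknown or missing channels are an error. Columns are validated
#' non-negative and renormalized to sum exactly to 1 (tolerating small
#' rounding in the file).
#'
#' @param path File path.
#' @return Channels x signatures numeric matrix.
#' @export
read_signature_catalog <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- df[[1]]
  target <- if (all(sort(labels) == sort(sbs96_channels()))) sbs96_channels()
            else if (all(sort(labels) == sort(dbs78_channels()))) dbs78_channels()
            else stop("catalog channel labels are not the SBS-96 or DBS-78 set")
  m <- as.matrix(df[match(target, labels), -1, drop = FALSE])
  rownames(m) <- target
  storage.mode(m) <- "double"
  if (any(m < 0)) stop("negative signature probabilities")
  s <- colSums(m)
  if (any(abs(s - 1) > 0.01)) {
    stop("signature column(s) do not sum to 1: ",
         paste(colnames(m)[abs(s - 1) > 0.01], collapse = ", "))
  }
  sweep(m, 2, s, "/")
}

#' @rdname read_signature_catalog
#' @param catalog Channels x signatures matrix.
#' @export
write_signature_catalog <- function(catalog, path) {
  df <- data.frame(Type = rownames(catalog), catalog, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read an IPS weight table
#'
#' Tab-separated `gene`, `factor`, `category` (MHC/CP/EC/SC), `weight`.
#'
#' @param path File path.
#' @return data.frame.
#' @export
read_ips_weights <- function(path) {
  validate_ips_weights(utils::read.delim(path, stringsAsFactors = FALSE,
                                         check.names = FALSE))
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [generate_cohort()] result as the pipeline's input files:
#' `expression.tsv`, `mutations.maf.tsv`, `segments.seg`, `clinical.tsv`.
#'
#' @param cohort List from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    expression = file.path(dir, "expression.tsv"),
    mutations = file.path(dir, "mutations.maf.tsv"),
    segments = file.path(dir, "segments.seg"),
    clinical = file.path(dir, "clinical.tsv")
  )
  write_expression_tsv(cohort$expression$tpm, paths["expression"])
  write_maf(cohort$mutations, paths["mutations"])
  write_seg(cohort$segments, paths["segments"])
  write_clinical(cohort$clinical, paths["clinical"])
  paths
}
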