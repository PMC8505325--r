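#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")
SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

comp_base <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' SBS-96 channel labels
#'
#' The conventional 96 single-base-substitution channels: 6 pyrimidine-centred
#' substitution classes (C>A, C>G, C>T, T>A, T>C, T>G) crossed with the 4
#' possible 5' and 4 possible 3' flanking bases. Labels have the form
#' `"A[C>T]G"`. Ordering is substitution-class major, then 5' base, then 3'
#' base.
#'
#' @return Character vector of length 96.
#' @export
sbs96_channels <- function() {
  unlist(lapply(SBS_CLASSES, function(cls) {
    unlist(lapply(BASES, function(f) {
      paste0(f, "[", cls, "]", BASES)
    }))
  }))
}

# Canonical 78 doublet-base-substitution channels (SigProfiler/COSMIC
# convention). Non-canonical doublets are mapped in by reverse complement;
# this fixed lookup is the documented fixture for that mapping.
DBS78_CHANNELS <- c(
  "AC>CA", "AC>CG", "AC>CT", "AC>GA", "AC>GG", "AC>GT", "AC>TA", "AC>TG", "AC>TT",
  "AT>CA", "AT>CC", "AT>CG", "AT>GA", "AT>GC", "AT>TA",
  "CC>AA", "CC>AG", "CC>AT", "CC>GA", "CC>GG", "CC>GT", "CC>TA", "CC>TG", "CC>TT",
  "CG>AT", "CG>GC", "CG>GT", "CG>TA", "CG>TC", "CG>TT",
  "CT>AA", "CT>AC", "CT>AG", "CT>GA", "CT>GC", "CT>GG", "CT>TA", "CT>TC", "CT>TG",
  "GC>AA", "GC>AG", "GC>AT", "GC>CA", "GC>CG", "GC>TA",
  "TA>AT", "TA>CG", "TA>CT", "TA>GC", "TA>GG", "TA>GT",
  "TC>AA", "TC>AG", "TC>AT", "TC>CA", "TC>CG", "TC>CT", "TC>GA", "TC>GG", "TC>GT",
  "TG>AA", "TG>AC", "TG>AT", "TG>CA", "TG>CC", "TG>CT", "TG>GA", "TG>GC", "TG>GT",
  "TT>AA", "TT>AC", "TT>AG", "TT>CA", "TT>CC", "TT>CG", "TT>GA", "TT>GC", "TT>GG"
)

#' DBS-78 channel labels
#'
#' The 78 canonical doublet-base-substitution channels. All 144 possible
#' doublet substitutions (16 reference doublets x 9 alternates with both bases
#' changed) collapse onto this set by reverse complement.
#'
#' @return Character vector of length 78.
#' @export
dbs78_channels <- function() DBS78_CHANNELS

#' Classify a single-base substitution into its SBS-96 channel
#'
#' Purine-reference mutations are reverse-complemented so the mutated base is
#' a pyrimidine (C or T); the flanking bases swap and complement accordingly.
#' Vectorized over all four arguments.
#'
#' @param ref,alt Reference and alternate base (single characters).
#' @param fiveprime,threeprime Flanking bases immediately 5' and 3' of the
#'   mutated position on the reported strand.
#' @return Character vector of channel labels such as `"A[C>T]G"`; `NA` where
#'   any base is ambiguous (not A/C/G/T).
#' @export
classify_sbs96 <- function(ref, alt, fiveprime, threeprime) {
  ref <- toupper(ref); alt <- toupper(alt)
  fiveprime <- toupper(fiveprime); threeprime <- toupper(threeprime)
  n <- length(ref)
  stopifnot(length(alt) == n, length(fiveprime) == n, length(threeprime) == n)
  if (any(ref == alt, na.rm = TRUE)) {
    stop("classify_sbs96: ref and alt must differ for a substitution")
  }
  ok <- ref %in% BASES & alt %in% BASES &
    fiveprime %in% BASES & threeprime %in% BASES
  out <- rep(NA_character_, n)
  flip <- ok & ref %in% c("A", "G")
  r <- ref; a <- alt; f <- fiveprime; t3 <- threeprime
  r[flip] <- comp_base(ref[flip])
  a[flip] <- comp_base(alt[flip])
  f[flip] <- comp_base(threeprime[flip])
  t3[flip] <- comp_base(fiveprime[flip])
  out[ok] <- paste0(f[ok], "[", r[ok], ">", a[ok], "]", t3[ok])
  out
}

#' Classify a doublet substitution into its DBS-78 channel
#'
#' Doublets not in the canonical set are reverse-complemented into it.
#'
#' @param ref2,alt2 Two-base reference and alternate strings; both bases must
#'   change.
#' @return Character vector of canonical channel labels like `"CC>TT"`; `NA`
#'   for ambiguous bases.
#' @export
classify_dbs <- function(ref2, alt2) {
  ref2 <- toupper(ref2); alt2 <- toupper(alt2)
  n <- length(ref2)
  stopifnot(length(alt2) == n)
  valid <- grepl("^[ACGT]{2}$", ref2) & grepl("^[ACGT]{2}$", alt2)
  both_change <- valid &
    substr(ref2, 1, 1) != substr(alt2, 1, 1) &
    substr(ref2, 2, 2) != substr(alt2, 2, 2)
  if (any(valid & !both_change)) {
    stop("classify_dbs: both bases of a doublet substitution must change")
  }
  lab <- paste0(ref2, ">", alt2)
  out <- rep(NA_character_, n)
  hit <- valid & lab %in% DBS78_CHANNELS
  out[hit] <- lab[hit]
  need_rc <- valid & !hit
  if (any(need_rc)) {
    rc_lab <- paste0(revcomp(ref2[need_rc]), ">", revcomp(alt2[need_rc]))
    bad <- !(rc_lab %in% DBS78_CHANNELS)
    if (any(bad)) {
      stop("classify_dbs: doublet(s) not mappable to the canonical set: ",
           paste(unique(lab[need_rc][bad]), collapse = ", "))
    }
    out[need_rc] <- rc_lab
  }
  out
}
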