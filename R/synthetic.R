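# Synthetic cohorts with the statistical structure the downstream stages
# assume: copula-correlated GZMA/PRF1, UV-dominated SBS mixtures, injected
# kataegis showers and oscillating chromothriptic chromosomes, Beta-mixture
# VAFs, and group-dependent exponential survival. All randomness flows from
# the single integer seed in the config (Mersenne-Twister / Inversion).

SYN_GENOME <- setNames(rep(1e8, 10), paste0("chr", 1:10))

#' Synthetic genome chromosome sizes
#'
#' Ten 100-Mb chromosomes. Coordinates in the synthetic cohort are not tied
#' to any real assembly; this table plays the role of a `chrom.sizes` file.
#'
#' @return Named numeric vector of chromosome lengths in bp.
#' @export
synthetic_genome <- function() SYN_GENOME

#' Bundled fixture signature catalog
#'
#' Four signature-like probability vectors over the 96 SBS channels:
#' \describe{
#'   \item{UV}{dominant C>T at dipyrimidine contexts (5' C or T), mimicking
#'     the UV photoproduct signatures that dominate melanoma.}
#'   \item{clock_flat}{broad, flat-ish profile with mild C>T / T>C
#'     preference, mimicking the clock-like flat signature.}
#'   \item{deamination}{C>T at NpCpG contexts, mimicking 5-methylcytosine
#'     deamination.}
#'   \item{uniform}{1/96 everywhere; a null control.}
#' }
#' These are synthetic stand-ins for test and simulation use, not COSMIC
#' vectors; a real COSMIC-layout TSV can be dropped in via
#' [read_signature_catalog()].
#'
#' @return 96 x 4 matrix, rows named by channel, columns summing to 1.
#' @export
fixture_signature_catalog <- function() {
  ch <- sbs96_channels()
  five <- substr(ch, 1, 1)
  cls <- substr(ch, 3, 5)
  three <- substr(ch, 7, 7)

  uv <- ifelse(cls == "C>T" & five %in% c("C", "T"), 10,
        ifelse(cls == "C>T", 1, 0.05))
  clock <- ifelse(cls %in% c("C>T", "T>C"), 2, 1)
  deam <- ifelse(cls == "C>T" & three == "G", 12, 0.05)
  unif <- rep(1, 96)

  m <- cbind(UV = uv, clock_flat = clock, deamination = deam, uniform = unif)
  rownames(m) <- ch
  sweep(m, 2, colSums(m), "/")
}

#' Build a synthetic-cohort configuration
#'
#' Defaults emulate the structure of a UV-driven melanoma exome cohort:
#' tightly co-expressed GZMA/PRF1 (target Spearman rho 0.9), a mostly
#' metastatic cohort, exposure mixtures dominated by the UV-like process with
#' clock-like and deamination-like minorities, and CYT-group-dependent
#' survival hazards.
#'
#' @param n_samples Number of tumors (>= 4).
#' @param frac_metastatic Fraction labeled metastatic (rest primary).
#' @param cyt_rho Target Spearman correlation between GZMA and PRF1.
#' @param mean_mutations Mean somatic SNVs per sample (Poisson).
#' @param exposure_matrix Optional samples x signatures non-negative matrix;
#'   default rows are Dirichlet draws centred on (0.65, 0.20, 0.15, 0) over
#'   the fixture catalog (UV, clock_flat, deamination, uniform).
#' @param kataegis_spec `data.frame(sample, chrom, start, n_mutations,
#'   spacing)`; clusters injected verbatim. `n_mutations` must be >= 6.
#' @param chromothripsis_spec `data.frame(sample, chrom, n_oscillations,
#'   amplitude)`; amplitude must be >= 0.3.
#' @param mean_dbs Mean doublet substitutions per sample (emitted as two
#'   adjacent SNV records); 0 disables doublets.
#' @param frac_biclonal Fraction of samples with a second VAF clone.
#' @param survival_hazards Named per-day hazards for CYT groups
#'   (`high`, `mid`, `low`).
#' @param censor_hazard Independent exponential censoring hazard per day.
#' @param n_filler_genes Unstructured background genes in the expression
#'   universe, in addition to the immune panels.
#' @param seed Integer RNG seed; fixed seed gives byte-identical cohorts.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 470,
                          frac_metastatic = 0.78,
                          cyt_rho = 0.9,
                          mean_mutations = 300,
                          exposure_matrix = NULL,
                          kataegis_spec = NULL,
                          chromothripsis_spec = NULL,
                          mean_dbs = 2,
                          frac_biclonal = 0.3,
                          survival_hazards = c(high = 1 / 3000,
                                               mid = 1 / 2200,
                                               low = 1 / 1500),
                          censor_hazard = 1 / 2500,
                          n_filler_genes = 300,
                          seed = 1L) {
  stopifnot(n_samples >= 4, cyt_rho >= -1, cyt_rho <= 1,
            frac_metastatic >= 0, frac_metastatic <= 1,
            mean_mutations > 0, is.numeric(seed))
  seed <- as.integer(seed)
  samples <- sprintf("S%04d", seq_len(n_samples))

  if (is.null(exposure_matrix)) {
    set.seed(seed)
    # sparse Dirichlet (shape < 1 per process): tumors differ strongly in
    # which processes dominate, emulating the partly mutually exclusive
    # exposure patterns seen in melanoma cohorts
    base <- c(UV = 0.65, clock_flat = 0.20, deamination = 0.15, uniform = 0)
    conc <- 2
    g <- matrix(stats::rgamma(n_samples * 4, shape = rep(base * conc + 1e-9,
                                                         each = n_samples)),
                nrow = n_samples)
    exposure_matrix <- g / rowSums(g)
    colnames(exposure_matrix) <- names(base)
    rownames(exposure_matrix) <- samples
  }
  if (any(exposure_matrix < 0)) stop("exposures must be non-negative")
  if (!is.null(kataegis_spec)) {
    kataegis_spec <- as.data.frame(kataegis_spec)
    stopifnot(all(c("sample", "chrom", "start", "n_mutations", "spacing")
                  %in% names(kataegis_spec)))
    if (any(kataegis_spec$n_mutations < 6)) {
      stop("kataegis_spec: n_mutations must be >= 6")
    }
  }
  if (!is.null(chromothripsis_spec)) {
    chromothripsis_spec <- as.data.frame(chromothripsis_spec)
    stopifnot(all(c("sample", "chrom", "n_oscillations", "amplitude")
                  %in% names(chromothripsis_spec)))
    if (any(chromothripsis_spec$amplitude < 0.3)) {
      stop("chromothripsis_spec: amplitude must be >= 0.3")
    }
  }
  structure(list(
    n_samples = n_samples, samples = samples,
    frac_metastatic = frac_metastatic, cyt_rho = cyt_rho,
    mean_mutations = mean_mutations, exposure_matrix = exposure_matrix,
    kataegis_spec = kataegis_spec, chromothripsis_spec = chromothripsis_spec,
    mean_dbs = mean_dbs, frac_biclonal = frac_biclonal,
    survival_hazards = survival_hazards, censor_hazard = censor_hazard,
    n_filler_genes = n_filler_genes, genome = SYN_GENOME, seed = seed
  ), class = "cohort_config")
}

syn_seed <- function(config, offset) {
  set.seed((config$seed + offset) %% .Machine$integer.max,
           kind = "Mersenne-Twister", normal.kind = "Inversion")
}

panel_gene_universe <- function(n_filler) {
  panel <- unique(c("GZMA", "PRF1",
                    ifng_signature_genes(), expanded_immune_genes(),
                    default_ips_weights()$gene))
  c(panel, sprintf("GENE%04d", seq_len(n_filler)))
}

#' Generate a synthetic TPM expression matrix
#'
#' GZMA and PRF1 are drawn from a bivariate Gaussian copula whose latent
#' correlation is chosen so the population Spearman correlation equals
#' `cyt_rho` (r = 2 sin(pi * rho / 6)); marginals are log-normal TPM. All
#' other genes are independent log-normal.
#'
#' @param config A [cohort_config()].
#' @return List of class `melan_expression` with `tpm` (genes x samples
#'   matrix) and `samples` (data.frame with `sample`, `tumor_type`).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  syn_seed(config, 1L)
  n <- config$n_samples
  genes <- panel_gene_universe(config$n_filler_genes)
  if (!all(c("GZMA", "PRF1") %in% genes)) {
    stop("gene universe must contain GZMA and PRF1")
  }

  r <- 2 * sin(pi * config$cyt_rho / 6)
  z1 <- stats::rnorm(n)
  z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
  tpm <- matrix(0, nrow = length(genes), ncol = n,
                dimnames = list(genes, config$samples))
  tpm["GZMA", ] <- exp(log(20) + 1.1 * z1)
  tpm["PRF1", ] <- exp(log(15) + 1.1 * z2)
  other <- setdiff(genes, c("GZMA", "PRF1"))
  mu <- stats::rnorm(length(other), mean = log(10), sd = 1)
  tpm[other, ] <- exp(matrix(stats::rnorm(length(other) * n, mean = mu,
                                          sd = 0.8),
                             nrow = length(other)))

  n_met <- round(n * config$frac_metastatic)
  tumor_type <- rep("primary", n)
  tumor_type[sample.int(n, n_met)] <- "metastatic"
  structure(list(
    tpm = tpm,
    samples = data.frame(sample = config$samples, tumor_type = tumor_type,
                         stringsAsFactors = FALSE)
  ), class = "melan_expression")
}

# positions on one chromosome with pairwise gaps > min_gap: k sorted
# uniforms on the shrunk interval, then spread by i * (min_gap + 1)
draw_spaced_positions <- function(k, chrom_len, min_gap = 1e4) {
  if (k == 0) return(numeric(0))
  slack <- chrom_len - k * (min_gap + 1)
  if (slack <= 0) {
    stop("cannot place ", k, " mutations with >", min_gap,
         " bp spacing on a ", chrom_len, " bp chromosome")
  }
  u <- sort(ceiling(stats::runif(k, 0, slack)))
  u + (seq_len(k) - 1) * (min_gap + 1) + 1
}

channel_parts <- function(channel) {
  data.frame(
    five = substr(channel, 1, 1),
    ref = substr(channel, 3, 3),
    alt = substr(channel, 5, 5),
    three = substr(channel, 7, 7),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic somatic mutation table
#'
#' Each sample's SNV channels are drawn multinomially from its
#' exposure-weighted mixture of the catalog columns. Background positions are
#' spaced > 10 kb apart; kataegis clusters from `config$kataegis_spec` are
#' injected verbatim (consecutive positions at the given spacing, C>T
#' dominated). Doublet substitutions are emitted as two adjacent SNV records.
#' VAFs follow a Beta mixture of one or two clones; read counts are binomial
#' at Poisson depth.
#'
#' @param config A [cohort_config()].
#' @param catalog Channel x signature probability matrix (defaults to
#'   [fixture_signature_catalog()]); columns must match
#'   `config$exposure_matrix` columns.
#' @return MAF-like data.frame with columns `Tumor_Sample_Barcode`,
#'   `Chromosome`, `Start_Position`, `Reference_Allele`, `Tumor_Seq_Allele2`,
#'   `ref_count`, `alt_count`, `trinucleotide_context`, `Hugo_Symbol`.
#' @export
generate_mutations <- function(config, catalog = fixture_signature_catalog()) {
  stopifnot(inherits(config, "cohort_config"))
  expo <- config$exposure_matrix
  if (!identical(colnames(expo), colnames(catalog))) {
    stop("exposure_matrix columns must match catalog signature names")
  }
  if (any(rowSums(expo) == 0)) {
    stop("exposure row(s) summing to 0: ",
         paste(rownames(expo)[rowSums(expo) == 0], collapse = ", "))
  }
  syn_seed(config, 2L)
  ch <- rownames(catalog)
  genome <- config$genome
  genes <- synthetic_gene_table()
  ct_channels <- ch[substr(ch, 3, 5) == "C>T"]

  out <- vector("list", config$n_samples)
  for (i in seq_len(config$n_samples)) {
    s <- config$samples[i]
    mix <- as.vector(catalog %*% (expo[i, ] / sum(expo[i, ])))
    n_mut <- stats::rpois(1, config$mean_mutations)
    channels <- if (n_mut > 0) sample(ch, n_mut, replace = TRUE, prob = mix)
                else character(0)
    chroms <- sample(names(genome), n_mut, replace = TRUE,
                     prob = genome / sum(genome))
    pos <- numeric(n_mut)
    for (cc in unique(chroms)) {
      idx <- which(chroms == cc)
      pos[idx] <- draw_spaced_positions(length(idx), genome[[cc]])
    }
    df <- data.frame(Tumor_Sample_Barcode = rep(s, n_mut),
                     Chromosome = chroms, Start_Position = pos,
                     channel = channels, kataegis = FALSE,
                     stringsAsFactors = FALSE)

    # doublets: two adjacent C>T records (CC>TT dominated, UV-style)
    n_dbs <- if (config$mean_dbs > 0) stats::rpois(1, config$mean_dbs) else 0L
    if (n_dbs > 0) {
      dchrom <- sample(names(genome), n_dbs, replace = TRUE)
      dpos <- vapply(dchrom, function(cc)
        draw_spaced_positions(1, genome[[cc]]), numeric(1))
      d1 <- data.frame(Tumor_Sample_Barcode = s, Chromosome = dchrom,
                       Start_Position = dpos, channel = "C[C>T]C",
                       kataegis = FALSE, stringsAsFactors = FALSE)
      d2 <- d1; d2$Start_Position <- d1$Start_Position + 1
      d2$channel <- "C[C>T]A"
      df <- rbind(df, d1, d2)
    }

    if (!is.null(config$kataegis_spec)) {
      ks <- config$kataegis_spec[config$kataegis_spec$sample == s, ,
                                 drop = FALSE]
      if (nrow(ks) > 0) {
        for (j in seq_len(nrow(ks))) {
          nk <- ks$n_mutations[j]
          kpos <- ks$start[j] + (seq_len(nk) - 1) * ks$spacing[j]
          is_ct <- stats::runif(nk) < 0.89
          kch <- ifelse(is_ct,
                        sample(ct_channels, nk, replace = TRUE),
                        sample(setdiff(ch, ct_channels), nk, replace = TRUE))
          df <- rbind(df, data.frame(
            Tumor_Sample_Barcode = s, Chromosome = ks$chrom[j],
            Start_Position = kpos, channel = kch, kataegis = TRUE,
            stringsAsFactors = FALSE))
        }
      }
    }

    m <- nrow(df)
    if (m > 0) {
      parts <- channel_parts(df$channel)
      df$Reference_Allele <- parts$ref
      df$Tumor_Seq_Allele2 <- parts$alt
      df$trinucleotide_context <- paste0(parts$five, parts$ref, parts$three)

      # clone structure -> VAF -> read counts
      m1 <- stats::runif(1, 0.30, 0.50)
      biclonal <- stats::runif(1) < config$frac_biclonal
      m2 <- if (biclonal) stats::runif(1, 0.08, 0.22) else m1
      clone <- 1 + (stats::runif(m) < ifelse(biclonal, 0.4, 0))
      vmean <- ifelse(clone == 1, m1, m2)
      conc <- 60
      vaf <- stats::rbeta(m, vmean * conc, (1 - vmean) * conc)
      depth <- pmax(10L, stats::rpois(m, 80))
      df$alt_count <- stats::rbinom(m, depth, vaf)
      df$ref_count <- depth - df$alt_count
      df$Hugo_Symbol <- sample(genes$gene, m, replace = TRUE,
                               prob = genes$length_bp)
    } else {
      df <- empty_mutation_table()
    }
    out[[i]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
          "Reference_Allele", "Tumor_Seq_Allele2", "ref_count", "alt_count",
          "trinucleotide_context", "Hugo_Symbol", "kataegis")]
}

empty_mutation_table <- function() {
  data.frame(Tumor_Sample_Barcode = character(0), Chromosome = character(0),
             Start_Position = numeric(0), channel = character(0),
             kataegis = logical(0), Reference_Allele = character(0),
             Tumor_Seq_Allele2 = character(0),
             trinucleotide_context = character(0),
             alt_count = integer(0), ref_count = integer(0),
             Hugo_Symbol = character(0), stringsAsFactors = FALSE)
}

#' Synthetic gene table
#'
#' 200 synthetic genes with lengths spanning 2-200 kb, used to assign
#' mutations to genes and as the length input of the simplified
#' recurrently-mutated-gene test. Purely synthetic coordinates.
#'
#' @return data.frame with `gene`, `chrom`, `start`, `end`, `length_bp`.
#' @export
synthetic_gene_table <- function() {
  n <- 200
  lens <- round(2e3 * (1 + (seq_len(n) - 1) %% 20)^1.5)
  chrom <- paste0("chr", 1 + (seq_len(n) - 1) %% 10)
  start <- 1e6 + 2e6 * ((seq_len(n) - 1) %/% 10)
  data.frame(gene = sprintf("SYNG%03d", seq_len(n)), chrom = chrom,
             start = start, end = start + lens - 1, length_bp = lens,
             stringsAsFactors = FALSE)
}

#' Generate a synthetic copy-number segment table
#'
#' Background chromosomes carry 0-3 change points with |seg.mean| < 0.3.
#' Each `chromothripsis_spec` row replaces the named sample-chromosome with
#' an oscillating profile: `n_oscillations + 1` segments of 400 kb
#' alternating between +amplitude/2 and -amplitude/2, flanked by segments at
#' -amplitude/2.
#'
#' @param config A [cohort_config()].
#' @return SEG-style data.frame: `ID`, `chrom`, `loc.start`, `loc.end`,
#'   `num.mark`, `seg.mean`.
#' @export
generate_segments <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  syn_seed(config, 3L)
  genome <- config$genome
  ct <- config$chromothripsis_spec
  out <- list()
  for (i in seq_len(config$n_samples)) {
    s <- config$samples[i]
    for (cc in names(genome)) {
      L <- genome[[cc]]
      spec <- if (!is.null(ct)) ct[ct$sample == s & ct$chrom == cc, ,
                                   drop = FALSE] else NULL
      if (!is.null(spec) && nrow(spec) > 0) {
        n_osc <- spec$n_oscillations[1]
        amp <- spec$amplitude[1]
        seg_len <- 4e5
        start0 <- 2e7
        n_seg <- n_osc + 1
        starts <- start0 + (seq_len(n_seg) - 1) * seg_len
        ends <- starts + seg_len - 1
        means <- ifelse(seq_len(n_seg) %% 2 == 1, amp / 2, -amp / 2)
        df <- data.frame(
          ID = s, chrom = cc,
          loc.start = c(1, starts, ends[n_seg] + 1),
          loc.end = c(start0 - 1, ends, L),
          seg.mean = c(-amp / 2, means, -amp / 2),
          stringsAsFactors = FALSE)
      } else {
        n_cp <- sample(0:3, 1)
        bp <- sort(ceiling(stats::runif(n_cp, 2, L - 1)))
        starts <- c(1, bp)
        ends <- c(bp - 1, L)
        df <- data.frame(ID = s, chrom = cc, loc.start = starts,
                         loc.end = ends,
                         seg.mean = round(stats::runif(n_cp + 1, -0.2, 0.2), 4),
                         stringsAsFactors = FALSE)
      }
      df$num.mark <- pmax(5L, as.integer((df$loc.end - df$loc.start + 1) / 1e4))
      out[[length(out) + 1]] <- df
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")]
}

#' Generate synthetic survival outcomes
#'
#' Event times are exponential with the per-group hazard from
#' `config$survival_hazards`; censoring times are independent exponential
#' with `config$censor_hazard`.
#'
#' @param config A [cohort_config()].
#' @param groups Per-sample group labels (names of `survival_hazards`),
#'   in `config$samples` order.
#' @return data.frame with `sample`, `group`, `time` (days), `event`
#'   (1 death, 0 censored).
#' @export
generate_survival <- function(config, groups) {
  stopifnot(inherits(config, "cohort_config"),
            length(groups) == config$n_samples)
  haz <- config$survival_hazards[as.character(groups)]
  if (any(is.na(haz))) {
    stop("groups contain labels absent from survival_hazards: ",
         paste(setdiff(unique(groups), names(config$survival_hazards)),
               collapse = ", "))
  }
  syn_seed(config, 4L)
  t_event <- stats::rexp(config$n_samples, rate = haz)
  t_cens <- if (config$censor_hazard > 0)
    stats::rexp(config$n_samples, rate = config$censor_hazard)
  else rep(Inf, config$n_samples)
  data.frame(sample = config$samples, group = as.character(groups),
             time = round(pmin(t_event, t_cens), 2),
             event = as.integer(t_event <= t_cens),
             stringsAsFactors = FALSE)
}

#' Generate a complete synthetic cohort in memory
#'
#' Runs all four generators and CYT stratification so every downstream stage
#' has its inputs.
#'
#' @inheritParams generate_mutations
#' @return List with `expression`, `mutations`, `segments`, `clinical`,
#'   `cyt` (stratified CYT table) and the `config`.
#' @export
generate_cohort <- function(config, catalog = fixture_signature_catalog()) {
  expr <- generate_expression(config)
  cyt <- compute_cyt(expr)
  strat <- stratify_quartiles(cyt, strata = expr$samples$tumor_type)
  muts <- generate_mutations(config, catalog)
  segs <- generate_segments(config)
  surv_group <- ifelse(is.na(strat$group), "mid", strat$group)
  clin <- generate_survival(config, surv_group)
  clin$group <- strat$group
  clin$tumor_type <- expr$samples$tumor_type
  list(expression = expr, mutations = muts, segments = segs,
       clinical = clin, cyt = strat, config = config)
}
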