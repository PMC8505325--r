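# End-to-end orchestration: one validated config drives every stage
# (stratify -> spectra -> signatures -> kataegis -> SCNA -> chromothripsis
# -> heterogeneity -> survival -> IPS), writing per-stage TSVs, a JSON-lines
# log and a deterministic manifest with input/output checksums.

pipeline_defaults <- function() {
  list(
    pseudocount = 0.01,
    stratify_by = "tumor_type",
    kataegis = list(min_mutations = 6, max_imd = 1000),
    scna = list(amp_cut = 0.6, del_cut = -0.4, bin_size = 1e6,
                n_permutations = 199, q_threshold = 0.1),
    chromothripsis = list(min_switches = 20, min_lr = 8,
                          signal_distance = 0.3, min_segment_size = 1e4,
                          window = 5e7, step = 1e7,
                          gain_cut = 0.15, loss_cut = -0.15),
    nmf = list(rank_min = 2, rank_max = 4, n_restarts = 10,
               max_iter = 500, stability_threshold = 0.8, min_cosine = 0.8),
    smg = list(q_threshold = 0.1),
    heterogeneity = list(max_clusters = 4)
  )
}

check_keys <- function(x, allowed, path = "config") {
  unknown <- setdiff(names(x), allowed)
  if (length(unknown) > 0) {
    stop("unknown ", path, " key(s): ", paste(unknown, collapse = ", "))
  }
  invisible(x)
}

merge_params <- function(defaults, user, path = "params") {
  check_keys(user, names(defaults), path)
  for (nm in names(user)) {
    if (is.list(defaults[[nm]])) {
      defaults[[nm]] <- merge_params(defaults[[nm]], user[[nm]],
                                     paste0(path, "$", nm))
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a pipeline configuration
#'
#' YAML with top-level keys `inputs` (paths: `expression`, `mutations`,
#' `segments`, `clinical`, optional `signature_catalog`, `ips_weights`,
#' `gene_table`), `params` (any subset of the stage parameters; unknown
#' keys are a hard error), `seed` and `out_dir`. Defaults encode the
#' conventional thresholds: 0.25 quartiles, SCNA cuts 0.6 / -0.4, kataegis
#' 6 mutations / 1000 bp, chromothripsis 20 switches / LR 8 / 10 kb / 0.3
#' with display cuts +-0.15, FDR 0.1.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return Validated config list with defaults filled in.
#' @export
load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  check_keys(config, c("inputs", "params", "seed", "out_dir"))
  if (is.null(config$inputs)) stop("config needs an 'inputs' section")
  check_keys(config$inputs,
             c("expression", "mutations", "segments", "clinical",
               "signature_catalog", "ips_weights", "gene_table"),
             "inputs")
  for (req in c("expression", "mutations", "segments", "clinical")) {
    p <- config$inputs[[req]]
    if (is.null(p)) stop("inputs$", req, " is required")
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  config$params <- merge_params(pipeline_defaults(),
                                if (is.null(config$params)) list()
                                else config$params)
  if (is.null(config$seed)) config$seed <- 1L
  config$seed <- as.integer(config$seed)
  if (is.null(config$out_dir)) stop("config needs out_dir")
  config
}

fmt_num <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) df[[nm]] <- signif(df[[nm]], 10)
  }
  df
}

#' Run the full cytolytic-subgroup analysis pipeline
#'
#' Executes all stages from one config and writes per-stage TSVs plus
#' `manifest.tsv` (stage, parameter echo, output files and their MD5
#' checksums — byte-identical across reruns of the same config and seed)
#' and `log.jsonl`. The IPS stage is optional: a failure there is a warning
#' and the stage is skipped; failures in any other stage abort.
#'
#' @param config YAML path or config list (see [load_run_config()]).
#' @return Invisible list with the per-stage results and the manifest.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.jsonl")
  unlink(log_path)
  manifest <- list()
  results <- list()
  t0 <- Sys.time()

  log_line <- function(...) {
    rec <- list(...)
    rec$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 3)
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = log_path,
        append = TRUE, sep = "")
  }
  record <- function(stage, params, files) {
    manifest[[stage]] <<- data.frame(
      stage = stage,
      params = as.character(jsonlite::toJSON(params, auto_unbox = TRUE)),
      output = basename(files),
      md5 = unname(tools::md5sum(files)),
      stringsAsFactors = FALSE)
    log_line(stage = stage, status = "ok", outputs = basename(files))
  }

  log_line(stage = "config", status = "resolved",
           config = cfg[c("inputs", "params", "seed")])

  expr <- read_expression_tsv(cfg$inputs$expression)
  muts <- read_maf(cfg$inputs$mutations)
  segs <- read_seg(cfg$inputs$segments)
  clin <- read_clinical(cfg$inputs$clinical)
  catalog <- if (!is.null(cfg$inputs$signature_catalog)) {
    read_signature_catalog(cfg$inputs$signature_catalog)
  } else fixture_signature_catalog()

  p <- cfg$params

  # 1. CYT stratification
  cyt <- compute_cyt(expr, pseudocount = p$pseudocount)
  strata <- if (identical(p$stratify_by, "tumor_type") &&
                "tumor_type" %in% names(clin)) {
    clin$tumor_type[match(cyt$sample, clin$sample)]
  } else NULL
  cyt <- stratify_quartiles(cyt, strata = strata)
  rho <- coexpression_rho(expr, "GZMA", "PRF1")
  cyt_path <- file.path(out_dir, "cyt.tsv")
  write_tsv(fmt_num(cyt), cyt_path)
  results$cyt <- cyt
  groups <- setNames(cyt$group, cyt$sample)
  two_groups <- groups[groups %in% c("high", "low")]
  record("cyt", list(pseudocount = p$pseudocount,
                     stratify_by = p$stratify_by,
                     gzma_prf1_rho = round(rho$rho, 4)), cyt_path)

  # 2. Mutation spectra
  sbs <- build_sbs96_matrix(muts)
  dbs <- build_dbs78_matrix(muts)
  spec <- substitution_spectrum(
    muts, groups = if (length(unique(two_groups)) == 2) two_groups else NULL)
  smg <- smg_frequency_test(muts, synthetic_gene_table(),
                            q_threshold = p$smg$q_threshold)
  f1 <- file.path(out_dir, "sbs96_matrix.tsv")
  f2 <- file.path(out_dir, "dbs78_matrix.tsv")
  f3 <- file.path(out_dir, "substitution_spectrum.tsv")
  f4 <- file.path(out_dir, "smg.tsv")
  write_signature_catalog(sbs, f1)
  write_signature_catalog(dbs, f2)
  write_tsv(fmt_num(data.frame(class = rownames(spec$fractions),
                               spec$fractions, check.names = FALSE)), f3)
  write_tsv(fmt_num(smg), f4)
  results$spectra <- list(sbs96 = sbs, dbs78 = dbs, spectrum = spec,
                          smg = smg)
  record("spectra", list(q_threshold = p$smg$q_threshold,
                         method = attr(smg, "method")), c(f1, f2, f3, f4))

  # 3. Signature inference
  nmf <- extract_signatures_nmf(
    sbs, rank_range = seq(p$nmf$rank_min, p$nmf$rank_max),
    n_restarts = p$nmf$n_restarts, seed = cfg$seed,
    max_iter = p$nmf$max_iter,
    stability_threshold = p$nmf$stability_threshold)
  matches <- match_to_reference(nmf$signatures, catalog,
                                min_cosine = p$nmf$min_cosine)
  f1 <- file.path(out_dir, "signatures_denovo.tsv")
  f2 <- file.path(out_dir, "exposures.tsv")
  f3 <- file.path(out_dir, "signature_matches.tsv")
  write_signature_catalog(round(nmf$signatures, 8), f1)
  write_tsv(fmt_num(data.frame(sample = rownames(nmf$exposures),
                               nmf$exposures, check.names = FALSE)), f2)
  write_tsv(fmt_num(matches), f3)
  results$signatures <- c(nmf, list(matches = matches))
  record("signatures", list(rank = nmf$rank,
                            n_restarts = p$nmf$n_restarts,
                            stability_threshold = p$nmf$stability_threshold),
         c(f1, f2, f3))

  # 4. Kataegis
  events <- call_kataegis(muts, min_mutations = p$kataegis$min_mutations,
                          max_imd = p$kataegis$max_imd)
  rain <- rainfall_data(muts)
  f1 <- file.path(out_dir, "kataegis_events.tsv")
  f2 <- file.path(out_dir, "rainfall.tsv")
  write_tsv(fmt_num(events), f1)
  write_tsv(fmt_num(rain), f2)
  results$kataegis <- list(events = events,
                           summary = kataegis_summary(events, groups))
  record("kataegis", p$kataegis, c(f1, f2))

  # 5. SCNA burden and recurrence
  labeled <- threshold_scna(segs, amp_cut = p$scna$amp_cut,
                            del_cut = p$scna$del_cut)
  burden <- scna_burden(
    labeled, groups = if (length(unique(two_groups)) == 2) two_groups
                      else NULL)
  genome <- infer_genome(segs)
  gscore <- recurrence_gscore(labeled, genome = genome,
                              bin_size = p$scna$bin_size,
                              n_permutations = p$scna$n_permutations,
                              seed = cfg$seed,
                              q_threshold = p$scna$q_threshold)
  f1 <- file.path(out_dir, "scna_burden.tsv")
  f2 <- file.path(out_dir, "gscore.tsv")
  write_tsv(fmt_num(burden$per_sample), f1)
  write_tsv(fmt_num(gscore), f2)
  results$scna <- list(burden = burden, gscore = gscore)
  record("scna", p$scna, c(f1, f2))

  # 6. Chromothripsis
  gene_table <- if (!is.null(cfg$inputs$gene_table)) {
    utils::read.delim(cfg$inputs$gene_table, stringsAsFactors = FALSE)
  } else NULL
  ct <- call_chromothripsis(
    segs, genome = genome, min_switches = p$chromothripsis$min_switches,
    min_lr = p$chromothripsis$min_lr,
    signal_distance = p$chromothripsis$signal_distance,
    min_segment_size = p$chromothripsis$min_segment_size,
    window = p$chromothripsis$window, step = p$chromothripsis$step,
    gain_cut = p$chromothripsis$gain_cut,
    loss_cut = p$chromothripsis$loss_cut, gene_table = gene_table)
  f1 <- file.path(out_dir, "chromothripsis_calls.tsv")
  f2 <- file.path(out_dir, "chromothripsis_summary.tsv")
  write_tsv(fmt_num(ct), f1)
  write_tsv(fmt_num(chromothripsis_group_summary(ct, groups)), f2)
  results$chromothripsis <- ct
  record("chromothripsis", p$chromothripsis, c(f1, f2))

  # 7. Heterogeneity
  het <- vaf_profile(muts, max_clusters = p$heterogeneity$max_clusters)
  f1 <- file.path(out_dir, "heterogeneity.tsv")
  write_tsv(fmt_num(het), f1)
  results$heterogeneity <- het
  record("heterogeneity", p$heterogeneity, f1)

  # 8. Survival
  clin_g <- clin
  clin_g$group <- groups[clin$sample]
  km <- km_estimate(clin_g[!is.na(clin_g$group), ])
  lr <- tryCatch(logrank_test(clin_g, "high", "low"),
                 error = function(e) list(chisq = NA, p = NA))
  syn <- synergy_analysis(expr, clin)
  f1 <- file.path(out_dir, "km_curves.tsv")
  f2 <- file.path(out_dir, "survival_tests.tsv")
  write_tsv(fmt_num(km), f1)
  tests <- rbind(
    data.frame(contrast = "cyt_high_vs_low", n_in = sum(groups == "high",
                                                        na.rm = TRUE),
               n_out = sum(groups == "low", na.rm = TRUE),
               chisq = lr$chisq, p = lr$p, stringsAsFactors = FALSE),
    syn)
  write_tsv(fmt_num(tests), f2)
  results$survival <- list(km = km, tests = tests)
  record("survival", list(contrasts = tests$contrast), c(f1, f2))

  # 9. IPS (optional stage)
  ips_res <- tryCatch({
    weights <- if (!is.null(cfg$inputs$ips_weights)) {
      read_ips_weights(cfg$inputs$ips_weights)
    } else default_ips_weights()
    ips <- compute_ips(expr, weights)
    f1 <- file.path(out_dir, "ips.tsv")
    write_tsv(fmt_num(ips), f1)
    record("ips", list(n_weight_genes = nrow(weights)), f1)
    ips
  }, error = function(e) {
    warning("IPS stage skipped: ", conditionMessage(e))
    log_line(stage = "ips", status = "skipped",
             reason = conditionMessage(e))
    NULL
  })
  results$ips <- ips_res

  manifest_df <- do.call(rbind, manifest)
  rownames(manifest_df) <- NULL
  write_tsv(manifest_df, file.path(out_dir, "manifest.tsv"))
  results$manifest <- manifest_df
  invisible(results)
}

# chromosome lengths implied by a segment table (used when no chrom.sizes
# is supplied): each chromosome ends at its last segment end
infer_genome <- function(segments) {
  L <- tapply(segments$loc.end, segments$chrom, max)
  setNames(as.numeric(L), names(L))
}
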