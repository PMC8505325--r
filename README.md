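# melanomics

Genomic characterization of tumor cohorts stratified by **immune cytolytic
activity (CYT)** — the geometric mean of *GZMA* (granzyme A) and *PRF1*
(perforin) expression,

```
CYT_s = sqrt((GZMA_s + c) * (PRF1_s + c)),   c = 0.01 TPM
```

the transcript-level readout of how actively cytotoxic T and NK cells are
killing tumor cells. Melanoma cohorts split into CYT-high and CYT-low
quartiles differ in far more than immune infiltration, and this package
implements the full downstream comparison as a tested, reusable pipeline
for anyone analyzing expression + mutation + copy-number cohorts:

- **Stratification** — quartile CYT groups within tumor-type strata;
  Spearman co-expression; mean-z gene-set scores (IFN-γ and
  expanded-immune panels included); Mann–Whitney group tests with BH or
  Bonferroni adjustment.
- **Mutation spectra** — SBS-96 and DBS-78 context matrices with
  pyrimidine strand collapse and adjacent-pair doublet extraction; 6-class
  spectra; a clearly-labeled simplified recurrently-mutated-gene frequency
  test.
- **Mutational signatures** — de novo KL-divergence NMF with
  restart-clustering stability for rank selection, cosine matching to a
  COSMIC-layout reference catalog, NNLS exposure attribution, per-group
  contribution tests, presence/absence co-occurrence.
- **Kataegis** — showers of ≥ 6 consecutive mutations with mean
  inter-mutation distance ≤ 1 kb, called identically to an exhaustive
  brute-force enumeration; rainfall-plot export.
- **Copy number** — amplification/deletion thresholds (≥ 0.6 / ≤ −0.4),
  per-sample SCNA burden, and a GISTIC-like recurrence G-score with a
  circular-permutation FDR.
- **Chromothripsis-like regions** — ≥ 20 copy-number status switches and
  Poisson log10 likelihood ratio ≥ 8 in sliding windows, after 10-kb /
  0.3-signal-distance profile simplification; ±0.15 gain/loss annotation
  and gene overlap.
- **Heterogeneity** — MATH score (100 × 1.4826 × MAD/median of VAFs) and
  BIC-selected Gaussian-mixture VAF clustering.
- **Survival** — Kaplan–Meier with Greenwood errors, log-rank
  (Mantel–Cox), and the two-gene synergy contrasts (both-high / both-low
  vs rest).
- **Immunophenoscore** — sample-wise z-scores → weighted factor and
  category scores (MHC, CP, EC, SC) → the 0–10 IPS scale.
- **Synthetic cohorts** — a seeded generator producing expression
  (copula-correlated GZMA/PRF1), MAF-like mutations (signature mixtures,
  planted kataegis, Beta-mixture VAFs), SEG copy-number (planted
  oscillating chromosomes), and clinical tables, so the whole pipeline
  runs with no external data.

## Worked example

```r
library(melanomics)

cfg <- cohort_config(
  n_samples = 100, mean_mutations = 150, seed = 42,
  kataegis_spec = data.frame(sample = "S0007", chrom = "chr2",
                             start = 5e6, n_mutations = 10, spacing = 400),
  chromothripsis_spec = data.frame(sample = "S0010", chrom = "chr4",
                                   n_oscillations = 25, amplitude = 0.5))
cohort <- generate_cohort(cfg)

head(cohort$cyt, 3)
#>   sample       CYT cyt_log2 tumor_type group
#> 1  S0001 13.691902 3.775251 metastatic   mid
#> 2  S0002  3.343413 1.741322 metastatic   low
#> 3  S0003  6.035062 2.593369 metastatic   low

coexpression_rho(cohort$expression)$rho   # target rho was 0.9
#> [1] 0.9206001

call_kataegis(cohort$mutations)[, 1:6]    # the planted shower, verbatim
#>   sample chrom start     end n_mutations mean_imd
#> 1  S0007  chr2 5e+06 5003600          10      400

call_chromothripsis(cohort$segments)[, c("sample", "chrom",
                                         "n_switches", "log10_lr")]
#>   sample chrom n_switches log10_lr
#> 1  S0010  chr4         26 19.52621

sbs <- build_sbs96_matrix(cohort$mutations)
nmf <- extract_signatures_nmf(sbs, rank_range = 2:4, n_restarts = 10,
                              seed = 1)
match_to_reference(nmf$signatures, fixture_signature_catalog())
#>   denovo   reference    cosine
#> 1    DN1          UV 0.9979392
#> 2    DN2 deamination 0.9981769
#> 3    DN3  clock_flat 0.9253371
```

The CYT table shows each sample's cytolytic index, its log2, and its
quartile group within its tumor-type stratum. The kataegis caller returns
exactly the planted 10-mutation, 400-bp-spacing shower; the chromothripsis
detector flags exactly the planted oscillating chromosome (26 switches,
log10 LR ≈ 19.5, both far over the 20 / 8 thresholds); and NMF at the
selected rank 3 matches all three planted signature processes at cosine
0.93–1.00.

The same analysis runs from files via one YAML config
(`run_pipeline("config.yaml")`, stages written as TSVs with a
checksummed manifest) or per stage from a shell through
`inst/cli/cyt.R`.

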