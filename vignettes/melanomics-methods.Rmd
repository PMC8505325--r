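---
title: "Methods: cytolytic-subgroup genomics of skin melanoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cytolytic-subgroup genomics of skin melanoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melanomics)
```

## The analysis in one paragraph

Cytotoxic T and NK cells kill tumor cells by delivering granzyme A (GZMA)
through perforin (PRF1) pores, so the two transcripts together index the
intratumoral immune cytolytic activity, CYT. `melanomics` stratifies a
melanoma cohort by CYT and asks how the genomic landscape differs between
the most and least cytolytic tumors: single- and doublet-base substitution
spectra, de novo mutational signatures, kataegis showers, copy-number burden
and recurrence, chromothripsis-like shattering, intra-tumor heterogeneity,
survival, and the immunophenoscore. A seeded synthetic-cohort generator
provides inputs with the statistical structure each stage assumes, so every
stage is testable end to end without any external download.

## CYT and stratification

Per sample, `CYT = sqrt((GZMA + c)(PRF1 + c))` on the TPM scale with a
pseudocount `c = 0.01` TPM so a single zero transcript does not annihilate
the geometric mean; `log2(CYT)` is reported alongside. The pseudocount is a
package choice (0.01 TPM is an order of magnitude below meaningful
expression) and configurable.

Stratification marks samples at or above the 75th CYT percentile as
CYT-high and at or below the 25th as CYT-low, within each tumor-type
stratum (primary / metastatic) by default so the extreme groups keep the
cohort's histology admixture; a pooled mode exists. Percentiles use linear
interpolation (type 7). Ties that span both boundaries fall to `mid`,
keeping the extreme groups conservative rather than inflating them; strata
under 4 samples are skipped with a warning. For tie-free cohorts divisible
by four, the extreme groups are exactly n/4 each.

## Mutation spectra

Substitutions are collapsed to the pyrimidine strand and classified into
the conventional 96 channels (6 substitution classes x 16 trinucleotide
contexts). Two same-sample substitutions at adjacent positions are one
doublet event, classified into the canonical 78 DBS channels (reverse
complement maps the other 66 orientations in); runs of three or more
adjacent substituted positions are excluded from both matrices and tallied,
matching the convention of the standard matrix generators. Context comes
from the `trinucleotide_context` column when present, else from a reference
FASTA (1-based MAF coordinates).

The recurrently-mutated-gene test is deliberately minimal: a one-sided
binomial test of the number of samples hitting a gene against
`1 - exp(-r L)`, with `r` the cohort-median per-Mb rate over the surveyed
territory and `L` the gene length, BH-adjusted at q < 0.1. It carries a
`simplified_frequency_test` label precisely because it ignores the
expression/replication-timing covariates a full driver test uses; it ranks
recurrence, nothing more.

## Signature inference

De novo extraction is KL-divergence NMF with multiplicative updates
(restart-randomized, 1000 iterations cap, relative-change tolerance 1e-6).
For each candidate rank the restart signatures are clustered by
partitioning around medoids on cosine dissimilarity. The stability of a
rank is the silhouette width of its *weakest* cluster: a rank whose extra
signature cannot be reproduced across restarts is overfitting even when the
other clusters are tight, so the minimum — not the mean, which is also
reported — decides. The selected rank is the largest with stability at or
above 0.8. Consensus signatures are cluster medoids polished by a short
additional run of multiplicative updates; exposures are per-sample
non-negative least squares rescaled to observed mutation counts. Matching
against a reference catalog (COSMIC-layout TSV) is greedy one-to-one on
cosine similarity with a 0.8 floor, and channel-label alignment is enforced
rather than assumed.

Planted-mixture recovery has a real identifiability limit worth stating:
when every sample carries all processes in similar proportions, distinct
factorizations fit the counts equally well and the flat, clock-like
signature is recovered poorly no matter how hard the optimizer works. Real
melanoma cohorts are not in that regime — UV-dominated tumors and
clock-dominated tumors coexist, and UV exposures are reported as partly
mutually exclusive with the clock-like ones — so the generator draws
exposures from a sparse Dirichlet (shape < 1 per process), under which the
factorization is identifiable and recovery is reliable.

## Kataegis

An event is at least 6 consecutive same-sample, same-chromosome mutations
whose mean successive inter-mutation distance is at most 1000 bp. The two
thresholds leave the maximality rule open; the package emits events left to
right, taking from the current scan point the qualifying window with the
smallest start and the largest end and resuming past it. Events therefore
never overlap, each satisfies both thresholds verbatim (a blanket merge of
overlapping windows would not guarantee the mean-distance bound), and the
caller is checkable against an exhaustive window enumeration, which the
test suite does on random geometries. No substitution-class constraint is
imposed; the class composition of each event is reported instead.

## Copy number

Segments with seg.mean >= 0.6 are amplifications and <= -0.4 deletions —
the conventional reading of the asymmetric somatic-vs-normal segment-mean
cutoffs; per-sample counts feed a Mann-Whitney group comparison. Recurrence
uses a simplified, GISTIC-like G-score: the genome is tiled into 1-Mb bins
and a bin's score is the overlap-weighted sum of |seg.mean| over aberrant
segments across samples — amplitude times frequency. Its null distribution
comes from circular permutation of each sample's segments along each
chromosome, which preserves every sample's segment-length and amplitude
multiset while destroying cross-sample positional recurrence; empirical
p-values use (1 + b)/(n + 1) and are BH-adjusted. This is not GISTIC2 (no
peak deconvolution, no arm/focal separation) and outputs say so.

## Chromothripsis-like detection

Profiles are first simplified: segments under 10 kb are dropped and
adjacent segments closer than 0.3 in seg.mean are merged length-weighted to
a fixed point, so every surviving boundary is a genuine copy-number status
switch. A 50-Mb window sliding in 10-Mb steps qualifies when it contains at
least 20 switches and a log10 likelihood ratio of at least 8; overlapping
qualifying windows merge into maximal regions. The likelihood-ratio
statistic is a package choice (the tool the thresholds come from does not
publish its internals): a Poisson comparison of the local breakpoint rate
k/W against the sample's genome-wide rate K/G,
`log10 LR = (k ln(lambda1/lambda0) - W(lambda1 - lambda0)) / ln 10`,
which is closed-form, monotone in the local excess, and oracle-checkable.
Gains and losses inside a region are annotated at the +-0.15 display
thresholds — a different role than the 0.3 merge distance, hence the
different value — and genes attach by interval overlap with a user table.

## Heterogeneity

VAF is alt/(alt+ref). MATH is 100 x 1.4826 x MAD/median of a sample's
VAFs; the 1.4826 factor is the Gaussian-consistency constant of the
original MATH definition. Mode counting fits 1-D Gaussian mixtures for k =
1..4 selected by BIC (mclust; hierarchical initialization makes it
deterministic); fewer than 5 mutations force k = 1 flagged low-confidence.

## Survival and synergy

Kaplan-Meier curves carry Greenwood standard errors; group differences use
the two-group log-rank (Mantel-Cox) test with p from chi-square(1). The
two-gene synergy analysis dichotomizes each gene at its median (quartile
cutpoints available) and reports four log-rank contrasts: each gene alone,
both-high vs the rest, both-low vs the rest, with raw p-values by default
as in the source analyses.

## Immunophenoscore

Gene z-scores are taken across samples (sample sd, n-1; configurable).
Factor scores are weighted means of member-gene z-scores, category scores
(MHC, CP, EC, SC) are unweighted means of their factors, and the aggregate
AZ is the sum of the four categories with suppressive weights already
negative in the table. IPS is 0 for AZ <= 0, 10 for AZ >= 3, else AZ x 10/3
rounded half-up — the published 0-10 scaling. The shipped weight table
(`ips_weights_synthetic.tsv`) is a synthetic working example, because the
published gene/weight assignments are not reprinted here; any table with
columns gene/factor/category/weight drops in. On unstructured synthetic
expression most samples score 0 — without planted immune structure AZ
rarely exceeds 0, which is the honest output, not a defect.

## The synthetic cohort: what it does and does not emulate

The generator emulates exactly the dependencies the stages test: a Gaussian
copula ties GZMA to PRF1 at Spearman rho 0.9 (latent r = 2 sin(pi rho/6));
all other genes are independent log-normals. Mutation channels are
multinomial draws from exposure-weighted mixtures of a bundled 4-vector
fixture catalog (UV-like dipyrimidine C>T, clock-like flat, NpCpG
deamination-like, uniform control — synthetic stand-ins, not COSMIC
vectors). Background positions keep > 10 kb spacing so planted kataegis
clusters are the only sub-kb structure; doublets are emitted as adjacent
record pairs. Copy-number backgrounds have at most 3 change points per
chromosome inside +-0.3; planted chromothriptic chromosomes oscillate in
400-kb segments at +-amplitude/2. VAFs come from one or two Beta clones;
survival times are exponential per CYT group with independent exponential
censoring. The genome is ten 100-Mb chromosomes.

What it does not emulate — and what green tests therefore do not show —
includes realistic gene models and coordinates, caller artifacts and
coverage-dependent VAF noise, purity/ploidy distortion of seg.mean,
correlated immune gene programs, and any coupling between expression and
mutation load. Passing tests demonstrate that the algorithms recover known
planted structure under the stated statistical assumptions, not that the
pipeline reproduces any specific patient cohort's numbers.

## Problem sizes and numerical choices

Tests and the acceptance script run cohorts of 4-200 samples with 40-500
mutations per sample, 20 restarts for NMF at ranks 2-4, 199-399
permutations for the G-score null, and 1000-2000 replicates for the
type-I-error calibrations; these sizes were chosen so the planted effects
are comfortably detectable while the whole suite stays desk-scale.
Determinism everywhere flows from one integer seed (Mersenne-Twister,
inversion normals); reruns of the pipeline produce byte-identical
manifests. Degenerate inputs are handled explicitly: zero vectors error in
cosine similarity, zero-median VAFs error in MATH, zero-variance genes get
z = 0 with a warning, all-censored groups error in the log-rank test, and
an empty mutation table yields empty, well-typed outputs.
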