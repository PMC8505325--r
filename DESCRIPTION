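Package: melanomics
Title: Cytolytic-Subgroup Genomics of Skin Melanoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stratifies tumor cohorts by immune cytolytic activity (CYT, the
    geometric mean of GZMA and PRF1 expression) and characterizes each
    subgroup's genomic landscape: SBS-96/DBS-78 mutation spectra, de novo
    mutational-signature extraction by KL-divergence NMF with cosine matching
    to a reference catalog, kataegis calling from inter-mutation distances,
    copy-number burden and a simplified recurrence G-score, chromothripsis-like
    oscillation detection, MATH-score intra-tumor heterogeneity, Kaplan-Meier
    survival synergy of the two cytolytic genes, and the 0-10 immunophenoscore.
    Ships a seeded synthetic-cohort generator emulating the statistical
    structure of UV-driven melanoma exomes so the full pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    mclust,
    cluster,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
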