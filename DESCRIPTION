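Package: dnamdrift
Title: DNA Methylation Age Drift Stratification of Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts DNA methylation (DNAm) age from CpG beta values with
    linear epigenetic clock models through an invertible age transform,
    classifies per-sample DNAm age drift (acceleration/deceleration) against
    chronological age, and selects the high-deceleration (hDNAmad) tumor
    subgroup by a dual-clock tercile rule. Downstream characterization of the
    resulting groups is provided: single-sample gene-set enrichment (ssGSEA)
    scoring of expression signature panels, differential methylation probe
    calling with clock-CpG exclusion and genomic-region composition,
    aneuploidy score and tumor mutation burden, two-group contingency tests,
    and Kaplan-Meier/log-rank/Cox survival association. A seed-reproducible
    synthetic cohort generator emulates the assumed data structure so the
    full pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
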