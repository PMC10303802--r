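# dnamdrift

Tumors often show striking drift between their DNA-methylation (DNAm) age —
the age predicted from CpG beta values by a linear epigenetic clock — and
the patient's chronological age. `dnamdrift` implements the full
stratification workflow built around that observation for tumor cohorts:
predict DNAm age with two clocks, classify per-sample drift, select the
high-deceleration (**hDNAmad**) subgroup with a dual-clock tercile rule, and
characterize the resulting groups molecularly and clinically. A
seed-reproducible synthetic-cohort generator makes every stage testable
without any external download.

It is aimed at computational epigenetics researchers working with
450K-style methylation matrices, expression matrices and standard clinical
tables.

## The model

A clock is a linear predictor over CpG probes with an invertible age
transform *F*:

    DNAm age = F^-1( alpha_0 + sum_i alpha_i * beta_i )

Horvath-style clocks use the piecewise calibration
F(a) = log(a+1) − log(A+1) for a ≤ A and (a − A)/(A+1) for a > A (adult age
A = 20); PhenoAge-style clocks are linear in years (identity transform).
Per sample and clock, the deviation is `dnam_age − chron_age`; with band
*b* = 3 yr a sample is **matched** (|dev| < b), **DNAmaa** (dev ≥ b,
acceleration) or **DNAmad** (dev ≤ −b, deceleration). The hDNAmad rule
takes the DNAmad candidates of the primary clock, keeps the most
decelerated `floor(fraction * n_candidates)` (fraction 1/3 by default —
403 candidates give 134), and labels positive those the second clock also
calls DNAmad.

Downstream group characterization: ssGSEA signature scoring (myeloid,
T-effector, cell-cycle, telomerase panels built in), rank-based
differential expression (|log2 FC| > 1.5, BH-adjusted p < 0.05),
differential methylation probes (|Δβ| > 0.20, adjusted p < 0.05, clock
CpGs excluded) with CpG-island/gene-region composition, aneuploidy score
(count of altered chromosome arms), tumor mutation burden (non-silent
mutations per Mb), 2×2 contingency tests, and Kaplan–Meier / log-rank /
Cox survival association.

## Worked example

```r
library(dnamdrift)

cfg    <- cohort_config(n_samples = 200, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> Synthetic cohort: 200 samples, 500 probes, 230 genes, 39 truth-positive (19.5%)
#> Clocks: horvath_like, phenoage_like

preds <- do.call(rbind, lapply(cohort$clocks, predict, beta = cohort$beta))
chron <- setNames(cohort$clinical$age, cohort$clinical$sample_id)
drift <- compute_drift(chron, preds)
cohort_summary(drift, "horvath_like")
#> Clock 'horvath_like' on 200 samples
#>   Pearson r = 0.929 (p = 2.61e-87)
#>   MAD = 3.77 yr; deviation range [-17.5, 3.4] yr

lab <- select_hdnamad(drift, "horvath_like", "phenoage_like", fraction = 1)
sum(lab)
#> [1] 39        # exactly the 39 simulated truth-positives, no false calls

scores <- score_panels(cohort$expression)
grp <- setNames(factor(ifelse(lab, "pos", "neg"), c("pos", "neg")), names(lab))
compare_group_scores(scores[, "cell_cycle"], grp)$p_value
#> [1] 3.7e-22   # the injected +2 log2 panel shift is highly significant

cl <- cohort$clinical
cl$hdnamad <- as.integer(lab[cl$sample_id])
cox_fit(cl, "os_time", "os_event", "hdnamad")
#>      term       hr    ci_low ci_high  p_value flagged
#> 1 hdnamad 1.517372 0.8533476  2.6981 0.155621   FALSE
```

The Pearson r and MAD describe how well DNAm age tracks chronological age
across the cohort (the 19.5% rejuvenated subgroup inflates the MAD); the
hazard ratio estimates the mortality increase of the hDNAmad-positive
group (the simulated HR is 2; at 39 events the CI is wide).

For a file-based run, `write_bundle()` + `bundle_pipeline_config()` +
`run_pipeline()` execute every stage from disk and write per-stage TSVs
plus a `summary.tsv`.

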