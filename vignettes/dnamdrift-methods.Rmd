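---
title: "Methods: DNAm-age drift stratification and its synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: DNAm-age drift stratification and its synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dnamdrift)
```

This vignette documents the models, the parameter choices and their
rationale, the numerical decisions, and what the synthetic cohorts do and
do not demonstrate about real data.

## Clock engine

A clock model is a linear predictor over CpG beta values composed with an
invertible age transform. Two transform kinds cover the published clock
families:

* **piecewise log/linear** (Horvath-style): `F(a) = log(a+1) - log(A+1)`
  for `a <= A`, `(a - A)/(A+1)` for `a > A`, with adult age `A = 20` yr.
  `F` is continuous and strictly increasing, so the inverse is closed-form
  per branch; the round trip is exact to machine precision (tested to
  1e-9 over 0–120 yr).
* **identity** (PhenoAge-style): the linear predictor is already in years.

The transform is a pluggable `transform_spec`, so both families run
through one prediction engine. Negative ages are a domain error for the
piecewise form only.

**Missing probes.** Real 450K exports frequently lack a handful of clock
CpGs. The default policy imputes the probe's cohort mean (falling back to
beta 0.5, with a warning, for probes absent from the matrix entirely);
`impute_half` and a strict `error` policy are available. With no missing
data all three policies are identical (tested). The per-sample count of
missing clock probes is always reported.

## Drift classification and the hDNAmad rule

Deviation is the plain difference `dnam_age - chron_age` in years. A
regression-residual mode (residuals of DNAm age on chronological age) is
available behind a flag, because cohort practice varies; the plain
difference is the default since the ±3-yr matched band and the reported
deviation ranges are naturally phrased in raw years. The matched band is
strict (`|dev| < 3`), so a deviation of exactly ±3 belongs to the
acceleration/deceleration classes.

The hDNAmad (high-deceleration) rule: candidates are the primary clock's
DNAmad samples, ranked by deviation ascending with ties broken by sample
id for determinism; the top `floor(fraction * n_candidates)` are kept
(`floor` is adopted because it reproduces the 403 → 134 worked example);
a kept sample is positive iff the confirmation clock also calls it
DNAmad.

**Choice of `fraction` in recovery experiments.** The tercile default
(`1/3`) is a cohort-stratification dial: it deliberately selects only the
most extreme third of candidates. When a simulation injects a clean
rejuvenated subgroup at prevalence ~0.2, the candidate set itself is the
natural estimate of that subgroup, and capping at a third of it would
bound sensitivity near 1/3 *by construction* — a property of the rule,
not an estimation failure. Recovery experiments therefore run
`fraction = 1`, reducing the rule to dual-clock confirmation, while the
tercile path is exercised by the 403-candidate worked example.

## ssGSEA kernel

Genes are ranked by descending expression (ties broken by gene id). The
score is the sum over list positions of (weighted cumulative in-set
fraction − unweighted cumulative out-of-set fraction). In-set weights are
`rank^tau` with rank counted from the bottom (top gene = N); `tau = 0`
gives the unweighted kernel, which satisfies the anti-symmetry identity
`score(S) = -score(universe \ S)` and is compared against an independent
brute-force implementation on every test run. The default `tau = 0.25`
follows common single-sample GSEA practice of damping rank weights.
Across-sample range renormalization, which some implementations apply, is
off by default (a `normalize` flag exists): group comparisons here are
rank-based and invariant to it.

The four built-in panels are fixed gene lists (myeloid, T-effector,
cell-cycle, telomerase), with legacy symbols mapped to HGNC names
(KI-67 → MKI67, TCAB1 → WRAP53) through a shipped, replaceable alias
table. The stemness panel is defined in external work and is therefore a
user-supplied GMT; the shipped `stemness_panel_synthetic.gmt` is a
109-entry synthetic placeholder for tests only. The 21-gene checkpoint
list is shipped as an editable text file: ten members are fixed by the
differential analysis it supports, the remainder are canonical checkpoint
genes and explicitly user-replaceable.

## Rank tests, DMPs and DEGs

Group comparisons use two-sided Wilcoxon rank-sum (two groups) or
Kruskal–Wallis (more). The per-probe/per-gene test is a deliberate
substitution: count-model DEG callers need raw counts, while the inputs
here are log2-scale abundances and beta fractions, for which rank tests
are the robust default. The retention rules are applied exactly as
specified: DEGs need `|log2 FC| > 1.5` (strict) and BH-adjusted p < 0.05;
DMPs need `|Δβ| > 0.20` (strict) and adjusted p < 0.05, with clock CpGs
excluded *before* testing so the multiple-testing burden reflects only
tested probes. BH is the default adjustment (Bonferroni available behind
a flag, since "adjusted p" is ambiguous in common usage).

For small designs with tied values, the rank-sum p is computed by exact
enumeration of the permutation null of the midrank-sum statistic (up to
1e5 assignments); untied small designs use the exact distribution, larger
designs the normal approximation. This makes the 5-vs-5 non-overlapping
fixture yield exactly p = 2/252 whether or not values are tied.

Region composition counts island relations uniquely per probe
(fractions sum to 1 per direction) but counts gene regions by
multi-membership: a `TSS200;Body` probe contributes one assignment to
each region. Manifest island relations collapse N/S shores and shelves;
open-sea probes (empty relation) become `GenePoor`.

## Genomic scores and contingency tests

Aneuploidy is the count of non-zero arm calls over the 39 autosomal arms
(acrocentric p-arms excluded; configurable). Arm calls are an *input*:
real pipelines produce them upstream, and only the synthetic path uses
the ±0.2 mean-value thresholding helper. TMB divides non-silent mutation
counts by a configurable callable size, default 38 Mb (the conventional
whole-exome denominator; the silent-class mapping is editable). The 2×2
test auto-selects Fisher's exact test when any expected cell is below 5,
chi-square otherwise, both available explicitly; a zero margin is
reported as p = 1 with an undefined odds ratio rather than an error.

## Survival

Kaplan–Meier, log-rank and Cox fits delegate to the survival package.
Ties use the Efron approximation and CIs are 95% Wald intervals — the
defaults of mature implementations, documented here as this package's own
choices. Covariates follow the conventional dichotomies (age ≥ 60,
stage III+IV, grade 3, non-endometrioid histology, hDNAmad ±).
Inestimable coefficients (collinearity) and monotone-likelihood warnings
are surfaced as a `flagged` column instead of being silently dropped.

## Synthetic cohorts: what they emulate

`simulate_cohort()` generates, from one master seed with independent
per-table substreams (so regenerating one table never perturbs another):

* **Clock betas.** Each synthetic clock gets random weights and baseline
  betas; per sample, betas are the minimum-norm solution of
  `intercept + w·beta = F(target age)`, so noise-free betas reproduce the
  target age exactly (tested to 1e-6 yr). Truth-positives target
  `chron − δ` (δ default 15 yr, injected on the transformed scale of each
  clock so both branches of the piecewise form behave); identity-clock
  weights are scaled up so the per-probe adjustment stays small on the
  year scale. Gaussian noise (sd 0.01) is added and values clipped to
  [0,1]; clipping is rare because baselines live in (0.25, 0.75).
* **Background probes** draw from beta distributions (concentration 6,
  means in 0.15–0.85), giving realistic [0,1] dispersion without copying
  any real array. Effect probes (default 40 of 300) shift the group mean
  by Δβ = 0.30, 90% hypomethylated in truth-positives.
* **Expression** is Gaussian on the log2 scale (per-gene baselines
  U(2,8), sd 1, clamped at 0), with ±2 log2 shifts on the
  proliferation/telomerase vs immune panels in truth-positives.
* **Survival** is exponential (baseline median 60 months OS, 40 PFS)
  with the group hazard ratio (default 2); uniform censoring whose
  horizon is solved numerically so the expected censored fraction matches
  the configured rate (default 0.6, typical of cohort follow-up).
* **Mutations** are Poisson per group (defaults 120 vs 40, making the
  decelerated group mutation-poor) with a fixed class mix ~25% silent;
  **arm calls** are per-arm Bernoulli with random sign (defaults 0.10 vs
  0.35, making the decelerated group aneuploid).

Cohort defaults (n = 429, prevalence 0.19, ages 40–90) mirror the target
study design. Test and acceptance runs scale n to 100–1000 — sizes at
which every injected effect is comfortably detectable — and state their
sizes explicitly.

**What passing tests do not show.** The generator makes no attempt to
match real marginal beta distributions, probe counts (485k), linkage
between tables beyond the group labels, batch or cell-composition
structure, or real manifest coordinates. Recovery results therefore
validate the *correctness of the computations*, not the biological effect
sizes or the discriminative power of the rule on real tumors.

## Numerical choices

* Ties: gene ranking and candidate ranking break ties lexicographically;
  results are fully deterministic given inputs.
* Serialization: all numeric matrices and clock files are written with 17
  significant digits, so write/read round trips are bit-exact and bundle
  checksums are reproducible.
* Degenerate inputs: constant age vectors yield an `NA` (undefined, not
  zero) Pearson r while the MAD is still computed; zero DNAmad candidates
  yield an all-negative labelling with a warning; empty DMP sets yield
  empty composition tables.
* The pipeline communicates between stages only via files in the output
  directory, so any stage can be rerun in isolation, and a rerun on
  identical inputs is byte-identical (tested).

## Known limitations

* No IDAT/raw-array processing, normalization, or clock training; inputs
  start from level-3 beta values.
* The rank-test DEG substitution is documented, not asserted to be
  equivalent to count-model callers.
* No immune deconvolution, external gene-set enrichment against pathway
  databases, HERV quantification, or molecular-subtype calling; no
  proportional-hazards diagnostics or competing-risks models.
* Clinical covariate simulation is coarse (independent categorical draws
  given the group label) and supports interface testing more than
  epidemiological realism.
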