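---
title: "Cognitive performance variability in a viral challenge cohort: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cognitive performance variability in a viral challenge cohort: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpvar)
```

## The scientific setting

In a human viral challenge study, healthy volunteers complete a repeated
cognitive test battery (the NCPT: four subtests yielding 18 per-session
scores) over a 3-day baseline, are then inoculated with rhinovirus, and their
viral shedding (log10 TCID50/ml from daily nasal lavage) and symptom diaries
are collected afterwards. The question this package operationalizes: does
*intra-individual variability* in pre-exposure cognitive performance carry
information about post-exposure infection severity?

The core quantity is the cognitive performance variability (CPV) score, a
max-pooled change statistic over the 18 NCPT variables. This vignette
explains the statistic, the modelling choices behind every stage, the
synthetic cohort generator used for testing, and the numerical and design
decisions a maintainer should know about — including two places where our
own verification contradicts the statistic's nominal calibration.

## The variability index and the CPV score

For one participant and one NCPT variable, let `x(1..N)` be the baseline
session values in time order (the screening session, index 0, is excluded by
default) and `d(m) = x(m) - x(m-1)` the successive differences. Two
method-of-moments variance estimates are contrasted:

* `sigma0^2 = sum(d^2) / (N-1)` — the variance of the differences assuming
  they have mean zero (no session-to-session change in mean performance);
* `sigma1^2 = sum((d - dbar)^2) / (N-2)` — the variance after centering at
  the observed mean difference `dbar`.

The variability index is `T = sigma0^2 / (sigma0^2 + sigma1^2)`, which lies
in `[0, 1]`, grows with `|dbar|` relative to the residual spread, and is
invariant to affine rescaling of the variable (so units never matter).
`T` rewards *consistent drift* — a persistent shift in performance across
sessions — rather than mere scatter, which is what distinguishes it from a
coefficient of variation.

The univariate CPV is a tail transform of `T` against a Beta reference:

```
CPV = -log(1 - I_T(a, b)),    a = (N-1)/2,  b = (N-2)/2
```

with `I` the regularized incomplete beta function and natural logarithms.
The participant's CPV score is the maximum of the univariate CPV values over
the selected NCPT variables (`cpv_score()`), and `cpv_matrix()` assembles
the full participants-by-variables matrix in the conventional heatmap
ordering (participants by decreasing total shedding, variables by decreasing
column maximum).

Worked example: `x = (0, 1, 0, 1, 0)` gives `d = (1, -1, 1, -1)`,
`sigma0^2 = 1`, `sigma1^2 = 4/3`, hence `T = 3/7` and

```{r worked}
cpv_univariate(c(0, 1, 0, 1, 0))[c("T", "cpv")]
```

### Numerical choices

* **Cap at `T = 1`.** A perfect ramp has zero residual variance, `T = 1`,
  and an exactly zero tail probability. Scores are capped at
  `cpv_cap()` (= `-log` of the smallest positive normalized double, about
  708.4) with a `capped` flag, so downstream correlations stay finite.
* **Constant series** (all differences zero) are a 0/0 case; they are
  defined to score 0, the natural no-variability floor, with a
  `"constant"` status.
* **Missing sessions.** Differences are formed between consecutive
  *retained* sessions, whatever the time gap, and `N` is the retained
  count; a variable with fewer than 3 retained sessions is incomputable for
  that participant. This pairwise-complete rule is our choice; no
  imputation is attempted.
* **Tail computation** uses `pbeta(..., lower.tail = FALSE, log.p = TRUE)`
  so the `-log p` is accurate near `T = 1`.
* The `shape = "unhalved"` switch exposes the Beta(N-1, N-2) variant of the
  reference for comparison.

### What the Beta reference actually is

The Beta((N-1)/2, (N-2)/2) reference treats `sigma0^2` and `sigma1^2` as
independent chi-square variates, which they are not: the raw sum of squares
decomposes as `sum(d^2) = sum((d-dbar)^2) + (N-1)*dbar^2`, so the two
estimates share their centered component. Because `dbar` is independent of
the centered sum of squares for i.i.d. Gaussian differences, the exact null
law of `T` follows from a single Beta(1/2, (n-1)/2) variate
(`n = N - 1` differences):

```
T = (n-1) / (2n - 1 - n*B),    B = n*dbar^2 / sum(d^2) ~ Beta(1/2, (n-1)/2)
```

implemented in `cpv_exact_pvalue()` and verified by simulation in the test
suite. The exact null is supported on `[(n-1)/(2n-1), 1]` and is far more
concentrated than the nominal Beta reference; consequently the nominal CPV
is *not* Exp(1)-calibrated under the null, and a Kolmogorov–Smirnov test
against the nominal reference rejects decisively at any practical sample
size. The same verification shows that the one-way ANOVA p-value computed on
the 2-row matrix of consecutive session pairs (`anova_oracle()`) is not
equal to `exp(-CPV)` either — the discrepancy is systematic (up to ~0.5 per
series), not a parameterization detail, and the test suite records it.

Practical consequence: the CPV should be read as a monotone, affine-invariant
*index* of drift-dominated variability — perfectly serviceable for ranking,
correlation and discrimination, which is how every downstream stage uses
it — not as a calibrated p-value. Users who need calibrated tail
probabilities should use `cpv_exact_pvalue()`.

## Outcome scoring

* **Total shedding** is the sum of daily log10 TCID50/ml titers over the
  post-inoculation window (study days 5–8).
* **Symptom severity**: each diary entry's 8 symptom ranks (0–3) sum to a
  modified Jackson score (0–24); entries are averaged within day and the
  daily means summed over the 5 post-inoculation days. A day with no
  entries contributes 0 (with a warning) so totals remain comparable.
* **High/low shedders** split at the cohort median of total shedding,
  strictly-greater = high. A total exactly at the median is labeled low
  with a warning; the tie rule is arbitrary but deterministic.

## Association measures

Pearson correlation uses Fisher z-transform inference (two-sided p and 95%
CI with standard error `1/sqrt(n-3)`); the `R^2` of the one-predictor linear
fit equals the squared correlation and is computed through `lm()` as a
cross-check; and discrimination of high vs low shedders is the rank
(Mann–Whitney) AUC. The rank AUC equals the AUC of a univariate logistic
regression because AUC is invariant under strictly monotone scoring — and it
remains well-defined under perfect separation, exactly the regime a strong
score produces in a cohort of 18, where an iterative logistic fit diverges.

The comparator score (`cov_score()`) is the coefficient of variation
`sd/|mean|` per variable, max-pooled across variables to stay structurally
parallel to the CPV. Pooling by maximum is our choice; the comparator is
reported with the same association measures.

## Sensitivity analyses

`loo_session_cpv()` recomputes each univariate CPV once per left-out
session (at least 4 sessions required). For an equal-step ramp, removing an
endpoint preserves `T = 1` while removing an interior point creates a
double step and strictly lowers `T` — a useful reminder that the index
responds to the *pattern* of differences, not only their spread.

The combinatorial timing study enumerates all 968 subsets of the 10 session
slots (slot 1 = screening, slot 10 = last pre-exposure session) with 3 to 10
members, recomputes every participant's CPV from only the slots in the
pattern, and measures the association with total shedding. Screening
membership is governed by the pattern itself. A participant retaining fewer
than 3 sessions is dropped for that pattern; patterns retaining fewer than 4
participants are unevaluable. The screening rule — all leave-one-participant-out
correlations at least 0.69 — interprets the cross-validated criterion
conservatively as a minimum; `lopo_rule = "mean"` exposes the laxer
alternative. Ties in the top-pattern ranking break by smaller pattern size,
then lexicographic bitmask, so the top-15 report is reproducible.

## Gene screen and pathway enrichment

The screen pools (participant, session) pairs across the cohort, matching
expression samples (`participant:session` columns, TPM values used as
provided; `log_transform` is available but off by default) to the same
session's NCPT value — with 18 participants and 9 baseline sessions this
gives up to 162 pairs per gene, which is what makes the tiny p-values of a
pooled Pearson test attainable. Pooling ignores within-participant repeated
measures; that limitation is deliberate and documented, and the per-gene
`n` is reported. BH step-up controls FDR across genes per variable.

Enrichment is a one-sided Fisher exact test of over-representation over a
configurable background (default: all genes tested), with the odds ratio
computed from the raw 2x2 table (Haldane 0.5 correction when a cell is
zero — `fisher.test()`'s conditional MLE estimate is deliberately not used
for the reported ratio), and BH across pathways.

## The synthetic cohort generator

`simulate_study()` draws a study-shaped data set whose defaults mirror the
cohort layout: 18 participants, screening at hour -96 plus 9 baseline
sessions (three per day, 8 h apart, exposure after hour 80), 18 NCPT
variables, 4 shedding days, 5 symptom days, 300 genes at 162
participant-session samples, 20 pathways of 30 genes.

A latent susceptibility `s_i in [0, 1]` — drawn as a balanced low/high
mixture (9 each, uniform on [0.05, 0.30] and [0.70, 0.95]), mirroring the
clear shedder separation in challenge cohorts — drives every planted
relation, each with independent noise:

* **Cognitive drift.** One affected variable per participant (drawn from
  the six clinically prominent measures, varying across participants)
  receives increments with mean `drift_effect * s_i` in units of the
  session noise sd. The drift *sign* is drawn once per participant: the
  index detects the overall mean successive difference, and opposing
  per-day signs cancel it (with mixed signs `T` is bounded near 0.52 no
  matter how large the drift — a pilot observation that fixed this design).
  `sign_flip_prob` re-enables per-day flips for sensitivity studies.
  `drift_effect = 6` was frozen after a one-off pilot sweep as the smallest
  value at which recovery is comfortable (correlation with shedding >= 0.8
  and AUC = 1 in ~85% of seeds) while the drift-free null stays clean.
* **Shedding**: planted total `1.5 + 9 * s_i` (cohort median near 5.7),
  observed with sd-0.4 noise and split over the 4 days by random
  proportions.
* **Symptoms**: a noisy severity `s_i + N(0, 0.25)` sets the per-rank
  binomial probability; the noise level calibrates the symptom–shedding
  correlation to the `link_rho = 0.8` target.
* **Covariates**: perceived stress increases with `s_i`; fatigue-scale mean
  increases and its spread decreases; sleep-duration spread decreases; a
  morningness score is independent (negative control).
* **Expression**: 25 planted genes are affine in the standardized session
  series of one NCPT variable (slope 0.8, noise 0.8, pooled correlation
  ~0.7); the rest are independent noise. Pathway `PW01` shares 15 of the
  planted genes; the other 19 pathways are random.

The recorded ground truth (susceptibilities, affected variables, planted
totals, planted genes and pathway) is sufficient to score recovery, and all
randomness flows from one seed, so every experiment is reproducible.

What the generator does **not** emulate: learning curves and circadian
structure in the cognitive series, protocol non-compliance (all synthetic
participants attend all sessions), demographic structure, dropout, and the
count nature and mean–variance coupling of real RNA-seq abundances. Passing
recovery tests therefore demonstrates that the pipeline detects the
mechanism the statistic targets under clean conditions — not that real
cohorts behave this way.

## Problem sizes used by the test suite

The packaged experiments run at deliberately modest sizes chosen to give
stable Monte-Carlo estimates: 100 seeds for signal recovery and the
comparator, 200 seeds for the drift-free null, 5000 replicates for the
null-calibration check, 1000 series for the brute-force and ANOVA-oracle
comparisons, all 968 patterns for the timing study, and all 40320
permutations of 8 p-values for the BH cross-check.

## Known limitations

* The nominal Beta calibration of the CPV is inaccurate (see above); the
  package keeps it as the operational definition and provides the exact
  null separately.
* Cohort-scale inference (n = 18) leans on the Fisher z approximation;
  confidence intervals at this n are wide and the package reports them.
* The gene screen's pooled correlations conflate within- and
  between-participant variation by design.
* The median-split tie rule and the CoV pooling convention are fixed,
  documented choices; both are exposed as the natural place to vary in
  sensitivity analyses.
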