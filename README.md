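# cpvar

Analysis pipeline for **cognitive performance variability (CPV)** in human
viral challenge studies: does session-to-session variability in a
participant's pre-exposure cognitive test scores predict how severely they
respond to a subsequent viral exposure?

The package is aimed at biostatisticians working with longitudinal
challenge-study data: repeated cognitive-test sessions over a short
baseline (here, the 18-score NCPT battery over 3 days), then daily viral
shedding titers (log10 TCID50/ml) and thrice-daily symptom diaries after
inoculation, optionally with baseline covariates (stress, fatigue, sleep)
and a TPM gene-expression matrix sampled at the same sessions.

## The statistic

For participant *i*, variable *j*, with baseline session values
*x(1..N)* in time order and successive differences *d(m) = x(m) − x(m−1)*:

```
        (N−2) Σ d(m)²                         σ₀²
T  =  ─────────────────────────────────  =  ─────────
      (N−2) Σ d(m)² + (N−1) Σ (d(m)−d̄)²    σ₀² + σ₁²
```

σ₀² is the raw second moment of the differences (the no-change null
estimate), σ₁² the centered one. *T* ∈ [0,1] grows with the magnitude of
the mean difference relative to its spread — it rewards consistent drift,
not scatter — and is affine-invariant. The univariate score is the tail
transform

```
CPV_ij = −log(1 − I_T((N−1)/2, (N−2)/2))
```

(regularized incomplete beta *I*, natural log), and the participant score
is the max-pool `CPV_i = max_j CPV_ij`. Downstream stages relate `CPV_i`
to total shedding and total symptom score (Pearson/Fisher-z, linear R²,
rank AUC on the high/low shedder median split), run leave-one-session-out
and combinatorial session-timing sensitivity studies, and screen gene
expression for NCPT-correlated genes with BH FDR and Fisher-exact pathway
enrichment. A synthetic cohort generator with recorded ground truth makes
every stage testable without external data. See the methods vignette
(`vignettes/cpv-methods.Rmd`) for the model, its assumptions, and the
package's own analysis of the statistic's null calibration.

## Worked example

```r
library(cpvar)

study    <- simulate_study(sim_config(), seed = 1)   # 18 participants, planted signal
analysis <- run_study_analysis(study)
analysis
#> CPV study analysis
#>   participants: 18
#>   CPV vs shedding: rho = 0.803 (p = 1.8e-05), R2 = 0.645, AUC = 0.975
#>   CPV vs symptoms: rho = 0.713 (p = 0.00053)
#>   gene screen [digSym-correct]: 26 significant at FDR
```

The pooled CPV of each synthetic participant tracks their planted
susceptibility: the Pearson correlation with total post-exposure shedding
is 0.80 (Fisher-z p = 1.8e-05, 95% CI 0.54–0.92), the one-predictor linear
model explains 64% of the shedding variance, and the rank AUC of 0.975
means the score almost perfectly separates high from low shedders (above
vs below the cohort median). The gene screen pools the 162
participant-session pairs and recovers the planted genes at the top of the
FDR ranking:

```r
head(analysis$gene_screens[["digSym-correct"]], 3)
#>   gene    rho  p_value   n      fdr significant
#> 1 G0020 0.788 1.76e-35 162 5.29e-33 TRUE
#> 2 G0006 0.757 2.42e-31 162 3.63e-29 TRUE
#> 3 G0009 0.741 1.93e-29 162 1.93e-27 TRUE

head(analysis$enrichment[["digSym-correct"]], 2)
#>   pathway odds_ratio  p_value      fdr pathway_size shared_size
#> 1 PW01        23.5   8.85e-11 1.77e-09           30          15
#> 2 PW04         0.338 9.43e-01 1.00e+00           30           1
```

`PW01` is the pathway the generator planted (15 of its 30 genes are
signal genes); its enrichment odds ratio and FDR fall out of the one-sided
Fisher test over the 300-gene background.

The session-timing study enumerates all 968 subsets of the 10 session
slots (sizes 3–10), recomputes the CPV per pattern and screens patterns by
leave-one-participant-out correlation:

```r
oc   <- outcome_table(study$shedding, study$symptoms)
pats <- evaluate_patterns(enumerate_patterns(), study$sessions, oc)
pattern_report(pats, k = 15)$frequencies   # slot-inclusion among top patterns
```

A command-line wrapper with `simulate | cpv | outcomes | associate |
perturb | genes | report` subcommands is installed under
`inst/scripts/cpv-pipeline.R`.

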