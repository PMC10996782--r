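# farsight

Tools for studying intertemporal choice in relation to eating-disorder
risk and future-oriented cognition. People at risk of anorexia nervosa
tend to be unusually *farsighted*: they discount delayed rewards less
steeply than low-risk individuals. `farsight` implements the full
analysis pipeline needed to study that phenomenon — from raw binary
choices and item-level questionnaire responses to a bootstrap mediation
analysis — together with a synthetic-cohort generator with known ground
truth, so every stage is testable without access to human data.

## What it computes

**Discounting.** Subjective value is hyperbolic, `SV = A / (1 + k t)`,
and choices follow a lapse-and-acuity rule:

    p(LL) = eps + (1 - 2 eps) * Phi((SV_LL - SV_SS) / alpha)

Per-participant parameters `(log k, alpha, eps)` are estimated by a
hierarchical Bayesian model — `log k_i ~ N(mu, sigma)` with
`mu ~ N(-5.3, 2.5)` — fitted by an adaptive Metropolis-within-Gibbs
sampler with rank-normalized split R-hat convergence checks (threshold
1.01). Risk groups are fitted separately; random responders are flagged
from the posterior lapse rate and predictive accuracy.

**Questionnaires.** Deterministic scoring of the EAT-26 (risk groups at
the total > 20 cutoff, with a restrictive-symptom variant excluding the
binge/purge items), CFC, ZTPI future subscale, PFE thought-listing ratio,
BDI, trait STAI and ATQ-NA, plus protocol-style quality exclusions
(75% completion; 3 SD single-pass outlier rule).

**Latent factors.** Future orientation and dispositional negativity as
first principal components of the standardized indicators (SVD + varimax),
with loadings, variance proportions and unit-variance factor scores.

**Temporal accuracy.** Signed interval-production errors per pacing block
and anchored subjective/objective growth ratios for horizon estimation.

**Inference.** Pooled-variance t-tests with Cohen's d, Pearson
correlations, type-II ANCOVA, and OLS bootstrap mediation with partially
standardized indirect effects (percentile intervals, parallel mediators
supported).

## Worked example

Simulate a cohort under the default study conditions (55 high-risk, 94
low-risk participants; group log(k) means -4.394 / -3.928; a d = 0.45
future-orientation group effect) and run the full pipeline:

```r
library(farsight)
cfg <- pipeline_config(n_boot = 2000, seed = 1)
rep <- run_pipeline(cfg)

rep$samples
#> # A tibble: 2 x 4
#>   stream        eligible analyzed excluded
#>   <chr>            <int>    <int>    <int>
#> 1 discounting        149      124       25
#> 2 questionnaire      149      149        0

dplyr::select(rep$tests, test, statistic, df, p_value, d)
#> # A tibble: 3 x 5
#>   test                                   statistic    df  p_value      d
#>   <chr>                                      <dbl> <dbl>    <dbl>  <dbl>
#> 1 log_k by risk group                        -1.73   122 0.0434   -0.322
#> 2 future orientation by risk group            2.95   147 0.00184   0.501
#> 3 dispositional negativity by risk group      3.62   147 0.000410  0.614

rep$mediation[rep$mediation$path == "indirect", c("estimate", "ci_lo", "ci_hi")]
#> # A tibble: 1 x 3
#>   estimate  ci_lo    ci_hi
#>      <dbl>  <dbl>    <dbl>
#> 1  -0.0818 -0.199 -0.00143
```

Reading the output: the discounting stream drops catch-trial failures and
model-flagged random responders (25 of 149 here); the high-risk group
shows lower log(k) (one-tailed pooled t, d = -0.32) and higher
future-orientation factor scores (d = 0.50); and the indirect effect of
risk group on log(k) through future orientation is negative with a
bootstrap interval excluding zero — the mediation pattern the pipeline is
designed to detect. Both hierarchical fits converge (all rank-normalized
split R-hat at or below 1.01) and classify about 92% of simulated choices
correctly.

Individual stages are ordinary functions returning tibbles:
`build_choice_set()`, `simulate_cohort()`, `score_cohort_items()`,
`fit_discounting()` (with `tidy()`, `glance()`, `autoplot()`),
`fit_pca_factor()`, `volle_accuracy()`, `zauberman_growth_ratio()`,
`group_ttest()`, `mediate()`.

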