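---
title: "Delay discounting, future orientation and eating-disorder risk: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{farsight methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Anorexia nervosa is unusual among psychiatric conditions in that affected
individuals appear *more* farsighted in intertemporal choice: they discount
delayed rewards less steeply than controls. `farsight` implements a complete
analysis pipeline for studying this phenomenon in at-risk (subclinical)
samples: estimating each person's discount rate from binary
smaller-sooner/larger-later (SS/LL) choices, scoring eating-disorder-risk
and future-orientation questionnaires, condensing the latter into latent
factor scores, and testing whether future-oriented cognition statistically
mediates the group difference in discounting. A synthetic-cohort generator
with known ground truth makes every stage testable end to end.

## The choice model

Subjective value of an amount $A$ delayed by $t$ days follows the
hyperbolic discount function

$$SV = \frac{A}{1 + k\,t},$$

with discount rate $k$ per day, analyzed throughout on the natural-log
scale, $\log(k)$, which normalizes its distribution (lower $\log(k)$ =
more farsighted). Choices are a noisy function of the subjective-value
difference:

$$p(\text{choose LL}) = \epsilon + (1 - 2\epsilon)\,
  \Phi\!\left(\frac{SV_{LL} - SV_{SS}}{\alpha}\right),$$

where $\Phi$ is the standard normal CDF, $\epsilon \in [0, 0.5]$ is a lapse
rate (value-independent random responding) and $\alpha > 0$ (money units)
is the acuity of the value comparison. The probability is bounded in
$[\epsilon, 1-\epsilon]$ and equals $1/2$ at indifference. The
constant-sensitivity (Ebert–Prelec) discount function
$SV = A\,e^{-(a t)^b}$ is also provided (`ebert_prelec_sv()`); it nests
exponential discounting at $b = 1$ and is exposed for exploratory
model-form comparisons, not fitted hierarchically here.

## The task

The default `task_design()` encodes the task configuration: 144
trials; sooner amounts \$15–\$85; relative reward differences
$A_{LL}/A_{SS} - 1$ from 2% to 100% (so later amounts span \$16–\$170);
sooner delays of today, 2 weeks or 1 month; later delays from 1 week to
6 months, always beyond the sooner delay. Calendar conversions are fixed:
1 week = 7 d, 1 month = 30 d, 6 months = 180 d.

Because a concrete administration fixes amounts, ratios and delays in a
static table, the generator approximates such a table: amounts and ratios are evenly
spaced grids over their ranges, randomly paired, with the two extreme
pairings pinned so the printed endpoints (\$16 and \$170) are attained
exactly. Later amounts are rounded *up* to whole dollars: ceiling is the
only integer rule that reproduces the \$16 minimum from
$15 \times 1.02 = 15.3$, and it simultaneously guarantees strict dominance
of the later amount and keeps the realized relative difference inside
[0.02, 1.00]. A verbatim trial table can be supplied instead
(`build_choice_set(design, table = ...)`).

Later delays are chosen to make the set informative across the whole
plausible range of discount rates. Each non-catch trial has an
indifference rate $k^* = (R - 1)/(t_{LL} - R\,t_{SS})$ (with
$R = A_{LL}/A_{SS}$); the generator assigns each trial a target $k^*$
from an even grid on the log scale spanning what the design ranges can
express (about $e^{-9}$ to $e^{-2}$ per day), rank-matched with jitter to
the reward ratios, and realizes the target through the later delay,
clamped so every later delay exceeds both the sooner delay plus a week
and the bound $R\,t_{SS}$ below which no positive indifference rate
exists. Trial indifference points then tile the range evenly — which is
what lets individual discount rates anywhere in the plausible span be
estimated from 144 trials — and a noiseless chooser splits evenly near
$\log(k) \approx -5.4$, consistent with the prior below.

Catch trials pair a larger-sooner with a smaller-later reward (the later
option is dominated); any dominated choice marks the participant as
inattentive, the strictest reading of "failed a catch trial". Grid search
over a noiseless chooser (`balanced_log_k()`) confirms the design splits
preferences evenly near $\log(k) = -5.3$, which motivates the prior below.

## Hierarchical estimation

Participant parameters are estimated jointly per risk group (groups are
fitted separately to keep their estimates statistically independent):

* $\log k_i \sim \mathrm{N}(\mu, \sigma)$, partial pooling;
* $\mu \sim \mathrm{N}(-5.3,\ 2.5)$ — centred where the choice set is
  balanced, with the conventional wide spread;
* $\sigma \sim \text{half-N}(2.5)$;
* $\epsilon_i \sim \mathrm{Beta}(1.1, 10.9)$ truncated to $[0, 0.5]$
  (mode near 0.01: lapses are rare but not impossible);
* $\alpha_i \sim \text{half-N}(20)$ — scale set from the task's money
  range (value differences up to ~\$100).

Sampling uses an adaptive Metropolis-within-Gibbs scheme written for this
model: each participant's $(\log k, \log\alpha, \mathrm{logit}(2\epsilon))$
block gets a joint random-walk proposal whose covariance adapts to the
empirical posterior covariance with diminishing weight (Haario-style), the
group mean is updated by its conjugate Gibbs draw, and the group SD by a
log-scale random walk. All participants update in one vectorized pass, so
a 40-participant, 144-trial fit takes about a minute on one core. Four
overdispersed chains (group-mean starts spread over roughly $-6.8$ to
$-3.8$) are run by default for 5,000 iterations each (1,500 burn-in, four
block updates per stored draw; the proposal-covariance accumulator is
reset when burn-in ends so the adapted geometry reflects the converged
region) — enough for rank-normalized split R-hat to clear 1.01 on
cohorts of this size; the full-scale setting of 25,000 iterations with 1,000 burn-in (96,000 retained draws) is
`mcmc_settings(n_samples = 25000, n_burnin = 1000, n_thin = 1)`.

Convergence is assessed by rank-normalized split R-hat (maximum of the
bulk and folded statistics) for every parameter, threshold 1.01. A fit
that misses the threshold is flagged `converged = FALSE`; it is never
silently accepted. An independent implementation of the identical model
in JAGS serves as a cross-check in the test suite on a small fixture.

Downstream statistics use the posterior mean of $\log k_i$. Random
responders are flagged when the posterior median of $\epsilon_i$ reaches
0.25 or the model's posterior-predictive *expected* accuracy —
$\overline{\max(p, 1-p)}$ over the participant's trials, the model's own
hit probability for its argmax predictions — falls to 0.55 or below
(both thresholds configurable). Expected accuracy is used instead of the
realized hit rate because it is exactly 0.5 whenever the fitted model
cannot distinguish the options (a coin-flip responder can otherwise be
absorbed by a large fitted $\alpha$ while the realized hit rate
fluctuates binomially above the cutoff); flagged participants leave the
discounting stream. Model fit is summarized as classification accuracy: predicted
choice is LL iff fitted $p(LL) > 0.5$ at the posterior point estimates,
ties scored as SS.

```{r fit-example}
library(farsight)
sim <- simulate_cohort(cohort_config(n_high = 20, n_low = 20, seed = 1))
fit <- fit_discounting(sim$choices, sim$trials)
glance(fit)
autoplot(fit)
```

## Questionnaire scoring and exclusions

* **EAT-26** (eating-disorder risk): items 1–25 coded
  Never/Rarely/Sometimes = 0, Often = 1, Usually = 2, Always = 3; item 26
  reverse-coded; totals above 20 (21+) label "high risk". The instrument's
  six response labels are collapsed onto four codes exactly as printed; a
  restrictive-symptom variant drops the binge/purge items 4, 9 and 25
  before summing and reapplies the same cutoff.
* **CFC** (12 items, total 12–60): items 3–5 and 9–12 reverse-coded.
* **ZTPI future subscale**: mean of the 13 future items of the 56-item
  inventory (9, 24 and 56 reverse-keyed), per the published instrument, which
  defines the item set and the reverse keys.
* **PFE**: fraction of up to ten listed recent thoughts labeled "future".
* **Dispositional-negativity instruments**: BDI sum (21 items, 0–3),
  trait-STAI sum (20 items, 1–4, anxiety-absent items reverse-keyed),
  ATQ-NA mean (26 items, 1–7; scored as a plain mean — recode upstream if
  an administration uses reversed items).

Quality exclusions follow two rules, each logged with a reason: less than
75% completion on any used scale, and (single pass, non-iterative, using
the pre-exclusion mean and SD) a future-orientation factor score more than
3 SD from the sample mean. The pipeline keeps two independent exclusion
ledgers — discounting stream (catch failures, then model-flagged random
responders) and questionnaire stream — mirroring the two final samples an
empirical report would track.

## Latent factors

Future orientation is the first principal component of the standardized
CFC total, ZTPI-future mean and PFE ratio (a 2-indicator CFC + ZTPI
variant is first-class too, as is dispositional negativity over BDI,
STAI and ATQ-NA). Standardization before the SVD is deliberate: the
indicators live on incommensurable scales (a 12–60 sum, a 1–5 mean, a 0–1
ratio), so covariance-based PCA would be dominated by the widest scale.
Varimax rotation is applied when more than one component is retained; on
a single retained component it is the identity, and the package
reproduces that convention without further interpretation. Loadings are
indicator–component correlations; a component's variance proportion is
its summed squared loadings over the number of indicators; scores are the
projections of the standardized indicators, rescaled to unit sample
variance and sign-oriented so the CFC (or the configured anchor) loads
positively.

## Temporal accuracy

Two tasks probe subjective time. In the counting task (1 Hz and 0.5 Hz
pacing blocks), accuracy is the signed mean of produced-minus-target
interval per block, in seconds; the produced interval is operationalized
as the elapsed time at the participant's stop response. In the
horizon-estimation task, slider placements for horizons from 1 week to 10
years are anchored at the 1-week trial; each non-anchor trial's growth
ratio is subjective relative growth over objective relative growth, and
the participant summary is the arithmetic mean of per-trial ratios, the
simplest summary that weights every horizon equally. The ratio cancels any common slider rescaling; a zero anchor
response leaves it undefined and flags the participant. Horizon
conversions: 1 week = 7 d, 1 month = 30 d, 1 year = 365 d.

## Inference

Group contrasts use pooled-variance t-tests ($df = n_1 + n_2 - 2$) with
pooled-SD Cohen's d; the two directional primary hypotheses (discounting
lower, future orientation higher in the high-risk group) are one-tailed,
everything else two-tailed. Continuous associations use
Pearson correlations. Covariate-adjusted contrasts use type-II F tests.

Mediation uses OLS path models: $a$ from $M \sim X$, $b$ and $c'$ from
$Y \sim X + M$, total effect $c$ from $Y \sim X$, covariates entered in
every model; the identity $c = c' + \sum_j a_j b_j$ holds to numerical
precision, and is asserted in the tests at $10^{-10}$. Effects are
*partially standardized*: the outcome is z-scored on the analysis sample
while the binary group stays on its 0/1 scale (mediator scaling cancels
in the product). Uncertainty comes from a case-resampling percentile
bootstrap, 10,000 resamples by default, re-estimating all paths (and the
outcome standardization) in each resample; the percentile interval is
used because it is assumption-light and reproducible — a bias-corrected
variant would change intervals only marginally at these sample sizes.
Parallel mediation reports one indirect effect per mediator from a single
joint outcome model.

## The synthetic cohort

`simulate_cohort()` emulates the study conditions: 55 high-risk and 94
low-risk participants; true $\log k$ drawn per group from normals with
means $-4.394$ (high) and $-3.928$ (low) and SD 1.5; a standardized
future-orientation group effect of $d = 0.451$; a within-group
future-orientation/$\log k$ correlation of $-0.26$; a
negativity/risk-severity correlation of 0.314. Correlations are imposed
on latent standard normals and questionnaire targets are monotone
transforms of them (a Gaussian-copula-style construction), so marginal
score ranges and the correlation structure can both be honored.
Item-level responses are then constructed to reproduce each agent's
target scale scores exactly (deterministic mode) or within one scale unit
(noisy mode).

Where the study conditions do not pin a generative value, one was chosen
once on substantive grounds: lapse rates follow Beta(2, 50) (mode 0.02,
mean 0.038) and acuity noise a half-normal(4) with a 0.25 floor — values
at which simulated cohorts reproduce the observed order of magnitude of
data-quality exclusions (roughly 5% catch-trial failures and a handful of
random-responder flags per 150 participants) and an in-sample
classification accuracy near 87%. High-risk agents receive
eating-attitudes totals strictly above the clinical cutoff and low-risk
agents at or below it, so group assignment is exact by construction.

What the generator does *not* emulate: response times, order and fatigue
effects, realistic item-level psychometrics beyond score targets (items
within a scale are exchangeable), demographic covariates, and any
selection process linking traits to catch-trial failure. Passing tests
therefore demonstrate that the estimators recover the generative
structure they target, not that real questionnaire data satisfy that
structure.

## Numerical choices and degenerate inputs

* Choice probabilities are clamped to $[10^{-12}, 1-10^{-12}]$ inside the
  likelihood.
* Proposal adaptation targets 30% acceptance (joint 3-parameter blocks)
  and 44% (scalar group SD), with $t^{-0.55}$ step-size decay and a
  $10^{-6}$ ridge on adapted covariances.
* Classification ties ($p(LL)$ exactly 0.5) count as SS predictions.
* Continuous questionnaire targets are snapped to the nearest attainable
  score (e.g. multiples of 1/13 for the ZTPI-future mean).
* Constant indicators, missing values in factor input, zero-variance
  correlation input, rank-deficient ANCOVA designs, constant mediators,
  empty groups and catch/response misalignment all raise immediate errors
  rather than propagating.

## Problem sizes used in the checks

The test suite and acceptance script run the full design at reduced
sampler scale, chosen to keep a complete run on one core comfortable:
recovery studies use 40 agents at 144 trials with the default 4 chains ×
2,500 iterations; the end-to-end pipeline uses the default 149-agent
cohort; mediation calibration uses 500 null replicates at 2,000 bootstrap
resamples. The full-scale sampler settings remain available via
`mcmc_settings()`.

## Known limitations

* The sampler is tailored to this model family; it is not a generic MCMC
  engine, and very pathological datasets (e.g. all-identical choices for
  every participant) can still mix slowly — the R-hat flag reports this
  honestly rather than working around it.
* Random-responder flagging thresholds are explicit substitutes for an
  unpublished toolbox rule; both thresholds are arguments.
* The EAT-26 response-menu mapping accepts the six printed labels only;
  administrations with other label sets need a recode step upstream.
* Mediation is a statistical decomposition; no causal claim follows from
  a significant indirect effect.
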