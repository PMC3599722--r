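---
title: "Markov transition models for smoking panels with non-ignorable non-response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov transition models for smoking panels with non-ignorable non-response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovquit)
```

## The model

`markovquit` analyses long-format panels of a binary smoking status
$Y_{it} \in \{0, 1\}$ (1 = smoking, 0 = abstinent) recorded at occasions
$t = 0, 1, \dots, T$ for subjects who are all smokers at enrollment
($Y_{i0} = 1$, an invariant the data model enforces). The core is a
two-state, first-order Markov chain: the distribution of $Y_{it}$ depends on
the history only through $Y_{i,t-1}$. Its two informative conditional
probabilities are modelled as separate logistic regressions,

$$\operatorname{logit} P(Y_t = 0 \mid Y_{t-1} = 1) = x'\beta_1
  \qquad \text{(abstinence)},$$
$$\operatorname{logit} P(Y_t = 1 \mid Y_{t-1} = 0) = x'\beta_0
  \qquad \text{(relapse)},$$

which share no parameters, so their joint maximum likelihood factorises into
two independent fits on the transition pairs whose previous state selects the
submodel. Strict stationarity is not assumed: time dummies (`time3`,
`time4`, ... = indicators of the current occasion) let the transition
probabilities vary by interval, the time-inhomogeneous chain. Covariates are
baseline-only by design — the data model rejects time-varying covariates,
because in the emulated trial design all covariates are enrollment measures
and silent support would invite misuse.

Non-response is frequent in cessation trials and plausibly related to the
unrecorded status itself (non-responders may be more likely to be smoking).
Writing $R_{it}$ for the response indicator ($R_{i0} = 1$ by design), the
package models the response process jointly with the outcome through a
selection model,

$$\operatorname{logit} P(R_t = 1) =
  \alpha_0 + \alpha_1 r_{t-1} + \alpha_2 y_{t-1} + \alpha_3 y_t +
  x^{*\prime}\alpha_x,$$

whose coefficients encode the missingness taxonomy implemented by
`classify_mechanism()`: $\alpha_2 = \alpha_3 = 0$ is MCAR, $\alpha_3 = 0 \ne
\alpha_2$ is MAR, and $\alpha_3 \ne 0$ — dependence on the possibly
unobserved current outcome — is NMAR. The complete-data likelihood of a
subject multiplies, over $t = 1, \dots, T$, a Bernoulli factor for $R_t$
(evaluated at the completed outcomes) and the transition probability of
$(y_{t-1} \to y_t)$; `complete_data_loglik()` exposes it directly.

## Estimation

`fit_transition()` is the available-data analysis: only consecutive pairs of
*observed* outcomes contribute, an intermittent gap breaks both pairs it
touches, and a pair missing a covariate required by its submodel is dropped
from that submodel only (so the two submodels can legitimately use slightly
different denominators, which is why Wald F denominators can differ across
contrasts of the same table).

`fit_em()` maximises the observed-data likelihood of the joint model by EM.
The E-step enumerates all $2^m$ completions of a subject's $m$ missing
outcomes — exact for the design sizes this package targets ($T = 4$ gives at
most 16 completions) — and weights each by its complete-data likelihood
normalised within subject, conditioning on both the observed outcomes and
the full response vector (the response model depends on outcome values, so
$R$ is informative about $Y^{mis}$). Normalisation is done in log space
(log-sum-exp), a numerical contract the E-step tests hold to $10^{-12}$. The
M-step maximises the expected complete-data log-likelihood, which decomposes
into three weighted logistic regressions over the completion-expanded
pseudo-data; the expansion is built once and only the weights move across
iterations.

All logistic fits, weighted or not, run through one Newton–Raphson engine:
start at zero (or a warm start), convergence when the gradient norm falls
below $10^{-8}$ or the relative log-likelihood change below $10^{-10}$, at
most 100 iterations, with step-halving so the likelihood never decreases.
Model-based covariance is the inverse observed information. A separated or
rank-deficient design is an error in user-facing fits, but inside the M-step
it is handled with a ridge-stabilised step and a warning: completion-expanded
pseudo-data can be legitimately degenerate (most visibly in the no-missing
limit, where the response model has nothing to estimate) without
invalidating the transition estimates.

EM iterates until the largest parameter change is below $10^{-6}$ *and* the
relative change in the observed-data log-likelihood is below $10^{-9}$, with
a ceiling of 500 iterations; a fit that hits the ceiling is returned flagged
rather than discarded, with its full log-likelihood trace. The trace is
non-decreasing (EM ascent), asserted in the tests with $10^{-8}$ slack.
Initialisation: transition coefficients from the available-data fit,
response-model coefficients from a logistic fit of $R_t$ on its outcome-free
terms with the outcome coefficients at zero. This start reproduces the
available-data fit immediately in the ignorable limit.

Two properties of the EM deserve emphasis because they are easy to
misread:

* Under *monotone* dropout with an outcome-free response model, the
  likelihood factorises and the EM transition estimates equal the
  available-data estimates (the tests assert this to $10^{-6}$). With
  *intermittent* ignorable gaps they differ, and should: the observed-data
  likelihood then contains multi-step transition probabilities that the
  available-pairs analysis discards.
* Identifiability of the response-model coefficients is fragile. Jointly
  modelled outcome and missingness parameters can share near-flat likelihood
  directions, so `fit_em()` computes the condition number of a numerical
  observed-information matrix at the optimum and flags the response-model
  estimates "interpret with caution" when it exceeds $10^6$ (or cannot be
  computed). The transition estimates are typically stable even when the
  response-model ones are not; the package never suppresses the latter, it
  labels them.

Standard errors for EM fits come exclusively from `bootstrap_fit()`:
subjects (entire trajectories) are resampled with replacement $N$-out-of-$N$,
the estimator is re-run per replicate, and the SE is the standard deviation
of replicate estimates, with 2.5/97.5 percentile intervals as a by-product.
The default $B = 1000$ matches common practice for publication-grade SEs;
tests and examples use smaller $B$. Replicates that fail to converge are
dropped and counted, with a warning above 1% failures. The last M-step's
inverse information is *not* reported as an SE for EM fits because it is a
complete-data quantity that understates the information lost to missingness.

`bootstrap_p()` converts estimates and bootstrap SEs to normal-approximation
p-values. Two-sided is the default everywhere; the one-sided variant exists
because published selection-model tables in this literature are sometimes
consistent with one-sided reporting (e.g. an estimate/SE pair of
$-0.026/0.193$ printed as $p = 0.446$), and the package makes the choice
explicit rather than silent.

## Tests, odds ratios, BIC

`wald_test()` follows the conventions of the mixed-procedure software
tradition this model family is usually fitted in: a single contrast gives a
z statistic with a two-sided normal p-value; a multi-row contrast gives the
quadratic-form F with numerator df = rank of the contrast and denominator
df = the number of transition pairs in the combined fit, with the asymptotic
chi-square p-value reported alongside. The denominator-df choice is a
documented convention, not an exact distributional claim. `odds_ratio()`
returns $\exp(c'\hat\beta)$ with a delta-method SE on the log scale;
display rounding is two decimals, machine outputs keep full precision.
`bic()` uses $-2\ell + p\log n$ with $n$ = transition pairs, the analysis
units of the conditional likelihood; the sample-size convention is
configurable via the `n` argument because subject-count penalties are also
defensible, and `compare_bic()` ranks candidate specifications on the same
panel.

## What the simulator emulates — and what it does not

`kanquit_truth()` encodes the study conditions the package is tested under:
750 subjects in three equal arms, four six-monthly follow-ups, covariates
drawn from the published trial marginals (age N(47.2, 13.1); male 0.415;
income > 40K 0.386; cigarettes/day N(23.7, 10.4) truncated at ≥ 10 by
inverse-CDF sampling; nicotine dependence within 5 minutes 0.380; motivation
N(8.6, 2.1) and confidence N(6.1, 2.7) clipped to the 0–10 scale; serious
quit attempt 0.240), transition coefficients set to the published
available-data estimates, and response-model coefficients set to the
published selection-model estimates, which make the mechanism NMAR
($\alpha_3 = -0.428$). Under these defaults the simulated missing fraction
falls around 0.13–0.16 across seeds, bracketing the 15.3% of the emulated
trial; no tuning constant was introduced. `simulate_cohort()` evolves the
latent chain from the true states and draws each $R_t$ *after* $Y_t$ is
realised (the selection-model factorisation), masking but never altering the
latent trajectory.

Known departures from real trial data, hence limits on what passing tests
show: covariates are drawn independently (only marginals are published, so
no correlation structure is emulated); arm allocation is exactly balanced;
the response model is the only attrition mechanism (no per-arm attrition
curves); and the published coefficients used as truth are themselves
estimates. Tests on synthetic cohorts validate the estimators under the
model, not the model against any real cohort.

## Numerical and design choices

* Outcome coding is fixed internally to 1 = smoking, 0 = abstinent (the row
  order of the transition matrix depends on it); `read_panel()` accepts a
  `status_map` for files coded otherwise, and writes missing statuses as
  empty CSV fields, reading both empty and `NA` tokens back.
* Crude matrices report empty rows as undefined (`NA`), never 0/0 — at the
  first follow-up the abstinent row is always empty because everyone smokes
  at baseline.
* Degenerate inputs: duplicate (id, time) rows, gaps in the time grid,
  non-binary statuses, a missing or non-smoking baseline, and time-varying
  covariates are all rejected with specific messages at panel construction.
* Ties/reference levels: time dummies leave undummied occasions as the
  reference; the relapse model's first possible occasion is $t = 2$ since no
  one is abstinent at $t = 0$.
* The EM's completion expansion uses the first-varying-fastest binary grid,
  so completion order is deterministic; seed-controlled functions
  (`simulate_cohort()`, `bootstrap_fit()`) are bit-reproducible given the
  seed, and `bootstrap_fit()` restores the caller's RNG state.

## Problem sizes used in the checks

The test-suite and acceptance-script runs use sizes chosen to keep the full
battery in the minutes range on a single CPU while leaving Monte-Carlo error
well inside each tolerance: exact published arithmetic (milliseconds);
E-step-versus-Bayes enumeration on 6-subject, $T = 4$ instances
($10^{-12}$); EM-versus-direct-maximisation on a 10-subject, $T = 2$
instance ($10^{-4}$); monotone-dropout ignorability at $N = 200$
($10^{-6}$); recovery of the generating coefficients over 100 cohorts of
$N = 750$ (mean absolute bias bound 0.05 — note that a mean over 100
replicates carries Monte-Carlo SE near 0.035 for the sparsest relapse
coefficients, so this bound is a precision statement about the study size,
not a bias claim sharper than the noise); crude-matrix consistency at
$N = 20{,}000$ (0.01); and bootstrap-versus-information SE agreement at
$B = 500$ (15%). One caveat worth repeating: with ten subjects and an NMAR
response model the observed-data likelihood can attain its supremum on the
parameter boundary (quasi-separation through the free latent outcomes), so
the direct-maximisation comparison is run on an instance where every
parameter has an interior maximum; the NMAR machinery is exercised by the
E-step oracle and the full-specification EM runs instead.

## Limitations

Two outcome states only, on a fixed discrete time grid; no continuous-time
or multi-state extension. No GEE/GLMM comparators, no pattern-mixture or
shared-parameter alternatives to selection modelling, no multiple
imputation, no multi-step transition-probability likelihood, and no latent
(hidden Markov) layer for misreported status — these are deliberate
non-goals. Response-model estimates from the joint fit should be read as
sensitivity-analysis devices, not as substantive estimates of the
missingness process.
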