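---
title: "Optimal confidence criteria: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal confidence criteria: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metacrit)
```

## The model

`metacrit` works in the equal-variance signal detection model of a
two-alternative discrimination with binary confidence. On each trial a
stimulus S1 or S2 (prior `p(S2)`) generates evidence `x` from
`N(-d'/2, 1)` or `N(+d'/2, 1)`. The observer responds "S2" iff `x > c1`
and rates the response high confidence iff the evidence clears the
response-specific type 2 criterion: `x > c2_"S2"` for "S2" responses,
`x < c2_"S1"` for "S1" responses, with the consistency constraint
`c2_"S1" <= c1 <= c2_"S2"` so confidence regions nest inside response
regions.

**Coordinate convention.** The distributions sit at `-d'/2` and `+d'/2`
with unit variance — not at 0 and `d'`. This is load-bearing: it makes the
likelihood ratio of S2 to S1 at any point `x` equal `exp(x d')`, which is
what gives every optimal-criterion formula its `ln(.)/d'` shape and makes
the posterior `p(S2 | x)` a logistic function of `x d'` plus the prior
log-odds. All criteria in the package are expressed on this axis.

Type 2 ("metacognitive") performance treats the confidence report as a
classifier of the type 1 response's accuracy: a type 2 hit is a
high-confidence correct response, a type 2 false alarm a high-confidence
error. Response-specific type 2 rates are truncated-normal mass ratios,
e.g. `HR2_"S2" = P(x > c2_"S2" | S2) / P(x > c1 | S2)`; overall rates
weight the response-specific numerators and denominators by the stimulus
priors.

## The four optimization contexts

Each context defines an outcome measure and a closed-form optimum for the
type 2 criteria, always clipped to the response's side of the actual `c1`
(clipping is reported via flags so callers can distinguish interior optima
from constraint-bound ones). Writing `c1_A = ln(p(S1)/p(S2)) / d'` for the
accuracy-optimal type 1 criterion:

* **Type 2 accuracy** — maximize the probability that confidence is
  congruent with accuracy. Optimum: both criteria as close to `c1_A` as
  the constraint allows. When `c1 = c1_A` the observer should never report
  low confidence; low confidence is informative only as an error flag for
  evidence falling between the actual and optimal type 1 criteria.
* **Type 2 reward** — maximize expected payoff under a type 2 payoff
  matrix, summarized by `Q2 = (R_CR2 - R_FA2) / (R_hit2 - R_miss2)`.
  Optima sit symmetrically around `c1_A` at distance `ln(Q2)/d'`. `Q2` is
  defined only when both payoff differences are strictly positive; zero or
  mixed-sign differences leave the optimum undefined and raise a typed
  error, and the both-negative case (where the formula would pick the
  *minimum* of the inverted reward function) raises an error naming that
  pathology rather than silently "optimizing".
* **Calibration** — report high confidence only where the posterior
  probability of being correct exceeds a target `p_T`; the criterion is
  the crossing of `p(correct | x)` with `p_T`, at distance
  `ln(O_T)/d'` from `c1_A` with `O_T = p_T/(1 - p_T)`. `O_T` plays exactly
  the role of `Q2`, which is why a reward context with `Q2 = 5.37` and a
  calibration context with `p_T = 0.843` prescribe the same criteria.
* **HR2 − FAR2** — maximize the difference between type 2 hit and false
  alarm rates. The optimum uses the type 1 rates themselves
  (`ln(HR1/FAR1)/d'` for "S2") and is independent of stimulus priors;
  unclipped, the "S2" optimum is always positive and the "S1" optimum
  always negative. Because the numerator and `d'` co-vary, the optimum is
  nearly flat in `d'`: over `d'` in `[0.5, 5]` at `c1 = 0` its range is
  below 0.25 axis units (the package tests assert this bound, our chosen
  quantification of "approximately constant"). With equal priors and
  `c1 = 0` this context coincides with calibrating to one's own overall
  accuracy.

`d' = 0` edge cases: formulas with `d'` in the denominator error out,
except on genuine plateaus (equal-prior accuracy, the HR1 − FAR1 maximand)
where the conventional representative 0 is returned; zero sensitivity with
unequal priors yields a signed infinite accuracy criterion (always give
the prior-favoured response).

## The brute-force oracle

Every closed form is checked against `outcome_curve()` +
`argmax_c2()`: the outcome evaluated on a criterion grid on one response's
side of `c1`. Design choices:

* Default grid `[c1, c1 + 6]` (mirrored for "S1") at step `1e-3`. Six
  units cover typical parameters; the optimum sits at roughly
  `|c1_A - c1| + ln(Q2)/d'` from `c1`, so the randomized test suites widen
  the grid accordingly at small `d'` and extreme priors.
* Exact ties in the argmax break toward `c1` (the liberal end) — arbitrary
  but fixed, so a flat curve yields a deterministic, most-liberal policy.
* Accuracy and reward values decompose into a constant (fixed by `c1`)
  plus a criterion-dependent tail-mass term. Curves carry the two
  separately and the argmax maximizes the varying term: the orderings
  agree analytically, but when the optimum lies many SDs into a tail the
  varying term is ~1e-16 of the constant and the summed value is
  numerically flat. Tail masses throughout the package go through the
  complementary CDF to avoid the same cancellation.
* The calibration "optimum" is a crossing, not a maximum; it is found by
  bisection (`calibration_crossing()`, tolerance `1e-9`) and must agree
  with the closed form to `1e-6`. For the same reason
  `cost_of_ignoring_suboptimality()` is defined only for the three
  contexts with a maximand.
* Reward curves are response-conditional expectations (conditioning on the
  response matches how the per-response objective is defined); the
  response-probability-weighted overall expectation is also available from
  `expected_reward2()`.

## Process models of suboptimal metacognition

Two generative extensions let confidence rely on degraded evidence:
type 2 noise, `x2 = x1 + e` with `e ~ N(0, sigma2^2)`, and type 2 signal
loss, `x2 = (1 - k) x1 + e`. Both leave type 1 behaviour untouched and
pull meta-d' below d'. Per stimulus, `(x1, x2)` are jointly normal
(variances `1` and `(1-k)^2 + sigma2^2`, covariance `1 - k`), so all
confidence-cell probabilities are bivariate-normal rectangle masses —
the "exact" engine (via `mvtnorm`, with univariate reductions at the
`sigma2 = 0` and `k = 1` boundaries). The degenerate pair `k = 1,
sigma2 = 0` (deterministic `x2 = 0`) is rejected at construction.

Decisions worth flagging:

* **Confidence rule.** The response's criterion is compared against `x2`
  even when `x2` falls on the opposite side of `c1` from the response
  (possible once `x2 != x1`); such trials are simply low confidence. The
  alternative — re-deciding the response from `x2` — would change type 1
  behaviour, which these models deliberately leave intact.
* **Signal-loss default** `sigma2 = 0.1`: a small noise floor is required
  for `k` to degrade meta-d' smoothly rather than merely rescale the
  axis (with `sigma2 = 0` exactly, `x2` is a monotone transform of `x1`
  and confidence is unimpaired for any `k < 1`).
* **Monte-Carlo engine.** One common sample of `(stimulus, x1, x2)` is
  drawn per curve and reused at every grid point, so curves are pointwise
  reproducible from the seed and the argmax is not jittered by independent
  sampling noise across grid points.
* Under the standard model (`sigma2 = 0, k = 0`) every process-model
  quantity reduces exactly to its closed-form counterpart; the tests
  assert agreement to `1e-9` and recovery of the closed-form optima within
  one grid step.

Model-aware optimization reproduces the qualitative signatures: at
`d' = 2, c1 = 0, Q2 = 3`, type 2 noise `sigma2 = 0.8` makes the
reward-optimal criteria more liberal but the HR2 − FAR2-optimal criteria
more conservative, while signal loss (`k = 0.5, sigma2 = 0.1`) makes both
more liberal — and ignoring signal loss is far more costly than ignoring
noise. Matched M-ratio does not imply matched optima across models, which
is the core reason a process model must be specified before "optimal
confidence" is well-defined when meta-d' < d'.

## Meta-d' estimation

`fit_metad()` estimates the sensitivity a hypothetical SDT-ideal observer
would need to produce the observed binary-confidence counts. Conventions
(the measure's literature fixes none of these; ours are the prevailing
ones, implemented as explicit choices):

* Type 1 quantities come from the type 1 marginals
  (`d' = z(HR1) - z(FAR1)`); the fit preserves the *relative* criterion,
  `meta_c = (c1/d') * meta_d`.
* The likelihood is multinomial on confidence conditional on each
  response, with three free parameters (meta-d' and one criterion offset
  per response), maximized by bounded L-BFGS-B with meta-d' in
  `[0, 5 d']`, multi-started from `{0.5, 1, 1.5} d'`.
* Zero cells: 0.5 is added to *every* cell iff any cell is zero
  (switchable via `zero_correction`).
* Degenerate inputs — an empty response cell, constant confidence, or
  type 1 marginals with `d' <= 0` — are rejected with explicit errors
  rather than returning boundary estimates.
* Only binary confidence is supported (one type 2 criterion per response);
  multi-level rating fits and response-specific meta-d' are out of scope.

Exact expected counts (`expected_counts()`) give a deterministic path for
parameter sweeps: `sweep_mratio()` shows M-ratio = 1 under the standard
model and strictly decreasing in `sigma2` and in `k`.

## The simulator as a study stand-in

`simulate_trials()` generates exactly the world the theory assumes:
i.i.d. trials, stationary Gaussian evidence, a fixed criterion set, and
binary confidence read deterministically off `x2`. Passing tests therefore
certify the mathematics and the implementation, not robustness to the
ways real data deviate: unequal-variance evidence (typical of detection
tasks), criterion drift and sequential effects, lapses and finger errors,
graded confidence scales, and post-decisional evidence accumulation are
all outside this generative family. Default simulation sizes in the test
suite (2–3 × 10^5 trials for 3-standard-error rate checks, 10^5 for
meta-d' recovery) were chosen so that Monte-Carlo error is well below the
effect sizes being verified while the whole suite runs in well under a
minute.

## Known limitations

Equal-variance SDT only; binary confidence only; the two process models
are illustrative mechanisms, not a claim about which mechanism produces
suboptimal metacognition in any given dataset (adding another model
requires only a new joint distribution of `(x1, x2)` behind the same cell
interface); `fit_metad()` estimates a point fit without standard errors —
resampling is the intended route to uncertainty.
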