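---
title: "Models and methods behind discountmed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind discountmed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

discountmed implements a complete analysis chain linking emotion-regulation
strategy to temporal impulsivity: per-subject estimation of the hyperbolic
delay-discounting rate from binary intertemporal choices, questionnaire
scoring with reliability, covariate-adjusted rank correlation, and
covariate-adjusted linear mediation with bootstrap inference on the indirect
effect. This vignette documents the models, the defaults, and the design
decisions the code embodies.

## The choice model

Each trial offers a fixed immediate reward of 10,000 KRW against a larger
delayed reward (11,000–48,000 KRW at 2–180 days). Subjective value follows
the hyperbolic form

$$SV = \frac{A}{1 + kD},$$

where $A$ is the amount, $D$ the delay in days and $k$ the subject's
discount rate per day; larger $k$ means steeper devaluation of delayed
rewards. Choice is stochastic in the value difference via a logistic
(softmax) rule with inverse temperature $\beta$:

$$P(\text{delayed}) = \frac{1}{1 + e^{-\beta\,(SV_\text{delayed} - SV_\text{immediate})}}.$$

Because $\beta$ multiplies KRW-scale value differences, plausible values are
small (around $10^{-3}$): $\beta = 0$ is random choice, $\beta \gtrsim
10^{-2}$ is near-deterministic on this menu.

### Trial menu

The exact 120 amount–delay pairs of the original task are not published, so
`generate_trial_set()` builds a documented default: 12 evenly spaced amounts
crossed with 10 log-spaced integer delays. Log spacing concentrates delays
where the hyperbola bends, which constrains $k$ better than linear spacing.
The menu is ordinary data (a CSV that can be replaced wholesale), so no
downstream estimation code depends on this choice. Before analysis log-spaced
delays are rounded to whole days, deduplicated, and re-padded to preserve the
requested count.

### Maximum-likelihood fitting

`fit_dd_subject()` minimizes the Bernoulli negative log-likelihood jointly
over $(\log_{10} k, \log_{10} \beta)$ with bounds $\log_{10} k \in [-5, 0]$
and $\log_{10} \beta \in [-6, 0]$. The log parameterization enforces
positivity and conditions the search. Because the likelihood can be
multi-modal for near-degenerate choosers, a deterministic 7×7 grid of
starting values is evaluated first and the best three starts are refined with
bounded L-BFGS-B; no randomness enters the fit, so refitting the same data is
bit-identical. Probabilities are floored at $10^{-12}$ inside the logs
(configurable via `dd_fit_config()`).

Degenerate response patterns are reported, not hidden. A subject who always
takes the immediate option has no interior optimum in $k$; the fit returns
the bound with `boundary_flag = "k_high"`. A perfectly consistent
(separable) responder saturates the likelihood, whose supremum in $\beta$
lies at the upper bound; a tie-break detects the flat region and reports the
bound with `boundary_flag = "beta_high"` rather than whichever interior point
the optimizer happened to stop at. Deterministic choices identify $k$ only up
to the cell of the partition induced by the menu's indifference rates
$k^* = (A/10{,}000 - 1)/D$; the test suite asserts recovery to exactly that
resolution.

## Questionnaire scoring and reliability

The ERQ's ten 7-point items split 6/4 into cognitive-reappraisal and
expressive-suppression subscales (`erq_item_map()` carries the standard
assignment and is configurable, since translated administrations may reorder
items). Scores are sums — the conventional scoring that matches the scale
ranges 6–42 and 4–28 — and missing items are an error rather than an
imputation. `cronbach_alpha()` uses sample variances with the $n-1$
denominator throughout, which makes the perfectly-correlated-items case
exactly 1.

## Covariate-adjusted rank correlation

"Spearman correlation controlling for covariates" is operationalized in
`partial_spearman()` as: rank-transform both variables (average ranks for
ties), residualize each rank vector on an intercept plus the covariates by
least squares, and correlate the residuals. The p-value uses the t
approximation with $n - 2 - q$ degrees of freedom. The alternative
convention — residualize the raw values, then rank — is available behind
`method = "residual-rank"` for sensitivity analysis, and an optional seeded
permutation p-value cross-checks the approximation. With no covariates the
statistic reduces exactly to plain Spearman.

The covariate set for this analysis is age, sex, handedness and years of
education. (Study reports of this design are sometimes inconsistent about
whether handedness or IQ enters the adjustment; this package implements the
handedness set and leaves the choice to the caller, who can pass any
covariate matrix.)

## Mediation

`fit_mediation_paths()` runs the three least-squares regressions of the
classical covariate-adjusted mediation triangle,

$$M = i_1 + aX + \gamma'C,\qquad
  Y = i_2 + c'X + bM + \delta'C,\qquad
  Y = i_3 + cX + \epsilon'C,$$

with X the reappraisal score, M a scalar brain mediator (e.g. mean
ventral-striatum gray-matter value), Y the log₁₀ discount rate, and C the
covariates (age, sex, handedness, education, total intracranial volume).
Because the covariates enter all three regressions identically, the
decomposition $c = c' + ab$ is an exact algebraic identity of nested OLS;
the code asserts it after every fit and the test suite checks it to 1e-10
across random configurations. Covariate columns are standardized internally
for numerical conditioning — this changes only the intercepts, never the
path coefficients.

`bootstrap_mediation()` resamples whole subject rows with replacement
(case resampling — the appropriate nonparametric bootstrap for observational
mediation), recomputes all five paths per resample, and reports:

* percentile confidence interval for $ab$ (default; bias-corrected and
  accelerated via `ci_type = "bca"` as a sensitivity option — which interval
  a given published toolbox used is often unstated, so the transparent
  percentile form is the default),
* two-sided bootstrap p-values from sign frequencies with the small-sample
  continuity correction $p = 2\min(\#\{\le 0\}+1, \#\{\ge 0\}+1)/(B+1)$,
* bootstrap standard errors (resample SDs).

Resamples that lose a covariate level (e.g. every resampled subject
right-handed) are rank-deficient and are redrawn; the redraw count is
reported and >1% triggers a warning. With a fixed seed the entire result is
reproducible byte for byte.

`classify_mediation()` labels the pattern (full-pattern / partial / none) at
a stated alpha, and always attaches a non-causal framing note: with
cross-sectional data these labels describe a statistical pattern, not a
causal mechanism.

## The synthetic-cohort generator

Participant-level data for this design are typically unavailable, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes. Defaults emulate the study conditions this package is
designed around: 155 subjects; $\log_{10} k \sim N(-2.002, 0.456^2)$;
reappraisal 27.632 ± 6.676 with $\alpha = 0.843$; suppression
14.077 ± 4.624 with $\alpha = 0.718$; age 22.56 ± 2.76; education
15.11 ± 1.39; 78/155 female; 150/155 right-handed; planted paths
$a = -0.002$, $b = 2.047$, $c' = -0.009$.

Two quantities are not pinned down by published descriptives and are this
package's own fixed choices:

* **Mediator scale.** The mediator is generated at mean 0.45, SD 0.05 —
  realistic for modulated gray-matter image values — with a standardized TIV
  coefficient of 0.3 reflecting the dependence of regional volume on head
  size. On this scale the planted paths imply an X–Y correlation of about
  −0.19, the same order as the weak association the design targets.
* **Choice stochasticity.** $\log_{10}\beta \sim N(-3.0, 0.3^2)$, chosen
  once to yield roughly 85–95% model-consistent choices on the default menu
  (the observed mean is ~94%).

Two calibrations run deterministically at configuration time:

* **Likert item calibration.** Items are a one-factor Gaussian model
  discretized to 1–7. Discretization attenuates both the score SD and alpha,
  so the continuous item mean, SD and loading are solved numerically
  (quadrature over the latent factor) such that the *discretized* sums hit
  the target score mean, SD and alpha. The calibration residual is on the
  order of 1e-16, so generated moments converge to the configured targets —
  a property the test suite checks at n = 50,000.
* **Residual back-solving.** The mediation chain's residual SDs are solved
  from the requested marginal SDs of M and Y, so the planted paths and the
  printed-style descriptives coexist; a configuration whose paths already
  exceed a marginal variance is rejected at construction.

What the generator does *not* emulate: item-level response styles beyond a
single factor, shared method variance between questionnaire and task, trial
order effects, non-Gaussian covariate tails, and any spatial structure in
the mediator (it is generated directly as a scalar). Passing tests therefore
demonstrate the correctness and calibration of the estimation machinery
under the assumed data-generating process — not the robustness of the
published findings to violations of that process.

## Pipeline and reproducibility

`run_all()` executes simulate → fit → score → describe → correlate →
mediate, mirroring a correlation-first design: mediation runs only for
subscales whose adjusted correlation passes the gate (`gate_alpha`,
configurable; 1 disables the gate — necessary for null-calibration studies,
where a frozen gate would make the mediation stage unreachable). Every
output file is hashed into `manifest.json`; the manifest contains only
deterministic content, so a rerun with the same seed is byte-identical.
Stage timings go to logging, not the manifest.

## Problem sizes and numerical choices

The shipped tests use cohorts of 12–155 subjects for pipeline checks,
n = 20,000–50,000 for asymptotic anchors (alpha limits, null generators,
moment convergence), 500 Monte-Carlo replicates with 2,000 bootstrap
resamples for the size of the indirect-effect test, and 2,000 replicates for
the size of the adjusted rank correlation; the full-scale analysis default
is 10,000 bootstrap resamples. The indirect-effect size study uses 2,000
resamples per replicate rather than 10,000 because the p-value near the 0.05
threshold is already stable to ±0.01 at that resolution while the study
remains 5× cheaper.

Tolerances worth knowing: probability floor $10^{-12}$ in the likelihood;
boundary detection within $10^{-4}$ log₁₀ units of a search bound;
flat-likelihood tie-break at $10^{-8}$ nll units; the OLS decomposition
identity asserted at 1e-10; quantiles of bootstrap draws use R's default
(type 7) definition.

## Known limitations

* Only the hyperbolic discounting functional is fitted; exponential and
  quasi-hyperbolic alternatives are out of scope.
* Estimation is per-subject maximum likelihood, not hierarchical; subjects
  with near-degenerate choice patterns carry boundary flags and their
  $\log_{10} k$ values sit at search bounds.
* The mediator enters as a precomputed scalar; `roi_mean()` supplies a
  mask-mean from pre-aligned NIfTI images but performs no registration,
  segmentation or voxelwise search.
* The bootstrap treats subjects as exchangeable rows; clustered or
  longitudinal designs need a different resampling unit.
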