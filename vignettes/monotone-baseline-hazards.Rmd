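---
title: "Monotone baseline hazards for left-truncated right-censored data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monotone baseline hazards for left-truncated right-censored data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isohaz)
```

## The model and its assumptions

Each subject contributes a record $(t_i, y_i, \delta_i, z_i)$: a
delayed-entry (left-truncation) time, a follow-up time
$y = \min(x, c)$ for event time $x$ and censoring time $c$, an event
indicator, and a covariate vector. Observation is conditional on
$t \le y$: subjects failing before their entry time never appear, which
biases naive estimators. We assume

* the Cox proportional hazards model
  $\lambda(y \mid z) = \lambda_0(y) e^{\beta' z}$,
* $(T, C)$ conditionally independent of $X$ given $Z$ (independent
  truncation and censoring),
* a **nondecreasing** baseline hazard $\lambda_0$.

The monotonicity assumption is the substantive one. It is natural for
late-life mortality (Gompertz-type aging), progressive disease and
wear-out processes, and it is what stabilises estimation at early times,
where delayed entry leaves only a handful of subjects at risk. It should
be checked (e.g. with a smoothed nonparametric hazard estimate) before
the estimator is trusted; under a genuinely non-monotone hazard the fit
is the best nondecreasing approximation, not the truth.

## Estimation in two stages

**Stage 1.** `cox_fit()` maximises the delayed-entry partial likelihood
with risk sets $R(y) = \{j : t_j \le y \le y_j\}$, Breslow's convention
for ties, Newton–Raphson from $\beta = 0$, step-halving (up to 20
halvings) whenever a step fails to increase the log partial likelihood,
and convergence when the max-norm of the score falls below $10^{-8}$
(at most 50 iterations). These defaults make fits reproducible and match
standard practice; they are exposed as arguments. A coefficient
magnitude above 15 flags monotone-likelihood divergence — beyond that,
$e^{\beta' z}$ risk weights poison every downstream weighted sum, so the
fit is marked not converged rather than silently returned.

**Stage 2.** Given $\hat\beta$ (never re-estimated), the conditional
log-likelihood of a nondecreasing step hazard on the pooled grid
$v_1 < \dots < v_k$ of entries and follow-up times reduces to
$\sum_i \{s_i \log \lambda_0(v_i) - \lambda_0(v_i)\} w_i$ with interval
weights $w_i = (v_{i+1} - v_i) \sum_l e^{\hat\beta' z_l}
\mathbf{1}\{t_l \le v_i < y_l\}$ and levels $s_i = d(v_i)/w_i$. Note the
*right-open* risk predicate: a subject exiting at $v_i$ spends no time
at risk on $[v_i, v_{i+1})$. `iso_rates()` maximises this by weighted
isotonic regression (pool-adjacent-violators), which equals the left
derivatives of the greatest convex minorant of the cumulative sum
diagram and the max–min formula
$\hat\lambda_j = \max_{r \le j} \min_{j \le s \le k-1}
\sum_{i=r}^{s} d(v_i) / \sum_{i=r}^{s} w_i$.
The cumulative hazard integrates the step function (continuous,
piecewise linear), and survival prediction applies
$\exp\{-\hat\Lambda_0(y) e^{\hat\beta' z}\}$.

Special cases: with $\beta$ empty the fit is the univariate monotone MLE
for LTRC data (`tsai_hazard()`); with all entries zero it is the
right-censored-data construction (`lopuhaa_hazard()` deliberately zeroes
entries to serve as the truncation-ignoring comparator).

## Numerical choices and degenerate inputs

* **Knot uniqueness is exact floating-point equality.** Simulated
  continuous times are almost surely distinct and recorded ages are
  integers; tolerance-based merging would silently change the failure
  counts $d(\cdot)$.
* **Records with `time == entry`** are rejected with an error, not
  dropped: such a record carries no information and usually signals a
  data problem. The latent-data filter (`observe_latent()`) tallies
  exact ties separately (`n_ties`), a probability-zero event for
  continuous times.
* **Failures stranded on zero-weight intervals.** Under heavy truncation
  a subject can fail at a knot $v_i$ with nobody at risk on
  $[v_i, v_{i+1})$ in the right-open sense. The unconstrained
  conditional likelihood is then unbounded (the discrete-hazard NPMLE
  fails to exist), but the max–min estimator remains well defined: the
  solver works on $(d, w)$ block sums, a zero-weight block with failures
  pools its mass into the following block, and positions after the last
  positive weight receive per-position steepest-chord values. The
  implementation is verified to agree *exactly* with a brute-force
  enumeration of the max–min formula on thousands of random instances,
  including these pathologies.
* **Zero-weight, zero-failure intervals** impose no constraint; the
  max–min formula assigns them the level of the next positive-weight
  block (the last level beyond it), keeping the sequence nondecreasing.
* **Boundary conventions.** $\hat\lambda_0(y) = 0$ before $v_1$; the
  last rate is extended for $y \ge v_k$. A lone failure at the terminal
  knot lies outside every likelihood interval (the sums stop at $k-1$)
  and contributes nothing to the rates; the constant extension covers
  both a censored and a failed largest observation.
* **Ties between a failure and a censoring at the same time**: the
  censored record stays in the closed risk set at that time
  ($t \le y \le y_j$ holds), consistent with the product-limit risk-set
  definition.
* **Cox risk sums** are computed from cumulative sums over entry- and
  exit-sorted records rather than per-failure-time scans, making a full
  fit on $n = 1000$ take milliseconds; the observed information is
  assembled the same way for arbitrary covariate dimension.

## The simulation harness

`sim_scenario()` / `generate_scenario()` implement a two-group Weibull
design: gender $Z \in \{0, 1\}$ with equal initial sizes, event and
censoring times i.i.d. Weibull with shared shape $a$ and scales 1000
(males) and 2000 (females) — exchangeability of event and censoring
times induces ~50 % censoring among the observed — and truncation times
Weibull($a$, $b$), with observation iff $T \le Y$. A common shape makes
proportional hazards exact with true coefficient $a \log(1/2)$ and true
group medians $m_Z = (\log 2)^{1/a} \theta_Z$. The scenario battery
$(a, b) \in \{(1,50), (2,250), (4,500), (6,600)\}$ keeps observed sizes
comparable across shapes; $a = 1$ is the constant-hazard boundary case
of the monotone assumption. `run_study()` evaluates each estimator's
survival probability at the true median and reports average bias,
empirical standard error and MSE across replicates; replicate seeds are
spawned deterministically from one root seed, so results are
bit-reproducible and single replicates can be regenerated.

The extreme early-truncation design (`generate_extreme()`) draws
two-gender latent pools of 100 000 with truncation scale $b = 3000$,
far above the male event scale, so that only a few hundred males per
pool survive the filter; pools are regenerated (accumulating eligible
records) until an eligible early outlier ($T < 200$) exists, all early
outliers are retained, and the sample is filled uniformly to a fixed
observed $n = 1000$. The resulting male subgroup of a few dozen with a
lone very early entrant is the stress case for discrete-hazard
estimators. A cap of 100 pool regenerations converts a pathological
parameterisation into a diagnosable error.

Degenerate replicates (a subgroup with no failures, a non-converged
regression) contribute their computable values where defined (a
failure-free product-limit curve is identically 1) and are tallied in
the `degenerate` column; replicates are never re-drawn, since re-drawing
would bias the Monte-Carlo distribution.

**What the generator does not emulate:** covariate-dependent truncation
or censoring, non-proportional hazards, discrete or tied event times,
and non-monotone baseline hazards. Passing simulation checks therefore
says nothing about robustness to violations of those assumptions on real
data.

**The Lopuhaä-style comparator** in the harness ignores delayed entry
throughout — both the coefficient fit and the baseline construction run
on entry-zeroed data — which is the natural reading of a method
restricted to right-censored data and makes its systematic
overestimation of baseline survival under truncation visible.

## Problem sizes used by the checks

The packaged tests run the scenario battery at reduced replicate counts
chosen to keep Monte-Carlo error well inside the comparison tolerances
(3 standard errors): 200 replicates at $n = 1000$, 1000 at $n = 100$,
150 for the extreme design; the acceptance script uses 1000 extreme
replicates. Oracle comparisons (max–min enumeration, greatest-convex-
minorant slopes, an independent univariate reimplementation, reference
fits from the survival package) run on hundreds of small random
instances with fixed seeds.

## Known limitations

* Only nondecreasing hazards; no nonincreasing variant.
* No confidence bands: the estimator converges at rate $n^{1/3}$ with a
  non-Gaussian (Chernoff-type) limit, so naive bootstrap or Wald bands
  are unreliable and interval estimation is out of scope here.
* No smoothing of the step hazard, and no automatic diagnostic for the
  monotonicity assumption itself.
* The two-stage construction takes $\hat\beta$ as fixed; uncertainty in
  $\hat\beta$ is not propagated into the baseline estimate.
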