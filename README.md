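# isohaz

Monotone baseline hazard estimation under the Cox proportional hazards
model for left-truncated, right-censored (LTRC) survival data.

## The problem

In studies with delayed entry — retirement-home mortality recorded from
age at move-in, registry data with late enrolment — a subject is observed
only if the event time exceeds the entry time. The risk sets of the
classical estimators are then very small at early times, and a couple of
early failures among a handful of at-risk subjects can drag the whole
estimated survival curve down (in the worst case the discrete-hazard
NPMLE drops to zero and never recovers). When the baseline hazard can be
assumed nondecreasing — aging, progressive disease — a monotone maximum
likelihood estimator pools information across adjacent time intervals and
stays stable exactly where the step estimators collapse.

The package is aimed at biostatisticians analysing LTRC time-to-event
data with baseline covariates, and at methodologists who want the
comparator estimators and a replication harness in one place.

## The estimator

Data are i.i.d. records (tᵢ, yᵢ, δᵢ, zᵢ): entry time, follow-up time
y = min(event, censoring), event indicator, covariates. Under the Cox
model λ(y|z) = λ₀(y) exp(β′z), the regression coefficients β̂ are first
estimated by the partial likelihood with delayed-entry risk sets
R(y) = {j : tⱼ ≤ y ≤ yⱼ} (Newton–Raphson, Breslow ties). Given β̂, the
conditional likelihood of a *nondecreasing* baseline hazard reduces, on
the grid v₁ < … < v_k of pooled entry and follow-up times, to

    ℓ*(λ₀) = Σᵢ { sᵢ log λ₀(vᵢ) − λ₀(vᵢ) } wᵢ ,

with interval weights and levels

    wᵢ = (vᵢ₊₁ − vᵢ) Σₗ exp(β̂′zₗ) 1{tₗ ≤ vᵢ < yₗ},   sᵢ = d(vᵢ)/wᵢ,

where d(vᵢ) counts failures at vᵢ. The maximiser subject to
λ̂₁ ≤ … ≤ λ̂_{k−1} is the weighted isotonic regression of s on w —
computed by pool-adjacent-violators, equal to the left derivatives of the
greatest convex minorant of the cumulative sum diagram and to the max–min
formula

    λ̂ⱼ = max_{r≤j} min_{j≤s≤k−1} ( Σᵢ₌ᵣˢ d(vᵢ) ) / ( Σᵢ₌ᵣˢ wᵢ ).

The fitted hazard is a nondecreasing step function, its cumulative hazard
Λ̂₀ is continuous and piecewise linear, and covariate-specific survival is
Ŝ(y|z) = exp{−Λ̂₀(y) e^{β̂′z}} — a continuous curve, unlike the
product-limit stairs. With no covariates the estimator reduces to Tsai's
univariate monotone MLE; with no truncation it coincides with the
Lopuhaä–Nane estimator for right-censored data. Both special cases, the
left-truncation-modified Kaplan–Meier and the truncation-modified Breslow
estimator are included as comparators, plus a Weibull simulation harness
measuring bias / empirical standard error / MSE of Ŝ at the true median.

## Worked example

```r
library(isohaz)
set.seed(42)

scn <- sim_scenario(2, 250, 1000)   # Weibull shape 2, truncation scale 250
g   <- generate_scenario(scn)       # 79 of 1000 latent subjects truncated
smp <- g$sample

fit <- cox_fit(smp)
fit
#> Delayed-entry Cox fit (Breslow ties)
#>   beta: -1.264
#>   loglik: -2520.65806  score_norm: 2.56e-13  iterations: 4  converged: TRUE

h  <- monotone_hazard(smp, fit$beta)
m0 <- true_median(2, 1000)          # 832.6, the true male median
surv_monotone(h, fit$beta, z = 0, y = m0)
#> 0.5268
```

The fitted log hazard ratio −1.264 estimates the true β = 2·log(½) ≈
−1.386 (one replicate; the average over replicates recovers it). The
monotone survival estimate at the true male median, 0.527, sits near the
true value 0.5; the truncated Kaplan–Meier on the male subgroup gives
0.497 and the Breslow estimator 0.515 on the same data. A small replicate
study:

```r
run_study(scn, reps = 50, seed = 7, estimators = c("proposed", "km"))
#> Replicate study: R = 50, mean observed sizes: 445, 484
#>  estimator group  bias   ese   mse n_valid degenerate
#>   proposed     0 0.009 0.027 0.001      50          0
#>         km     0 0.000 0.030 0.001      50          0
#>   proposed     1 0.002 0.022 0.000      50          0
#>         km     1 0.001 0.026 0.001      50          0
```

`bias` is the mean estimated Ŝ(m_Z|Z) minus the true 0.5, `ese` the
standard deviation across replicates, `mse` the mean squared deviation.

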