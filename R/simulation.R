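#' True median of a Weibull distribution
#'
#' Median of the Weibull with shape `a` and scale `theta` in the standard
#' scale parameterisation (density (a/theta)(x/theta)^(a-1)
#' exp\{-(x/theta)^a\}): m = (log 2)^(1/a) theta.
#'
#' @param shape Weibull shape a > 0.
#' @param scale Weibull scale theta > 0.
#' @return The median survival time.
#' @examples
#' true_median(1, 1000)  # 693.1
#' @export
true_median <- function(shape, scale) {
  stopifnot(shape > 0, scale > 0)
  (log(2))^(1 / shape) * scale
}

#' Simulation scenario for the two-group Weibull design
#'
#' Event and censoring times within each gender are iid Weibull with a
#' shared shape `a` and gender-specific scales (1000 for males, z = 0;
#' 2000 for females, z = 1), which induces roughly 50% censoring among
#' the observed.  The truncation time is Weibull(a, b) and a subject is
#' observed only when it does not exceed the follow-up time.  With a
#' common shape the proportional hazards assumption holds exactly and the
#' true log hazard ratio (female vs male) is a log(1/2).
#'
#' @param shape shared Weibull shape a > 0.
#' @param trunc_scale truncation scale b > 0.
#' @param n_initial initial (pre-truncation) sample size; must be even
#'   (equal gender split).
#' @param scales length-2 vector of event/censoring scales for z = 0, 1.
#' @return Object of class `sim_scenario`.
#' @export
sim_scenario <- function(shape, trunc_scale, n_initial = 1000L,
                         scales = c(1000, 2000)) {
  stopifnot(shape > 0, trunc_scale > 0, length(scales) == 2L,
            n_initial >= 2L, n_initial %% 2L == 0L)
  structure(list(shape = shape, trunc_scale = trunc_scale,
                 n_initial = as.integer(n_initial), scales = scales,
                 true_beta = shape * log(1 / 2),
                 medians = true_median(shape, scales)),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(
    "Weibull LTRC scenario: a = %g, b = %g, n = %d, scales = (%g, %g)\n",
    x$shape, x$trunc_scale, x$n_initial, x$scales[1], x$scales[2]))
  invisible(x)
}

#' Draw one observed dataset from a scenario
#'
#' Draws the latent triples (T, X, C) for n/2 males and n/2 females and
#' applies the observation filter T <= min(X, C).  The observed sample
#' carries the binary covariate column `z`.
#'
#' @param scenario a [sim_scenario].
#' @return List: `sample` (an [ltrc_sample]), `n_dropped`, and
#'   `n_latent`.
#' @export
generate_scenario <- function(scenario) {
  n_half <- scenario$n_initial %/% 2L
  a <- scenario$shape
  z <- rep(c(0, 1), each = n_half)
  theta <- scenario$scales[z + 1L]
  latent <- data.frame(
    entry = stats::rweibull(2L * n_half, a, scenario$trunc_scale),
    event_time = stats::rweibull(2L * n_half, a, theta),
    censor_time = stats::rweibull(2L * n_half, a, theta),
    z = z)
  obs <- observe_latent(latent)
  list(sample = obs$sample, n_dropped = obs$n_dropped,
       n_latent = nrow(latent))
}

#' Draw one extreme early-truncation dataset
#'
#' Robustness design with very wide truncation support: latent pools of
#' `pool_size` records (half male, z = 0, event/censoring scale 1000;
#' half female, z = 1, scale 2000) with a common truncation distribution
#' T ~ Weibull(shape, trunc_scale) are generated repeatedly,
#' accumulating the records that pass the observation filter, until at
#' least one eligible early outlier (entry < `outlier_cut`) exists and
#' at least `n_target` eligible records are available.  All eligible
#' early outliers are retained and the remainder of the sample is drawn
#' uniformly without replacement from the other eligible records, for a
#' fixed observed size `n_target`.
#'
#' Because the male scale is far below the truncation scale, only a few
#' hundred of the eligible records per pool are male; the observed
#' sample therefore contains a male subgroup of only a few dozen, which
#' is what makes early male risk sets extreme.
#'
#' @param pool_size latent pool size per regeneration (split equally
#'   between the genders).
#' @param n_target fixed observed sample size.
#' @param outlier_cut entry-time threshold defining an early outlier.
#' @param shape,trunc_scale shared Weibull shape and truncation scale
#'   (defaults: the extreme design a = 4, b = 3000).
#' @param scales event/censoring scales for z = 0, 1.
#' @param max_pools safety cap on pool regenerations.
#' @return List: `sample` (an [ltrc_sample] of exactly `n_target`
#'   records with binary covariate `z`), `n_outliers`, `n_pools`.
#' @export
generate_extreme <- function(pool_size = 100000L, n_target = 1000L,
                             outlier_cut = 200, shape = 4,
                             trunc_scale = 3000, scales = c(1000, 2000),
                             max_pools = 100L) {
  eligible <- NULL
  n_pools <- 0L
  n_half <- pool_size %/% 2L
  repeat {
    n_pools <- n_pools + 1L
    if (n_pools > max_pools)
      stop("no eligible early outlier within ", max_pools, " latent pools")
    z <- rep(c(0, 1), each = n_half)
    theta <- scales[z + 1L]
    latent <- data.frame(
      entry = stats::rweibull(2L * n_half, shape, trunc_scale),
      event_time = stats::rweibull(2L * n_half, shape, theta),
      censor_time = stats::rweibull(2L * n_half, shape, theta),
      z = z)
    obs <- observe_latent(latent)
    if (!is.null(obs$sample))
      eligible <- rbind(eligible, as.data.frame(obs$sample))
    if (!is.null(eligible) &&
        any(eligible$entry < outlier_cut) &&
        nrow(eligible) >= n_target) break
  }
  outlier <- eligible$entry < outlier_cut
  n_out <- sum(outlier)
  if (n_out >= n_target) {
    keep <- which(outlier)[seq_len(n_target)]
  } else {
    fill <- sample(which(!outlier), n_target - n_out)
    keep <- c(which(outlier), fill)
  }
  list(sample = ltrc_sample(eligible[keep, , drop = FALSE]),
       n_outliers = n_out, n_pools = n_pools)
}

#' Survival probability estimate at the true median
#'
#' Evaluates one of the five estimators on one dataset at the true
#' group-specific median m.  The subgroup estimators (`km`, `tsai`) are
#' fit on the subjects with z = `group` only; the covariate estimators
#' (`proposed`, `breslow`, `lopuhaa`) fit the regression coefficients on
#' the full sample and predict at z = `group`.  The Lopuhaa comparator
#' ignores delayed entry throughout (coefficients and baseline are fit
#' with all entries zeroed).  On a sample with p = 0 the covariate
#' estimators drop the regression stage (empty coefficient vector).
#'
#' A degenerate fit (e.g. Cox non-convergence) yields `NA`, never an
#' error; callers tally degeneracies.
#'
#' @param sample an [ltrc_sample]; covariate column `z` when p = 1.
#' @param estimator one of `"proposed"`, `"tsai"`, `"lopuhaa"`,
#'   `"breslow"`, `"km"`.
#' @param group covariate value z defining the subgroup / prediction
#'   profile (ignored when p = 0).
#' @param m evaluation time (the true median of the group).
#' @return Estimated survival probability, or `NA` on degeneracy.
#' @export
evaluate_at_median <- function(sample, estimator, group, m) {
  res <- evaluate_estimators(sample, estimator, group, m)
  res$estimates[1L, 1L]
}

# Shared evaluation engine: fits the delayed-entry and entry-ignoring Cox
# models at most once each and evaluates every requested estimator at
# every requested group's median.  medians may be a single value or one
# per group.
evaluate_estimators <- function(sample, estimators, groups, medians) {
  estimators <- match.arg(estimators,
                          c("proposed", "tsai", "lopuhaa", "breslow", "km"),
                          several.ok = TRUE)
  p <- attr(sample, "p")
  medians <- rep_len(medians, length(groups))
  safe <- function(expr) tryCatch(expr, error = function(e) NULL,
                                  warning = function(w) NULL)
  fit <- fit0 <- NULL
  if (p >= 1L) {
    if (any(estimators %in% c("proposed", "breslow"))) {
      fit <- safe(cox_fit(sample))
      if (!is.null(fit) && !fit$converged) fit <- NULL
    }
    if ("lopuhaa" %in% estimators) {
      df0 <- as.data.frame(sample); df0$entry <- 0
      s0 <- ltrc_sample(df0)
      fit0 <- safe(cox_fit(s0))
      if (!is.null(fit0) && !fit0$converged) fit0 <- NULL
    }
  }
  beta <- if (p == 0L) numeric(0) else if (!is.null(fit)) fit$beta else NA
  beta0 <- if (p == 0L) numeric(0) else if (!is.null(fit0)) fit0$beta else NA
  prop_h <- if (!anyNA(beta) && "proposed" %in% estimators)
    safe(monotone_hazard(sample, beta)) else NULL
  bres_h <- if (!anyNA(beta) && "breslow" %in% estimators)
    safe(breslow_cumhaz(sample, beta)) else NULL
  lop_h <- if (!anyNA(beta0) && "lopuhaa" %in% estimators)
    safe(lopuhaa_hazard(sample, beta0)) else NULL
  est <- matrix(NA_real_, length(estimators), length(groups),
                dimnames = list(estimators, paste0("z", groups)))
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    m <- medians[gi]
    zvec <- if (p == 0L) numeric(0) else g
    sub <- if (p == 0L) sample else {
      idx <- covariate_matrix(sample)[, 1L] == g
      if (any(idx)) subset_ltrc(sample, idx) else NULL
    }
    for (e in estimators) {
      est[e, gi] <- switch(e,
        proposed = if (!is.null(prop_h))
          surv_monotone(prop_h, beta, zvec, m) else NA_real_,
        breslow = if (!is.null(bres_h))
          predict_survival(eval_cumhaz_step(bres_h, m), beta, zvec)
          else NA_real_,
        lopuhaa = if (!is.null(lop_h))
          surv_monotone(lop_h, beta0, zvec, m) else NA_real_,
        tsai = if (!is.null(sub)) {
          h <- safe(tsai_hazard(sub))
          if (!is.null(h)) surv_monotone(h, y = m) else NA_real_
        } else NA_real_,
        km = if (!is.null(sub))
          eval_surv_step(km_truncated(sub), m) else NA_real_)
    }
  }
  list(estimates = est,
       beta = if (p >= 1L && !is.null(fit)) fit$beta else NULL)
}

#' Replicate study of survival-probability estimation at the median
#'
#' Runs `reps` independent replicates of a scenario (or of the extreme
#' early-truncation design), evaluates the requested estimators at the
#' true group-specific median(s), and summarises average bias
#' (mean estimate - 0.5), empirical standard error (SD of the estimates)
#' and mean squared error (mean squared deviation from 0.5).  Degenerate
#' replicates keep their computable values where defined and are tallied,
#' never re-drawn (re-drawing would bias the Monte-Carlo distribution).
#'
#' Replicate seeds are spawned deterministically from `seed`, so a given
#' (seed, reps) pair is bit-reproducible and each replicate can be
#' regenerated individually.
#'
#' @param scenario a [sim_scenario], or the string `"extreme"` for the
#'   male-only extreme early-truncation design.
#' @param reps number of replicates (>= 2).
#' @param seed integer root seed.
#' @param estimators subset of proposed/tsai/lopuhaa/breslow/km.
#' @param groups covariate values to evaluate (default both genders;
#'   forced to 0 for the extreme design).
#' @param keep_beta record the fitted Cox coefficient per replicate.
#' @return Object of class `scenario_result`: `summary` data frame with
#'   one row per estimator x group (bias, ese, mse, n_valid,
#'   degenerate), `estimates` (reps x estimator x group array),
#'   `n_obs` (mean observed subgroup sizes), `censor_frac` (mean
#'   censoring fraction among observed), `medians`, `reps`, `seed`, and
#'   `beta` (per-replicate coefficients if requested).
#' @export
run_study <- function(scenario, reps, seed,
                      estimators = c("proposed", "tsai", "lopuhaa",
                                     "breslow", "km"),
                      groups = NULL, keep_beta = FALSE) {
  stopifnot(reps >= 2L)
  extreme <- identical(scenario, "extreme")
  if (extreme) {
    groups <- 0
    medians <- true_median(4, 1000)
  } else {
    stopifnot(inherits(scenario, "sim_scenario"))
    if (is.null(groups)) groups <- c(0, 1)
    medians <- true_median(scenario$shape, scenario$scales[groups + 1L])
  }
  set.seed(seed)
  rseeds <- sample.int(.Machine$integer.max, reps)
  est <- array(NA_real_, c(reps, length(estimators), length(groups)),
               dimnames = list(NULL, estimators, paste0("z", groups)))
  n_obs <- matrix(0, reps, length(groups))
  cens <- numeric(reps)
  betas <- if (keep_beta) numeric(reps) else NULL
  for (r in seq_len(reps)) {
    set.seed(rseeds[r])
    smp <- if (extreme) generate_extreme()$sample
           else generate_scenario(scenario)$sample
    p <- attr(smp, "p")
    n_obs[r, ] <- if (p == 0L) nrow(smp)
                  else vapply(groups, function(g)
                    sum(covariate_matrix(smp)[, 1L] == g), numeric(1))
    cens[r] <- mean(smp$status == 0)
    res <- evaluate_estimators(smp, estimators, groups, medians)
    est[r, , ] <- res$estimates
    if (keep_beta) betas[r] <- if (is.null(res$beta)) NA_real_
                               else res$beta[1L]
  }
  rows <- expand.grid(estimator = estimators,
                      group = groups, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    vals <- est[, rows$estimator[i], paste0("z", rows$group[i])]
    ok <- !is.na(vals)
    data.frame(estimator = rows$estimator[i], group = rows$group[i],
               bias = mean(vals[ok]) - 0.5,
               ese = stats::sd(vals[ok]),
               mse = mean((vals[ok] - 0.5)^2),
               n_valid = sum(ok), degenerate = sum(!ok))
  }))
  structure(list(summary = summ, estimates = est,
                 n_obs = colMeans(n_obs),
                 censor_frac = mean(cens),
                 medians = medians, groups = groups,
                 reps = reps, seed = seed, beta = betas,
                 scenario = scenario),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, digits = 3, ...) {
  cat(sprintf("Replicate study: R = %d, mean observed sizes: %s\n",
              x$reps, paste(round(x$n_obs), collapse = ", ")))
  out <- x$summary
  out$bias <- round(out$bias, digits)
  out$ese <- round(out$ese, digits)
  out$mse <- round(out$mse, digits)
  print(out, row.names = FALSE)
  invisible(x)
}

#' Average estimated survival curves over replicates
#'
#' Replicates a scenario, evaluates each estimator's survival curve for
#' one group on a fixed time grid (by default 100 evenly spaced points
#' over [0, 1.5 m_Z]), and averages pointwise across replicates.
#'
#' @param scenario a [sim_scenario].
#' @param reps number of replicates.
#' @param seed integer root seed.
#' @param group covariate value (0 or 1).
#' @param estimators estimators to include.
#' @param times evaluation grid (default as above).
#' @return Data frame with `time` and one averaged-survival column per
#'   estimator.
#' @export
average_curves <- function(scenario, reps, seed, group = 0,
                           estimators = c("proposed", "tsai", "lopuhaa",
                                          "breslow", "km"),
                           times = NULL) {
  m <- true_median(scenario$shape, scenario$scales[group + 1L])
  if (is.null(times)) times <- seq(0, 1.5 * m, length.out = 100L)
  set.seed(seed)
  rseeds <- sample.int(.Machine$integer.max, reps)
  acc <- matrix(0, length(times), length(estimators),
                dimnames = list(NULL, estimators))
  cnt <- matrix(0, length(times), length(estimators))
  for (r in seq_len(reps)) {
    set.seed(rseeds[r])
    smp <- generate_scenario(scenario)$sample
    curves <- estimator_curves(smp, estimators, group, times)
    ok <- !is.na(curves)
    acc[ok] <- acc[ok] + curves[ok]
    cnt <- cnt + ok
  }
  data.frame(time = times, acc / cnt)
}

# Fit each requested estimator once on one dataset and evaluate its
# survival curve for one group over a whole time grid.
estimator_curves <- function(sample, estimators, group, times) {
  p <- attr(sample, "p")
  safe <- function(expr) tryCatch(expr, error = function(e) NULL,
                                  warning = function(w) NULL)
  zvec <- if (p == 0L) numeric(0) else group
  sub <- if (p == 0L) sample else {
    idx <- covariate_matrix(sample)[, 1L] == group
    if (any(idx)) subset_ltrc(sample, idx) else NULL
  }
  out <- matrix(NA_real_, length(times), length(estimators),
                dimnames = list(NULL, estimators))
  fit <- if (p >= 1L && any(estimators %in% c("proposed", "breslow"))) {
    f <- safe(cox_fit(sample)); if (!is.null(f) && f$converged) f else NULL
  } else NULL
  beta <- if (p == 0L) numeric(0) else if (!is.null(fit)) fit$beta else NA
  for (e in estimators) {
    vals <- switch(e,
      proposed = if (!anyNA(beta)) {
        h <- safe(monotone_hazard(sample, beta))
        if (!is.null(h)) surv_monotone(h, beta, zvec, times)
      },
      breslow = if (!anyNA(beta)) {
        ch <- safe(breslow_cumhaz(sample, beta))
        if (!is.null(ch))
          predict_survival(eval_cumhaz_step(ch, times), beta, zvec)
      },
      lopuhaa = {
        df0 <- as.data.frame(sample); df0$entry <- 0
        s0 <- ltrc_sample(df0)
        f0 <- if (p >= 1L) {
          f <- safe(cox_fit(s0))
          if (!is.null(f) && f$converged) f else NULL
        } else NULL
        b0 <- if (p == 0L) numeric(0)
              else if (!is.null(f0)) f0$beta else NA
        if (!anyNA(b0)) {
          h <- safe(lopuhaa_hazard(sample, b0))
          if (!is.null(h)) surv_monotone(h, b0, zvec, times)
        }
      },
      tsai = if (!is.null(sub)) {
        h <- safe(tsai_hazard(sub))
        if (!is.null(h)) surv_monotone(h, y = times)
      },
      km = if (!is.null(sub)) eval_surv_step(km_truncated(sub), times))
    if (!is.null(vals)) out[, e] <- vals
  }
  out
}
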