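#' Interval weights and levels for the monotone baseline hazard
#'
#' For the grid knots v_1 < ... < v_k pooled from entries and follow-up
#' times, the conditional log-likelihood of a nondecreasing baseline
#' hazard (given the regression coefficients) reduces to a weighted sum
#' over the k - 1 inter-knot intervals with
#' \deqn{w_i = (v_{i+1} - v_i) \sum_l \exp(\beta' z_l) 1\{t_l \le v_i < y_l\},
#'       \qquad s_i = d(v_i) / w_i,}
#' where the indicator uses the right-open risk set (a subject whose
#' follow-up ends at v_i spends no time at risk in [v_i, v_{i+1})).
#' `s_i` is taken as 0 when both w_i and d(v_i) vanish; w_i = 0 with
#' d(v_i) > 0 cannot occur (a subject failing at v_i was at risk just
#' before it) and is guarded by an assertion.
#'
#' @param sample an [ltrc_sample].
#' @param grid the [time_grid()] of `sample` (built if omitted).
#' @param beta coefficient vector of length p.
#' @return Object of class `hazard_levels`: `w` (interval weights),
#'   `s` (levels), `d` (failure counts at v_1..v_{k-1}), `grid`,
#'   `beta_used`, `n`.
#' @export
hazard_levels <- function(sample, grid = time_grid(sample),
                          beta = numeric(0)) {
  ew <- exp_score(sample, beta)
  v <- grid$knots
  k <- grid$k
  if (k < 2L) stop("degenerate grid: fewer than two distinct times")
  vi <- v[-k]
  # risk weight over [v_i, v_{i+1}): sum of ew with t_l <= v_i minus
  # sum with y_l <= v_i  (every t and y is itself a knot)
  ot <- order(sample$entry)
  oy <- order(sample$time)
  cum_t <- c(0, cumsum(ew[ot]))
  cum_y <- c(0, cumsum(ew[oy]))
  at_risk <- cum_t[findInterval(vi, sample$entry[ot]) + 1L] -
    cum_y[findInterval(vi, sample$time[oy]) + 1L]
  at_risk[at_risk < 0] <- 0  # guard against roundoff in the cumsums
  w <- diff(v) * at_risk
  d <- grid$failures[-k]
  # w_i = 0 with d(v_i) > 0 happens when a subject fails at v_i and no
  # one else remains at risk on [v_i, v_{i+1}): the discrete-hazard NPMLE
  # does not exist there, but the max-min estimator is still defined
  # (the failure mass is absorbed by adjacent windows); s_i is reported
  # as Inf and the isotonic solver works on (d, w) directly.
  s <- ifelse(w > 0, d / w, ifelse(d > 0, Inf, 0))
  structure(list(w = w, s = s, d = d, grid = grid, beta_used = beta,
                 n = nrow(sample)),
            class = "hazard_levels")
}

#' Cumulative sum diagram of the weighted levels
#'
#' Points P_0 = (0, 0) and P_i = (sum_{j<=i} w_j / n, sum_{j<=i} w_j s_j / n)
#' for i = 1..k-1.  The y-coordinate telescopes to the cumulative failure
#' count over v_1..v_i divided by n; the isotonic rates are the left
#' derivatives of the greatest convex minorant of this diagram.
#'
#' @param levels a [hazard_levels] object.
#' @param n sample size (defaults to the one recorded in `levels`).
#' @return Object of class `cumsum_diagram` with vectors `x` and `y`
#'   (both of length k, starting at the origin).
#' @export
cumsum_diagram <- function(levels, n = levels$n) {
  # w_i s_i = d(v_i) by construction; written this way the identity also
  # covers intervals where w_i = 0 strands a failure (s_i = Inf)
  wy <- ifelse(levels$w > 0, levels$w * levels$s, levels$d)
  structure(list(x = c(0, cumsum(levels$w)) / n,
                 y = c(0, cumsum(wy)) / n),
            class = "cumsum_diagram")
}

# Pool-adjacent-violators solver for the max-min rates, working on the
# (failure count, interval weight) pairs directly.
#
# Up to the last positive-weight interval jp, blocks carry partial sums
# (D, W) with level D/W; a block with W = 0 and D > 0 has level Inf and
# is always pooled into whatever follows it (its failure mass inflates
# the next block), matching the zero-denominator-window skipping of the
# max-min formula.  Positions with D = W = 0 carry neither mass nor
# constraint and take the level of the next retained position.
#
# Beyond jp no window gains further weight, so the inner minimum of the
# max-min formula is attained at s = j and each trailing position gets
# the steepest chord (Dcum_j - Dcum_{r-1}) / (Wcum_jp - Wcum_{r-1})
# over r (trailing failures push these levels up position by position).
pava_blocks <- function(d, w) {
  stopifnot(length(d) == length(w), all(w >= 0), all(d >= 0))
  k1 <- length(d)
  if (!any(w > 0)) return(rep(0, k1))
  jp <- max(which(w > 0))
  dh <- d[seq_len(jp)]; wh <- w[seq_len(jp)]
  pos <- which(wh > 0 | dh > 0)
  dv <- dh[pos]; wv <- wh[pos]
  m <- length(pos)
  Db <- numeric(m); Wb <- numeric(m); size <- integer(m)
  top <- 0L
  lvl <- function(i) if (Wb[i] > 0) Db[i] / Wb[i] else Inf
  for (i in seq_len(m)) {
    top <- top + 1L
    Db[top] <- dv[i]; Wb[top] <- wv[i]; size[top] <- 1L
    while (top > 1L && lvl(top - 1L) >= lvl(top)) {
      Db[top - 1L] <- Db[top - 1L] + Db[top]
      Wb[top - 1L] <- Wb[top - 1L] + Wb[top]
      size[top - 1L] <- size[top - 1L] + size[top]
      top <- top - 1L
    }
  }
  fit_pos <- rep(vapply(seq_len(top), lvl, numeric(1)),
                 size[seq_len(top)])
  idx <- findInterval(seq_len(jp) - 0.5, pos) + 1L
  out <- numeric(k1)
  out[seq_len(jp)] <- fit_pos[pmin(idx, m)]
  if (jp < k1) {
    Dc <- cumsum(d); Wc <- cumsum(w)
    A <- c(0, Dc[seq_len(jp - 1L)])          # Dcum_{r-1}, r = 1..jp
    B <- Wc[jp] - c(0, Wc[seq_len(jp - 1L)]) # Wcum_jp - Wcum_{r-1}
    keep <- B > 0
    for (j in (jp + 1L):k1)
      out[j] <- max((Dc[j] - A[keep]) / B[keep])
  }
  out
}

#' Isotonic baseline hazard rates
#'
#' The nondecreasing rates maximising the conditional log-likelihood:
#' the weighted isotonic regression of the levels s on the interval
#' weights w, equal to the left derivatives of the greatest convex
#' minorant of the cumulative sum diagram and to the max-min formula
#' (see [maxmin_rates()]).
#'
#' @param levels a [hazard_levels] object.
#' @return Numeric vector of k - 1 nondecreasing, nonnegative rates.
#' @export
iso_rates <- function(levels) pava_blocks(levels$d, levels$w)

#' Brute-force max-min rates (reference oracle)
#'
#' Direct O(k^3) evaluation of
#' \deqn{\hat\lambda_j = \max_{r \le j} \min_{j \le s \le k-1}
#'   \frac{\sum_{i=r}^s d(v_i)}{\sum_{i=r}^s w_i},}
#' enumerating every window.  Windows with zero weight sum impose no
#' constraint and are skipped.  Intended as an independent check of
#' [iso_rates()] on small grids, not for production use.
#'
#' @param levels a [hazard_levels] object.
#' @return Numeric vector of k - 1 rates.
#' @export
maxmin_rates <- function(levels) {
  d <- levels$d; w <- levels$w
  m <- length(w)
  vapply(seq_len(m), function(j) {
    best <- -Inf
    for (r in seq_len(j)) {
      worst <- Inf
      for (s in j:m) {
        wsum <- sum(w[r:s])
        if (wsum > 0) worst <- min(worst, sum(d[r:s]) / wsum)
      }
      if (is.finite(worst)) best <- max(best, worst)
    }
    if (is.finite(best)) best else 0
  }, numeric(1))
}

#' Covariate-adjusted monotone baseline hazard estimator
#'
#' The maximum conditional likelihood estimator of a nondecreasing
#' baseline hazard under the Cox proportional hazards model for
#' left-truncated right-censored data.  Given regression coefficients
#' (typically from [cox_fit()]; the baseline stage never re-estimates
#' them), the pipeline is: merged time grid, interval weights and levels
#' with the right-open risk set, weighted isotonic regression.  The
#' fitted hazard is piecewise constant and left-closed: 0 before v_1,
#' rate j on [v_j, v_{j+1}), and the last rate extended beyond v_k.
#'
#' A failure at the terminal knot v_k falls outside every likelihood
#' interval (the sums stop at k - 1) and contributes nothing to the
#' rates; the constant extension beyond v_k covers both a censored and a
#' failed largest observation.
#'
#' @param sample an [ltrc_sample].
#' @param beta coefficient vector of length p.
#' @return Object of class `step_hazard`: `knots`, `rates` (length
#'   k - 1, nondecreasing), `beta_used`, `levels`.
#' @examples
#' s <- ltrc_sample(data.frame(entry = c(0, 0), time = c(1, 2),
#'                             status = c(1, 0)))
#' h <- monotone_hazard(s)
#' eval_hazard(h, c(0.5, 1.5))  # 0, 1
#' @export
monotone_hazard <- function(sample, beta = numeric(0)) {
  grid <- time_grid(sample)
  lv <- hazard_levels(sample, grid, beta)
  rates <- iso_rates(lv)
  structure(list(knots = grid$knots, rates = rates, beta_used = beta,
                 levels = lv),
            class = "step_hazard")
}

#' @export
print.step_hazard <- function(x, ...) {
  cat(sprintf("Monotone step hazard on %d knot(s); rates in [%.4g, %.4g]\n",
              length(x$knots), min(x$rates), max(x$rates)))
  invisible(x)
}

#' Evaluate the step hazard
#' @param hazard a `step_hazard`.
#' @param y numeric vector of times.
#' @return Hazard values: 0 before the first knot, the last rate at and
#'   beyond the terminal knot.
#' @export
eval_hazard <- function(hazard, y) {
  k <- length(hazard$knots)
  idx <- findInterval(y, hazard$knots)
  c(0, hazard$rates, hazard$rates[k - 1L])[pmin(idx, k) + 1L]
}

#' Cumulative baseline hazard of a monotone fit
#'
#' Integral of the piecewise-constant hazard from 0 to `y`: continuous,
#' piecewise linear and nondecreasing, 0 up to the first knot, and
#' growing at the terminal rate beyond the last knot.
#'
#' @param hazard a `step_hazard`.
#' @param y numeric vector of nonnegative times.
#' @return Numeric vector of cumulative hazards.
#' @export
cum_hazard <- function(hazard, y) {
  if (any(y < 0)) stop("evaluation times must be nonnegative")
  v <- hazard$knots
  k <- length(v)
  rates <- hazard$rates
  cum_at_knot <- c(0, cumsum(diff(v) * rates))  # Lambda at v_1..v_k
  idx <- findInterval(y, v)                     # 0 => y < v_1
  out <- numeric(length(y))
  inside <- idx >= 1L & idx < k
  out[inside] <- cum_at_knot[idx[inside]] +
    (y[inside] - v[idx[inside]]) * rates[idx[inside]]
  beyond <- idx >= k
  out[beyond] <- cum_at_knot[k] + (y[beyond] - v[k]) * rates[k - 1L]
  out
}

#' Covariate-specific survival from the monotone fit
#'
#' S(y | z) = exp(-Lambda_0(y) exp(beta' z)) with the continuous
#' piecewise-linear cumulative hazard of [cum_hazard()]; the resulting
#' survival curve is continuous and nonincreasing (a piecewise
#' exponential distribution with nondecreasing rates).
#'
#' @param hazard a `step_hazard`.
#' @param beta coefficient vector.
#' @param z covariate vector.
#' @param y numeric vector of nonnegative times.
#' @return Survival probabilities in (0, 1].
#' @export
surv_monotone <- function(hazard, beta = numeric(0), z = numeric(0), y) {
  predict_survival(cum_hazard(hazard, y), beta, z)
}

#' Univariate monotone hazard (Tsai special case)
#'
#' With no covariates (or within a single covariate stratum) every exp
#' term is 1 and the covariate-adjusted estimator reduces to the
#' univariate monotone MLE for left-truncated right-censored data.
#'
#' @param sample an [ltrc_sample] (covariate columns, if any, are
#'   ignored).
#' @return A `step_hazard`.
#' @export
tsai_hazard <- function(sample) {
  df <- as.data.frame(sample)[, c("entry", "time", "status")]
  monotone_hazard(ltrc_sample(df), numeric(0))
}

#' Censoring-only monotone hazard (Lopuhaa-Nane construction)
#'
#' The right-censored-data comparator: delayed entry is deliberately
#' ignored by zeroing every entry time before fitting, so risk sets are
#' supersets of the truncation-aware ones.  On genuinely untruncated
#' data this coincides with [monotone_hazard()]; on truncated data it
#' systematically overestimates baseline survival.
#'
#' @param sample an [ltrc_sample].
#' @param beta coefficient vector of length p.
#' @return A `step_hazard`.
#' @export
lopuhaa_hazard <- function(sample, beta = numeric(0)) {
  df <- as.data.frame(sample)
  df$entry <- 0
  monotone_hazard(ltrc_sample(df), beta)
}

#' Conditional log-likelihood of a candidate baseline hazard
#'
#' Evaluates sum_i \{s_i log lambda(v_i) - lambda(v_i)\} w_i over the
#' inter-knot intervals, with the convention 0 log 0 = 0.  A candidate
#' that is 0 on an interval carrying failures has likelihood -Inf
#' (returned, not raised).  The fitted rates of [monotone_hazard()]
#' maximise this over all nondecreasing nonnegative step functions on
#' the grid.
#'
#' @param rates candidate rates on the k - 1 intervals (or a
#'   `step_hazard`, whose rates are used).
#' @param levels the [hazard_levels] defining w, s.
#' @return Scalar log-likelihood (possibly -Inf).
#' @export
cond_loglik <- function(rates, levels) {
  if (inherits(rates, "step_hazard")) rates <- rates$rates
  stopifnot(length(rates) == length(levels$w), all(rates >= 0))
  if (any(rates == 0 & levels$d > 0)) return(-Inf)
  # d_i = w_i s_i, so writing the log term through d keeps the value
  # finite when a failure sits on a zero-weight interval
  logterm <- ifelse(levels$d > 0, levels$d * log(rates), 0)
  sum(logterm - rates * levels$w)
}
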