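#' Truncated product-limit (Kaplan-Meier) estimator
#'
#' Product-limit estimator of the survival function for left-truncated,
#' right-censored data: at each distinct failure time y_(j) the survival
#' is multiplied by 1 - d(y_(j)) / n(y_(j)), where the at-risk count
#' n(y) = #\{i : t_i <= y <= y_i\} excludes subjects who have not yet
#' entered.  With all entries 0 this is the standard Kaplan-Meier
#' estimator.
#'
#' @param sample an [ltrc_sample].
#' @return Object of class `surv_step` with `time` (distinct failure
#'   times) and `surv` (value just after each failure time); evaluate with
#'   [eval_surv_step()] (right-continuous, 1 before the first failure).
#' @export
km_truncated <- function(sample) {
  ft <- sort(unique(sample$time[sample$status == 1]))
  if (length(ft) == 0L)
    return(structure(list(time = numeric(0), surv = numeric(0)),
                     class = "surv_step"))
  # n(y) = #{t_i <= y} - #{y_i < y}, valid because entries/times are pooled
  st <- sort(sample$entry)
  sy <- sort(sample$time)
  n_at_risk <- findInterval(ft, st) -
    findInterval(ft, sy, left.open = FALSE) +
    vapply(ft, function(v) sum(sy == v), numeric(1))
  d <- vapply(ft, function(v)
    sum(sample$time == v & sample$status == 1), numeric(1))
  surv <- cumprod(1 - d / n_at_risk)
  structure(list(time = ft, surv = surv), class = "surv_step")
}

#' Evaluate a step survival curve
#'
#' Right-continuous evaluation: S(y) equals the value at the last jump
#' time <= y, and 1 before the first jump.
#'
#' @param fit a `surv_step` object.
#' @param y numeric vector of evaluation times.
#' @return Numeric vector of survival probabilities.
#' @export
eval_surv_step <- function(fit, y) {
  idx <- findInterval(y, fit$time)
  c(1, fit$surv)[idx + 1L]
}

#' @export
print.surv_step <- function(x, ...) {
  cat(sprintf("Step survival curve with %d jump(s)\n", length(x$time)))
  invisible(x)
}

# Breslow-ties partial log-likelihood, score and information for the
# delayed-entry Cox model.  Risk sets are closed: {j : t_j <= u <= y_j};
# the risk sums S0, S1, S2 at every distinct failure time are computed in
# one pass from cumulative sums over entry- and exit-sorted records.
cox_derivs <- function(entry, time, status, Z, beta) {
  p <- ncol(Z)
  eta <- as.vector(Z %*% beta)
  e <- exp(eta)
  fails <- status == 1
  ft <- sort(unique(time[fails]))
  d <- tabulate(match(time[fails], ft), length(ft))
  # weighted moment columns: e, e z_a (a = 1..p), e z_a z_b (a <= b)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  W <- cbind(e, e * Z,
             Z[, pairs[, 1], drop = FALSE] *
               Z[, pairs[, 2], drop = FALSE] * e)
  ot <- order(entry); oy <- order(time)
  cum_t <- rbind(0, apply(W[ot, , drop = FALSE], 2L, cumsum))
  cum_y <- rbind(0, apply(W[oy, , drop = FALSE], 2L, cumsum))
  n_in <- findInterval(ft, entry[ot])                    # t_j <= u
  n_out <- findInterval(ft, time[oy], left.open = TRUE)  # y_j <  u
  S <- cum_t[n_in + 1L, , drop = FALSE] - cum_y[n_out + 1L, , drop = FALSE]
  s0 <- S[, 1L]
  s1 <- S[, 1L + seq_len(p), drop = FALSE]
  loglik <- sum(eta[fails]) - sum(d * log(s0))
  score <- colSums(Z[fails, , drop = FALSE]) - colSums(d * s1 / s0)
  info <- matrix(0, p, p)
  for (q in seq_len(nrow(pairs))) {
    a <- pairs[q, 1]; b <- pairs[q, 2]
    val <- sum(d * (S[, 1L + p + q] / s0 - s1[, a] * s1[, b] / s0^2))
    info[a, b] <- info[b, a] <- val
  }
  list(loglik = loglik, score = score, info = info)
}

#' Cox proportional hazards fit with delayed entry
#'
#' Maximises the partial likelihood under the Breslow tie convention with
#' risk sets modified for left truncation, \{j : t_j <= y <= y_j\}, by
#' Newton-Raphson started at beta = 0 with step-halving whenever a step
#' fails to increase the log partial likelihood.  Convergence is declared
#' when the max-norm of the score drops below `tolerance`.
#'
#' A coefficient whose magnitude exceeds 15 on the exp scale signals
#' monotone-likelihood divergence (risk weights e^15 and beyond poison all
#' downstream weighted sums); the fit is flagged, not silently returned.
#'
#' @param sample an [ltrc_sample] with p >= 1 and at least one failure.
#' @param tolerance convergence tolerance on the max-norm of the score.
#' @param max_iter maximum Newton iterations.
#' @return Object of class `cox_ltrc`: `beta`, `loglik`, `score_norm`,
#'   `information` (observed, p x p), `converged`, `iterations`,
#'   `monotone_likelihood` flag.
#' @examples
#' s <- ltrc_sample(data.frame(entry = 0, time = c(1, 2, 3),
#'                             status = c(1, 1, 0), z = c(0, 1, 0)))
#' cox_fit(s)$beta  # log(2)/2
#' @export
cox_fit <- function(sample, tolerance = 1e-8, max_iter = 50L) {
  p <- attr(sample, "p")
  if (p < 1L) stop("cox_fit needs at least one covariate (p >= 1)")
  if (n_events(sample) == 0L) stop("cox_fit needs at least one failure")
  Z <- covariate_matrix(sample)
  if (any(apply(Z, 2L, function(col) diff(range(col))) == 0))
    stop("singular information: constant covariate column")
  entry <- sample$entry; time <- sample$time; status <- sample$status
  beta <- numeric(p)
  dv <- cox_derivs(entry, time, status, Z, beta)
  iter <- 0L
  converged <- max(abs(dv$score)) <= tolerance
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(dv$info, dv$score),
                     error = function(e)
                       stop("singular information matrix in Newton step"))
    new_beta <- beta + step
    new_dv <- cox_derivs(entry, time, status, Z, new_beta)
    halvings <- 0L
    while (new_dv$loglik < dv$loglik && halvings < 20L) {
      halvings <- halvings + 1L
      step <- step / 2
      new_beta <- beta + step
      new_dv <- cox_derivs(entry, time, status, Z, new_beta)
    }
    beta <- new_beta
    dv <- new_dv
    converged <- max(abs(dv$score)) <= tolerance
  }
  monotone <- any(abs(beta) > 15)
  if (monotone)
    warning("coefficient magnitude > 15: likely monotone partial likelihood")
  structure(list(beta = as.vector(beta),
                 loglik = dv$loglik,
                 score_norm = max(abs(dv$score)),
                 information = dv$info,
                 converged = converged && !monotone,
                 iterations = iter,
                 monotone_likelihood = monotone),
            class = "cox_ltrc")
}

#' @export
print.cox_ltrc <- function(x, ...) {
  cat("Delayed-entry Cox fit (Breslow ties)\n")
  cat("  beta:", format(x$beta, digits = 5), "\n")
  cat(sprintf("  loglik: %.5f  score_norm: %.2e  iterations: %d  converged: %s\n",
              x$loglik, x$score_norm, x$iterations, x$converged))
  invisible(x)
}

#' Truncation-modified Breslow cumulative baseline hazard
#'
#' Step estimator of the cumulative baseline hazard with increment
#' d(y_(k)) / sum over the closed delayed-entry risk set of exp(beta' z)
#' at each distinct failure time.  With `beta` empty on untruncated data
#' this is the Nelson-Aalen estimator.
#'
#' @param sample an [ltrc_sample].
#' @param beta coefficient vector of length p (typically from
#'   [cox_fit()]; `numeric(0)` when p = 0).
#' @return Object of class `cumhaz_step` with `time` (distinct failure
#'   times) and `increments`; evaluate with [eval_cumhaz_step()].
#' @export
breslow_cumhaz <- function(sample, beta = numeric(0)) {
  ew <- exp_score(sample, beta)
  ft <- sort(unique(sample$time[sample$status == 1]))
  inc <- vapply(ft, function(u) {
    d <- sum(sample$time == u & sample$status == 1)
    denom <- sum(ew[sample$entry <= u & u <= sample$time])
    d / denom
  }, numeric(1))
  structure(list(time = ft, increments = inc), class = "cumhaz_step")
}

#' Evaluate a step cumulative hazard
#'
#' Right-continuous: the cumulative hazard at `y` is the sum of the
#' increments at failure times <= y (0 before the first failure).
#'
#' @param fit a `cumhaz_step` object.
#' @param y numeric vector of evaluation times.
#' @return Numeric vector of cumulative hazards.
#' @export
eval_cumhaz_step <- function(fit, y) {
  cum <- c(0, cumsum(fit$increments))
  cum[findInterval(y, fit$time) + 1L]
}

#' @export
print.cumhaz_step <- function(x, ...) {
  cat(sprintf("Step cumulative hazard with %d jump(s)\n", length(x$time)))
  invisible(x)
}

#' Covariate-specific survival from a cumulative hazard value
#'
#' S(y | z) = exp(-Lambda_0(y) exp(beta' z)); applies to both the step
#' (Breslow) and continuous (monotone) cumulative baseline hazards.
#'
#' @param cumhaz_at_y nonnegative cumulative baseline hazard value(s).
#' @param beta coefficient vector.
#' @param z covariate vector (same length as `beta`).
#' @return Survival probability in (0, 1].
#' @export
predict_survival <- function(cumhaz_at_y, beta = numeric(0),
                             z = numeric(0)) {
  if (length(beta) != length(z))
    stop("beta and z must have the same length")
  if (any(cumhaz_at_y < 0)) stop("cumulative hazard must be nonnegative")
  exp(-cumhaz_at_y * exp(sum(beta * z)))
}
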