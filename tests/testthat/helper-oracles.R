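# Fixture generators and independent reference implementations used as
# oracles.  These deliberately use naive enumeration (double/triple
# loops) and share no code with the package internals they check.

# Small random LTRC sample with continuous times; truncation kept mild
# so that every record passes entry < time by construction.
random_ltrc <- function(n, p = 0, truncated = TRUE) {
  entry <- if (truncated) runif(n, 0, 1) else rep(0, n)
  time <- entry + rexp(n, rate = 1)
  df <- data.frame(entry = entry, time = time,
                   status = rbinom(n, 1, 0.6))
  if (sum(df$status) == 0) df$status[1] <- 1
  if (p > 0) for (j in seq_len(p)) df[[paste0("z", j)]] <- rnorm(n)
  ltrc_sample(df)
}

# Random weighted-level instances for the isotonic solver, optionally
# with zero-weight intervals and failures stranded on them.
random_levels <- function(kmax = 12, zero_frac = 0.25) {
  k <- sample(2:kmax, 1)
  w <- round(runif(k, 0.05, 3), 2)
  w[runif(k) < zero_frac] <- 0
  d <- rpois(k, 1)
  list(w = w, d = d,
       s = ifelse(w > 0, d / w, ifelse(d > 0, Inf, 0)))
}

# Independent univariate (no-covariate) monotone hazard reference:
# grid, interval weights and failure counts by per-record double loops,
# rates by direct max-min enumeration over all windows.
tsai_reference <- function(entry, time, status) {
  v <- sort(unique(c(entry, time)))
  k <- length(v)
  m <- k - 1L
  w <- numeric(m); d <- numeric(m)
  for (i in seq_len(m)) {
    for (l in seq_along(entry))
      if (entry[l] <= v[i] && v[i] < time[l])
        w[i] <- w[i] + (v[i + 1L] - v[i])
    d[i] <- sum(time == v[i] & status == 1)
  }
  rates <- numeric(m)
  for (j in seq_len(m)) {
    best <- -Inf
    for (r in 1:j) {
      worst <- Inf
      for (s in j:m) {
        ww <- sum(w[r:s])
        if (ww > 0) worst <- min(worst, sum(d[r:s]) / ww)
      }
      if (is.finite(worst)) best <- max(best, worst)
    }
    rates[j] <- if (is.finite(best)) best else 0
  }
  list(knots = v, rates = rates)
}

# Left derivatives of the greatest convex minorant of points
# (x_0, y_0) .. (x_m, y_m) with strictly increasing x, evaluated at
# x_1 .. x_m; computed via the lower convex hull.
gcm_left_derivs <- function(x, y) {
  hx <- x[1]; hy <- y[1]
  for (i in 2:length(x)) {
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
    nh <- length(hx)
    while (nh >= 3 &&
           (hy[nh] - hy[nh - 2]) * (hx[nh - 1] - hx[nh - 2]) <=
           (hy[nh - 1] - hy[nh - 2]) * (hx[nh] - hx[nh - 2])) {
      hx <- hx[-(nh - 1)]; hy <- hy[-(nh - 1)]
      nh <- nh - 1
    }
  }
  slopes <- diff(hy) / diff(hx)
  vapply(x[-1], function(xi) {
    seg <- which(hx[-1] >= xi - 1e-12)[1]
    slopes[seg]
  }, numeric(1))
}

# Random sample on which the constrained MLE exists: no failure may sit
# on a zero-weight interval (there the conditional likelihood is
# unbounded and only the max-min estimate is defined).
regular_ltrc <- function(n) {
  repeat {
    s <- random_ltrc(n)
    lv <- hazard_levels(s)
    if (!any(lv$w == 0 & lv$d > 0)) return(list(sample = s, levels = lv))
  }
}

# Random nondecreasing nonnegative candidate rate vector.
random_monotone_rates <- function(m, scale = 1) {
  cumsum(rexp(m, rate = 1 / scale)) * sample(c(0.5, 1, 2), 1)
}
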