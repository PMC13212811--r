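test_that("interval weights and levels match hand enumeration", {
  s <- ltrc_sample(data.frame(entry = c(0, 1), time = c(2, 3),
                              status = c(1, 0)))
  lv <- hazard_levels(s)
  expect_equal(lv$w, c(1, 2, 1))
  expect_equal(lv$s, c(0, 0, 1))
  expect_equal(lv$d, c(0, 0, 1))

  s2 <- ltrc_sample(data.frame(entry = c(0, 0), time = c(1, 2),
                               status = c(1, 0), z = c(0, 1)))
  lv2 <- hazard_levels(s2, beta = log(2))
  expect_equal(lv2$w, c(3, 2))
  expect_equal(lv2$s, c(0, 1 / 2))

  # with beta empty the weights are Tsai's unweighted at-risk times
  set.seed(23)
  s3 <- random_ltrc(20, p = 1)
  lv3 <- hazard_levels(s3, beta = 0)
  g <- time_grid(s3)
  v <- g$knots
  manual <- vapply(seq_len(g$k - 1L), function(i)
    (v[i + 1] - v[i]) * sum(s3$entry <= v[i] & v[i] < s3$time),
    numeric(1))
  expect_equal(lv3$w, manual)
})

test_that("cumulative sum diagram satisfies its telescoping identity", {
  lv <- list(w = c(1, 2, 1), s = c(0, 0, 1), d = c(0, 0, 1), n = 2)
  cs <- cumsum_diagram(lv, n = 2)
  expect_equal(cs$x, c(0, 0.5, 1.5, 2))
  expect_equal(cs$y, c(0, 0, 0, 0.5))

  flat <- cumsum_diagram(list(w = c(2, 3), s = c(0, 0), d = c(0, 0)),
                         n = 4)
  expect_equal(flat$y, c(0, 0, 0))

  # y-coordinates are cumulative failure fractions, and x-increments
  # equal the double-sum risk integral computed directly
  set.seed(29)
  for (i in 1:10) {
    s <- random_ltrc(sample(5:30, 1), p = 1)
    b <- rnorm(1) / 2
    lv <- hazard_levels(s, beta = b)
    cs <- cumsum_diagram(lv)
    expect_equal(cs$y[-1], cumsum(lv$d) / nrow(s))
    v <- time_grid(s)$knots
    ew <- exp(b * covariate_matrix(s)[, 1])
    wn <- function(upper) {
      # integral over [v_1, upper) of the weighted at-risk process
      sum(vapply(seq_len(length(v) - 1L), function(j) {
        if (v[j + 1] > upper) return(0)
        (v[j + 1] - v[j]) *
          sum(ew[s$entry <= v[j] & v[j] < s$time])
      }, numeric(1))) / nrow(s)
    }
    for (ii in c(1L, length(v) - 1L))
      expect_equal(cs$x[ii + 1L], wn(v[ii + 1L]), tolerance = 1e-12)
  }
})

test_that("isotonic rates reproduce hand-pooled PAVA solutions", {
  expect_equal(iso_rates(list(w = c(1, 2, 1), d = c(0, 0, 1))),
               c(0, 0, 1))
  # pooling (2, 0) to 2/3 then all to 3/4
  expect_equal(iso_rates(list(w = c(1, 1, 2), d = c(1, 2, 0))),
               c(0.75, 0.75, 0.75))
  expect_equal(iso_rates(list(w = c(1, 1), d = c(2, 1))), c(1.5, 1.5))
  expect_equal(maxmin_rates(list(w = 2, d = 1)), 0.5)
})

test_that("fast isotonic solver equals the max-min enumeration exactly", {
  set.seed(42)
  for (i in 1:400) {
    lv <- random_levels(zero_frac = if (i %% 2) 0 else 0.3)
    expect_equal(iso_rates(lv), maxmin_rates(lv), tolerance = 1e-13)
  }
})

test_that("isotonic rates are the GCM left derivatives of the CSD", {
  set.seed(43)
  for (i in 1:100) {
    lv <- random_levels(zero_frac = 0)      # strictly increasing x
    lv$n <- 1
    cs <- cumsum_diagram(lv, n = 1)
    expect_equal(iso_rates(lv), gcm_left_derivs(cs$x, cs$y),
                 tolerance = 1e-10)
  }
})

test_that("monotone baseline hazard follows the boundary conventions", {
  s <- ltrc_sample(data.frame(entry = c(0, 0), time = c(1, 2),
                              status = c(1, 0)))
  h <- monotone_hazard(s)
  expect_equal(h$rates, c(0, 1))
  expect_equal(eval_hazard(h, c(0.5, 1.5, 5)), c(0, 1, 1))
  expect_equal(eval_hazard(h, -0.1), 0)

  s2 <- ltrc_sample(data.frame(entry = c(0, 0), time = c(1, 2),
                               status = c(1, 0), z = c(0, 1)))
  h2 <- monotone_hazard(s2, beta = log(2))
  expect_equal(h2$rates, c(0, 0.5))

  # a lone failure at the terminal knot lies outside every window
  h1 <- monotone_hazard(ltrc_sample(
    data.frame(entry = 0, time = 1, status = 1)))
  expect_equal(h1$rates, 0)

})

test_that("cumulative hazard integrates the step function", {
  s <- ltrc_sample(data.frame(entry = c(0, 0), time = c(1, 2),
                              status = c(1, 0)))
  h <- monotone_hazard(s)
  expect_equal(cum_hazard(h, 1.5), 0.5)
  expect_equal(cum_hazard(h, 0.3), 0)
  expect_equal(cum_hazard(h, 2), 1)
  expect_equal(cum_hazard(h, 3), 2)  # terminal rate continues
  expect_error(cum_hazard(h, -1), "nonnegative")

  expect_equal(surv_monotone(h, y = 1.5), exp(-0.5))
  expect_equal(surv_monotone(h, y = 0), 1)
  expect_equal(surv_monotone(h, beta = log(2), z = 1, y = 1.5),
               exp(-0.5)^2)

  # continuity, monotonicity and range of the survival curve
  set.seed(51)
  for (i in 1:10) {
    s <- random_ltrc(sample(5:40, 1))
    h <- monotone_hazard(s)
    expect_true(all(diff(h$rates) >= -1e-12))
    y <- seq(0, max(s$time) * 1.2, length.out = 200)
    surv <- surv_monotone(h, y = y)
    expect_true(all(diff(surv) <= 1e-12))
    expect_true(all(surv > 0 & surv <= 1))
    lam <- cum_hazard(h, y)
    expect_true(all(diff(lam) >= -1e-12))
    # piecewise linear: refining the grid never jumps
    expect_lt(max(abs(diff(lam))), max(h$rates) * (y[2] - y[1]) + 1e-9)
  }
})

test_that("univariate reduction matches an independent implementation", {
  set.seed(61)
  for (i in 1:25) {
    s <- random_ltrc(sample(3:25, 1), p = if (i %% 2) 1 else 0)
    h <- monotone_hazard(ltrc_sample(
      as.data.frame(s)[, c("entry", "time", "status")]), numeric(0))
    ref <- tsai_reference(s$entry, s$time, s$status)
    expect_equal(h$knots, ref$knots)
    expect_equal(h$rates, ref$rates, tolerance = 1e-12)
    # tsai_hazard is definitionally the beta-empty fit
    expect_equal(tsai_hazard(s)$rates, h$rates)
  }
})

test_that("subgroup Tsai fit equals the univariate fit on that subgroup", {
  set.seed(67)
  s <- random_ltrc(40, p = 1)
  s$z1 <- rbinom(40, 1, 0.5)
  sub <- s[s$z1 == 0, c("entry", "time", "status")]
  h <- tsai_hazard(ltrc_sample(as.data.frame(s)[s$z1 == 0, ]))
  ref <- tsai_reference(sub$entry, sub$time, sub$status)
  expect_equal(h$rates, ref$rates, tolerance = 1e-12)
})

test_that("censoring-only construction ignores delayed entry", {
  set.seed(71)
  s0 <- random_ltrc(30, p = 1, truncated = FALSE)
  b <- 0.3
  expect_equal(lopuhaa_hazard(s0, b)$rates,
               monotone_hazard(s0, b)$rates)

  s <- random_ltrc(30, p = 1, truncated = TRUE)
  lw <- hazard_levels(local({
    df <- as.data.frame(s); df$entry <- 0; ltrc_sample(df)
  }), beta = b)
  tw <- hazard_levels(s, time_grid(s), beta = b)
  # zeroing entries enlarges every risk set, but on a different grid;
  # compare the weighted at-risk process at shared knots instead
  for (y in sort(unique(s$time))[1:5]) {
    expect_gte(risk_weight(local({
      df <- as.data.frame(s); df$entry <- 0; ltrc_sample(df)
    }), y, b, "right_open"),
    risk_weight(s, y, b, "right_open"))
  }
  expect_true(all(diff(lopuhaa_hazard(s, b)$rates) >= -1e-12))
})

test_that("fitted rates maximise the conditional log-likelihood", {
  lv <- list(w = c(1, 2, 1), s = c(0, 0, 1), d = c(0, 0, 1))
  expect_equal(cond_loglik(c(0, 0, 1), lv), -1)
  expect_equal(cond_loglik(c(0, 0, 0), lv), -Inf)
  none <- list(w = c(1, 2), s = c(0, 0), d = c(0, 0))
  expect_equal(cond_loglik(c(0, 0), none), 0)

  set.seed(73)
  for (i in 1:10) {
    lv <- regular_ltrc(sample(5:30, 1))$levels
    fit <- iso_rates(lv)
    best <- cond_loglik(fit, lv)
    for (j in 1:30) {
      cand <- random_monotone_rates(length(lv$w),
                                    scale = max(fit, 0.2))
      expect_gte(best, cond_loglik(cand, lv))
    }
    # local perturbations of the fit itself cannot improve it either
    for (eps in c(0.9, 1.1))
      expect_gte(best, cond_loglik(pmax(fit * eps, 0), lv))
  }
})
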