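#' Left-truncated right-censored samples
#'
#' An `ltrc_sample` holds one row per subject: the delayed-entry
#' (truncation) time `entry`, the observed follow-up time
#' `time = min(event, censoring)`, the event indicator `status`
#' (1 = failure, 0 = censored) and any number of numeric covariate
#' columns.  Subjects are only observable when `entry <= time`; a record
#' with `time == entry` carries no information about the hazard beyond its
#' entry point and is rejected outright rather than silently dropped.
#'
#' @param data data frame with columns `entry`, `time`, `status` and
#'   optional numeric covariate columns.  All non-reserved numeric columns
#'   are treated as covariates, in column order.
#' @return An object of class `ltrc_sample`: the validated data frame with
#'   attributes `covariates` (character vector of covariate column names)
#'   and `p` (covariate dimension, possibly 0).
#' @examples
#' s <- ltrc_sample(data.frame(entry = c(0, 1, 0), time = c(2, 3, 4),
#'                             status = c(1, 1, 0)))
#' n_events(s)
#' @export
ltrc_sample <- function(data) {
  data <- as.data.frame(data)
  req <- c("entry", "time", "status")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols) > 0L)
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(data) < 1L)
    stop("an LTRC sample needs at least one record (n >= 1)")
  covars <- setdiff(names(data), req)
  for (cl in c(req, covars))
    if (!is.numeric(data[[cl]]))
      stop("column '", cl, "' must be numeric")
  if (any(!is.finite(data$entry)) || any(!is.finite(data$time)))
    stop("entry and time must be finite")
  if (any(data$entry < 0))
    stop("entry times must be nonnegative")
  bad <- which(data$time <= data$entry)
  if (length(bad) > 0L)
    stop("time must exceed entry; violated at row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "))
  if (!all(data$status %in% c(0, 1)))
    stop("status must be 0 (censored) or 1 (failure)")
  structure(data[, c(req, covars), drop = FALSE],
            covariates = covars,
            p = length(covars),
            class = c("ltrc_sample", "data.frame"))
}

#' Read an LTRC sample from a delimited file
#'
#' Expects a header row with columns `entry`, `time`, `status`; every other
#' numeric column is taken as a covariate, in column order.
#'
#' @param file path to a comma-separated file.
#' @return An [ltrc_sample].
#' @export
read_ltrc <- function(file) {
  df <- utils::read.csv(file, header = TRUE)
  ltrc_sample(df)
}

#' @export
print.ltrc_sample <- function(x, ...) {
  cat(sprintf("LTRC sample: n = %d, events = %d, covariates = %d (%s)\n",
              nrow(x), n_events(x), attr(x, "p"),
              if (attr(x, "p") > 0)
                paste(attr(x, "covariates"), collapse = ", ") else "none"))
  NextMethod()
}

#' Number of observed failures
#' @param sample an [ltrc_sample].
#' @return Integer count of records with `status == 1`.
#' @export
n_events <- function(sample) sum(sample$status == 1)

#' Covariate matrix of a sample
#' @param sample an [ltrc_sample].
#' @return Numeric n-by-p matrix (0 columns when p = 0).
#' @export
covariate_matrix <- function(sample) {
  covars <- attr(sample, "covariates")
  as.matrix(as.data.frame(sample)[, covars, drop = FALSE])
}

#' Apply the observation filter to latent records
#'
#' Latent records carry the pre-truncation triple (entry, event time,
#' censoring time).  A subject is observed only when the entry time does
#' not exceed the follow-up time `min(event_time, censor_time)`; the
#' observed record has `time = min(event_time, censor_time)` and
#' `status = 1` iff the event precedes (or ties with) censoring.
#'
#' Records whose entry exactly equals the follow-up time satisfy the
#' filter but form invalid (zero-information) LTRC records; they are
#' excluded and tallied separately in `n_ties` (a probability-zero event
#' for continuous latent times).
#'
#' @param latent data frame with columns `entry`, `event_time`,
#'   `censor_time` and optional numeric covariate columns.
#' @return List with elements `sample` (an [ltrc_sample] of the observed
#'   records; `NULL` when none survive the filter), `n_dropped` and
#'   `n_ties`.
#' @export
observe_latent <- function(latent) {
  latent <- as.data.frame(latent)
  req <- c("entry", "event_time", "censor_time")
  if (!all(req %in% names(latent)))
    stop("latent records need columns entry, event_time, censor_time")
  if (any(latent$event_time <= 0) || any(latent$censor_time <= 0))
    stop("event and censoring times must be positive")
  y <- pmin(latent$event_time, latent$censor_time)
  keep <- latent$entry < y
  n_ties <- sum(latent$entry == y)
  n_dropped <- sum(latent$entry > y)
  if (!any(keep))
    return(list(sample = NULL, n_dropped = n_dropped, n_ties = n_ties))
  obs <- data.frame(entry = latent$entry[keep],
                    time = y[keep],
                    status = as.numeric(latent$event_time[keep] <=
                                          latent$censor_time[keep]))
  covars <- setdiff(names(latent), req)
  for (cl in covars) obs[[cl]] <- latent[[cl]][keep]
  list(sample = ltrc_sample(obs), n_dropped = n_dropped, n_ties = n_ties)
}

#' Merged time grid of entry and follow-up times
#'
#' The grid knots v_1 < ... < v_k are the distinct ordered values pooled
#' from all entry and follow-up times; `failures[j]` counts failures
#' observed exactly at knot v_j (censored records contribute 0).  Knot
#' uniqueness is exact floating-point equality: simulated continuous times
#' are almost surely distinct and recorded ages are integers, and any
#' tolerance merging would silently change the failure counts.
#'
#' @param sample an [ltrc_sample].
#' @return List of class `time_grid` with `knots`, `failures` and `k`.
#' @export
time_grid <- function(sample) {
  knots <- sort(unique(c(sample$entry, sample$time)))
  ft <- sample$time[sample$status == 1]
  failures <- vapply(knots, function(v) sum(ft == v), numeric(1))
  structure(list(knots = knots, failures = failures, k = length(knots)),
            class = "time_grid")
}

#' Risk-set weight at a time point
#'
#' Sums exp(beta' z) over the records at risk at time `y`.  Two risk-set
#' conventions are used in LTRC estimation: the closed set
#' \{j : t_j <= y <= y_j\} (product-limit, partial likelihood, Breslow)
#' and the right-open set \{l : t_l <= y < y_l\} (interval weights of the
#' monotone estimator).  With `beta` empty (p = 0) the weight is the plain
#' at-risk count n(y).
#'
#' @param sample an [ltrc_sample].
#' @param y time point (scalar).
#' @param beta coefficient vector of length p (use `numeric(0)` when
#'   p = 0, making every exp term 1).
#' @param closure `"closed"` for t <= y <= time, `"right_open"` for
#'   t <= y < time.
#' @return Nonnegative scalar.
#' @export
risk_weight <- function(sample, y, beta = numeric(0),
                        closure = c("closed", "right_open")) {
  closure <- match.arg(closure)
  ew <- exp_score(sample, beta)
  at_risk <- if (closure == "closed")
    sample$entry <= y & y <= sample$time
  else
    sample$entry <= y & y < sample$time
  sum(ew[at_risk])
}

# exp(beta' z_i) for every record; validates the coefficient dimension.
exp_score <- function(sample, beta) {
  p <- attr(sample, "p")
  if (length(beta) != p)
    stop("beta has length ", length(beta), " but the sample has p = ", p)
  if (p == 0L) return(rep(1, nrow(sample)))
  as.vector(exp(covariate_matrix(sample) %*% beta))
}

# Subset rows of a sample, preserving class and covariate attributes.
subset_ltrc <- function(sample, idx) {
  df <- as.data.frame(sample)[idx, , drop = FALSE]
  rownames(df) <- NULL
  ltrc_sample(df)
}
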