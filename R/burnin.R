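#' Pre-genomic burn-in and its stationarity test battery
#'
#' A run begins with a burn-in during which individuals move and reproduce
#' without genomes or selection. Burn-in ends when a battery of stationarity
#' tests passes for three series: total population size, and the mean and
#' standard deviation of timestep-differenced cell-wise individual counts
#' (temporal and spatial demographic stability respectively). Each series must
#' pass both a time-lagged two-sample t-test (no mean shift between the most
#' recent window and the window one lag earlier) and an augmented
#' Dickey-Fuller test (unit root rejected).
#'
#' @name burnin
NULL

#' Mean and SD of timestep-differenced cell-wise counts
#'
#' @param counts_t,counts_prev per-cell count matrices at consecutive
#'   timesteps.
#' @return c(mean, sd) over cells of the elementwise difference.
#' @export
spatial_diff_stats <- function(counts_t, counts_prev) {
  if (!all(dim(counts_t) == dim(counts_prev))) stop("dimension mismatch")
  d <- counts_t - counts_prev
  c(mean = mean(d), sd = stats::sd(d))
}

#' Augmented Dickey-Fuller unit-root test (constant, no trend)
#'
#' Regression `diff(y)_t = a + rho * y_{t-1} + sum_i phi_i diff(y)_{t-i}`,
#' with the lag order chosen by AIC up to `k_max`. The t statistic on `rho`
#' is compared to MacKinnon (2010) finite-sample critical values for the
#' constant-only case. A constant series is reported as stationary.
#'
#' @param series numeric series (length >= 10).
#' @param alpha significance level: one of 0.01, 0.05, 0.1.
#' @param k_max maximum augmentation lag (default Schwert-style rule).
#' @return list with `statistic`, `critical`, `reject` (TRUE = unit root
#'   rejected, i.e. stationary signal).
#' @export
adf_test <- function(series, alpha = 0.05, k_max = NULL) {
  y <- as.numeric(series)
  n <- length(y)
  if (n < 10) stop("series too short for ADF test")
  if (stats::sd(y) == 0) {
    return(list(statistic = -Inf, critical = NA_real_, reject = TRUE))
  }
  if (is.null(k_max)) k_max <- max(0L, min(floor(4 * (n / 100)^0.25),
                                           floor(n / 3) - 2L))
  dy <- diff(y)
  best <- NULL; best_aic <- Inf
  for (k in 0:k_max) {
    m <- length(dy) - k
    if (m < 5) break
    rows <- (k + 1):length(dy)
    X <- cbind(1, y[rows])  # y_{t-1}
    if (k > 0) {
      lagmat <- sapply(seq_len(k), function(i) dy[rows - i])
      X <- cbind(X, lagmat)
    }
    yy <- dy[rows]
    fit <- stats::lm.fit(X, yy)
    rss <- sum(fit$residuals^2)
    aic <- m * log(rss / m) + 2 * ncol(X)
    if (aic < best_aic) {
      best_aic <- aic
      best <- list(fit = fit, X = X, yy = yy, m = m)
    }
  }
  fit <- best$fit
  rss <- sum(fit$residuals^2)
  dfree <- best$m - ncol(best$X)
  XtXinv <- chol2inv(chol(crossprod(best$X)))
  se_rho <- sqrt(rss / dfree * XtXinv[2, 2])
  stat <- fit$coefficients[2] / se_rho
  crit <- adf_critical(alpha, best$m)
  list(statistic = unname(stat), critical = crit, reject = unname(stat) < crit)
}

# MacKinnon (2010) response-surface critical values, constant, no trend
adf_critical <- function(alpha, n) {
  tab <- list(`0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
              `0.05` = c(-2.86154, -2.8903, -4.234, -40.040),
              `0.1`  = c(-2.56677, -1.5384, -2.809, 0))
  key <- as.character(alpha)
  if (!key %in% names(tab)) {
    key <- names(tab)[which.min(abs(as.numeric(names(tab)) - alpha))]
  }
  b <- tab[[key]]
  b[1] + b[2] / n + b[3] / n^2 + b[4] / n^3
}

#' Stationarity decision for one series
#'
#' TRUE iff (a) a Welch t-test between the most recent lag-length window and
#' the window `lag` steps earlier fails to reject equal means at `alpha`, and
#' (b) the ADF test rejects a unit root at `alpha`. A series shorter than
#' `2 * lag` is "not yet testable" (returns NA).
#'
#' @param series numeric series.
#' @param lag window length / offset (timesteps).
#' @param alpha significance level.
#' @return TRUE / FALSE, or NA when not yet testable.
#' @export
series_is_stationary <- function(series, lag = 50, alpha = 0.05) {
  n <- length(series)
  if (n < 2 * lag) return(NA)
  recent <- series[(n - lag + 1):n]
  earlier <- series[(n - 2 * lag + 1):(n - lag)]
  t_ok <- if (stats::sd(recent) == 0 && stats::sd(earlier) == 0) {
    mean(recent) == mean(earlier)
  } else {
    stats::t.test(recent, earlier)$p.value > alpha
  }
  # ADF on the comparison window: the early transient is not evidence about
  # the current state
  adf_ok <- adf_test(series[(n - 2 * lag + 1):n], alpha = alpha)$reject
  isTRUE(t_ok) && isTRUE(adf_ok)
}

#' Burn-in completion decision
#'
#' Complete iff the popsize, spatial-mean, and spatial-SD series all pass
#' [series_is_stationary()] and the burn-in has run at least `min_length`
#' timesteps.
#'
#' @param state list with numeric series `popsize`, `spatial_mean`,
#'   `spatial_sd`, and scalars `min_length`, `lag`, `alpha`.
#' @export
burnin_complete <- function(state) {
  n <- length(state$popsize)
  if (n < state$min_length) return(FALSE)
  ok <- vapply(list(state$popsize, state$spatial_mean, state$spatial_sd),
               series_is_stationary, logical(1),
               lag = state$lag, alpha = state$alpha)
  all(!is.na(ok)) && all(ok)
}
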