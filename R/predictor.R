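#' Best-linear-predictor weights from an autocovariance
#'
#' Solves the Toeplitz normal equations for the conditional mean of element
#' n + 1 of a zero-mean stationary series given elements 1..n:
#' `T w = c`, where `T[i, j] = acv[|i - j| + 1]` and `c[i] = acv[n + 2 - i]`.
#' A singular system is regularized by a small ridge on the diagonal, with a
#' warning.
#'
#' @param acv autocovariance at lags 0..n (length n + 1).
#' @param n number of conditioning elements; defaults to `length(acv) - 1`.
#' @return numeric weight vector of length n; the prediction is
#'   `sum(w * x[1:n])` for a centered series `x`.
#' @export
blp_weights <- function(acv, n = length(acv) - 1L) {
  stopifnot(length(acv) >= n + 1, n >= 1)
  Tm <- stats::toeplitz(acv[seq_len(n)])
  cv <- acv[(n + 1):2]
  w <- tryCatch(solve(Tm, cv), error = function(e) NULL)
  if (is.null(w)) {
    warning("singular autocovariance matrix; using ridge-regularized solve")
    w <- solve(Tm + diag(1e-8 * acv[1], n), cv)
  }
  w
}

#' Theoretically predicted final tone pitch (p34*)
#'
#' The optimal (conditional-mean) linear prediction of the 34th tone pitch
#' from the 33 preceding pitches of a 1/f^beta sequence. The mean-centered
#' log-pitch series is extrapolated with best-linear-predictor weights
#' derived from the synthesis autocovariance, then back-transformed to Hz.
#'
#' @param pitches numeric vector of 33 pitches in Hz (or `n` pitches with
#'   `n = length(pitches)` conditioning elements in general).
#' @param beta spectral exponent used to synthesize the sequence.
#' @param M circulant dimension used at synthesis (autocovariance must match).
#' @return list with `predicted_hz` (continuous prediction in Hz),
#'   `weights` (length 33) and `weight_sum` (diagnostic; near 1 for strongly
#'   autocorrelated processes, near 0 for white ones).
#' @export
predict_final_pitch <- function(pitches, beta, M = 128L) {
  n <- length(pitches)
  stopifnot(n >= 2, all(pitches > 0))
  acv <- onef_autocovariance(beta, max_lag = n, M = M)
  w <- blp_weights(acv, n)
  x <- log(pitches)
  mu <- mean(x)
  pred_log <- mu + sum(w * (x - mu))
  list(predicted_hz = exp(pred_log), weights = w, weight_sum = sum(w))
}

#' Running linear prediction of the final pitch
#'
#' For each i, the best linear prediction of element `n_total` of the
#' centered log-pitch series given elements 1..i. Used by the synthetic-data
#' generator to model the gradual build-up of predictive information.
#'
#' @param z centered (standardized) log-pitch series, length >= 1.
#' @param beta spectral exponent.
#' @param n_total index of the predicted element (default `length(z) + 1`).
#' @param M circulant dimension.
#' @return numeric vector `pred[i]` = prediction of `z[n_total]` from
#'   `z[1..i]`, for i = 1..length(z).
#' @export
running_prediction <- function(z, beta, n_total = length(z) + 1L, M = 128L) {
  n <- length(z)
  acv <- onef_autocovariance(beta, max_lag = n_total, M = M)
  out <- numeric(n)
  for (i in seq_len(n)) {
    Tm <- stats::toeplitz(acv[seq_len(i)])
    cv <- acv[(n_total - seq_len(i)) + 1L]
    w <- tryCatch(solve(Tm, cv),
                  error = function(e) solve(Tm + diag(1e-8, i), cv))
    out[i] <- sum(w * z[seq_len(i)])
  }
  out
}
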