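#' Circulant spectrum of a 1/f^beta process
#'
#' Eigenvalues of the circulant covariance used for synthesis and for the
#' best linear predictor. Power at discrete frequency j/M (j = 1..M-1,
#' folded at Nyquist) is |f|^-beta; the zero-frequency power is set equal to
#' the lowest nonzero-frequency power to avoid the DC divergence. Eigenvalues
#' are normalized to unit process variance.
#'
#' @param beta spectral exponent, in (0, 2).
#' @param M circulant dimension (even, >= 4).
#' @return numeric vector of M nonnegative eigenvalues.
#' @keywords internal
onef_eigenvalues <- function(beta, M = 128L) {
  stopifnot(M >= 4, M %% 2 == 0)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta >= 2) {
    stop("`beta` must lie in the open interval (0, 2)")
  }
  j <- seq_len(M) - 1L
  f <- pmin(j, M - j) / M
  lam <- c(NA_real_, (f[-1])^(-beta))
  lam[1] <- lam[2] # DC convention: copy lowest nonzero frequency
  neg <- lam < 0
  if (any(neg)) {
    clipped <- sum(abs(lam[neg])) / sum(abs(lam))
    lam[neg] <- 0
    if (clipped > 0.01) {
      warning(sprintf("circulant eigenvalue clipping removed %.1f%% of power",
                      100 * clipped))
    }
  }
  lam / mean(lam)
}

#' Autocovariance of the circulant 1/f^beta process
#'
#' Inverse DFT of the circulant eigenvalues; `acv[k + 1]` is the
#' autocovariance at lag k. Variance (lag 0) is 1 by construction.
#'
#' @inheritParams onef_eigenvalues
#' @param max_lag largest lag to return (< M).
#' @return numeric vector of length `max_lag + 1`.
#' @export
onef_autocovariance <- function(beta, max_lag = 33L, M = 128L) {
  stopifnot(max_lag < M)
  lam <- onef_eigenvalues(beta, M)
  r <- Re(stats::fft(lam, inverse = TRUE)) / M
  r[seq_len(max_lag + 1L)]
}

#' Synthesize a stationary Gaussian 1/f^beta series
#'
#' Samples from the stationary Gaussian process whose covariance is the
#' circulant embedding of the 1/f^beta spectrum (Hermitian-symmetric
#' spectral synthesis), and returns the first `length` elements of one
#' period. Deterministic given `seed`.
#'
#' @param beta spectral exponent, in (0, 2).
#' @param length series length (>= 2, <= M).
#' @param seed integer seed; if `NULL` the current RNG stream is used.
#' @param M circulant dimension (even, >= 2 * length recommended).
#' @return numeric vector of length `length`, zero mean, unit variance
#'   marginally.
#' @examples
#' x <- synthesize_series(0.99, 33, seed = 1)
#' @export
synthesize_series <- function(beta, length, seed = NULL, M = 128L) {
  if (!is.numeric(length) || length < 2) stop("`length` must be >= 2")
  if (length > M) stop("`length` must not exceed the circulant dimension M")
  lam <- onef_eigenvalues(beta, M) # validates beta
  draw <- function() {
    half <- M / 2
    X <- complex(M)
    X[1] <- sqrt(lam[1]) * stats::rnorm(1)
    ab <- matrix(stats::rnorm(2 * (half - 1)), ncol = 2)
    X[2:half] <- sqrt(lam[2:half] / 2) * complex(real = ab[, 1], imaginary = ab[, 2])
    X[half + 1] <- sqrt(lam[half + 1]) * stats::rnorm(1)
    X[(half + 2):M] <- Conj(X[half:2])
    x <- Re(stats::fft(X, inverse = TRUE)) / sqrt(M)
    x[seq_len(length)]
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# batched circulant sampler: B independent series as columns, using the
# current RNG stream (callers manage seeding)
.synthesize_batch <- function(beta, length, B, M = 128L) {
  lam <- onef_eigenvalues(beta, M)
  half <- M / 2
  X <- matrix(0 + 0i, M, B)
  X[1, ] <- sqrt(lam[1]) * stats::rnorm(B)
  a <- matrix(stats::rnorm((half - 1) * B), half - 1, B)
  b <- matrix(stats::rnorm((half - 1) * B), half - 1, B)
  X[2:half, ] <- sqrt(lam[2:half] / 2) * complex(real = a, imaginary = b)
  X[half + 1, ] <- sqrt(lam[half + 1]) * stats::rnorm(B)
  X[(half + 2):M, ] <- Conj(X[half:2, , drop = FALSE])
  Re(stats::mvfft(X, inverse = TRUE))[seq_len(length), , drop = FALSE] / sqrt(M)
}

#' Fit the log-log spectral slope of a series
#'
#' Least-squares fit of log periodogram power against log frequency over a
#' mid-band frequency range; for a 1/f^beta series the slope estimates -beta.
#'
#' @param x numeric series.
#' @param band numeric length-2: frequency band (cycles/sample) used in the
#'   fit; defaults to the mid-band (4/n, 0.25).
#' @return fitted slope (a single number).
#' @export
fit_spectral_slope <- function(x, band = NULL) {
  n <- length(x)
  stopifnot(n >= 16)
  if (is.null(band)) band <- c(4 / n, 0.25)
  x <- x - mean(x)
  pw <- Mod(stats::fft(x))^2 / n
  f <- (seq_len(n) - 1) / n
  keep <- f >= band[1] & f <= band[2] & pw > 0
  stats::lsfit(log(f[keep]), log(pw[keep]))$coefficients[["X"]]
}
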