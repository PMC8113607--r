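# Neuromagnetic correlates of prediction: activity during the penultimate
# tone (constant 440 Hz across trials) regressed on the theoretically
# predicted final pitch p34*, cluster-level group inference, the M100
# early-sensory spatial filter, and low/high-p34* ERF contrasts.

#' Regress penultimate-tone activity on the predicted final pitch
#'
#' Per sensor and window, OLS slope and intercept of windowed activity at
#' tone 33 on p34* across trials (three distinct p34* values per condition by
#' design; tone-33 pitch itself is constant and drops out).
#'
#' @param wa [window_average()] output for one condition.
#' @param tone tone index whose windows are regressed (default 33).
#' @param log_pstar use log-Hz p34* instead of Hz.
#' @return list of class `prediction_fit`: `slope`, `intercept` (matrices
#'   sensor x window), `pstar` (per-trial covariate).
#' @export
regress_prediction <- function(wa, tone = 33L, log_pstar = FALSE) {
  stopifnot(inherits(wa, "windowed_activity"))
  x <- wa$trials$predicted_final
  if (log_pstar) x <- log(x)
  if (stats::var(x) == 0) stop("p34* is constant across trials; slope undefined")
  xc <- x - mean(x)
  N <- wa$N[, , tone, , drop = FALSE] # S x W x 1 x trials
  S <- dim(N)[1]; W <- dim(N)[2]
  Nm <- matrix(N, S * W, length(x))
  slope <- (Nm %*% xc) / sum(xc^2)
  intercept <- rowMeans(Nm) - slope * mean(x)
  structure(list(slope = matrix(slope, S, W),
                 intercept = matrix(intercept, S, W), pstar = x),
            class = "prediction_fit")
}

# fast per-subject slope maps for permuted covariates
.slope_map <- function(Nm, x) {
  xc <- x - mean(x)
  (Nm %*% xc) / sum(xc^2)
}

#' Detect sensor clusters encoding the predicted final pitch
#'
#' Group-level one-sample t-test of per-subject regression slopes against 0,
#' per sensor and window; spatial clusters of uncorrected p < `alpha`
#' same-sign sensors are scored by |sum t| and ranked against a max-statistic
#' null built by shuffling, independently per subject, the across-trial
#' pairing between activity and p34* (permutation shared across sensors).
#' Two-tailed: clusters are significant at cluster p < 0.025.
#'
#' @param was list of [window_average()] outputs, one per subject.
#' @param adjacency sensor adjacency matrix.
#' @param n_perm permutations (default 1000).
#' @param alpha cluster-forming threshold on sensor-level p.
#' @param tone regressed tone (default 33).
#' @param seed integer seed.
#' @return list of class `prediction_clusters`: per window, `t` map and
#'   `clusters` (members, stat, p, d_cluster, sign); plus `slopes`
#'   (subject x sensor x window).
#' @export
detect_predictive_clusters <- function(was, adjacency, n_perm = 1000L,
                                       alpha = 0.05, tone = 33L, seed = 1L) {
  stopifnot(length(was) >= 2)
  n_sub <- length(was)
  S <- dim(was[[1]]$N)[1]; W <- was[[1]]$n_windows
  Nms <- lapply(was, function(wa) {
    matrix(wa$N[, , tone, , drop = FALSE], S * W, dim(wa$N)[4])
  })
  xs <- lapply(was, function(wa) wa$trials$predicted_final)
  slopes <- vapply(seq_len(n_sub),
                   function(j) as.vector(.slope_map(Nms[[j]], xs[[j]])),
                   numeric(S * W)) # (S*W) x subjects
  tmap_of <- function(sl) {
    m <- rowMeans(sl)
    se <- apply(sl, 1, stats::sd) / sqrt(ncol(sl))
    t <- m / se
    list(t = t, p = 2 * stats::pt(-abs(t), df = ncol(sl) - 1))
  }
  obs <- tmap_of(slopes)
  null_max <- matrix(NA_real_, n_perm, W)
  perm_res <- withr::with_seed(seed, {
    for (r in seq_len(n_perm)) {
      sl <- vapply(seq_len(n_sub), function(j) {
        as.vector(.slope_map(Nms[[j]], sample(xs[[j]])))
      }, numeric(S * W))
      pm <- tmap_of(sl)
      for (w in seq_len(W)) {
        idx <- ((w - 1) * S + 1):(w * S)
        null_max[r, w] <- max_cluster_stat(pm$t[idx], pm$p[idx], adjacency,
                                           alpha, signed = TRUE)
      }
    }
    null_max
  })
  windows <- vector("list", W)
  for (w in seq_len(W)) {
    idx <- ((w - 1) * S + 1):(w * S)
    cl <- find_clusters(obs$t[idx], obs$p[idx], adjacency, alpha,
                        signed = TRUE)
    cl <- permutation_pvalues(cl, perm_res[, w], tail = "upper")
    windows[[w]] <- list(window = w, t = obs$t[idx],
                         p_uncorrected = obs$p[idx], clusters = cl)
  }
  structure(list(windows = windows,
                 slopes = array(t(slopes), dim = c(n_sub, S, W)),
                 n_perm = n_perm, alpha_cluster = 0.025),
            class = "prediction_clusters")
}

#' @export
print.prediction_clusters <- function(x, ...) {
  for (wres in x$windows) {
    sig <- Filter(function(cl) cl$p < x$alpha_cluster, wres$clusters)
    cat(sprintf("window %d: %d cluster(s) significant (two-tailed, p < %.3f)\n",
                wres$window, length(sig), x$alpha_cluster))
    for (cl in sig) {
      cat(sprintf("  %d sensors, p = %.3f, d_cluster = %.1f\n",
                  length(cl$members), cl$p, cl$d_cluster))
    }
  }
  invisible(x)
}

#' Sensors of the significant predictive-processing clusters
#'
#' @param pc [detect_predictive_clusters()] result.
#' @param window window index (default: union over windows).
#' @return integer sensor indices.
#' @export
predictive_sensors <- function(pc, window = NULL) {
  ws <- if (is.null(window)) seq_along(pc$windows) else window
  sort(unique(unlist(lapply(pc$windows[ws], function(wres) {
    unlist(lapply(Filter(function(cl) cl$p < pc$alpha_cluster, wres$clusters),
                  `[[`, "members"))
  }))))
}

#' M100 early-sensory spatial filter
#'
#' Sensor weights proportional to the squared tone-locked evoked response
#' averaged over the M100 window (75-125 ms after tone onset), normalized to
#' sum 1. Filter output is the weighted sum of the raw (non-squared) sensor
#' signals.
#'
#' @param recording a `recording`.
#' @param window_s M100 window in seconds after tone onset.
#' @param n_tones tones averaged (default 34).
#' @return numeric weight vector (one per sensor, nonnegative, sums to 1).
#' @export
build_m100_filter <- function(recording, window_s = c(0.075, 0.125),
                              n_tones = 34L) {
  stopifnot(inherits(recording, "recording"))
  act <- recording$activity
  fs <- recording$fs
  erf <- colMeans(act) # sensors x samples
  n_off <- round((window_s[2] - window_s[1]) * fs)
  acc <- matrix(0, dim(erf)[1], n_off)
  for (i in seq_len(n_tones)) {
    a <- round((recording$onsets[i] + window_s[1]) * fs) + 1L
    acc <- acc + erf[, a:(a + n_off - 1L)]
  }
  m100 <- rowMeans((acc / n_tones)^2)
  if (sum(m100) == 0) {
    warning("all-zero M100 window; falling back to uniform weights")
    return(rep(1 / length(m100), length(m100)))
  }
  m100 / sum(m100)
}

#' Project a recording through sensor weights
#'
#' @param recording a `recording`.
#' @param weights one weight per sensor (e.g. an M100 filter), or a set of
#'   sensor indices to average with equal weight.
#' @return matrix trials x samples.
#' @export
apply_spatial_filter <- function(recording, weights) {
  act <- recording$activity
  S <- dim(act)[2]
  if (all(weights == round(weights)) && length(weights) < S &&
      all(weights >= 1)) {
    w <- rep(0, S)
    w[weights] <- 1 / length(weights)
  } else {
    stopifnot(length(weights) == S)
    w <- weights
  }
  d <- dim(act)
  A <- matrix(aperm(act, c(2, 1, 3)), S, d[1] * d[3])
  matrix(as.vector(w %*% A), d[1], d[3])
}

#' Per-subject low/high-p34* ERF time courses
#'
#' Combines sensors (cluster average or spatial-filter projection), low-pass
#' filters at `lp_hz` (zero-phase 4th-order Butterworth), subtracts the mean
#' of the 500 ms window preceding the first tone, and averages trials within
#' the low- and high-p34* bins.
#'
#' @param recording a `recording`.
#' @param target sensor indices (cluster) or a weight vector (filter).
#' @param lp_hz low-pass cutoff (default 35).
#' @param baseline_s pre-sequence baseline span in seconds (default 0.5).
#' @return list with `low`, `high` (sample-wise means), `times` and `fs`.
#' @export
erf_timecourse <- function(recording, target, lp_hz = 35, baseline_s = 0.5) {
  y <- apply_spatial_filter(recording, target) # trials x samples
  fs <- recording$fs
  bf <- signal::butter(4, lp_hz / (fs / 2), type = "low")
  on0 <- recording$trials$seq_onset[1]
  bl_idx <- seq_len(round(baseline_s * fs))
  for (n in seq_len(nrow(y))) {
    m <- mean(y[n, ]) # demean first: avoids zero-phase filter edge transients
    v <- signal::filtfilt(bf, y[n, ] - m) + m
    y[n, ] <- v - mean(v[bl_idx + round((on0 - baseline_s) * fs)])
  }
  bins <- recording$trials$pstar_bin
  list(low = colMeans(y[bins == "low", , drop = FALSE]),
       high = colMeans(y[bins == "high", , drop = FALSE]),
       times = (seq_len(ncol(y)) - 1) / fs, fs = fs,
       onsets = recording$onsets)
}

#' Group contrast of low vs high predicted-pitch ERFs
#'
#' Sample-wise one-sample t-test of per-subject (low - high) ERF differences
#' against zero, from the offset of the first tone to the end of the epoch,
#' with temporal cluster correction (consecutive-sample adjacency; null by
#' per-subject sign flips of the difference time courses). Two-tailed:
#' epochs significant at cluster p < 0.025.
#'
#' @param erfs list of [erf_timecourse()] results, one per subject.
#' @param n_perm permutations (default 1000).
#' @param alpha sample-level cluster-forming threshold.
#' @param seed integer seed.
#' @return list of class `erf_contrast`: `t`, `p_uncorrected`, `clusters`
#'   (each with start/end sample and times), `range` (analyzed samples),
#'   `mean_low`, `mean_high`.
#' @export
erf_contrast <- function(erfs, n_perm = 1000L, alpha = 0.05, seed = 1L) {
  stopifnot(length(erfs) >= 2)
  fs <- erfs[[1]]$fs
  diffs <- do.call(rbind, lapply(erfs, function(e) e$low - e$high))
  tone2 <- erfs[[1]]$onsets[2] # offset of the first tone
  range_idx <- (round(tone2 * fs) + 1L):ncol(diffs)
  D <- diffs[, range_idx, drop = FALSE]
  n_sub <- nrow(D)
  tmap_of <- function(M) {
    m <- colMeans(M)
    se <- apply(M, 2, stats::sd) / sqrt(nrow(M))
    t <- m / se
    list(t = t, p = 2 * stats::pt(-abs(t), df = nrow(M) - 1))
  }
  obs <- tmap_of(D)
  adj <- chain_adjacency(ncol(D))
  null_max <- withr::with_seed(seed, vapply(seq_len(n_perm), function(r) {
    flips <- sample(c(-1, 1), n_sub, replace = TRUE)
    pm <- tmap_of(D * flips)
    max_cluster_stat(pm$t, pm$p, adj, alpha, signed = TRUE)
  }, numeric(1)))
  cl <- permutation_pvalues(find_clusters(obs$t, obs$p, adj, alpha, TRUE),
                            null_max, tail = "upper")
  cl <- lapply(cl, function(c1) {
    c1$start_time <- (range_idx[min(c1$members)] - 1) / fs
    c1$end_time <- (range_idx[max(c1$members)] - 1) / fs
    c1
  })
  structure(list(t = obs$t, p_uncorrected = obs$p, clusters = cl,
                 range = range_idx, fs = fs,
                 mean_low = colMeans(do.call(rbind, lapply(erfs, `[[`, "low"))),
                 mean_high = colMeans(do.call(rbind, lapply(erfs, `[[`, "high"))),
                 alpha_cluster = 0.025),
            class = "erf_contrast")
}
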