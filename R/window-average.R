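#' Average a recording into 50-ms tone windows
#'
#' For every tone and every nonoverlapping window of `window_ms` within the
#' tone, the raw (non-baseline-corrected) samples are averaged, yielding the
#' activity tensor N[sensor, window, tone, trial]. The number of windows per
#' tone is `tone_duration / window_ms` (3, 6, 12 for 150/300/600 ms tones at
#' the 50 ms default). Sample boundaries use nearest-sample binning when the
#' rate does not divide the window exactly.
#'
#' @param recording a `recording` from [simulate_session()].
#' @param window_ms window length in ms (default 50).
#' @param n_tones tones to window (default 34).
#' @return object of class `windowed_activity`: list with `N` (array
#'   [sensor, window, tone, trial]), `trials`, `tone_duration`, `window_ms`,
#'   `n_windows`.
#' @export
window_average <- function(recording, window_ms = 50, n_tones = 34L) {
  stopifnot(inherits(recording, "recording"))
  act <- recording$activity
  fs <- recording$fs
  n_trial <- dim(act)[1]
  S <- dim(act)[2]
  Tn <- dim(act)[3]
  W <- as.integer(round(recording$tone_duration / window_ms))
  onsets <- recording$onsets[seq_len(n_tones)]
  N <- array(NA_real_, dim = c(S, W, n_tones, n_trial))
  for (i in seq_len(n_tones)) {
    for (w in seq_len(W)) {
      a <- onsets[i] + (w - 1) * window_ms / 1000
      b <- onsets[i] + w * window_ms / 1000
      idx <- (round(a * fs) + 1L):round(b * fs)
      if (idx[length(idx)] > Tn) {
        stop(sprintf("tone %d window %d extends past the recording", i, w))
      }
      # mean over samples, for all trials and sensors at once
      m <- t(rowMeans(act[, , idx, drop = FALSE], dims = 2))
      N[, w, i, ] <- m
    }
  }
  structure(list(N = N, trials = recording$trials,
                 tone_duration = recording$tone_duration,
                 window_ms = window_ms, n_windows = W,
                 layout = recording$layout),
            class = "windowed_activity")
}
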