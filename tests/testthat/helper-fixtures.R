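# Shared fixtures, built lazily and cached for the whole test run. All
# fixtures are generated in code; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fx_set <- function() {
  if (is.null(.fx$set)) .fx$set <- build_stimulus_set(seed = 42)
  .fx$set
}

fx_trials <- function() {
  if (is.null(.fx$trials)) .fx$trials <- assign_final_tones(fx_set(), seed = 43)
  .fx$trials
}

# one noiseless subject on a small grid: exact generative means, used by the
# k'-engine and simulator tests
fx_clean_session <- function() {
  if (is.null(.fx$clean)) {
    lay <- make_sensor_layout(4, 4)
    truth <- make_ground_truth(lay, n_subjects = 1, gain_predictive = 0)
    .fx$clean <- list(
      layout = lay, truth = truth,
      session = simulate_session(fx_set(), fx_trials(), truth, subject = 1,
                                 noise = noise_config(0, 0), fs = 100,
                                 seed = 11))
  }
  .fx$clean
}

# hand-built windowed activity whose response is an exact linear function of
# the design: N[s, w, i, n] = sum_k coefs[[s]][k+1] * z(p_{i-k}) (+ optional
# p34* term via pstar_coef), no noise unless noise_sd > 0
fx_manual_wa <- function(coefs, windows = 3L, tone_duration = 150,
                         pstar_coef = 0, noise_sd = 0, seed = 99) {
  set <- fx_set()
  trials <- fx_trials()
  tr <- trials[trials$tone_duration == tone_duration, ]
  tr <- tr[order(tr$trial), ]
  zmat <- (log(sequence_pitches(set)) - log(440)) /
    stats::sd(log(set$grid$values))
  S <- length(coefs)
  N <- array(0, dim = c(S, windows, 34, nrow(tr)))
  withr::with_seed(seed, {
    for (n in seq_len(nrow(tr))) {
      z <- zmat[, tr$sequence_id[n]]
      for (s in seq_len(S)) {
        cf <- coefs[[s]]
        lev <- vapply(1:33, function(i) {
          kk <- 0:min(length(cf) - 1, i - 1)
          sum(cf[kk + 1] * z[i - kk])
        }, numeric(1))
        lev <- c(lev, 0)
        lev[33] <- lev[33] + pstar_coef * tr$predicted_final[n]
        for (w in seq_len(windows)) N[s, w, , n] <- lev
      }
    }
    if (noise_sd > 0) N <- N + array(stats::rnorm(length(N), sd = noise_sd),
                                     dim = dim(N))
  })
  structure(list(N = N, trials = tr, tone_duration = tone_duration,
                 window_ms = 50, n_windows = windows, layout = NULL),
            class = "windowed_activity")
}

# minimal recording object with prescribed activity
fx_manual_recording <- function(activity, fs = 100, tone_duration = 300,
                                trials = NULL) {
  if (is.null(trials)) {
    tt <- fx_trials()
    trials <- tt[tt$tone_duration == tone_duration, ]
    trials <- trials[order(trials$trial), ][seq_len(dim(activity)[1]), ]
  }
  onsets <- trials$seq_onset[1] + (0:33) * tone_duration / 1000
  structure(list(activity = activity, fs = fs,
                 tone_duration = tone_duration, onsets = onsets,
                 trials = trials, layout = NULL),
            class = "recording")
}
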