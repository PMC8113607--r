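# Synthetic multi-sensor sessions with planted ground truth.

# standardized log pitch: zero at 440 Hz, unit = SD of the log grid
.zlog <- function(pitch_hz, grid) {
  (log(pitch_hz) - log(440)) / stats::sd(log(grid$values))
}

# evoked kernel: gamma-like, peaks at `peak` seconds, support [0, support)
.evoked_kernel <- function(t, peak = 0.1, support = 0.4) {
  k <- (t / peak) * exp(1 - t / peak)
  k[t < 0 | t >= support] <- 0
  k
}

# history level of tone i given pitch-z series and K integrated tones
.history_levels <- function(z, K, lambda) {
  n <- length(z)
  w <- lambda^(0:(K - 1))
  vapply(seq_len(n), function(i) {
    kk <- 0:min(K - 1, i - 1)
    sum(w[kk + 1] * z[i - kk])
  }, numeric(1))
}

#' Simulate one subject's recording session
#'
#' Generates, for every tone-duration condition in the trial table, a
#' sensor-array recording time-locked to the tone sequences, plus the
#' subject's behavioral ratings. Sensor activity follows the planted ground
#' truth: sensory sensors carry an evoked response to the current tone pitch,
#' informational sensors a weighted sum of the current and `k_info - 1`
#' preceding tone pitches plus a slowly varying offset proportional to the
#' running linear prediction of the final pitch, temporal sensors the same
#' history sum with a tone count set by a fixed integration span, and noise
#' sensors nothing. White noise and a non-baselined 1/f drift are added
#' everywhere. Deterministic given `seed`.
#'
#' @param set stimulus set (supplies template pitches and betas).
#' @param trials full trial table from [assign_final_tones()].
#' @param truth [make_ground_truth()] object.
#' @param subject subject index (selects `k_info`, `k_subj`, `gamma`).
#' @param noise [noise_config()] object.
#' @param fs sampling rate in Hz (default 300).
#' @param seed integer seed.
#' @param post_s silent gap after the final tone included in the epoch.
#' @return list of class `session` with elements `recordings` (named list,
#'   one `recording` per condition: `activity` array [trial, sensor, sample],
#'   `fs`, `tone_duration`, `onsets`, `trials`), `behavior` (data.frame) and
#'   `truth`.
#' @export
simulate_session <- function(set, trials, truth, subject = 1L,
                             noise = noise_config(), fs = 300, seed = 1L,
                             post_s = 0.4) {
  stopifnot(inherits(set, "stimulus_set"), inherits(truth, "ground_truth"),
            inherits(noise, "noise_config"), subject <= truth$n_subjects)
  layout <- truth$layout
  durations <- sort(unique(trials$tone_duration))
  recs <- vector("list", length(durations))
  names(recs) <- as.character(durations)
  withr::with_seed(seed, {
    for (ci in seq_along(durations)) {
      recs[[ci]] <- .simulate_condition(set, trials, truth, subject, noise,
                                        fs, durations[ci], post_s)
    }
    behavior <- .simulate_behavior_impl(set, trials, truth, subject)
  })
  structure(list(recordings = recs, behavior = behavior, truth = truth,
                 subject = subject, seed = seed),
            class = "session")
}

.simulate_condition <- function(set, trials, truth, subject, noise, fs,
                                duration_ms, post_s) {
  layout <- truth$layout
  grid <- set$grid
  S <- nrow(layout)
  tr <- trials[trials$tone_duration == duration_ms, , drop = FALSE]
  tr <- tr[order(tr$trial), , drop = FALSE]
  dur <- duration_ms / 1000
  onsets <- tr$seq_onset[1] + (0:33) * dur
  total <- tr$seq_onset[1] + 34 * dur + post_s
  Tn <- round(total * fs)
  tt <- (seq_len(Tn) - 1) / fs

  k_info <- truth$k_info[subject]
  k_temp <- round(truth$t_int_ms / duration_ms)
  if (k_temp < 1) {
    warning("integration span shorter than tone duration; temporal sensors degenerate to K = 1")
    k_temp <- 1L
  }
  Ks <- unique(c(k_info, k_temp))

  # per-unique-sequence component time courses
  zmat <- .zlog(sequence_pitches(set), grid) # 33 x 9
  n_seq <- ncol(zmat)
  tone_of <- findInterval(tt, onsets) # 0 = baseline, 1..34 tones, 34 incl gap
  in_tone <- function(i) tone_of == i & tt < onsets[i] + dur
  seg34 <- tone_of == 34L # final tone and post gap
  comps <- vector("list", n_seq)
  for (u in seq_len(n_seq)) {
    z <- zmat[, u]
    beta <- set$sequences[[u]]$beta
    sens <- numeric(Tn)
    for (i in 1:33) sens <- sens + z[i] * .evoked_kernel(tt - onsets[i])
    hist_list <- lapply(Ks, function(K) {
      h <- .history_levels(z, K, truth$lambda)
      lev <- numeric(Tn)
      for (i in 1:33) lev[in_tone(i)] <- h[i]
      lev
    })
    pred <- running_prediction(z, beta, n_total = 34L, M = set$M)
    plev <- numeric(Tn)
    for (i in 1:33) plev[in_tone(i)] <- pred[i]
    plev[seg34] <- pred[33] # prediction holds once the final tone arrives
    comps[[u]] <- rbind(sens, do.call(rbind, hist_list), pred = plev)
  }

  # sensor gain matrix over components [sens, hist_K..., pred]
  G <- matrix(0, S, length(Ks) + 2L)
  G[layout$role == "sensory", 1] <- truth$gain_sensory
  G[layout$role == "informational", 1 + match(k_info, Ks)] <- truth$gain_history
  G[layout$role == "temporal", 1 + match(k_temp, Ks)] <- truth$gain_history
  G[layout$role == "informational", length(Ks) + 2L] <- truth$gain_predictive
  base <- lapply(comps, function(cmp) G %*% cmp) # S x Tn per sequence

  # trial-specific final-tone terms
  w_hist <- truth$lambda^(0:(max(Ks) - 1))
  h34_base <- vapply(Ks, function(K) {
    vapply(seq_len(n_seq), function(u) {
      if (K > 1) sum(w_hist[2:K] * zmat[34 - (1:(K - 1)), u]) else 0
    }, numeric(1))
  }, numeric(n_seq)) # n_seq x length(Ks)
  kern34 <- .evoked_kernel(tt - onsets[34])
  sens_mask <- layout$role == "sensory"
  info_mask <- layout$role == "informational"
  temp_mask <- layout$role == "temporal"
  tone34_mask <- seg34 & tt < onsets[34] + dur

  # coarse-grid 1/f drift, linearly interpolated to the sampling rate
  fs_c <- 20
  n_c <- ceiling(total * fs_c) + 2L
  M_c <- 2^ceiling(log2(2 * n_c))
  pos <- tt * fs_c + 1
  i1 <- pmin(floor(pos), n_c - 1L)
  wq <- pos - i1

  act <- array(0, dim = c(nrow(tr), S, Tn))
  for (n in seq_len(nrow(tr))) {
    u <- tr$sequence_id[n]
    sig <- base[[u]]
    z34 <- .zlog(tr$presented_final[n], grid)
    # evoked response to the presented final tone
    if (any(sens_mask)) {
      sig[sens_mask, ] <- sig[sens_mask, ] +
        truth$gain_sensory * z34 * rep(kern34, each = sum(sens_mask))
    }
    # history level during the final tone
    h34_info <- truth$gain_history * (w_hist[1] * z34 + h34_base[u, match(k_info, Ks)])
    h34_temp <- truth$gain_history * (w_hist[1] * z34 + h34_base[u, match(k_temp, Ks)])
    sig[info_mask, tone34_mask] <- sig[info_mask, tone34_mask] + h34_info
    sig[temp_mask, tone34_mask] <- sig[temp_mask, tone34_mask] + h34_temp
    if (noise$drift_sd > 0) {
      D <- t(.synthesize_batch(noise$drift_beta, n_c, S, M = M_c)) * noise$drift_sd
      sig <- sig + D[, i1] * rep(1 - wq, each = S) + D[, i1 + 1L] * rep(wq, each = S)
    }
    if (noise$white_sd > 0) {
      sig <- sig + matrix(stats::rnorm(S * Tn, sd = noise$white_sd), S, Tn)
    }
    act[n, , ] <- sig
  }
  structure(list(activity = act, fs = fs, tone_duration = duration_ms,
                 onsets = onsets, trials = tr, layout = layout),
            class = "recording")
}

#' Simulate behavioral ratings
#'
#' Final-pitch likelihood rating: `5 - gamma * |z(p34) - zhat34|` plus noise,
#' rounded and clamped to 1..5, where `zhat34` is the subject's internal
#' prediction of the final pitch formed from the last `k_subj` tones
#' (restricted best linear predictor). Trend-strength rating is a noisy
#' readout of the sequence's autocorrelation level (1..3).
#'
#' @inheritParams simulate_session
#' @return data.frame with columns `subject`, `trial`, `sequence_id`,
#'   `tone_duration`, `pstar_bin`, `presented_final`, `likelihood_rating`,
#'   `trend_rating`.
#' @export
simulate_behavior <- function(set, trials, truth, subject = 1L, seed = 1L) {
  withr::with_seed(seed, .simulate_behavior_impl(set, trials, truth, subject))
}

.simulate_behavior_impl <- function(set, trials, truth, subject) {
  grid <- set$grid
  zmat <- .zlog(sequence_pitches(set), grid)
  K <- truth$k_subj[subject]
  gamma <- truth$gamma[subject]
  betas <- vapply(set$sequences, `[[`, numeric(1), "beta")
  beta_rank <- match(betas, sort(unique(betas)))
  # internal prediction of z34 from the last K tones, per unique sequence
  zhat <- vapply(seq_len(ncol(zmat)), function(u) {
    acv <- onef_autocovariance(betas[u], max_lag = K + 1L, M = set$M)
    w <- tryCatch(solve(stats::toeplitz(acv[1:K]), acv[2:(K + 1)]),
                  error = function(e) solve(stats::toeplitz(acv[1:K]) +
                                              diag(1e-8, K), acv[2:(K + 1)]))
    sum(w * zmat[33:(34 - K), u])
  }, numeric(1))
  z34 <- .zlog(trials$presented_final, grid)
  err <- abs(z34 - zhat[trials$sequence_id])
  raw <- 5 - gamma * err + stats::rnorm(nrow(trials), sd = truth$rating_noise_sd)
  rating <- pmin(5L, pmax(1L, as.integer(round(raw))))
  trend <- pmin(3L, pmax(1L, as.integer(round(
    beta_rank[trials$sequence_id] + stats::rnorm(nrow(trials), sd = 0.6)))))
  data.frame(subject = subject, trial = trials$trial,
             sequence_id = trials$sequence_id,
             tone_duration = trials$tone_duration,
             pstar_bin = trials$pstar_bin,
             presented_final = trials$presented_final,
             likelihood_rating = rating, trend_rating = trend)
}
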