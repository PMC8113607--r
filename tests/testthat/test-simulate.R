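test_that("noiseless window means equal the closed-form generative levels", {
  fx <- fx_clean_session()
  lay <- fx$layout
  truth <- fx$truth
  set <- fx_set()
  rec <- fx$session$recordings[["300"]]
  wa <- window_average(rec)
  zmat <- (log(sequence_pitches(set)) - log(440)) /
    stats::sd(log(set$grid$values))
  info_s <- which(lay$role == "informational")[1]
  noise_s <- which(lay$role == "noise")[1]
  temp_s <- which(lay$role == "temporal")[1]
  tr <- wa$trials
  for (n in c(1, 50)) {
    z <- zmat[, tr$sequence_id[n]]
    for (i in c(5, 20, 33)) {
      # manual history sums, independent of the generator's helper
      h_info <- sum(0.7^(0:min(6, i - 1)) * z[i - 0:min(6, i - 1)])
      expect_equal(wa$N[info_s, 2, i, n], h_info, tolerance = 1e-9)
      K <- round(1200 / 300)
      h_temp <- sum(0.7^(0:min(K - 1, i - 1)) * z[i - 0:min(K - 1, i - 1)])
      expect_equal(wa$N[temp_s, 2, i, n], h_temp, tolerance = 1e-9)
      expect_equal(wa$N[noise_s, 2, i, n], 0)
    }
  }
})

test_that("temporal sensors integrate round(T_int / duration) tones", {
  fx <- fx_clean_session()
  set <- fx_set()
  zmat <- (log(sequence_pitches(set)) - log(440)) /
    stats::sd(log(set$grid$values))
  temp_s <- which(fx$layout$role == "temporal")[1]
  for (d in c("150", "300", "600")) {
    K <- round(1200 / as.numeric(d)) # 8, 4, 2
    wa <- window_average(fx$session$recordings[[d]])
    tr <- wa$trials
    z <- zmat[, tr$sequence_id[1]]
    i <- 20
    expect_equal(wa$N[temp_s, 1, i, 1],
                 sum(0.7^(0:(K - 1)) * z[i - 0:(K - 1)]), tolerance = 1e-9)
  }
})

test_that("a sub-tone integration span degenerates to one tone with warning", {
  lay <- make_sensor_layout(4, 4)
  truth <- make_ground_truth(lay, n_subjects = 1, t_int_ms = 50)
  tt <- fx_trials()
  expect_warning(
    simulate_session(fx_set(), tt[tt$tone_duration == 150, ], truth,
                     noise = noise_config(0, 0), fs = 100, seed = 2),
    "degenerate")
})

test_that("sessions are bit-identical given the seed", {
  lay <- make_sensor_layout(4, 4)
  truth <- make_ground_truth(lay, n_subjects = 1)
  tt <- fx_trials()
  tt <- tt[tt$tone_duration == 150, ]
  a <- simulate_session(fx_set(), tt, truth, fs = 100, seed = 5)
  b <- simulate_session(fx_set(), tt, truth, fs = 100, seed = 5)
  expect_identical(a$recordings[["150"]]$activity,
                   b$recordings[["150"]]$activity)
  expect_identical(a$behavior, b$behavior)
})

test_that("OLS on a high-SNR informational sensor recovers history weights", {
  fx <- fx_clean_session()
  set <- fx_set()
  wa <- window_average(fx$session$recordings[["300"]])
  zmat <- (log(sequence_pitches(set)) - log(440)) /
    stats::sd(log(set$grid$values))
  info_s <- which(fx$layout$role == "informational")[1]
  tr <- wa$trials
  rows <- expand.grid(i = 16:32, n = seq_len(nrow(tr)))
  X <- t(vapply(seq_len(nrow(rows)),
                function(r) zmat[rows$i[r] - 0:6, tr$sequence_id[rows$n[r]]],
                numeric(7)))
  y <- wa$N[info_s, 1, 16:32, ][cbind(rows$i - 15, rows$n)]
  b <- stats::coef(stats::lm(y ~ X))[-1]
  expect_equal(unname(b), 0.7^(0:6), tolerance = 0.1)
})

test_that("ratings track the distance between presented and predicted pitch", {
  set <- fx_set()
  trials <- fx_trials()
  lay <- make_sensor_layout(4, 4)
  truth <- make_ground_truth(lay, n_subjects = 2, gamma = c(1.8, 0))
  beh <- simulate_behavior(set, trials, truth, subject = 1, seed = 21)
  expect_true(all(beh$likelihood_rating %in% 1:5))
  expect_true(all(beh$trend_rating %in% 1:3))
  # crossover: the lowest presented pitch is rated likelier after low-p34*
  # sequences than after high-p34* sequences
  lo <- beh$likelihood_rating[round(beh$presented_final) == 220]
  bin <- beh$pstar_bin[round(beh$presented_final) == 220]
  expect_gt(mean(lo[bin == "low"]), mean(lo[bin == "high"]))
  # gamma = 0: ratings carry no prediction signal
  beh0 <- simulate_behavior(set, trials, truth, subject = 2, seed = 21)
  m <- tapply(beh0$likelihood_rating, beh0$pstar_bin, mean)
  expect_lt(diff(range(m)), 0.25)
  expect_identical(beh0, simulate_behavior(set, trials, truth, 2, seed = 21))
})
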