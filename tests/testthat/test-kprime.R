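test_that("fold allocation balances repetitions of each unique sequence", {
  wa <- fx_manual_wa(list(c(1)), windows = 1L)
  fit <- fit_kprime(wa, fx_set(), windows = 1L, seed = 3)
  for (f in 1:6) {
    idx <- fit$fold_of == f
    expect_equal(sum(idx), 18)
    expect_true(all(table(wa$trials$sequence_id[idx]) == 2))
  }
})

test_that("noiseless current-tone-only activity selects k' = 0 in all folds", {
  wa <- fx_manual_wa(list(c(1)), windows = 1L)
  fit <- fit_kprime(wa, fx_set(), windows = 1L, seed = 3)
  expect_true(all(fit$fold_winners == 0))
  expect_equal(fit$kprime[1, 1], 0)
})

test_that("noiseless K-tone history selects k' = K - 1 exactly", {
  wa <- fx_manual_wa(list(0.7^(0:6), 0.7^(0:2)), windows = 1L)
  fit <- fit_kprime(wa, fx_set(), windows = 1L, seed = 3)
  expect_equal(fit$kprime[1, 1], 6)
  expect_equal(fit$kprime[2, 1], 2)
})

test_that("the CV engine matches a brute-force per-fold lm oracle", {
  wa <- fx_manual_wa(list(0.8^(0:3)), windows = 1L, noise_sd = 0.3, seed = 12)
  k_max <- 6
  fit <- fit_kprime(wa, fx_set(), k_max = k_max, windows = 1L, seed = 3)
  set <- fx_set()
  zmat <- (log(sequence_pitches(set)) - log(440)) /
    stats::sd(log(set$grid$values))
  tr <- wa$trials
  tones <- 16:32
  mk <- function(idx) {
    do.call(rbind, lapply(idx, function(n) {
      cbind(wa$N[1, 1, tones, n],
            t(vapply(tones, function(i) zmat[i - 0:k_max, tr$sequence_id[n]],
                     numeric(k_max + 1))))
    }))
  }
  brute <- integer(6)
  for (f in 1:6) {
    A <- mk(which(fit$fold_of != f))
    B <- mk(which(fit$fold_of == f))
    sse <- vapply(0:k_max, function(k) {
      Xtr <- cbind(1, A[, 2:(k + 2), drop = FALSE])
      Xte <- cbind(1, B[, 2:(k + 2), drop = FALSE])
      b <- qr.solve(Xtr, A[, 1])
      sum((B[, 1] - Xte %*% b)^2)
    }, numeric(1))
    brute[f] <- which.min(sse) - 1L
  }
  expect_equal(as.vector(fit$fold_winners[1, 1, ]), brute)
})

test_that("forcing identity permutations reproduces the unshuffled k'", {
  wa <- fx_manual_wa(list(0.7^(0:4)), windows = 1L, noise_sd = 0.2, seed = 8)
  fit <- fit_kprime(wa, fx_set(), windows = 1L, seed = 3)
  id_perms <- array(rep(1:32, 9 * 6 * 2), dim = c(32, 9, 6, 2))
  null <- fit_kprime_shuffled(wa, fx_set(), n_rep = 2, windows = 1L,
                              seed = 3, perms_override = id_perms)
  expect_equal(null$kprime[1, 1, 1], fit$kprime[1, 1])
  expect_equal(null$kprime[1, 1, 2], fit$kprime[1, 1])
})

test_that("real shuffles destroy the history signal", {
  wa <- fx_manual_wa(list(0.7^(0:6)), windows = 1L, noise_sd = 0.1, seed = 8)
  fit <- fit_kprime(wa, fx_set(), windows = 1L, seed = 3)
  null <- fit_kprime_shuffled(wa, fx_set(), n_rep = 20, windows = 1L, seed = 3)
  expect_equal(dim(null$kprime), c(1, 1, 20))
  # observed fits the genuine 7-tone history; shuffled training cannot
  expect_gt(fit$kprime[1, 1], mean(null$kprime[1, 1, ]))
})

test_that("selection is invariant to positive scaling of the activity", {
  wa <- fx_manual_wa(list(0.7^(0:4)), windows = 1L, noise_sd = 0.3, seed = 5)
  fit1 <- fit_kprime(wa, fx_set(), windows = 1L, seed = 3)
  wa$N <- wa$N * 7.3
  fit2 <- fit_kprime(wa, fx_set(), windows = 1L, seed = 3)
  expect_equal(fit1$kprime, fit2$kprime)
})

test_that("group aggregation draws the stated null and flags extremes", {
  S <- 3; W <- 2; n_rep <- 50
  mk_fit <- function(val) structure(list(kprime = matrix(val, S, W)),
                                    class = "kprime_fit")
  mk_null <- function(center) structure(
    list(kprime = array(stats::rnorm(S * W * n_rep, center, 0.5),
                        dim = c(S, W, n_rep)), n_rep = n_rep),
    class = "kprime_null")
  fits <- lapply(c(10, 11, 12), mk_fit)
  set.seed(1)
  nulls <- lapply(c(3, 3, 3), mk_null)
  g <- group_kprime_test(fits, nulls, n_draws = 1000, seed = 2)
  expect_equal(dim(g$null), c(S, W, 1000))
  expect_equal(g$observed[1, 1], 11)
  expect_true(all(g$p == 0)) # observed above every null draw
  expect_error(group_kprime_test(fits[1], nulls[1]), "length")
})

test_that("kprime_fit methods summarise and expose the estimates", {
  wa <- fx_manual_wa(list(c(1), 0.7^(0:2)), windows = 2L)
  fit <- fit_kprime(wa, fx_set(), windows = 1:2, seed = 3)
  expect_output(print(fit), "k' fit")
  expect_equal(coef(fit), fit$kprime)
  s <- summary(fit)
  expect_output(print(s), "per window")
  expect_error(fit_kprime(wa, fx_set(), k_max = 20, windows = 1L, seed = 1),
               "before the first tone")
})
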