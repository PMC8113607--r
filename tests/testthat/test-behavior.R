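# small factorial rating tables with known structure
mk_behavior <- function(ratings, dur, pstar, p34, subject = 1) {
  data.frame(subject = subject, trial = seq_along(ratings),
             sequence_id = 1, tone_duration = dur,
             pstar_bin = pstar, presented_final = p34,
             likelihood_rating = ratings, trend_rating = 1)
}

test_that("constant ratings give a zero interaction F", {
  d <- expand.grid(dur = c(150, 300), pstar = c("low", "high"),
                   p34 = c(220, 880), rep = 1:2)
  b <- mk_behavior(rep(3, nrow(d)), d$dur, d$pstar, d$p34)
  expect_equal(subject_interaction_F(b), 0)
})

test_that("empty design cells are reported by name", {
  d <- expand.grid(dur = c(150, 300), pstar = c("low", "high"),
                   p34 = c(220, 880))
  d <- d[-1, ]
  b <- mk_behavior(seq_len(nrow(d)), d$dur, d$pstar, d$p34)
  expect_error(subject_interaction_F(b), "empty design cell")
})

test_that("the interaction F matches a hand-computed sum-of-squares oracle", {
  # 2 x 2 x 2 design with 2 replicates, fully crossed
  d <- expand.grid(rep = 1:2, dur = c(150, 300), pstar = c("low", "high"),
                   p34 = c(220, 880))
  set.seed(40)
  y <- 3 + 0.8 * (d$pstar == "high") - 0.6 * (d$p34 == 880) +
    1.1 * (d$pstar == "high") * (d$p34 == 880) + rnorm(nrow(d), sd = 0.3)
  b <- mk_behavior(y, d$dur, d$pstar, d$p34)
  f_pkg <- subject_interaction_F(b)
  # oracle: textbook balanced three-way ANOVA partition, written out
  gm <- mean(y)
  eff <- function(g) tapply(y, g, mean) - gm
  a1 <- eff(d$dur); a2 <- eff(d$pstar); a3 <- eff(d$p34)
  cell12 <- tapply(y, list(d$pstar, d$p34), mean)
  ss23 <- 4 * sum((cell12 - outer(a2, rep(1, 2)) -
                     outer(rep(1, 2), a3) - gm)^2)
  cell123 <- tapply(y, list(d$dur, d$pstar, d$p34), mean)
  fitted_full <- cell123[cbind(match(d$dur, c(150, 300)),
                               match(d$pstar, c("low", "high")),
                               match(d$p34, c(220, 880)))]
  ss_err <- sum((y - fitted_full)^2)
  f_oracle <- (ss23 / 1) / (ss_err / 8)
  expect_equal(f_pkg, f_oracle, tolerance = 1e-8)
})

test_that("planted crossover exceeds the gamma = 0 Monte-Carlo null", {
  set <- fx_set()
  trials <- fx_trials()
  lay <- make_sensor_layout(4, 4)
  truth1 <- make_ground_truth(lay, n_subjects = 1, gamma = 1.8)
  truth0 <- make_ground_truth(lay, n_subjects = 1, gamma = 0,
                              rating_noise_sd = 1.5)
  f1 <- subject_interaction_F(simulate_behavior(set, trials, truth1, 1,
                                                seed = 50))
  f0 <- vapply(1:30, function(r) {
    subject_interaction_F(simulate_behavior(set, trials, truth0, 1,
                                            seed = 600 + r))
  }, numeric(1))
  expect_gt(f1, stats::quantile(f0, 0.95))
})

test_that("group RM-ANOVA agrees with a manual one-way decomposition", {
  set.seed(41)
  n_sub <- 8
  behaviors <- lapply(1:n_sub, function(j) {
    d <- expand.grid(rep = 1:2, dur = c(150, 300, 600),
                     pstar = c("low", "medium", "high"),
                     p34 = c(220, 880))
    y <- 3 + 0.5 * (d$pstar == "high") + rnorm(nrow(d), sd = 0.4) + j * 0.1
    mk_behavior(y, d$dur, d$pstar, d$p34, subject = j)
  })
  # car prints an informational note when HF epsilon exceeds 1; irrelevant
  # to the GG fallback tested here
  out <- suppressWarnings(group_rm_anova(behaviors, factors = "pstar"))
  # oracle: one-way within-subject ANOVA on subject x level cell means
  cm <- t(vapply(behaviors, function(b) {
    tapply(b$likelihood_rating, b$pstar_bin, mean)[c("low", "medium", "high")]
  }, numeric(3)))
  gm <- mean(cm)
  ss_a <- n_sub * sum((colMeans(cm) - gm)^2)
  ss_s <- 3 * sum((rowMeans(cm) - gm)^2)
  ss_err <- sum((cm - outer(rowMeans(cm), rep(1, 3)) -
                   outer(rep(1, n_sub), colMeans(cm)) + gm)^2)
  f_oracle <- (ss_a / 2) / (ss_err / (2 * (n_sub - 1)))
  expect_equal(out$F[out$effect == "pstar"], f_oracle, tolerance = 1e-8)
  expect_true(all(out$peta2 >= 0 & out$peta2 <= 1))
  expect_true(is.na(out$gg_eps[1]) || out$gg_eps[1] <= 1 + 1e-8)
})

test_that("rank correlations behave as Spearman requires", {
  fits <- function(vals) lapply(vals, function(v)
    structure(list(kprime = matrix(v, 2, 3)), class = "kprime_fit"))
  f_stats <- c(5, 3, 8, 1, 9, 2, 7, 4)
  k_sub <- -f_stats # perfect monotone decreasing
  fbc <- list(fits(k_sub), fits(k_sub), fits(k_sub))
  bb <- brain_behavior_correlation(fbc, sensors = 1:2, f_stats)
  expect_equal(bb$rho, rep(-1, 3))
  expect_true(all(bb$p_fdr >= bb$p - 1e-15)) # BH never shrinks p
  # invariance under strictly monotone transforms of either variable
  bb2 <- brain_behavior_correlation(fbc, 1:2, exp(f_stats / 3))
  expect_equal(bb2$rho, bb$rho)
  fbc3 <- list(fits(exp(k_sub / 10)), fits(exp(k_sub / 10)),
               fits(exp(k_sub / 10)))
  bb3 <- brain_behavior_correlation(fbc3, 1:2, f_stats)
  expect_equal(bb3$rho, bb$rho)
})

test_that("independent k' and F give near-zero correlation", {
  set.seed(42)
  fits <- function(vals) lapply(vals, function(v)
    structure(list(kprime = matrix(v, 2, 3)), class = "kprime_fit"))
  rhos <- vapply(1:50, function(r) {
    fbc <- list(fits(rnorm(10)), fits(rnorm(10)), fits(rnorm(10)))
    brain_behavior_correlation(fbc, 1:2, rnorm(10))$rho[1]
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.15)
})
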