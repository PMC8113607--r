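# Cross-validated sensory-history integration order (k') estimation.
#
# Windowed activity N[s, w, i, n] for tones i = 16..32 is regressed on the
# pitch of the current tone and k' preceding tones,
#   N = b0 + sum_{k=0}^{k'} b_{k+1} p_{i-k} + e,
# for k' = 0..15 (16 models). Model order is selected per sensor and window
# by six-fold cross-validated test SSE; the fold assignment allocates two
# repetitions of each unique sequence to every fold. The null re-estimates
# k' after shuffling tone order within each unique sequence in the training
# set only (current-tone pitch preserved, shuffle shared across tone-duration
# conditions).

# balanced fold assignment: two repetitions of each unique sequence per fold
.kprime_folds <- function(trials, folds) {
  seqs <- sort(unique(trials$sequence_id))
  fold_of <- integer(nrow(trials))
  for (u in seqs) {
    idx <- which(trials$sequence_id == u)
    reps <- length(idx)
    if (reps %% folds != 0L) {
      stop(sprintf("sequence %d has %d repetitions, not divisible into %d folds",
                   u, reps, folds))
    }
    per <- reps / folds
    fold_of[idx[sample.int(reps)]] <- rep(seq_len(folds), each = per)
  }
  fold_of
}

# per-(sequence, fold) response sums and squared sums over trials,
# for the pooled tone range
.kprime_suffstats <- function(wa, tones, windows) {
  N <- wa$N
  S <- dim(N)[1]
  W <- length(windows)
  C <- S * W
  nt <- length(tones)
  trials <- wa$trials
  seqs <- sort(unique(trials$sequence_id))
  list(S = S, W = W, C = C, nt = nt, seqs = seqs,
       # Y_n for trial n: nt x C matrix (cells ordered sensor-fastest)
       Y = lapply(seq_len(nrow(trials)), function(n) {
         matrix(as.vector(N[, windows, tones, n]), nrow = C, ncol = nt)
       }))
}

# design matrix for one sequence: intercept, current pitch, k_max lags;
# `z` is the (possibly shuffled) standardized log-pitch series, `z0` the
# unshuffled one supplying the current-tone column
.kprime_design <- function(z, z0, tones, k_max) {
  X <- matrix(0, length(tones), k_max + 2L)
  X[, 1] <- 1
  X[, 2] <- z0[tones]
  for (k in seq_len(k_max)) X[, k + 2L] <- z[tones - k]
  X
}

# per-cell winning k' for one fold given train/test sufficient statistics
.kprime_select <- function(G_tr, H_tr, G_te, H_te, yy_te, k_max) {
  C <- ncol(H_tr)
  sse <- matrix(NA_real_, k_max + 1L, C)
  for (k in 0:k_max) {
    idx <- seq_len(k + 2L)
    B <- tryCatch(solve(G_tr[idx, idx, drop = FALSE], H_tr[idx, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(B)) {
      warning("near-singular training design; using minimum-norm solve")
      sv <- svd(G_tr[idx, idx, drop = FALSE])
      pos <- sv$d > max(sv$d) * 1e-10
      B <- sv$v[, pos, drop = FALSE] %*%
        ((t(sv$u[, pos, drop = FALSE]) %*% H_tr[idx, , drop = FALSE]) / sv$d[pos])
    }
    sse[k + 1L, ] <- yy_te - 2 * colSums(B * H_te[idx, , drop = FALSE]) +
      colSums(B * (G_te[idx, idx, drop = FALSE] %*% B))
  }
  mins <- do.call(pmin, asplit(sse, 1))
  # ties (within relative tolerance) go to the smallest k'
  ok <- sweep(sse, 2, mins * (1 + 1e-9) + 1e-12, "<=")
  max.col(t(ok), ties.method = "first") - 1L
}

#' Estimate the sensory-history integration order k'
#'
#' Fits, per sensor and time window, 16 nested history regressions of
#' windowed activity on the current and up to 15 preceding tone pitches
#' (tones 16-32 pooled), selects the order minimizing six-fold
#' cross-validated test SSE (ties to the smaller order), and averages the
#' fold winners. Pitch covariates are standardized log pitch.
#'
#' @param wa [window_average()] output.
#' @param set stimulus set providing the unique-sequence pitches.
#' @param k_max largest history order (default 15).
#' @param folds number of CV folds (default 6).
#' @param windows window indices to fit (default all windows of the
#'   condition).
#' @param tones pooled current-tone indices (default 16:32).
#' @param seed integer seed for the fold assignment.
#' @return object of class `kprime_fit`: `kprime` (matrix sensor x window,
#'   fold-averaged), `fold_winners` (array sensor x window x fold), `fold_of`
#'   (per-trial fold), plus metadata.
#' @export
fit_kprime <- function(wa, set, k_max = 15L, folds = 6L, windows = NULL,
                       tones = 16:32, seed = 1L) {
  fit <- .kprime_engine(wa, set, k_max, folds, windows, tones, seed,
                        n_rep = 0L)
  d <- dim(fit$kprime)
  structure(list(kprime = matrix(fit$kprime[, , 1L], d[1], d[2]),
                 fold_winners = array(fit$winners[, , , 1L],
                                      dim = c(d[1], d[2], folds)),
                 fold_of = fit$fold_of, windows = fit$windows,
                 tone_duration = wa$tone_duration, k_max = k_max,
                 folds = folds, seed = seed, layout = wa$layout),
            class = "kprime_fit")
}

#' Shuffle-null distribution of k'
#'
#' Re-estimates k' after randomly permuting tone order (positions 1-32)
#' within every unique sequence in the training folds, keeping each row's
#' current-tone pitch at its original value and leaving test folds
#' unperturbed. One permutation per (sequence, fold, repetition); identical
#' `seed` and `n_rep` reproduce identical permutations, so nulls are shared
#' across tone-duration conditions as the paired geometry analysis requires.
#'
#' @inheritParams fit_kprime
#' @param n_rep number of shuffle repetitions (default 100; each yields a
#'   fold-averaged k'_shuff, i.e. `n_rep * folds` selections per cell).
#' @param perms_override optional array (32 x sequence x fold x rep) of
#'   permutations replacing the seeded ones (diagnostics).
#' @return object of class `kprime_null`: `kprime` (array sensor x window x
#'   rep, fold-averaged), `n_rep`, and metadata.
#' @export
fit_kprime_shuffled <- function(wa, set, n_rep = 100L, k_max = 15L,
                                folds = 6L, windows = NULL, tones = 16:32,
                                seed = 1L, perms_override = NULL) {
  fit <- .kprime_engine(wa, set, k_max, folds, windows, tones, seed,
                        n_rep = n_rep, perms_override = perms_override)
  structure(list(kprime = fit$kprime, fold_of = fit$fold_of,
                 windows = fit$windows, tone_duration = wa$tone_duration,
                 n_rep = n_rep, k_max = k_max, folds = folds, seed = seed),
            class = "kprime_null")
}

# shared CV engine; n_rep = 0 -> single pass with unshuffled designs;
# perms_override (array 32 x seq x fold x rep) replaces the seeded shuffles
.kprime_engine <- function(wa, set, k_max, folds, windows, tones, seed,
                           n_rep, perms_override = NULL) {
  stopifnot(inherits(wa, "windowed_activity"), inherits(set, "stimulus_set"))
  if (is.null(windows)) windows <- seq_len(wa$n_windows)
  stopifnot(all(windows >= 1), all(windows <= wa$n_windows))
  if (min(tones) - k_max < 1) {
    stop("history would reach before the first tone; raise `tones` or lower `k_max`")
  }
  trials <- wa$trials
  reps_per <- table(trials$sequence_id)
  if (length(unique(reps_per)) != 1L) {
    stop("unbalanced trial counts across unique sequences")
  }
  zmat <- .zlog(sequence_pitches(set), set$grid)
  ss <- .kprime_suffstats(wa, tones, windows)
  shuffled <- n_rep > 0L
  n_pass <- max(1L, n_rep)

  seed_state <- withr::with_seed(seed, {
    fold_of <- .kprime_folds(trials, folds)
    perms <- if (shuffled) {
      if (!is.null(perms_override)) perms_override else
        array(replicate(n_rep * folds * length(ss$seqs), sample.int(32L)),
              dim = c(32L, length(ss$seqs), folds, n_rep))
    }
    list(fold_of = fold_of, perms = perms)
  })
  fold_of <- seed_state$fold_of
  perms <- seed_state$perms

  X0 <- lapply(ss$seqs, function(u) .kprime_design(zmat[, u], zmat[, u],
                                                   tones, k_max))
  XtX0 <- lapply(X0, crossprod)

  # per-(sequence, fold) response sums / squared sums / counts
  n_seq <- length(ss$seqs)
  Ssum <- vector("list", n_seq)
  m_uf <- matrix(0L, n_seq, folds)
  yy_cells <- matrix(0, folds, ss$C)
  for (ui in seq_len(n_seq)) {
    Ssum[[ui]] <- vector("list", folds)
    for (f in seq_len(folds)) {
      idx <- which(trials$sequence_id == ss$seqs[ui] & fold_of == f)
      m_uf[ui, f] <- length(idx)
      acc <- matrix(0, ss$nt, ss$C)
      for (n in idx) {
        Yn <- t(ss$Y[[n]]) # nt x C
        acc <- acc + Yn
        yy_cells[f, ] <- yy_cells[f, ] + colSums(Yn^2)
      }
      Ssum[[ui]][[f]] <- acc
    }
  }
  Stot <- lapply(Ssum, function(l) Reduce(`+`, l))

  # test-side statistics per fold (always unshuffled)
  G_te <- vector("list", folds)
  H_te <- vector("list", folds)
  for (f in seq_len(folds)) {
    G <- matrix(0, k_max + 2L, k_max + 2L)
    H <- matrix(0, k_max + 2L, ss$C)
    for (ui in seq_len(n_seq)) {
      G <- G + m_uf[ui, f] * XtX0[[ui]]
      H <- H + crossprod(X0[[ui]], Ssum[[ui]][[f]])
    }
    G_te[[f]] <- G
    H_te[[f]] <- H
  }

  winners <- array(NA_integer_, dim = c(ss$C, folds, n_pass))
  for (r in seq_len(n_pass)) {
    for (f in seq_len(folds)) {
      G_tr <- matrix(0, k_max + 2L, k_max + 2L)
      H_tr <- matrix(0, k_max + 2L, ss$C)
      for (ui in seq_len(n_seq)) {
        m_tr <- sum(m_uf[ui, ]) - m_uf[ui, f]
        Xu <- if (shuffled) {
          zs <- zmat[, ss$seqs[ui]]
          zs[1:32] <- zs[perms[, ui, f, r]]
          .kprime_design(zs, zmat[, ss$seqs[ui]], tones, k_max)
        } else X0[[ui]]
        G_tr <- G_tr + m_tr * crossprod(Xu)
        H_tr <- H_tr + crossprod(Xu, Stot[[ui]] - Ssum[[ui]][[f]])
      }
      winners[, f, r] <- .kprime_select(G_tr, H_tr, G_te[[f]], H_te[[f]],
                                        yy_cells[f, ], k_max)
    }
  }
  kp <- apply(winners, c(1, 3), mean) # C x n_pass
  list(kprime = array(kp, dim = c(ss$S, ss$W, n_pass)),
       winners = array(winners, dim = c(ss$S, ss$W, folds, n_pass)),
       fold_of = fold_of, windows = windows)
}

#' Group-level test of k' against the shuffle null
#'
#' Observed statistic: across-subject mean k' per sensor and window. Null:
#' `n_draws` across-subject means, each drawing one shuffle repetition per
#' subject (with replacement). One-tailed p per cell = proportion of null
#' means greater than or equal to the observed mean.
#'
#' @param fits list of `kprime_fit`, one per subject (same condition).
#' @param nulls list of `kprime_null`, aligned with `fits`.
#' @param n_draws null draws (default 1000).
#' @param seed integer seed.
#' @return list of class `kprime_group`: `observed` (sensor x window),
#'   `null` (sensor x window x draw), `p` (sensor x window), `draws`
#'   (subject x draw rep indices).
#' @export
group_kprime_test <- function(fits, nulls, n_draws = 1000L, seed = 1L) {
  stopifnot(length(fits) >= 2, length(fits) == length(nulls))
  obs <- Reduce(`+`, lapply(fits, function(f) f$kprime)) / length(fits)
  draws <- withr::with_seed(seed, matrix(
    sample.int(nulls[[1]]$n_rep, length(nulls) * n_draws, replace = TRUE),
    nrow = length(nulls)))
  null <- array(0, dim = c(dim(obs), n_draws))
  for (j in seq_along(nulls)) {
    null <- null + nulls[[j]]$kprime[, , draws[j, ], drop = FALSE]
  }
  null <- null / length(nulls)
  p <- apply(sweep(null, c(1, 2), obs, ">="), c(1, 2), mean)
  structure(list(observed = obs, null = null, p = p, draws = draws),
            class = "kprime_group")
}

#' @export
print.kprime_fit <- function(x, ...) {
  cat(sprintf("k' fit: %d sensors x %d windows (%d ms tones), k' in [%g, %g]\n",
              nrow(x$kprime), ncol(x$kprime), x$tone_duration,
              min(x$kprime), max(x$kprime)))
  invisible(x)
}

#' @export
summary.kprime_fit <- function(object, ...) {
  s <- list(tone_duration = object$tone_duration,
            by_window = apply(object$kprime, 2, function(v)
              c(mean = mean(v), sd = stats::sd(v), min = min(v), max = max(v))),
            by_role = if (!is.null(object$layout))
              tapply(rowMeans(object$kprime), object$layout$role, mean))
  class(s) <- "summary.kprime_fit"
  s
}

#' @export
print.summary.kprime_fit <- function(x, ...) {
  cat(sprintf("k' estimates, %d ms tone duration\n", x$tone_duration))
  cat("per window (columns = 50 ms windows from tone onset):\n")
  print(round(x$by_window, 2))
  if (!is.null(x$by_role)) {
    cat("mean k' by planted sensor role:\n")
    print(round(x$by_role, 2))
  }
  invisible(x)
}

#' @export
coef.kprime_fit <- function(object, ...) object$kprime

#' @export
plot.kprime_fit <- function(x, ...) {
  graphics::matplot(t(x$kprime), type = "l", lty = 1,
                    col = grDevices::grey(0.6, 0.4),
                    xlab = "50 ms window", ylab = "k'",
                    main = sprintf("%d ms tone duration", x$tone_duration), ...)
  graphics::lines(colMeans(x$kprime), lwd = 2)
  invisible(x)
}
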