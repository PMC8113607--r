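# Behavioral prediction analyses: likelihood-rating ANOVAs, the per-subject
# p34* x p34 interaction F (the behavioral index of sensory-history use),
# and across-subject brain-behavior correlations.

.rating_factors <- function(behavior) {
  data.frame(rating = behavior$likelihood_rating,
             dur = factor(behavior$tone_duration),
             pstar = factor(behavior$pstar_bin,
                            levels = intersect(c("low", "medium", "high"),
                                               unique(behavior$pstar_bin))),
             p34 = factor(round(behavior$presented_final)))
}

#' Per-subject interaction F of predicted and presented final pitch
#'
#' Fixed-effects three-way factorial ANOVA (tone duration x p34* x p34) on
#' single-trial likelihood ratings; returns the F statistic of the
#' p34* x p34 interaction, the subject's behavioral index of how strongly
#' ratings depend on sequence history. Constant ratings yield F = 0.
#'
#' @param behavior one subject's behavior table from [simulate_behavior()].
#' @return single number (F >= 0).
#' @export
subject_interaction_F <- function(behavior) {
  d <- .rating_factors(behavior)
  cells <- table(d$dur, d$pstar, d$p34)
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)
    stop(sprintf("empty design cell(s), e.g. duration %s / p34* %s / p34 %s",
                 dimnames(cells)[[1]][bad[1, 1]],
                 dimnames(cells)[[2]][bad[1, 2]],
                 dimnames(cells)[[3]][bad[1, 3]]))
  }
  if (stats::var(d$rating) == 0) return(0)
  tab <- stats::anova(stats::lm(rating ~ dur * pstar * p34, data = d))
  f <- tab["pstar:p34", "F value"]
  if (!is.finite(f)) 0 else f
}

#' Group repeated-measures ANOVA on likelihood ratings
#'
#' Within-subject three-way ANOVA (tone duration x p34* x p34) on per-subject
#' cell means, with Greenhouse-Geisser correction applied whenever the
#' epsilon estimate is below 1, and partial eta squared per effect.
#'
#' @param behaviors list of behavior tables, one per subject.
#' @param factors subset of factors to keep (default all three).
#' @return data.frame of class `rm_anova`: per within-subject effect, F,
#'   uncorrected dfs and p, GG epsilon and corrected p, partial eta squared.
#' @export
group_rm_anova <- function(behaviors,
                           factors = c("dur", "pstar", "p34")) {
  stopifnot(length(behaviors) >= 2)
  cellmeans <- lapply(behaviors, function(b) {
    d <- .rating_factors(b)
    stats::aggregate(rating ~ dur + pstar + p34, data = d, FUN = mean)
  })
  base <- cellmeans[[1]][, c("dur", "pstar", "p34")]
  for (cm in cellmeans) {
    if (nrow(cm) != nrow(base)) stop("subjects differ in design cells")
  }
  keep <- factors
  idata <- base[, keep, drop = FALSE]
  Y <- do.call(rbind, lapply(cellmeans, function(cm) cm$rating))
  if (length(keep) < 3) {
    # marginalize over dropped factors
    key <- interaction(idata, drop = TRUE)
    Y <- t(apply(Y, 1, function(v) tapply(v, key, mean)))
    idata <- unique(idata)
    idata <- idata[order(interaction(idata, drop = TRUE)), , drop = FALSE]
  }
  mlm <- stats::lm(Y ~ 1)
  idesign <- stats::as.formula(paste("~", paste(keep, collapse = "*")))
  av <- car::Anova(mlm, idata = idata, idesign = idesign, type = 3)
  sm <- summary(av, multivariate = FALSE)
  ut <- sm$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  gg <- sm$pval.adjustments
  out <- data.frame(
    effect = effects,
    F = ut[effects, "F value"],
    df1 = ut[effects, "num Df"],
    df2 = ut[effects, "den Df"],
    p = ut[effects, "Pr(>F)"],
    gg_eps = NA_real_, p_gg = NA_real_,
    peta2 = ut[effects, "Sum Sq"] /
      (ut[effects, "Sum Sq"] + ut[effects, "Error SS"]),
    row.names = NULL)
  if (!is.null(gg)) {
    m <- match(out$effect, rownames(gg))
    out$gg_eps <- gg[m, "GG eps"]
    out$p_gg <- gg[m, "Pr(>F[GG])"]
  }
  # corrected p where epsilon < 1, otherwise the uncorrected one
  out$p_corrected <- ifelse(!is.na(out$p_gg) & out$gg_eps < 1, out$p_gg, out$p)
  class(out) <- c("rm_anova", "data.frame")
  out
}

#' Per-subject k' averaged across tone-duration conditions
#'
#' @param fits_by_cond list (length 3) of per-subject `kprime_fit` lists.
#' @param windows shared window indices (default 1:3).
#' @return array subject x sensor x window.
#' @export
subject_kprime_average <- function(fits_by_cond, windows = 1:3) {
  stopifnot(length(fits_by_cond) == 3)
  n_sub <- length(fits_by_cond[[1]])
  S <- nrow(fits_by_cond[[1]][[1]]$kprime)
  out <- array(0, dim = c(n_sub, S, length(windows)))
  for (ci in 1:3) {
    for (j in seq_len(n_sub)) {
      out[j, , ] <- out[j, , ] +
        fits_by_cond[[ci]][[j]]$kprime[, windows, drop = FALSE]
    }
  }
  out / 3
}

#' Correlate cluster-averaged k' with the behavioral interaction F
#'
#' For each shared time window, Spearman correlation across subjects between
#' the condition-averaged, cluster-averaged k' and the per-subject
#' p34* x p34 interaction F, with Benjamini-Hochberg FDR across windows.
#'
#' @param fits_by_cond list (length 3, ordered 150/300/600 ms) of per-subject
#'   `kprime_fit` lists.
#' @param sensors cluster sensor indices.
#' @param f_stats per-subject interaction F values.
#' @param windows shared windows (default 1:3).
#' @return data.frame with window, rho, p, p_fdr.
#' @export
brain_behavior_correlation <- function(fits_by_cond, sensors, f_stats,
                                       windows = 1:3) {
  kavg <- subject_kprime_average(fits_by_cond, windows)
  n_sub <- dim(kavg)[1]
  stopifnot(length(f_stats) == n_sub)
  if (n_sub < 5) warning("fewer than 5 subjects; rank correlation is unstable")
  res <- lapply(seq_along(windows), function(wi) {
    x <- rowMeans(kavg[, sensors, wi, drop = FALSE])
    ct <- stats::cor.test(x, f_stats, method = "spearman", exact = FALSE)
    data.frame(window = windows[wi], rho = unname(ct$estimate), p = ct$p.value)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

# spearman rho of each column of A against y
.spearman_cols <- function(A, y) {
  ry <- rank(y)
  R <- apply(A, 2, rank)
  suppressWarnings(as.vector(stats::cor(R, ry)))
}

#' Sensor-wise brain-behavior correlation with cluster correction
#'
#' Spearman rho maps (condition-averaged k' vs interaction F across
#' subjects) per sensor and shared window; the null correlates F with
#' condition-averaged k'_shuff draws (one repetition per subject per draw).
#' Clusters of same-sign sensors with uncorrected two-tailed p < `alpha` are
#' scored by |sum rho| and ranked against the max-statistic null
#' (significant at cluster p < 0.025, two-tailed).
#'
#' @inheritParams brain_behavior_correlation
#' @param nulls_by_cond list (length 3) of per-subject `kprime_null` lists.
#' @param adjacency sensor adjacency.
#' @param n_draws null draws (default 1000).
#' @param alpha cluster-forming threshold.
#' @param seed integer seed.
#' @return list of class `correlation_clusters`: per window, `rho`, `p_unc`,
#'   `clusters` (with mean rho per cluster).
#' @export
sensorwise_correlation_clusters <- function(fits_by_cond, nulls_by_cond,
                                            f_stats, adjacency,
                                            windows = 1:3, n_draws = 1000L,
                                            alpha = 0.05, seed = 1L) {
  kavg <- subject_kprime_average(fits_by_cond, windows)
  n_sub <- dim(kavg)[1]
  S <- dim(kavg)[2]
  W <- dim(kavg)[3]
  n_rep <- nulls_by_cond[[1]][[1]]$n_rep
  # condition-averaged null k' per subject: subject x sensor x window x rep
  nullavg <- array(0, dim = c(n_sub, S, W, n_rep))
  for (ci in 1:3) {
    for (j in seq_len(n_sub)) {
      nullavg[j, , , ] <- nullavg[j, , , ] +
        nulls_by_cond[[ci]][[j]]$kprime[, windows, , drop = FALSE]
    }
  }
  nullavg <- nullavg / 3
  draws <- withr::with_seed(seed, matrix(
    sample.int(n_rep, n_sub * n_draws, replace = TRUE), nrow = n_sub))

  obs_rho <- matrix(NA_real_, S, W)
  null_rho <- array(NA_real_, dim = c(S, W, n_draws))
  for (wi in seq_len(W)) {
    obs_rho[, wi] <- .spearman_cols(t(kavg[, , wi]), f_stats)
  }
  for (d in seq_len(n_draws)) {
    for (wi in seq_len(W)) {
      A <- vapply(seq_len(n_sub),
                  function(j) nullavg[j, , wi, draws[j, d]], numeric(S))
      null_rho[, wi, d] <- .spearman_cols(t(A), f_stats)
    }
  }
  res <- vector("list", W)
  for (wi in seq_len(W)) {
    nr <- abs(null_rho[, wi, ])              # S x n_draws
    p_unc <- rowMeans(nr >= abs(obs_rho[, wi]))
    # per-draw p maps by ranking within the null, then max cluster statistic
    cnt_ge <- n_draws - t(apply(nr, 1, rank, ties.method = "min")) + 1
    null_extreme <- vapply(seq_len(n_draws), function(d) {
      max_cluster_stat(null_rho[, wi, d], cnt_ge[, d] / n_draws, adjacency,
                       alpha, signed = TRUE)
    }, numeric(1))
    cl <- find_clusters(obs_rho[, wi], p_unc, adjacency, alpha, signed = TRUE)
    cl <- permutation_pvalues(cl, null_extreme, tail = "upper")
    cl <- lapply(cl, function(c1) {
      c1$mean_rho <- mean(obs_rho[c1$members, wi])
      c1
    })
    res[[wi]] <- list(window = windows[wi], rho = obs_rho[, wi],
                      p_unc = p_unc, clusters = cl)
  }
  structure(list(windows = res, alpha_cluster = 0.025),
            class = "correlation_clusters")
}
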