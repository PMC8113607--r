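# Hypothesis geometry: k'-triples across the three tone-duration conditions
# compared against the duration line (4, 2, 1) and information line (1, 1, 1)
# via vector norm, angle, and projection onto the plane the two lines span.

#' Hypothesis orientation lines
#'
#' Axes are ordered (150 ms, 300 ms, 600 ms). A fixed integration duration
#' means the integrated tone count halves as tone duration doubles, i.e.
#' direction (4, 2, 1); a fixed amount of information means an equal count at
#' every duration, i.e. direction (1, 1, 1).
#'
#' @return list with `v_dur`, `v_info` and the plane normal `normal`
#'   (= v_dur x v_info).
#' @export
hypothesis_lines <- function() {
  v_dur <- c(4, 2, 1)
  v_info <- c(1, 1, 1)
  list(v_dur = v_dur, v_info = v_info,
       normal = .cross3(v_dur, v_info))
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Euclidean norm of a k'-triple
#'
#' @param u numeric vector (or matrix with triples in rows).
#' @return nonnegative scalar (or vector, for a matrix).
#' @export
vector_norm <- function(u) {
  if (is.matrix(u)) return(sqrt(rowSums(u^2)))
  if (any(!is.finite(u))) stop("non-finite input")
  sqrt(sum(u^2))
}

#' Angle between a k'-triple and an orientation line
#'
#' Four-quadrant form: `atan2(||u x v||, u . v)`, in radians within [0, pi].
#'
#' @param u,v nonzero 3-vectors (`u` may be a matrix of row triples).
#' @return angle(s) in radians.
#' @export
vector_angle <- function(u, v) {
  if (is.matrix(u)) {
    return(apply(u, 1, vector_angle, v = v))
  }
  if (vector_norm(u) == 0 || vector_norm(v) == 0) {
    stop("angle undefined for the zero vector")
  }
  atan2(vector_norm(.cross3(u, v)), sum(u * v))
}

#' Project k'-triples onto the duration-information plane
#'
#' Orthogonal projection onto the plane spanned by the two orientation lines
#' (normal N = v_dur x v_info): `u - ((u . N)/(N . N)) N`. The literal
#' variant applies an absolute value to the correction coefficient, which
#' moves points lying on one side of the plane away from it instead of onto
#' it; it is provided for comparison only.
#'
#' @param u 3-vector or matrix of row triples.
#' @param lines [hypothesis_lines()] output.
#' @param literal use the non-signed (absolute-value) correction.
#' @return projected vector / matrix of the same shape.
#' @export
project_to_plane <- function(u, lines = hypothesis_lines(), literal = FALSE) {
  N <- lines$normal
  nn <- sum(N^2)
  if (nn == 0) stop("degenerate plane normal")
  if (is.matrix(u)) {
    co <- (u %*% N) / nn
    if (literal) co <- abs(-co)
    return(u + if (literal) outer(as.vector(co), N) else
      outer(as.vector(-co), N))
  }
  co <- (0 - sum(u * N)) / nn
  if (literal) co <- abs(co)
  u + co * N
}

#' k'-triples across tone-duration conditions
#'
#' Stacks group-averaged (or single-subject) k' maps from the three
#' conditions into per-sensor triples for the windows shared by all
#' conditions.
#'
#' @param fits_by_cond list of three `kprime_fit` lists (or matrices),
#'   ordered 150, 300, 600 ms; each element is either a sensor x window k'
#'   matrix or a list of per-subject `kprime_fit`s to be averaged.
#' @param windows shared window indices (default 1:3 = 0-150 ms).
#' @return array sensor x window x 3 (conditions).
#' @export
kprime_triples <- function(fits_by_cond, windows = 1:3) {
  stopifnot(length(fits_by_cond) == 3)
  mats <- lapply(fits_by_cond, function(fc) {
    if (is.matrix(fc)) return(fc)
    if (inherits(fc, "kprime_fit")) return(fc$kprime)
    Reduce(`+`, lapply(fc, function(f) f$kprime)) / length(fc)
  })
  S <- nrow(mats[[1]])
  out <- array(NA_real_, dim = c(S, length(windows), 3))
  for (ci in 1:3) out[, , ci] <- mats[[ci]][, windows, drop = FALSE]
  out
}

# draws of across-subject-mean null triples. With `couple_draws = FALSE`
# (default) the shuffle-repetition index is drawn independently per
# tone-duration condition, so null triples carry the same cross-condition
# estimation noise as the observed triples; with TRUE one index per subject
# per draw is shared across conditions (nulls then sit exactly on the
# information line because the tone-order permutations themselves are shared
# across conditions).
.null_triples <- function(nulls_by_cond, windows, n_draws, seed,
                          couple_draws = FALSE) {
  n_sub <- length(nulls_by_cond[[1]])
  n_rep <- nulls_by_cond[[1]][[1]]$n_rep
  draws <- withr::with_seed(seed, array(
    sample.int(n_rep, n_sub * n_draws * 3, replace = TRUE),
    dim = c(n_sub, n_draws, 3)))
  if (couple_draws) for (ci in 2:3) draws[, , ci] <- draws[, , 1]
  S <- dim(nulls_by_cond[[1]][[1]]$kprime)[1]
  W <- length(windows)
  out <- array(0, dim = c(S, W, 3, n_draws))
  for (ci in 1:3) {
    acc <- array(0, dim = c(S, W, n_draws))
    for (j in seq_len(n_sub)) {
      kp <- nulls_by_cond[[ci]][[j]]$kprime[, windows, , drop = FALSE]
      acc <- acc + array(kp[, , draws[j, , ci], drop = FALSE], dim = dim(acc))
    }
    out[, , ci, ] <- acc / n_sub
  }
  out
}

#' Cluster-level geometry test against the shuffle null
#'
#' Observed statistic: vector norm and angle to each orientation line of the
#' group-averaged k'-triples, averaged across the given sensors (arithmetic
#' mean of per-sensor values). Null: `n_draws` recomputations on
#' across-subject means of shuffle repetitions (one repetition index per
#' subject per condition per draw; see `couple_draws`). One-tailed p:
#' norm is significant when large (p = share of null >= observed), angle
#' when small (p = share of null <= observed).
#'
#' @param fits_by_cond list (length 3, ordered 150/300/600 ms) of per-subject
#'   `kprime_fit` lists.
#' @param nulls_by_cond matching list of per-subject `kprime_null` lists.
#' @param sensors sensor indices of the cluster.
#' @param window window index (within the shared 0-150 ms windows).
#' @param n_draws null draws (default 1000).
#' @param seed integer seed.
#' @param couple_draws share one shuffle-repetition index per subject across
#'   the three conditions in each null draw (default FALSE: independent per
#'   condition, matching the observed estimator's cross-condition noise).
#' @param plane2d also compute the statistics after projection onto the
#'   duration-information plane.
#' @return list of class `geometry_stat` with observed/null norm and angles
#'   and their p-values.
#' @export
cluster_geometry_test <- function(fits_by_cond, nulls_by_cond, sensors,
                                  window = 1L, n_draws = 1000L, seed = 1L,
                                  plane2d = FALSE, couple_draws = FALSE) {
  stopifnot(length(sensors) >= 1)
  lines <- hypothesis_lines()
  obs3 <- kprime_triples(fits_by_cond, windows = window)
  U <- matrix(obs3[sensors, 1, ], ncol = 3)
  null4 <- .null_triples(nulls_by_cond, window, n_draws, seed,
                         couple_draws)
  stat_of <- function(M) {
    if (plane2d) M <- project_to_plane(M, lines)
    c(norm = mean(vector_norm(M)),
      angle_info = mean(vector_angle(M, lines$v_info)),
      angle_dur = mean(vector_angle(M, lines$v_dur)))
  }
  obs <- stat_of(U)
  null <- vapply(seq_len(n_draws), function(d) {
    stat_of(matrix(null4[sensors, 1, , d], ncol = 3))
  }, numeric(3))
  p <- c(norm = mean(null["norm", ] >= obs["norm"]),
         angle_info = mean(null["angle_info", ] <= obs["angle_info"]),
         angle_dur = mean(null["angle_dur", ] <= obs["angle_dur"]))
  structure(list(observed = obs, null = null, p = p, sensors = sensors,
                 window = window, plane2d = plane2d, triples = U),
            class = "geometry_stat")
}

#' @export
print.geometry_stat <- function(x, ...) {
  cat(sprintf("cluster geometry (%d sensors, window %d%s):\n",
              length(x$sensors), x$window, if (x$plane2d) ", 2-D" else ""))
  cat(sprintf("  mean norm       %6.2f  (p = %.3f, one-tailed upper)\n",
              x$observed["norm"], x$p["norm"]))
  cat(sprintf("  angle to info   %6.3f  (p = %.3f, one-tailed lower)\n",
              x$observed["angle_info"], x$p["angle_info"]))
  cat(sprintf("  angle to dur    %6.3f  (p = %.3f, one-tailed lower)\n",
              x$observed["angle_dur"], x$p["angle_dur"]))
  invisible(x)
}

#' Array-wide geometry scan with cluster correction
#'
#' Per sensor (and shared window), norm and angle to the chosen line are
#' compared against the per-sensor shuffle null (one-tailed uncorrected p);
#' clusters of sub-threshold sensors are scored by the summed statistic and
#' ranked against a max-statistic null recomputed from the same draws.
#'
#' @inheritParams cluster_geometry_test
#' @param adjacency sensor adjacency matrix.
#' @param line `"info"` or `"duration"` (angle statistic), or `"norm"`.
#' @param alpha cluster-forming threshold.
#' @return list of class `geometry_scan`: per window, observed statistic,
#'   uncorrected p, and `clusters`.
#' @export
arraywide_geometry_scan <- function(fits_by_cond, nulls_by_cond, adjacency,
                                    line = c("info", "duration", "norm"),
                                    windows = 1:3, n_draws = 1000L,
                                    alpha = 0.05, seed = 1L,
                                    couple_draws = FALSE) {
  line <- match.arg(line)
  lines <- hypothesis_lines()
  lower <- line != "norm" # small angles are the extreme tail
  obs3 <- kprime_triples(fits_by_cond, windows = windows)
  null4 <- .null_triples(nulls_by_cond, windows, n_draws, seed,
                         couple_draws)
  S <- dim(obs3)[1]
  stat_of <- function(M) {
    switch(line,
           norm = vector_norm(M),
           info = vector_angle(M, lines$v_info),
           duration = vector_angle(M, lines$v_dur))
  }
  res <- vector("list", length(windows))
  for (wi in seq_along(windows)) {
    obs_stat <- stat_of(matrix(obs3[, wi, ], ncol = 3))
    null_stat <- vapply(seq_len(n_draws), function(d) {
      stat_of(matrix(null4[, wi, , d], ncol = 3))
    }, numeric(S)) # S x n_draws
    p_unc <- if (lower) rowMeans(null_stat <= obs_stat) else
      rowMeans(null_stat >= obs_stat)
    # Cluster scoring statistic. For the norm line, larger norm = more
    # extreme and the summed norm is used directly. Raw angles cannot be
    # summed coherently in either tail (sensors genuinely close to a line
    # have SMALL angles, so a bigger genuine cluster would score "less
    # extreme"); angle clusters are therefore scored by the summed
    # standardized deviation below the per-sensor null, z = (null mean -
    # angle) / null SD, and every cluster statistic is ranked against the
    # per-draw maxima in the upper tail.
    if (lower) {
      mu <- rowMeans(null_stat)
      sdv <- apply(null_stat, 1, stats::sd)
      sdv[sdv == 0] <- Inf
      score_obs <- (mu - obs_stat) / sdv
    } else {
      score_obs <- obs_stat
    }
    cl <- find_clusters(score_obs, p_unc, adjacency, alpha, signed = FALSE)
    null_extreme <- vapply(seq_len(n_draws), function(d) {
      st <- null_stat[, d]
      pd <- if (lower) rowMeans(null_stat <= st) else rowMeans(null_stat >= st)
      sc <- if (lower) (mu - st) / sdv else st
      max_cluster_stat(sc, pd, adjacency, alpha, signed = FALSE, tail = "upper")
    }, numeric(1))
    cl <- permutation_pvalues(cl, null_extreme, tail = "upper")
    res[[wi]] <- list(window = windows[wi], stat = obs_stat, p_unc = p_unc,
                      clusters = cl)
  }
  structure(list(line = line, windows = res, alpha_cluster = 0.05),
            class = "geometry_scan")
}

#' Sensors in significant scan clusters
#'
#' @param scan [arraywide_geometry_scan()] result.
#' @param window window position (default: union).
#' @return integer sensor indices.
#' @export
scan_sensors <- function(scan, window = NULL) {
  ws <- if (is.null(window)) seq_along(scan$windows) else window
  sort(unique(unlist(lapply(scan$windows[ws], function(wres) {
    unlist(lapply(Filter(function(cl) cl$p < scan$alpha_cluster,
                         wres$clusters), `[[`, "members"))
  }))))
}
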