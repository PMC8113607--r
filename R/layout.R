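#' Rectangular sensor layout with contiguous role patches
#'
#' Sensors live on an `nx` x `ny` grid (unit spacing). Roles are assigned in
#' spatially contiguous rectangular patches so that cluster-level inference
#' is meaningful: an `informational` patch (integrates a fixed number of
#' tones at every presentation rate), a `temporal` patch (integrates a fixed
#' time span, hence a rate-dependent number of tones), a `sensory` patch
#' (evoked response to the current tone only), and `noise` elsewhere.
#'
#' @param nx,ny grid dimensions (default 12 x 12 = 144 sensors).
#' @return data.frame of class `sensor_layout` with columns `sensor`, `x`,
#'   `y`, `role`.
#' @export
make_sensor_layout <- function(nx = 12L, ny = 12L) {
  stopifnot(nx >= 4, ny >= 4)
  pos <- expand.grid(x = seq_len(nx), y = seq_len(ny))
  ry <- max(2L, round(ny / 3))
  rx <- max(2L, round(0.4 * nx))
  role <- rep("noise", nrow(pos))
  role[pos$y <= ry & pos$x <= rx] <- "informational"
  role[pos$y <= ry & pos$x > nx - rx] <- "temporal"
  cx <- floor((nx - rx) / 2)
  role[pos$y > ny - ry & pos$x > cx & pos$x <= cx + rx] <- "sensory"
  out <- data.frame(sensor = seq_len(nrow(pos)), x = pos$x, y = pos$y,
                    role = role)
  class(out) <- c("sensor_layout", "data.frame")
  out
}

#' Sensor adjacency from a layout
#'
#' Undirected neighbor graph: sensors within Euclidean distance `max_dist`
#' (default 1.5 grid units, i.e. orthogonal and diagonal neighbors).
#'
#' @param layout a [make_sensor_layout()] data.frame.
#' @param max_dist neighbor distance threshold.
#' @return symmetric logical adjacency matrix without self-loops, with
#'   sensor ids as dimnames.
#' @export
layout_adjacency <- function(layout, max_dist = 1.5) {
  d <- as.matrix(stats::dist(cbind(layout$x, layout$y)))
  adj <- d > 0 & d <= max_dist
  dimnames(adj) <- list(layout$sensor, layout$sensor)
  adj
}

#' Planted ground truth for synthetic sessions
#'
#' Defines, per sensor, the generative role parameters (history-weight decay,
#' integration counts / span, gains) and, per subject, the internal
#' integration count `k_subj` and behavioral gain `gamma` used by the rating
#' model. Informational sensors integrate `k_info[subject]` tones at every
#' tone duration; temporal sensors integrate `round(t_int_ms / duration)`
#' tones; sensory sensors respond to the current tone only; noise sensors
#' carry no stimulus-driven signal.
#'
#' @param layout sensor layout.
#' @param n_subjects number of subjects.
#' @param k_info integrated tone count of informational sensors; scalar or
#'   one value per subject.
#' @param t_int_ms integration span (ms) of temporal sensors.
#' @param lambda geometric decay of history weights, `w_k = lambda^k`.
#' @param gain_sensory,gain_history,gain_predictive sensor gains (a, b, c).
#' @param k_subj per-subject internal integration count used by the
#'   behavioral rating model; defaults to `k_info`.
#' @param gamma per-subject behavioral gain (0 = ratings carry no
#'   prediction signal).
#' @param rating_noise_sd SD of pre-rounding rating noise.
#' @return list of class `ground_truth`.
#' @export
make_ground_truth <- function(layout, n_subjects = 12L, k_info = 7L,
                              t_int_ms = 1200, lambda = 0.7,
                              gain_sensory = 1, gain_history = 1,
                              gain_predictive = 0.1,
                              k_subj = NULL, gamma = rep(4 / 3, n_subjects),
                              rating_noise_sd = 0.5) {
  stopifnot(inherits(layout, "sensor_layout"), all(k_info >= 1),
            t_int_ms > 0, lambda > 0)
  k_info <- as.integer(rep(k_info, length.out = n_subjects))
  if (is.null(k_subj)) k_subj <- k_info
  k_subj <- as.integer(rep(k_subj, length.out = n_subjects))
  gamma <- rep(gamma, length.out = n_subjects)
  structure(list(layout = layout, n_subjects = as.integer(n_subjects),
                 k_info = k_info, t_int_ms = t_int_ms, lambda = lambda,
                 gain_sensory = gain_sensory, gain_history = gain_history,
                 gain_predictive = gain_predictive,
                 k_subj = k_subj, gamma = gamma,
                 rating_noise_sd = rating_noise_sd),
            class = "ground_truth")
}

#' Noise configuration for synthetic recordings
#'
#' @param white_sd per-sample SD of additive white sensor noise.
#' @param drift_sd marginal SD of the slow non-baselined 1/f drift.
#' @param drift_beta spectral exponent of the drift.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(white_sd = 0.5, drift_sd = 0.5, drift_beta = 1) {
  stopifnot(white_sd >= 0, drift_sd >= 0)
  structure(list(white_sd = white_sd, drift_sd = drift_sd,
                 drift_beta = drift_beta), class = "noise_config")
}
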