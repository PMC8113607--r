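#' Semitone pitch grid
#'
#' Build the set of candidate tone pitches: `n_steps` values starting at
#' `base_hz`, evenly spaced on the log scale with semitone (2^(1/12))
#' distance. The default grid (220 Hz, 25 steps) spans two octaves and ends
#' at 880 Hz.
#'
#' @param base_hz lowest pitch in Hz (> 0).
#' @param n_steps number of grid values (>= 2).
#' @return An object of class `pitch_grid`: a list with `values` (Hz,
#'   strictly increasing), `base` and `n_steps`.
#' @examples
#' g <- make_semitone_grid()
#' range(g$values) # 220 .. 880
#' @export
make_semitone_grid <- function(base_hz = 220, n_steps = 25) {
  if (!is.numeric(base_hz) || length(base_hz) != 1L || !is.finite(base_hz) ||
      base_hz <= 0) {
    stop("`base_hz` must be a single positive number")
  }
  if (!is.numeric(n_steps) || length(n_steps) != 1L || n_steps < 2 ||
      n_steps != round(n_steps)) {
    stop("`n_steps` must be an integer >= 2")
  }
  values <- base_hz * 2^((seq_len(n_steps) - 1) / 12)
  structure(list(values = values, base = base_hz, n_steps = as.integer(n_steps)),
            class = "pitch_grid")
}

#' @export
print.pitch_grid <- function(x, ...) {
  cat(sprintf("Semitone pitch grid: %d values, %.6g .. %.6g Hz\n",
              x$n_steps, x$values[1], x$values[x$n_steps]))
  invisible(x)
}

#' Scale a real-valued series onto the pitch grid
#'
#' Affinely maps a series onto the log-pitch range of the grid (min of the
#' series to `log(min(grid))`, max to `log(max(grid))`) and snaps each
#' element to the nearest grid value in log space. A value exactly midway
#' between two grid points snaps to the lower one.
#'
#' @param series numeric vector (any scale; only its shape matters).
#' @param grid a [make_semitone_grid()] object.
#' @return numeric vector of pitches in Hz, all elements of `grid$values`;
#'   the minimum maps to the lowest and the maximum to the highest grid value.
#' @export
scale_and_discretize <- function(series, grid) {
  stopifnot(inherits(grid, "pitch_grid"))
  if (!is.numeric(series) || anyNA(series) || any(!is.finite(series))) {
    stop("`series` must be finite numeric")
  }
  rng <- range(series)
  if (rng[1] == rng[2]) {
    stop("degenerate input: constant series has no range to scale")
  }
  lg <- log(grid$values)
  lo <- lg[1]
  hi <- lg[length(lg)]
  x <- (series - rng[1]) / (rng[2] - rng[1]) * (hi - lo) + lo
  grid$values[.snap_idx(x, lg)]
}

#' Snap pitches to the nearest grid value (log space)
#'
#' @param pitch_hz numeric vector of pitches in Hz.
#' @param grid a [make_semitone_grid()] object.
#' @return vector of grid values; ties snap to the lower grid point.
#' @export
snap_to_grid <- function(pitch_hz, grid) {
  stopifnot(inherits(grid, "pitch_grid"), all(pitch_hz > 0))
  grid$values[.snap_idx(log(pitch_hz), log(grid$values))]
}

# nearest value in the ascending vector lg, in index form; exact midpoints
# resolve to the lower grid point
.snap_idx <- function(x, lg) {
  mids <- (lg[-1] + lg[-length(lg)]) / 2
  findInterval(x, mids, left.open = TRUE) + 1L
}

#' The six candidate final tone pitches
#'
#' Final presented pitches sit 4, 8 or 12 semitone steps below/above 440 Hz.
#'
#' @param exact if `TRUE` (default) return exact values 440 * 2^(k/12);
#'   otherwise the conventional rounded labels (220, 277, 349, 554, 699, 880).
#' @return numeric vector of six pitches in Hz, ascending.
#' @export
final_tone_pitches <- function(exact = TRUE) {
  steps <- c(-12, -8, -4, 4, 8, 12)
  v <- 440 * 2^(steps / 12)
  if (exact) v else c(220, 277, 349, 554, 699, 880)
}
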