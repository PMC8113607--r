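#' Classify a predicted final pitch into the design bins
#'
#' Bins are defined on the semitone grid relative to 440 Hz: low = 2-3
#' semitones below (370/392 Hz), medium = exactly 440 Hz, high = 2-3
#' semitones above (494/523 Hz). Anything else falls outside the design.
#'
#' @param predicted_hz continuous predicted pitch in Hz.
#' @param grid pitch grid used for snapping.
#' @return one of "low", "medium", "high" or `NA_character_`.
#' @export
pstar_bin <- function(predicted_hz, grid = make_semitone_grid()) {
  snapped <- snap_to_grid(predicted_hz, grid)
  semis <- round(12 * log2(snapped / 440))
  out <- rep(NA_character_, length(semis))
  out[semis %in% c(-3, -2)] <- "low"
  out[semis == 0] <- "medium"
  out[semis %in% c(2, 3)] <- "high"
  out
}

#' Build the full set of tone-sequence templates
#'
#' Rejection-samples 33-tone sequences with 1/f^beta pitch statistics until
#' each cell of the 3 (beta) x 3 (predicted-final-pitch bin) design holds one
#' template whose penultimate tone is exactly 440 Hz and whose theoretically
#' predicted 34th pitch falls in the target bin. Deterministic given `seed`.
#'
#' @param beta_levels spectral exponents, default `c(0.5, 0.99, 1.5)`.
#' @param durations_ms tone durations crossed with the templates, default
#'   `c(150, 300, 600)`.
#' @param grid pitch grid.
#' @param seed integer seed.
#' @param budget maximum candidate sequences per (beta, bin) cell.
#' @param use_discretized if `TRUE` (default) the predictor runs on the
#'   discretized pitches the listener hears; `FALSE` uses the raw scaled
#'   series.
#' @param M circulant dimension for synthesis and prediction.
#' @return an object of class `stimulus_set`: list with `sequences` (list of
#'   9 templates, each with `beta`, `pstar_bin`, `pitches` (33 Hz values),
#'   `predicted_final` (continuous Hz), `predicted_snap` (grid Hz),
#'   `sequence_id`), plus `durations_ms`, `grid`, `seed`.
#' @export
build_stimulus_set <- function(beta_levels = c(0.5, 0.99, 1.5),
                               durations_ms = c(150, 300, 600),
                               grid = make_semitone_grid(),
                               seed = 1L, budget = 1e6,
                               use_discretized = TRUE, M = 128L) {
  bins <- c("low", "medium", "high")
  templates <- vector("list", length(beta_levels) * length(bins))
  lg <- log(grid$values)
  lo <- lg[1]
  span <- lg[length(lg)] - lo
  batch <- 2000L
  withr::with_seed(seed, {
    for (b in seq_along(beta_levels)) {
      beta <- beta_levels[b]
      need <- bins
      tries <- 0L
      while (length(need) > 0L) {
        if (tries >= budget) {
          stop(sprintf("rejection budget exhausted for beta = %g, bin(s): %s",
                       beta, paste(need, collapse = ", ")))
        }
        nb <- as.integer(min(batch, budget - tries))
        tries <- tries + nb
        X <- .synthesize_batch(beta, 33L, nb, M = M)
        # min-max map onto the log grid range, column-wise
        mins <- apply(X, 2, min)
        spans <- apply(X, 2, max) - mins
        LX <- sweep(sweep(X, 2, mins), 2, spans / span, "/") + lo
        P <- matrix(grid$values[.snap_idx(LX, lg)], 33L, nb)
        ok <- which(abs(P[33, ] - 440) < 1e-9)
        if (length(ok) == 0L) next
        for (cand in ok) {
          src <- if (use_discretized) P[, cand] else exp(LX[, cand])
          pf <- predict_final_pitch(src, beta, M = M)
          bin <- pstar_bin(pf$predicted_hz, grid)
          if (is.na(bin) || !(bin %in% need)) next
          templates[[(b - 1L) * 3L + match(bin, bins)]] <- list(
            sequence_id = NA_integer_, beta = beta, pstar_bin = bin,
            pitches = P[, cand], predicted_final = pf$predicted_hz,
            predicted_snap = snap_to_grid(pf$predicted_hz, grid),
            weight_sum = pf$weight_sum)
          need <- setdiff(need, bin)
          if (length(need) == 0L) break
        }
      }
    }
  })
  for (i in seq_along(templates)) templates[[i]]$sequence_id <- i
  structure(list(sequences = templates, durations_ms = durations_ms,
                 grid = grid, seed = seed, M = M),
            class = "stimulus_set")
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("Stimulus set: %d templates x %d durations (%s ms)\n",
              length(x$sequences), length(x$durations_ms),
              paste(x$durations_ms, collapse = "/")))
  for (s in x$sequences) {
    cat(sprintf("  seq %d: beta %.2f, bin %-6s p34* = %.1f Hz (snap %.1f)\n",
                s$sequence_id, s$beta, s$pstar_bin, s$predicted_final,
                s$predicted_snap))
  }
  invisible(x)
}

#' Matrix of template pitches
#'
#' @param set a [build_stimulus_set()] object.
#' @param log if `TRUE`, natural-log pitch.
#' @return 33 x n_sequences matrix.
#' @export
sequence_pitches <- function(set, log = FALSE) {
  m <- vapply(set$sequences, function(s) s$pitches, numeric(33))
  if (log) log(m) else m
}

#' Assemble the trial table with balanced final tones
#'
#' Crosses the 9 sequence templates with the tone durations and `n_blocks`
#' blocks (each distinct sequence once per block, order randomized within
#' block). Each trial's presented final pitch is drawn from the six
#' candidate values (4/8/12 semitones below/above 440 Hz) such that, across
#' the `n_blocks` repetitions of each distinct sequence, every value occurs
#' equally often.
#'
#' @param set a [build_stimulus_set()] object.
#' @param n_blocks number of blocks (default 12; must be a multiple of 6
#'   unless `balance = FALSE`).
#' @param seed integer seed.
#' @param balance require the six final pitches balanced per distinct
#'   sequence.
#' @return data.frame of class `trial_table` with columns `trial`, `block`,
#'   `sequence_id`, `beta`, `tone_duration` (ms), `pstar_bin`,
#'   `predicted_final` (Hz), `presented_final` (Hz, exact),
#'   `presented_semitones` (signed steps from 440), `seq_onset` (s, onset of
#'   tone 1 within the recording epoch). Tone i onset =
#'   `seq_onset + (i - 1) * tone_duration / 1000`.
#' @export
assign_final_tones <- function(set, n_blocks = 12L, seed = 1L,
                               balance = TRUE) {
  stopifnot(inherits(set, "stimulus_set"), n_blocks >= 1)
  finals <- final_tone_pitches()
  semis <- c(-12, -8, -4, 4, 8, 12)
  if (balance && n_blocks %% 6L != 0L) {
    stop("`n_blocks` must be a multiple of 6 to balance the six final pitches")
  }
  distinct <- expand.grid(sequence_id = vapply(set$sequences, `[[`,
                                               integer(1), "sequence_id"),
                          tone_duration = set$durations_ms)
  n_distinct <- nrow(distinct)
  withr::with_seed(seed, {
    # balanced final assignment: for each distinct sequence, a permutation of
    # n_blocks/6 copies of the six finals across blocks
    fin_idx <- matrix(0L, n_distinct, n_blocks)
    for (d in seq_len(n_distinct)) {
      pool <- if (balance) rep(seq_len(6L), n_blocks / 6L) else
        sample.int(6L, n_blocks, replace = TRUE)
      fin_idx[d, ] <- sample(pool)
    }
    rows <- vector("list", n_blocks)
    for (blk in seq_len(n_blocks)) {
      ord <- sample.int(n_distinct)
      df <- distinct[ord, , drop = FALSE]
      df$block <- blk
      df$fin <- fin_idx[cbind(ord, blk)]
      rows[[blk]] <- df
    }
  })
  tab <- do.call(rbind, rows)
  tab$trial <- seq_len(nrow(tab))
  seq_meta <- do.call(rbind, lapply(set$sequences, function(s) {
    data.frame(sequence_id = s$sequence_id, beta = s$beta,
               pstar_bin = s$pstar_bin, predicted_final = s$predicted_final)
  }))
  tab <- merge(tab, seq_meta, by = "sequence_id", sort = FALSE)
  tab <- tab[order(tab$trial), ]
  tab$presented_final <- finals[tab$fin]
  tab$presented_semitones <- semis[tab$fin]
  tab$seq_onset <- 0.5 # 500 ms pre-sequence baseline
  tab$fin <- NULL
  rownames(tab) <- NULL
  tab <- tab[, c("trial", "block", "sequence_id", "beta", "tone_duration",
                 "pstar_bin", "predicted_final", "presented_final",
                 "presented_semitones", "seq_onset")]
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Tone onset times for a trial-table row
#'
#' @param trials a trial table.
#' @param n_tones number of tones (default 34).
#' @return matrix [trial, tone] of onsets in seconds from recording start.
#' @export
tone_onsets <- function(trials, n_tones = 34L) {
  outer(trials$seq_onset, rep(1, n_tones)) +
    outer(trials$tone_duration / 1000, seq_len(n_tones) - 1)
}

#' Write / read a trial table as CSV
#'
#' The CSV carries a comment header documenting 1-based tone indexing and
#' the onset convention.
#'
#' @param trials trial table.
#' @param path file path.
#' @export
write_trial_table <- function(trials, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# trial table: one row per trial; tone indexing is 1-based (tones 1..34)",
    "# tone i onset (s) = seq_onset + (i - 1) * tone_duration / 1000"), con)
  utils::write.csv(trials, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @param path file path.
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, comment.char = "#")
  class(tab) <- c("trial_table", "data.frame")
  tab
}
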