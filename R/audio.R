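# Optional audio rendering of tone sequences. Analysis never touches audio
# samples; this exists so stimuli can be listened to / archived.

#' Render a tone sequence as audio samples
#'
#' Concatenated pure sine tones with 5 ms raised-cosine on/off ramps to
#' avoid clicks at tone boundaries.
#'
#' @param pitches_hz tone pitches in Hz.
#' @param tone_duration_ms duration per tone.
#' @param fs sampling frequency in Hz (default 44100).
#' @param ramp_ms on/off ramp length.
#' @param amplitude peak amplitude in (0, 1].
#' @return numeric vector of samples in [-1, 1].
#' @export
render_tone_sequence <- function(pitches_hz, tone_duration_ms, fs = 44100,
                                 ramp_ms = 5, amplitude = 0.9) {
  n <- round(tone_duration_ms / 1000 * fs)
  t <- (seq_len(n) - 1) / fs
  nr <- min(round(ramp_ms / 1000 * fs), floor(n / 2))
  env <- rep(1, n)
  if (nr > 0) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(nr) - 0.5) / nr))
    env[seq_len(nr)] <- ramp
    env[n + 1 - seq_len(nr)] <- ramp
  }
  unlist(lapply(pitches_hz, function(p) amplitude * env * sin(2 * pi * p * t)))
}

#' Write mono 16-bit PCM WAV
#'
#' @param samples numeric vector in [-1, 1].
#' @param path output file.
#' @param fs sampling frequency in Hz.
#' @export
write_wav <- function(samples, path, fs = 44100) {
  pcm <- as.integer(round(pmax(-1, pmin(1, samples)) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- 2L * length(pcm)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits/sample
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}
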