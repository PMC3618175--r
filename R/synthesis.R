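# Element glyph synthesis. Shapes are chosen so that distinct labels are
# separable by spectrogram correlation at default noise; timbre realism is a
# non-goal. All glyphs are deterministic given the RNG state.

synth_glyph <- function(glyph, freq_lo, freq_hi, duration, amplitude, sr) {
  n <- max(8L, round(duration * sr))
  t <- seq(0, by = 1 / sr, length.out = n)
  fc <- (freq_lo + freq_hi) / 2
  x <- switch(
    glyph,
    "whistle" = sin(2 * pi * fc * t),
    "sweep" = {
      # linear chirp lo -> hi (or hi -> lo when the band is stated inverted)
      f0 <- freq_lo
      k <- (freq_hi - freq_lo) / duration
      sin(2 * pi * (f0 * t + k * t^2 / 2))
    },
    "trill-pulse" = {
      env <- sin(pi * t / duration)^2
      sin(2 * pi * fc * t) * env
    },
    "buzz" = {
      am <- 0.5 * (1 + sign(sin(2 * pi * 70 * t)))
      (0.8 * sin(2 * pi * fc * t) + 0.4 * sin(2 * pi * 1.5 * fc * t)) * am
    },
    "click" = {
      # broadband burst: fast chirp across the stated band
      k <- (freq_hi - freq_lo) / duration
      sin(2 * pi * (freq_lo * t + k * t^2 / 2)) *
        exp(-t / (duration / 3))
    },
    abort(sprintf("Unknown glyph '%s'.", glyph))
  )
  # 5 ms raised-cosine fade at both ends to avoid clicks at boundaries
  nf <- min(n %/% 2L, max(2L, round(0.005 * sr)))
  fade <- 0.5 * (1 - cos(pi * seq_len(nf) / nf))
  x[seq_len(nf)] <- x[seq_len(nf)] * fade
  x[n - nf + seq_len(nf)] <- x[n - nf + seq_len(nf)] * rev(fade)
  # equalize loudness across glyph shapes: scale to RMS = amplitude/2 so the
  # relative amplitudes of the grammar parts (gamma loudest) hold for every
  # glyph, keeping the maximum-RMS template window on the gamma section
  rms <- sqrt(mean(x^2))
  if (rms > 0) x <- x * (0.5 / rms)
  amplitude * x
}

#' Render a song type to a waveform
#'
#' Synthesizes the element sequence of a song type into audio: each element
#' is a glyph-shaped tone repeated `reps` times with short intra-repetition
#' gaps and slightly longer inter-element gaps. The returned synthesis log is
#' the ground-truth element/part sequence used throughout the pipeline in
#' place of a human spectrogram reader.
#'
#' @param song_type A `song_type` from [draw_song_type()] or a catalogue row.
#' @param tempo_jitter Fractional uniform jitter on element/gap durations
#'   (e.g. `0.1` for +/-10%). Never changes the collapsed element sequence.
#' @param noise_db Additive white-noise level in dBFS RMS (`-Inf` = clean).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param sample_rate Hz, default 22050.
#' @param vary_reps If `TRUE`, repetition counts are redrawn from a truncated
#'   geometric around the canonical counts (repetition counts vary across
#'   renditions without affecting song-type identity).
#' @return List with `samples`, `sample_rate`, and `log`, a tibble of one row
#'   per repeated element occurrence (`label`, `part`, `start_s`, `end_s`).
#' @export
render_song <- function(song_type, tempo_jitter = 0, noise_db = -Inf,
                        seed = NULL, sample_rate = 22050, vary_reps = FALSE) {
  el <- song_type$elements
  if (!all(c("glyph", "freq_lo", "freq_hi", "duration", "amplitude") %in%
             names(el))) {
    abort("song_type$elements must carry glyph parameters.")
  }
  with_seed(seed, {
    sr <- sample_rate
    intra_gap <- 0.015
    inter_gap <- 0.045
    jit <- function(x) {
      if (tempo_jitter > 0) x * (1 + runif(length(x), -tempo_jitter,
                                           tempo_jitter)) else x
    }
    pieces <- list()
    logs <- list()
    pos <- 0
    for (i in seq_len(nrow(el))) {
      reps <- el$reps[i]
      if (vary_reps) {
        # repeated elements stay repeated: a rendition never drops a
        # repeated part to a single occurrence (repetition counts vary,
        # identity-bearing structure does not)
        lo <- if (reps >= 2L) max(2L, reps - 2L) else 1L
        reps <- as.integer(rtrunc_geom(1L, lo, reps + 2L))
      }
      for (r in seq_len(reps)) {
        d <- jit(el$duration[i])
        x <- synth_glyph(el$glyph[i], el$freq_lo[i], el$freq_hi[i], d,
                         el$amplitude[i], sr)
        pieces[[length(pieces) + 1L]] <- x
        logs[[length(logs) + 1L]] <- tibble(
          label = el$label[i], part = el$part[i],
          start_s = pos, end_s = pos + length(x) / sr)
        pos <- pos + length(x) / sr
        g <- jit(if (r < reps) intra_gap else inter_gap)
        pieces[[length(pieces) + 1L]] <- numeric(round(g * sr))
        pos <- pos + round(g * sr) / sr
      }
    }
    samples <- unlist(pieces)
    if (is.finite(noise_db)) {
      samples <- samples + rnorm(length(samples), sd = db_to_amp(noise_db))
    }
    list(samples = samples, sample_rate = sr, log = bind_rows(logs))
  })
}
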