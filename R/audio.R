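#' Spectrogram and preprocessing parameters
#'
#' Bundles the analysis settings used throughout the song pipeline:
#' FFT size 256, Hamming window, 50% overlap for the classification
#' spectrograms; resampling to 22.05 kHz; peak normalization to 85% of full
#' scale; and a spectral-gating noise reduction filter (STFT 512, bins below
#' -40 dBFS attenuated by 90 dB).
#'
#' @param fft_size STFT size for classification spectrograms (power of two).
#' @param overlap Window overlap fraction in `[0, 1)`.
#' @param resample_rate Target sampling rate, Hz.
#' @param normalize_peak Peak amplitude after volume normalization (0-1).
#' @param nr_fft Noise-reduction STFT size (power of two).
#' @param nr_threshold_db Gate threshold, dB relative to full scale.
#' @param nr_attenuation_db Attenuation applied to sub-threshold bins, dB.
#' @return A `spectrogram_params` list.
#' @export
spectrogram_params <- function(fft_size = 256L, overlap = 0.5,
                               resample_rate = 22050,
                               normalize_peak = 0.85,
                               nr_fft = 512L, nr_threshold_db = -40,
                               nr_attenuation_db = 90) {
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  if (bitwAnd(fft_size, fft_size - 1L) != 0L ||
      bitwAnd(nr_fft, nr_fft - 1L) != 0L) {
    abort("FFT sizes must be powers of two.")
  }
  structure(list(fft_size = as.integer(fft_size), overlap = overlap,
                 resample_rate = resample_rate,
                 normalize_peak = normalize_peak,
                 nr_fft = as.integer(nr_fft),
                 nr_threshold_db = nr_threshold_db,
                 nr_attenuation_db = nr_attenuation_db),
            class = "spectrogram_params")
}

# Short-time Fourier transform with hop = n/2 and a Hann window, plus the
# matching overlap-add inverse (Hann at 50% overlap sums to a constant).
stft_frames <- function(x, n) {
  hop <- n %/% 2L
  npad <- n + hop * ceiling(max(length(x) - n, 0) / hop)
  x <- c(x, numeric(npad - length(x)))
  starts <- seq(1L, npad - n + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / n)
  frames <- vapply(starts, function(s) x[s + 0:(n - 1L)] * w, numeric(n))
  list(spec = mvfft(frames), window = w, hop = hop, n = n)
}

istft_frames <- function(spec, window, hop, n, length_out) {
  frames <- Re(mvfft(spec, inverse = TRUE)) / n
  out <- numeric(ncol(frames) * hop + n)
  wsum <- numeric(length(out))
  for (j in seq_len(ncol(frames))) {
    idx <- (j - 1L) * hop + seq_len(n)
    out[idx] <- out[idx] + frames[, j] * window
    wsum[idx] <- wsum[idx] + window^2
  }
  # clamp the OLA normalizer at the boundaries (first/last half-frame) so
  # division cannot blow up where window coverage is partial
  out <- out / pmax(wsum, 0.25 * max(wsum))
  out[seq_len(length_out)]
}

# Spectral gating: attenuate STFT bins whose magnitude is below a dBFS
# threshold. A full-scale sine peaks at |X| = sum(w)/2, which defines the
# dBFS reference per bin.
spectral_gate <- function(x, n, threshold_db, attenuation_db) {
  hop <- n %/% 2L
  # pad both ends by one hop so the overlap-add window coverage is constant
  # across the whole original signal (no edge attenuation)
  xp <- c(numeric(hop), x, numeric(hop))
  st <- stft_frames(xp, n)
  ref <- sum(st$window) / 2
  mag_db <- amp_to_db(Mod(st$spec) / ref)
  gain <- ifelse(mag_db < threshold_db, db_to_amp(-attenuation_db), 1)
  out <- istft_frames(st$spec * gain, st$window, st$hop, st$n, length(xp))
  out[hop + seq_along(x)]
}

#' Preprocess a recording for song analysis
#'
#' Applies the standard conversion chain: resample to the target rate, scale
#' the waveform peak to `normalize_peak` of full scale, and run the
#' spectral-gating noise reduction. All-zero input is passed through
#' unchanged (the normalization guard).
#'
#' @param recording A `recording` (see [new_recording()], [read_wav()]).
#' @param params A [spectrogram_params()].
#' @return A preprocessed `recording` at `params$resample_rate`.
#' @export
preprocess <- function(recording, params = spectrogram_params()) {
  x <- recording$samples
  if (length(x) == 0L) abort("Empty signal.")
  sr <- recording$sample_rate
  if (sr != params$resample_rate) {
    g <- gcd_int(round(sr), round(params$resample_rate))
    x <- signal::resample(x, round(params$resample_rate) / g, round(sr) / g)
    sr <- params$resample_rate
  }
  peak <- max(abs(x))
  if (peak > 0) x <- x * (params$normalize_peak / peak)
  x <- spectral_gate(x, params$nr_fft, params$nr_threshold_db,
                     params$nr_attenuation_db)
  # gating can introduce small ripple; rescale so the output peak is exactly
  # the stated normalization target
  peak <- max(abs(x))
  if (peak > 0) x <- x * (params$normalize_peak / peak)
  new_recording(x, sr, recording$bird_id, recording$taxon_label,
                recording$locality)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Compute a magnitude spectrogram
#'
#' Magnitude STFT with a Hamming window of `fft_size` samples and hop
#' `fft_size * (1 - overlap)`, as used for template cross-correlation.
#'
#' @param samples Numeric waveform (or a `recording`).
#' @param sample_rate Hz; ignored when `samples` is a `recording`.
#' @param params A [spectrogram_params()].
#' @return A `song_spectrogram`: list with `mag` (frequency x time matrix),
#'   `freq` (Hz), `time` (s), `time_step`, `freq_step`, `params`.
#' @export
compute_spectrogram <- function(samples, sample_rate = 22050,
                                params = spectrogram_params()) {
  if (inherits(samples, "recording")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples
  }
  n <- params$fft_size
  if (length(samples) < n) abort("Input shorter than one FFT frame.")
  hop <- as.integer(round(n * (1 - params$overlap)))
  sp <- signal::specgram(samples, n = n, Fs = sample_rate,
                         window = signal::hamming(n), overlap = n - hop)
  structure(list(mag = Mod(sp$S), freq = as.numeric(sp$f),
                 time = as.numeric(sp$t),
                 time_step = hop / sample_rate,
                 freq_step = sample_rate / n, params = params),
            class = "song_spectrogram")
}

#' @export
print.song_spectrogram <- function(x, ...) {
  cat(sprintf("<song_spectrogram> %d freq bins x %d frames (%.2f s)\n",
              nrow(x$mag), ncol(x$mag),
              ncol(x$mag) * x$time_step))
  invisible(x)
}

#' Segment a recording into single songs
#'
#' Energy-based splitting: the smoothed RMS envelope is thresholded, and
#' maximal above-threshold runs separated by at least `min_gap_s` of silence
#' become song segments. Runs shorter than `min_song_s` are flagged
#' `fragmented` (fragmented and poorly recorded songs are excluded from
#' downstream category assignment).
#'
#' @param recording A `recording`.
#' @param silence_threshold_db Envelope threshold, dBFS (default -45).
#' @param min_gap_s Minimum silent gap separating songs (default 0.3 s).
#' @param min_song_s Minimum song duration (default 0.5 s).
#' @return Tibble: `segment_id`, `start_s`, `end_s`, `duration_s`,
#'   `fragmented`, and a `samples` list-column.
#' @export
segment_songs <- function(recording, silence_threshold_db = -45,
                          min_gap_s = 0.3, min_song_s = 0.5) {
  if (min_gap_s <= 0 || min_song_s <= 0) {
    abort("Thresholds must be positive.")
  }
  x <- recording$samples
  sr <- recording$sample_rate
  win <- max(1L, round(0.02 * sr))
  env <- sqrt(stats::filter(x^2, rep(1 / win, win), sides = 2))
  env[is.na(env)] <- 0
  active <- env > db_to_amp(silence_threshold_db)
  if (!any(active)) {
    return(tibble(segment_id = integer(), start_s = numeric(),
                  end_s = numeric(), duration_s = numeric(),
                  fragmented = logical(), samples = list()))
  }
  r <- rle(as.vector(active))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- tibble(start = starts[r$values], end = ends[r$values])
  # merge runs separated by less than min_gap_s
  if (nrow(runs) > 1L) {
    gap <- (runs$start[-1L] - runs$end[-nrow(runs)]) / sr
    grp <- cumsum(c(0L, as.integer(gap >= min_gap_s)))
    runs <- runs |>
      mutate(grp = grp) |>
      group_by(.data$grp) |>
      summarise(start = min(.data$start), end = max(.data$end),
                .groups = "drop") |>
      select(-"grp") |> (\(d) d[order(d$start), ])()
  }
  runs |>
    mutate(segment_id = row_number(),
           start_s = (.data$start - 1L) / sr, end_s = .data$end / sr,
           duration_s = .data$end_s - .data$start_s,
           fragmented = .data$duration_s < min_song_s,
           samples = purrr::map2(.data$start, .data$end,
                                 function(a, b) x[a:b])) |>
    select("segment_id", "start_s", "end_s", "duration_s", "fragmented",
           "samples")
}

#' Song rate of a recording
#'
#' Count of non-fragmented segments divided by the recording duration in
#' minutes.
#'
#' @param recording A `recording`.
#' @param segments Output of [segment_songs()].
#' @return Songs per minute (numeric scalar).
#' @export
song_rate <- function(recording, segments) {
  if (recording$duration <= 0) abort("Zero-duration recording.")
  sum(!segments$fragmented) / (recording$duration / 60)
}
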