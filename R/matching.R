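#' Extract maximum-amplitude templates from a rendering
#'
#' Slides a 0.5-s window along the waveform on the spectrogram hop grid and
#' returns the window(s) maximizing RMS amplitude (the "loudest" part of the
#' song type), as spectrogram excerpts. When `n_templates = 2`, the second
#' template is the loudest window that does not overlap the first. Equal-RMS
#' ties resolve to the earliest window.
#'
#' @param samples Waveform of a song-type rendering.
#' @param sample_rate Hz.
#' @param params [spectrogram_params()].
#' @param n_templates 1 or 2.
#' @param duration_s Template duration, default 0.5 s.
#' @return Tibble: `start_s`, `end_s`, `spec` (list-column of magnitude
#'   matrices).
#' @export
extract_template <- function(samples, sample_rate = 22050,
                             params = spectrogram_params(),
                             n_templates = 1L, duration_s = 0.5) {
  if (length(samples) < duration_s * sample_rate) {
    abort("Rendering shorter than the template duration.")
  }
  hop <- as.integer(round(params$fft_size * (1 - params$overlap)))
  win_n <- as.integer(round(duration_s * sample_rate / hop)) * hop
  starts <- seq(1L, length(samples) - win_n + 1L, by = hop)
  cs2 <- c(0, cumsum(samples^2))
  rms <- sqrt((cs2[starts + win_n] - cs2[starts]) / win_n)
  spec_full <- compute_spectrogram(samples, sample_rate, params)
  tframes <- as.integer(round(duration_s / spec_full$time_step))
  pick <- integer(0)
  avail <- rep(TRUE, length(starts))
  for (k in seq_len(n_templates)) {
    if (!any(avail)) break
    # near-equal RMS counts as a tie, resolved to the earliest window
    top <- max(rms[avail])
    best <- which(avail & rms >= top * (1 - 1e-3))[1L]
    pick <- c(pick, best)
    overlap <- abs(starts - starts[best]) < win_n
    avail <- avail & !overlap
  }
  purrr::map_dfr(pick, function(b) {
    f0 <- (starts[b] - 1L) %/% hop + 1L
    f1 <- min(f0 + tframes - 1L, ncol(spec_full$mag))
    tibble(start_s = (starts[b] - 1L) / sample_rate,
           end_s = (starts[b] - 1L + win_n) / sample_rate,
           spec = list(structure(
             list(mag = spec_full$mag[, f0:f1, drop = FALSE],
                  freq = spec_full$freq,
                  time = spec_full$time[f0:f1] - spec_full$time[f0],
                  time_step = spec_full$time_step,
                  freq_step = spec_full$freq_step, params = params),
             class = "song_spectrogram")))
  })
}

#' Spectrogram image cross-correlation
#'
#' Slides the template along the song's time axis (frequency axes aligned;
#' no frequency shifting) and computes, at each lag, the zero-mean
#' normalized correlation of the template with the overlapped patch. Only
#' lags with the template fully inside the song are scored. Returns the
#' maximum over lags, a score in `[-1, 1]`; the lag attaining it is attached
#' as attributes `lag_index` (0-based frames) and `lag_s`.
#'
#' @param song_spec `song_spectrogram` of the (at least as long) song.
#' @param template_spec `song_spectrogram` of the 0.5-s template.
#' @return Numeric score in `[-1, 1]` with lag attributes.
#' @export
cross_correlate <- function(song_spec, template_spec) {
  ps <- song_spec$params
  pt <- template_spec$params
  if (ps$fft_size != pt$fft_size || ps$overlap != pt$overlap ||
      ps$resample_rate != pt$resample_rate) {
    abort("Song and template spectrogram parameters differ.")
  }
  S <- song_spec$mag
  Tm <- template_spec$mag
  if (ncol(S) < ncol(Tm)) abort("Song shorter than template.")
  if (nrow(S) != nrow(Tm)) abort("Frequency axes differ.")
  nt <- ncol(Tm)
  ns <- ncol(S)
  npix <- nrow(Tm) * nt
  Tc <- Tm - mean(Tm)
  tss <- sum(Tc^2)
  X <- crossprod(S, Tc)                      # ns x nt
  d <- as.vector(row(X) - col(X))
  num_all <- rowsum(as.vector(X), group = d)
  lags <- 0:(ns - nt)
  num <- num_all[match(lags, as.integer(rownames(num_all)))]
  cs <- c(0, cumsum(colSums(S)))
  css <- c(0, cumsum(colSums(S^2)))
  psum <- cs[lags + nt + 1L] - cs[lags + 1L]
  pss <- css[lags + nt + 1L] - css[lags + 1L]
  pvar <- pmax(pss - psum^2 / npix, 0)
  denom <- sqrt(pvar * tss)
  score <- ifelse(denom > 0, num / denom, 0)
  score[is.na(score)] <- 0
  best <- which.max(score)
  structure(min(max(score[best], -1), 1),
            lag_index = lags[best],
            lag_s = lags[best] * song_spec$time_step)
}

#' Rank catalogue song types against one song
#'
#' Cross-correlates every catalogue template with the song; each song type
#' scores the maximum over its (one or two) templates. Types are ranked by
#' descending score, equal scores broken by lower template id, and the top
#' `top_k` retained for category assignment.
#'
#' @param song Song waveform, `recording`, or `song_spectrogram`.
#' @param catalogue A [build_catalogue()] result.
#' @param top_k Types retained (default 5; `Inf` keeps all).
#' @param sample_rate Hz, used when `song` is a bare waveform.
#' @return A `match_result` tibble: `rank`, `song_type_id`, `template_id`,
#'   `score`; attributes `best_song_type_id`, `best_score`.
#' @export
rank_templates <- function(song, catalogue, top_k = 5,
                           sample_rate = 22050) {
  if (nrow(catalogue$templates) == 0L) abort("Empty catalogue.")
  spec <- if (inherits(song, "song_spectrogram")) {
    song
  } else if (inherits(song, "recording")) {
    compute_spectrogram(song$samples, song$sample_rate, catalogue$params)
  } else {
    compute_spectrogram(song, sample_rate, catalogue$params)
  }
  scores <- vapply(catalogue$templates$spec, function(tm) {
    if (ncol(spec$mag) < ncol(tm$mag)) return(NA_real_)
    as.numeric(cross_correlate(spec, tm))
  }, numeric(1))
  per_tmpl <- catalogue$templates |>
    select("template_id", "song_type_id") |>
    mutate(score = scores) |>
    filter(!is.na(.data$score))
  ranked <- per_tmpl |>
    arrange(desc(.data$score), .data$template_id) |>
    group_by(.data$song_type_id) |>
    dplyr::slice(1L) |>
    ungroup() |>
    arrange(desc(.data$score), .data$template_id) |>
    mutate(rank = row_number()) |>
    select("rank", "song_type_id", "template_id", "score")
  kept <- ranked[seq_len(min(top_k, nrow(ranked))), ]
  structure(kept, class = c("match_result", class(kept)),
            best_song_type_id = if (nrow(kept)) kept$song_type_id[1L]
                                else NA_character_,
            best_score = if (nrow(kept)) kept$score[1L] else NA_real_)
}
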