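#' Perturb a catalogue song type into a partial variant
#'
#' Drops one or two beta-part elements so that the collapsed sequence
#' retains between 75% and 95% of the source type (the 'LM partial
#' catalogue' band), while keeping the loud gamma section intact so the
#' template match still finds the source type.
#'
#' @param song_type A `song_type`.
#' @return A perturbed `song_type` (id suffixed `"p"`).
#' @export
perturb_song_type <- function(song_type) {
  el <- song_type$elements
  L <- nrow(el)
  k <- if (L >= 8L) 2L else 1L
  beta_idx <- which(el$part == "beta")
  k <- min(k, length(beta_idx) - 1L)
  if (k < 1L) k <- 1L
  drop <- sample(beta_idx, k)
  structure(list(song_type_id = paste0(song_type$song_type_id, "p"),
                 species = song_type$species,
                 elements = el[-drop, ]),
            class = "song_type")
}

#' Draw a novel LM-grammar song type absent from the catalogue
#'
#' Rejection-samples the LM grammar until the draw resembles no catalogue
#' type by 75% or more (so it can only be identified through its song
#' organization and gamma parts, the 'LM' category).
#'
#' @param catalogue A `song_catalogue`.
#' @param grammar The LM grammar to draw from.
#' @param id Identifier for the new type.
#' @return A `song_type`.
#' @export
draw_novel_lm_type <- function(catalogue, grammar = song_grammar("LM"),
                               id = "N001") {
  for (i in 1:200) {
    st <- draw_song_type(grammar, id)
    res <- vapply(catalogue$types$collapsed, function(cs) {
      element_resemblance(collapsed_sequence(st), cs)
    }, numeric(1))
    if (all(res < 0.75)) return(st)
  }
  abort("Could not draw a song type distinct enough from the catalogue.")
}

#' Splice an LM gamma element onto an LL song type
#'
#' Produces the pathological case of Thrush Nightingale organization with
#' recognizable Common Nightingale gamma parts, which the cascade must send
#' to `UNCLEAR`.
#'
#' @param ll_type An LL `song_type`.
#' @param catalogue A `song_catalogue` (source of the gamma element).
#' @return A `song_type` (id suffixed `"x"`).
#' @export
splice_gamma <- function(ll_type, catalogue) {
  lm_alpha <- catalogue$grammar$alphabet
  gl <- unique(unlist(catalogue$types$gamma_labels))
  lab <- sample(gl, 1L)
  row <- lm_alpha[lm_alpha$label == lab, ]
  gamma_row <- tibble(label = lab, part = "gamma", reps = 4L,
                      glyph = row$glyph, freq_lo = row$freq_lo,
                      freq_hi = row$freq_hi, duration = row$duration,
                      amplitude = row$amplitude)
  structure(list(song_type_id = paste0(ll_type$song_type_id, "x"),
                 species = "LL",
                 elements = bind_rows(ll_type$elements, gamma_row)),
            class = "song_type")
}

#' Build a per-bird repertoire specification
#'
#' Assembles the pools a simulated singer draws from: catalogue song types
#' (truth `LM_CATALOGUE`), perturbed partial variants (`LM_PARTIAL_CATALOGUE`),
#' novel LM-grammar types (`LM`), LL-grammar types (`LL`) and optional
#' gamma-spliced LL types (`UNCLEAR`). `mixing_prop` is the probability that
#' a song is drawn from the LM-origin side (0 for a pure Thrush Nightingale
#' singer, 1 for a pure Common Nightingale repertoire).
#'
#' @param catalogue A `song_catalogue`.
#' @param mixing_prop Proportion of LM-origin songs in `[0, 1]`.
#' @param n_lm,n_partial,n_novel,n_ll,n_spliced Pool sizes per kind.
#' @param ll_grammar An LL [song_grammar()].
#' @param seed Integer seed.
#' @return A `repertoire_spec`: tibble of song types with `kind`,
#'   `truth_category`, `species`; attribute `mixing_prop`.
#' @export
make_repertoire <- function(catalogue, mixing_prop, n_lm = 5L,
                            n_partial = 2L, n_novel = 2L, n_ll = 5L,
                            n_spliced = 0L,
                            ll_grammar = song_grammar("LL"), seed = NULL) {
  stopifnot(mixing_prop >= 0, mixing_prop <= 1)
  with_seed(seed, {
    entries <- list()
    as_type <- function(i) {
      structure(list(song_type_id = catalogue$types$song_type_id[i],
                     species = "LM",
                     elements = catalogue$types$elements[[i]]),
                class = "song_type")
    }
    if (mixing_prop > 0) {
      pick <- sample(nrow(catalogue$types),
                     min(n_lm + n_partial, nrow(catalogue$types)))
      for (i in pick[seq_len(min(n_lm, length(pick)))]) {
        entries[[length(entries) + 1L]] <-
          list(type = as_type(i), kind = "catalogue",
               truth_category = "LM_CATALOGUE", species = "LM")
      }
      for (i in utils::tail(pick, max(0L, length(pick) - n_lm))) {
        entries[[length(entries) + 1L]] <-
          list(type = perturb_song_type(as_type(i)), kind = "partial",
               truth_category = "LM_PARTIAL_CATALOGUE", species = "LM")
      }
      for (j in seq_len(n_novel)) {
        entries[[length(entries) + 1L]] <-
          list(type = draw_novel_lm_type(catalogue, id = sprintf("N%03d", j)),
               kind = "novel_lm", truth_category = "LM", species = "LM")
      }
    }
    if (mixing_prop < 1 || n_spliced > 0) {
      for (j in seq_len(n_ll)) {
        entries[[length(entries) + 1L]] <-
          list(type = draw_song_type(ll_grammar, sprintf("L%03d", j)),
               kind = "ll", truth_category = "LL", species = "LL")
      }
      for (j in seq_len(n_spliced)) {
        llt <- draw_song_type(ll_grammar, sprintf("X%03d", j))
        entries[[length(entries) + 1L]] <-
          list(type = splice_gamma(llt, catalogue), kind = "spliced",
               truth_category = "UNCLEAR", species = "LL")
      }
    }
    spec <- tibble(
      song_type_id = vapply(entries, function(e) e$type$song_type_id, ""),
      kind = vapply(entries, `[[`, "", "kind"),
      truth_category = vapply(entries, `[[`, "", "truth_category"),
      species = vapply(entries, `[[`, "", "species"),
      type = purrr::map(entries, "type"))
    structure(spec, mixing_prop = mixing_prop,
              class = c("repertoire_spec", class(spec)))
  })
}

#' Simulate a field recording of one singing male
#'
#' Draws `round(duration_min * song_rate_per_min)` songs from the
#' repertoire (LM-origin side with probability `mixing_prop`), renders each
#' with tempo jitter and varying repetition counts, separates songs by
#' silent gaps of at least `min_gap_s`, adds white background noise, and
#' returns the waveform together with a ground-truth table for classifier
#' validation.
#'
#' @param repertoire A [make_repertoire()] spec.
#' @param duration_min Recording length, minutes.
#' @param song_rate_per_min Songs per minute.
#' @param seed Integer seed (fully deterministic).
#' @param noise_db Background white-noise RMS, dBFS (default -50).
#' @param min_gap_s Minimum inter-song silence (default 1 s).
#' @param sample_rate Hz.
#' @param tempo_jitter,vary_reps Per-rendition variation (see
#'   [render_song()]).
#' @return List: `recording` (a `recording`) and `truth`, a tibble with
#'   `song_idx`, `song_type_id`, `species`, `kind`, `truth_category`,
#'   `start_s`, `end_s` and the synthesis `log` list-column.
#' @export
simulate_recording <- function(repertoire, duration_min = 2,
                               song_rate_per_min = 8, seed = NULL,
                               noise_db = -50, min_gap_s = 1,
                               sample_rate = 22050, tempo_jitter = 0.05,
                               vary_reps = TRUE) {
  with_seed(seed, {
    n_songs <- round(duration_min * song_rate_per_min)
    mix <- attr(repertoire, "mixing_prop")
    lm_rows <- which(repertoire$species == "LM")
    ll_rows <- which(repertoire$species == "LL")
    renders <- vector("list", n_songs)
    meta <- vector("list", n_songs)
    for (i in seq_len(n_songs)) {
      from_lm <- runif(1) < mix
      rows <- if (from_lm && length(lm_rows)) lm_rows else ll_rows
      if (length(rows) == 0L) rows <- lm_rows
      r <- if (length(rows) == 1L) rows else sample(rows, 1L)
      renders[[i]] <- render_song(repertoire$type[[r]],
                                  tempo_jitter = tempo_jitter,
                                  sample_rate = sample_rate,
                                  vary_reps = vary_reps)
      meta[[i]] <- repertoire[r, c("song_type_id", "kind", "truth_category",
                                   "species")]
    }
    total_song <- sum(vapply(renders, function(r) length(r$samples),
                             numeric(1))) / sample_rate
    dur_s <- duration_min * 60
    slack <- dur_s - total_song - (n_songs + 1L) * min_gap_s
    if (slack < 0) {
      abort("Song rate x duration exceeds what the minimum gaps permit.")
    }
    w <- runif(n_songs + 1L)
    gaps <- min_gap_s + slack * w / sum(w)
    samples <- numeric(round(dur_s * sample_rate))
    truth <- vector("list", n_songs)
    pos <- gaps[1L]
    for (i in seq_len(n_songs)) {
      s0 <- round(pos * sample_rate)
      x <- renders[[i]]$samples
      samples[s0 + seq_along(x)] <- x
      log <- renders[[i]]$log |>
        mutate(start_s = .data$start_s + pos, end_s = .data$end_s + pos)
      truth[[i]] <- bind_cols(
        tibble(song_idx = i), meta[[i]],
        tibble(start_s = pos, end_s = pos + length(x) / sample_rate,
               log = list(log)))
      pos <- pos + length(x) / sample_rate + gaps[i + 1L]
    }
    if (is.finite(noise_db)) {
      samples <- samples + rnorm(length(samples), sd = db_to_amp(noise_db))
    }
    list(recording = new_recording(samples, sample_rate),
         truth = bind_rows(truth))
  })
}
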