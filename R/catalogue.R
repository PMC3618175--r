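#' Build a catalogue of Common Nightingale song types
#'
#' Generates `n_song_types` distinct song types from an LM grammar (no two
#' share a collapsed element sequence), renders a clean reference recording
#' of each, and cuts one or two 0.5-s maximum-amplitude spectrogram templates
#' per type. Song types containing a second repetitive phrase (a beta element
#' repeated at least three times, besides the always-repetitive gamma
#' section) are represented by two non-overlapping templates.
#'
#' @param n_song_types Number of distinct song types.
#' @param grammar An LM [song_grammar()].
#' @param seed Integer seed (full determinism: identical seeds give
#'   identical catalogues).
#' @param sample_rate Hz for the reference renderings.
#' @param params [spectrogram_params()] used for template spectrograms.
#' @return A `song_catalogue`: list with tibbles `types` (`song_type_id`,
#'   `species`, list-columns `elements`, `collapsed`, `gamma_labels`,
#'   `two_phrase`) and `templates` (`template_id`, `song_type_id`,
#'   `start_s`, `end_s`, `is_gamma`, list-column `spec`).
#' @export
build_catalogue <- function(n_song_types, grammar = song_grammar("LM"),
                            seed = 1L, sample_rate = 22050,
                            params = spectrogram_params()) {
  if (!inherits(grammar, "song_grammar") || grammar$species != "LM") {
    abort("The catalogue is built from an LM (Common Nightingale) grammar.")
  }
  stopifnot_scalar_number(n_song_types, "n_song_types", positive = TRUE)
  with_seed(seed, {
    seen <- character()
    types <- vector("list", n_song_types)
    attempts <- 0L
    i <- 0L
    while (i < n_song_types) {
      if (attempts > 60L * n_song_types) {
        abort("Alphabet too small to generate this many distinct song types.")
      }
      attempts <- attempts + 1L
      st <- draw_song_type(grammar, sprintf("A%03d", i + 1L))
      key <- paste(collapsed_sequence(st), collapse = "|")
      if (key %in% seen) next
      i <- i + 1L
      seen <- c(seen, key)
      types[[i]] <- st
    }
    tmpl <- vector("list", n_song_types)
    for (j in seq_len(n_song_types)) {
      st <- types[[j]]
      rend <- render_song(st, sample_rate = sample_rate)
      two <- any(st$elements$part == "beta" & st$elements$reps >= 3L)
      tm <- extract_template(rend$samples, sample_rate, params,
                             n_templates = if (two) 2L else 1L)
      gamma_iv <- rend$log[rend$log$part == "gamma", c("start_s", "end_s")]
      tm$is_gamma <- vapply(seq_len(nrow(tm)), function(k) {
        any(tm$start_s[k] < gamma_iv$end_s & tm$end_s[k] > gamma_iv$start_s)
      }, logical(1))
      tm$song_type_id <- st$song_type_id
      tmpl[[j]] <- tm
    }
    templates <- bind_rows(tmpl) |>
      mutate(template_id = sprintf("T%04d", row_number())) |>
      select("template_id", "song_type_id", "start_s", "end_s", "is_gamma",
             "spec")
    types_tbl <- tibble(
      song_type_id = vapply(types, `[[`, "", "song_type_id"),
      species = grammar$species,
      elements = purrr::map(types, "elements"),
      collapsed = purrr::map(types, collapsed_sequence),
      gamma_labels = purrr::map(types, function(s) {
        unique(s$elements$label[s$elements$part == "gamma"])
      }),
      two_phrase = vapply(types, function(s) {
        any(s$elements$part == "beta" & s$elements$reps >= 3L)
      }, logical(1))
    )
    structure(list(types = types_tbl, templates = templates,
                   grammar = grammar, sample_rate = sample_rate,
                   params = params, seed = seed),
              class = "song_catalogue")
  })
}

#' @export
print.song_catalogue <- function(x, ...) {
  cat(sprintf("<song_catalogue> %d song types, %d templates (%d gamma)\n",
              nrow(x$types), nrow(x$templates), sum(x$templates$is_gamma)))
  invisible(x)
}

#' Write a catalogue to a directory
#'
#' One WAV per template plus a TSV manifest (`template_id`, `song_type_id`,
#' `window_start_s`, `window_end_s`, `is_gamma`).
#'
#' @param catalogue A `song_catalogue`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_catalogue <- function(catalogue, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_len(nrow(catalogue$types))) {
    st <- structure(
      list(song_type_id = catalogue$types$song_type_id[j],
           species = catalogue$types$species[j],
           elements = catalogue$types$elements[[j]]),
      class = "song_type")
    rend <- render_song(st, sample_rate = catalogue$sample_rate)
    ids <- catalogue$templates$template_id[
      catalogue$templates$song_type_id == st$song_type_id]
    for (id in ids) {
      row <- catalogue$templates[catalogue$templates$template_id == id, ]
      a <- max(1L, round(row$start_s * catalogue$sample_rate))
      b <- min(length(rend$samples), round(row$end_s * catalogue$sample_rate))
      write_wav(rend$samples[a:b], catalogue$sample_rate,
                file.path(dir, paste0(id, ".wav")))
    }
  }
  manifest <- catalogue$templates |>
    select("template_id", "song_type_id", window_start_s = "start_s",
           window_end_s = "end_s", "is_gamma")
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(dir)
}
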