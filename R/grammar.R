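#' Species song grammars
#'
#' A song grammar describes how one species assembles songs: an alphabet of
#' acoustic elements (each a tibble row with a glyph shape, frequency band,
#' duration and relative amplitude) and an ordered list of song parts, each
#' with a pool of candidate elements and repetition-count ranges.
#'
#' The Common Nightingale (`LM`) grammar emits the canonical four-part
#' organization: a soft *alpha* introduction, a *beta* whistle series, a loud
#' repeated *gamma* section and a terminal *omega* element. The Thrush
#' Nightingale (`LL`) grammar always begins with a repeated initial part, has
#' no beta and no omega, and ends in a terminal trill.
#'
#' @param species `"LM"` (Common Nightingale) or `"LL"` (Thrush Nightingale).
#' @return A `song_grammar` object.
#' @examples
#' g <- song_grammar("LM")
#' g$parts
#' @export
song_grammar <- function(species = c("LM", "LL")) {
  species <- match.arg(species)
  if (species == "LM") {
    alphabet <- bind_rows(
      tibble(label = paste0("a", 1:3), glyph = "whistle", pool = "alpha",
             freq_lo = c(1700, 2000, 2300), freq_hi = c(2100, 2400, 2700),
             duration = 0.16, amplitude = 0.3),
      tibble(label = paste0("b", 1:6),
             glyph = rep(c("whistle", "sweep"), 3), pool = "beta",
             freq_lo = seq(2600, 6100, by = 700),
             freq_hi = seq(3200, 6700, by = 700),
             duration = 0.12, amplitude = 0.7),
      tibble(label = paste0("g", 1:12),
             glyph = rep(c("trill-pulse", "buzz"), 6), pool = "gamma",
             freq_lo = seq(1500, 4800, by = 300),
             freq_hi = seq(2300, 5600, by = 300),
             duration = rep(c(0.06, 0.07), 6), amplitude = 1.0),
      tibble(label = paste0("o", 1:3),
             glyph = c("click", "sweep", "click"), pool = "omega",
             freq_lo = c(1200, 4500, 2000), freq_hi = c(7000, 2000, 8000),
             duration = c(0.05, 0.15, 0.05), amplitude = 0.8)
    )
    parts <- list(
      list(part = "alpha", pool = "alpha", n_elements = c(1L, 1L),
           reps = c(1L, 2L)),
      list(part = "beta", pool = "beta", n_elements = c(2L, 4L),
           reps = c(2L, 3L)),
      list(part = "gamma", pool = "gamma", n_elements = c(2L, 2L),
           reps = c(4L, 5L)),
      list(part = "omega", pool = "omega", n_elements = c(1L, 1L),
           reps = c(1L, 1L))
    )
  } else {
    alphabet <- bind_rows(
      tibble(label = paste0("li", 1:4), glyph = "whistle", pool = "initial",
             freq_lo = c(900, 1200, 1500, 1800),
             freq_hi = c(1300, 1600, 1900, 2200),
             duration = 0.14, amplitude = 0.8),
      tibble(label = paste0("lm", 1:5),
             glyph = rep(c("sweep", "whistle"), length.out = 5),
             pool = "middle",
             freq_lo = seq(1600, 3600, by = 500),
             freq_hi = seq(2200, 4200, by = 500),
             duration = 0.12, amplitude = 0.7),
      tibble(label = paste0("lt", 1:4), glyph = "trill-pulse", pool = "trill",
             freq_lo = c(1000, 1400, 1800, 2200),
             freq_hi = c(1500, 1900, 2300, 2700),
             duration = 0.05, amplitude = 1.0)
    )
    parts <- list(
      list(part = "initial", pool = "initial", n_elements = c(1L, 1L),
           reps = c(3L, 6L)),
      list(part = "middle", pool = "middle", n_elements = c(1L, 3L),
           reps = c(1L, 3L)),
      list(part = "trill", pool = "trill", n_elements = c(1L, 1L),
           reps = c(5L, 9L))
    )
  }
  structure(list(species = species, alphabet = alphabet, parts = parts),
            class = "song_grammar")
}

#' @export
print.song_grammar <- function(x, ...) {
  cat(sprintf("<song_grammar> species %s: %d elements, parts %s\n",
              x$species, nrow(x$alphabet),
              paste(vapply(x$parts, `[[`, "", "part"), collapse = "-")))
  invisible(x)
}

# Truncated geometric repetition count on [lo, hi]; the field observation is
# only that repetition counts vary, so a short-memory distribution is used.
rtrunc_geom <- function(n, lo, hi, p = 0.45) {
  if (lo == hi) return(rep(lo, n))
  lo + pmin(rgeom(n, p), hi - lo)
}

#' Draw one song type from a grammar
#'
#' A song type fixes, for each part of the grammar, which elements occur and
#' a canonical repetition count per element. Song types are compared through
#' their *collapsed* element sequence (adjacent repeats removed), so the
#' repetition counts never affect identity.
#'
#' @param grammar A [song_grammar()].
#' @param song_type_id Identifier string.
#' @return A `song_type`: list with `song_type_id`, `species` and `elements`,
#'   a tibble with columns `label`, `part`, `reps`.
#' @export
draw_song_type <- function(grammar, song_type_id = "S001") {
  rows <- purrr::map(grammar$parts, function(p) {
    pool <- grammar$alphabet$label[grammar$alphabet$pool == p$pool]
    k <- sample(seq(p$n_elements[1], p$n_elements[2]), 1L)
    labs <- sample(pool, k)
    tibble(label = labs, part = p$part,
           reps = as.integer(rtrunc_geom(k, p$reps[1], p$reps[2])))
  })
  elements <- left_join(bind_rows(rows),
                        select(grammar$alphabet, -"pool"), by = "label")
  structure(list(song_type_id = song_type_id, species = grammar$species,
                 elements = elements),
            class = "song_type")
}

#' Collapsed element sequence of a song type
#' @param x A `song_type` or a character vector of element labels.
#' @return Character vector with adjacent repeats removed.
#' @export
collapsed_sequence <- function(x) {
  labs <- if (inherits(x, "song_type")) x$elements$label else x
  collapse_repeats(labs)
}

#' @export
print.song_type <- function(x, ...) {
  cat(sprintf("<song_type> %s (%s): %s\n", x$song_type_id, x$species,
              paste(x$elements$label, collapse = " ")))
  invisible(x)
}
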