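#' Collapse adjacent repeats in an element sequence
#'
#' Song types are characterized by the order of distinct elements; the
#' number of repetitions is variable and never influences assignment, so
#' maximal runs of the same label collapse to a single occurrence.
#'
#' @param element_sequence Character vector of element labels.
#' @return Collapsed character vector.
#' @examples
#' collapse_repeats(c("a", "a", "b", "b", "b", "c"))
#' @export
collapse_repeats <- function(element_sequence) {
  x <- as.character(element_sequence)
  if (length(x) == 0L) return(character())
  x[c(TRUE, x[-1L] != x[-length(x)])]
}

#' Element-sequence resemblance to a catalogue song type
#'
#' Fraction of the catalogue type's collapsed element sequence recovered in
#' the song, measured as the longest common subsequence (LCS) length divided
#' by the catalogue sequence length. LCS respects element order, so an
#' out-of-order rearrangement scores below an in-order partial copy.
#'
#' @param song_elements,catalogue_elements Collapsed element-label vectors.
#' @return Fraction in `[0, 1]`.
#' @export
element_resemblance <- function(song_elements, catalogue_elements) {
  if (length(catalogue_elements) == 0L) {
    abort("Empty catalogue element sequence.")
  }
  lcs_length(song_elements, catalogue_elements) / length(catalogue_elements)
}

# Classic O(mn) dynamic programme for LCS length.
lcs_length <- function(a, b) {
  m <- length(a)
  n <- length(b)
  if (m == 0L || n == 0L) return(0L)
  prev <- integer(n + 1L)
  for (i in seq_len(m)) {
    cur <- integer(n + 1L)
    for (j in seq_len(n)) {
      cur[j + 1L] <- if (a[i] == b[j]) prev[j] + 1L
                     else max(cur[j], prev[j + 1L])
    }
    prev <- cur
  }
  prev[n + 1L]
}

#' Detect species-typical song organization
#'
#' `LM_ORG`: all four Common Nightingale parts (alpha, beta, gamma, omega)
#' present, first occurrences in canonical order. `LL_ORG`: the song begins
#' with a repeated element and contains neither a beta nor an omega part.
#' `has_catalogue_gamma` reports whether any element of the song belongs to
#' a gamma-part element of the catalogue.
#'
#' @param song_elements Raw (uncollapsed) element labels of the song.
#' @param parts Part annotation per element (same length), from the
#'   synthesis log.
#' @param gamma_labels Character vector of catalogue gamma-part labels
#'   (e.g. `unique(unlist(catalogue$types$gamma_labels))`).
#' @return List: `org` in `{"LM_ORG","LL_ORG","NEITHER"}`,
#'   `has_catalogue_gamma` logical.
#' @export
detect_organization <- function(song_elements, parts, gamma_labels) {
  stopifnot(length(song_elements) == length(parts))
  lm_parts <- c("alpha", "beta", "gamma", "omega")
  firsts <- match(lm_parts, parts)
  lm_org <- !anyNA(firsts) && !is.unsorted(firsts, strictly = TRUE)
  starts_repeated <- length(song_elements) >= 2L &&
    song_elements[1L] == song_elements[2L]
  ll_org <- !lm_org && starts_repeated &&
    !any(parts %in% c("beta", "omega"))
  list(org = if (lm_org) "LM_ORG" else if (ll_org) "LL_ORG" else "NEITHER",
       has_catalogue_gamma = any(song_elements %in% gamma_labels))
}

#' The five song categories
#' @export
song_category_levels <- function() {
  c("LM_CATALOGUE", "LM_PARTIAL_CATALOGUE", "LM", "LL", "UNCLEAR")
}

#' Assign a song to one of the five categories
#'
#' The decision cascade applied to every non-excluded song:
#' \enumerate{
#'   \item resemblance to the best-matching catalogue type >= 0.95 ->
#'     `LM_CATALOGUE`;
#'   \item resemblance >= 0.75 -> `LM_PARTIAL_CATALOGUE`;
#'   \item Common Nightingale organization with recognizable catalogue gamma
#'     parts -> `LM`;
#'   \item Thrush Nightingale organization without catalogue gamma parts ->
#'     `LL`;
#'   \item anything else (including LL organization *with* catalogue gamma
#'     parts) -> `UNCLEAR`.
#' }
#' Resemblance is evaluated against every retained match candidate (the
#' `top_k` of [rank_templates()]) whose score clears `accept_threshold`,
#' taking the candidate with highest resemblance; when no candidate clears
#' the threshold the cascade starts at rule 3.
#'
#' @param song_elements,parts Raw element labels and part annotations.
#' @param match A `match_result` from [rank_templates()], or `NULL` for the
#'   sequence-only path (all catalogue types are then candidates).
#' @param catalogue A `song_catalogue`.
#' @param accept_threshold Minimum cross-correlation score for a candidate
#'   match (default 0.6).
#' @param full_threshold,partial_threshold Resemblance cut-offs (0.95, 0.75).
#' @return A single category label (see [song_category_levels()]).
#' @export
assign_category <- function(song_elements, parts, match, catalogue,
                            accept_threshold = 0.6,
                            full_threshold = 0.95,
                            partial_threshold = 0.75) {
  stopifnot(partial_threshold < full_threshold)
  collapsed <- collapse_repeats(song_elements)
  cand_ids <- if (is.null(match)) {
    catalogue$types$song_type_id
  } else {
    match$song_type_id[match$score >= accept_threshold]
  }
  best_res <- 0
  if (length(cand_ids) > 0L && length(collapsed) > 0L) {
    idx <- match(cand_ids, catalogue$types$song_type_id)
    best_res <- max(vapply(idx, function(i) {
      element_resemblance(collapsed, catalogue$types$collapsed[[i]])
    }, numeric(1)))
  }
  if (best_res >= full_threshold) return("LM_CATALOGUE")
  if (best_res >= partial_threshold) return("LM_PARTIAL_CATALOGUE")
  gamma_labels <- unique(unlist(catalogue$types$gamma_labels))
  org <- detect_organization(song_elements, parts, gamma_labels)
  if (org$org == "LM_ORG" && org$has_catalogue_gamma) return("LM")
  if (org$org == "LL_ORG" && !org$has_catalogue_gamma) return("LL")
  "UNCLEAR"
}

#' Classify every song of a simulated recording
#'
#' Runs the automated workflow over a simulated recording: segments the
#' audio, aligns segments with the ground-truth table by time overlap,
#' cross-correlates each non-fragmented segment against the catalogue
#' (unless `use_audio = FALSE`), and applies the category cascade using the
#' synthesis log's element sequence.
#'
#' @param sim Output of [simulate_recording()].
#' @param catalogue A `song_catalogue`.
#' @param use_audio If `FALSE`, skip cross-correlation and use the
#'   sequence-only path (faster; identical decisions on clean audio).
#' @param top_k,accept_threshold,full_threshold,partial_threshold See
#'   [rank_templates()] and [assign_category()].
#' @return Tibble: one row per segment with `segment_id`, `song_idx`,
#'   `start_s`, `end_s`, `fragmented`, `category`, `truth_category`,
#'   `best_song_type_id`, `best_score`.
#' @export
classify_songs <- function(sim, catalogue, use_audio = TRUE, top_k = 10,
                           accept_threshold = 0.6, full_threshold = 0.95,
                           partial_threshold = 0.75) {
  segs <- segment_songs(sim$recording)
  truth <- sim$truth
  rows <- purrr::map(seq_len(nrow(segs)), function(i) {
    mid <- (segs$start_s[i] + segs$end_s[i]) / 2
    ti <- which(truth$start_s <= mid & truth$end_s >= mid)
    if (length(ti) == 0L) ti <- which.min(abs(truth$start_s - segs$start_s[i]))
    tr <- truth[ti[1L], ]
    out <- tibble(segment_id = segs$segment_id[i], song_idx = tr$song_idx,
                  start_s = segs$start_s[i], end_s = segs$end_s[i],
                  fragmented = segs$fragmented[i],
                  category = NA_character_,
                  truth_category = tr$truth_category,
                  best_song_type_id = NA_character_,
                  best_score = NA_real_)
    if (segs$fragmented[i]) return(out)
    m <- NULL
    if (use_audio) {
      m <- rank_templates(segs$samples[[i]], catalogue, top_k = top_k,
                          sample_rate = sim$recording$sample_rate)
      out$best_song_type_id <- attr(m, "best_song_type_id")
      out$best_score <- attr(m, "best_score")
    }
    log <- tr$log[[1L]]
    out$category <- assign_category(log$label, log$part, m, catalogue,
                                    accept_threshold, full_threshold,
                                    partial_threshold)
    out
  })
  bind_rows(rows)
}

#' Summarize one bird's repertoire
#'
#' Per-bird category counts, the proportion of 'Identified' songs
#' (categories `LM_CATALOGUE`, `LM_PARTIAL_CATALOGUE` and `LM`, i.e. songs
#' of Common Nightingale origin) among non-excluded songs, the song rate,
#' and derived repertoire flags: a *mixed singer* sings both Identified and
#' `LL` songs; a repertoire is `pure_LM` when every song is Identified and
#' `pure_LL` when none is.
#'
#' @param labels Tibble with a `category` column and a logical `fragmented`
#'   column (fragmented songs are excluded), e.g. from [classify_songs()].
#' @param recording The source `recording` (for the song rate), or a
#'   duration in minutes.
#' @param bird_id Optional identifier copied into the output.
#' @param strict If `TRUE`, the Identified group is restricted to
#'   `LM_CATALOGUE` + `LM_PARTIAL_CATALOGUE` (the stricter criterion).
#' @return One-row tibble: `bird_id`, per-category counts, `n_songs`,
#'   `proportion_identified`, `song_rate`, `mixed_singer`,
#'   `repertoire_class`.
#' @export
summarize_bird <- function(labels, recording, bird_id = NA_character_,
                           strict = FALSE) {
  kept <- labels[!labels$fragmented & !is.na(labels$category), ]
  if (nrow(kept) == 0L) abort("All segments excluded; nothing to summarize.")
  lev <- song_category_levels()
  counts <- table(factor(kept$category, levels = lev))
  ident_lev <- if (strict) lev[1:2] else lev[1:3]
  n_ident <- sum(counts[ident_lev])
  prop <- n_ident / nrow(kept)
  dur_min <- if (inherits(recording, "recording")) {
    recording$duration / 60
  } else {
    as.numeric(recording)
  }
  mixed <- n_ident > 0 && counts[["LL"]] > 0
  tibble(bird_id = bird_id,
         !!!as.list(stats::setNames(as.integer(counts), lev)),
         n_songs = nrow(kept),
         proportion_identified = prop,
         song_rate = nrow(kept) / dur_min,
         mixed_singer = mixed,
         repertoire_class = if (mixed) "mixed"
           else if (prop == 1) "pure_LM"
           else if (prop == 0) "pure_LL" else "other")
}
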