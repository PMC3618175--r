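#' Demo run configuration
#'
#' Defines an end-to-end cohort: birds per taxon-by-region group, their
#' song-mixing proportions, catalogue size, per-bird recording length and
#' song rates, and the classification thresholds. The default cohort
#' mirrors a two-species secondary-contact study design: allopatric Common
#' Nightingales (pure LM repertoires), allopatric Thrush Nightingales (pure
#' LL), sympatric birds of both species - most sympatric Thrush
#' Nightingales being mixed singers with a wide range of mixing
#' proportions - and intermediate-phenotype F1 males dominated by paternal
#' (LM) song.
#'
#' @param n_catalogue Catalogue song types (scaled down from a full field
#'   catalogue for desk-scale runs).
#' @param duration_min Per-bird recording length, minutes.
#' @param rate_lm,rate_ll Songs per minute for LM-like and LL-like singers.
#' @param cohort Tibble: `bird_id`, `taxon`, `region`, `mixing_prop`,
#'   `pedigree_category`. `NULL` uses the default cohort.
#' @param use_audio Run spectrogram cross-correlation (slower) or the
#'   sequence-only cascade.
#' @param accept_threshold,full_threshold,partial_threshold Cascade
#'   thresholds (0.6, 0.95, 0.75).
#' @param seed Run seed; per-stage seeds are derived from it.
#' @return A `demo_config` list.
#' @export
demo_config <- function(n_catalogue = 20L, duration_min = 1,
                        rate_lm = 9.8, rate_ll = 7.2, cohort = NULL,
                        use_audio = TRUE, accept_threshold = 0.6,
                        full_threshold = 0.95, partial_threshold = 0.75,
                        seed = 1L) {
  stopifnot(partial_threshold < full_threshold,
            accept_threshold > 0, full_threshold <= 1)
  if (is.null(cohort)) {
    mk <- function(prefix, k, taxon, region, mixing, ped) {
      tibble(bird_id = sprintf("%s%02d", prefix, seq_len(k)), taxon = taxon,
             region = region, mixing_prop = mixing, pedigree_category = ped)
    }
    cohort <- bind_rows(
      mk("LMa", 11L, "LM", "allopatry", 1, "PureLM"),
      mk("LLa", 8L, "LL", "allopatry", 0, "PureLL"),
      mk("LLs", 9L, "LL", "sympatry",
         c(0, 0.07, 0.3, 0.45, 0.62, 0.75, 0.85, 0.94, 1.0), "PureLL"),
      mk("LMs", 8L, "LM", "sympatry", 1, "PureLM"),
      mk("HYB", 5L, "intermediate", "sympatry",
         c(0.86, 0.99, 1, 1, 1), "F1"))
  }
  structure(list(n_catalogue = n_catalogue, duration_min = duration_min,
                 rate_lm = rate_lm, rate_ll = rate_ll, cohort = cohort,
                 use_audio = use_audio,
                 accept_threshold = accept_threshold,
                 full_threshold = full_threshold,
                 partial_threshold = partial_threshold, seed = seed),
            class = "demo_config")
}

#' Run the full demonstration pipeline
#'
#' Executes every stage on synthetic data: build the catalogue, simulate
#' one recording per cohort bird and classify its songs, summarize
#' repertoires, simulate and classify genotypes (plus mtDNA maternal
#' assignment for F1 birds), and run the four repertoire comparisons
#' (sympatric vs allopatric LL, sympatric LL vs LM, sympatric vs allopatric
#' LM, F1 vs sympatric LL). All outputs are plain TSV/JSON when `out_dir`
#' is given; reruns with the same config are bit-identical.
#'
#' @param config A [demo_config()].
#' @param out_dir Optional output directory.
#' @return List: `summaries` (per-bird tibble), `songs` (per-song labels),
#'   `posteriors` ([classify_hybrids()] output), `maternal` (mtDNA
#'   assignments), `stats` (tibble of the four comparisons), `catalogue`.
#' @export
run_demo <- function(config = demo_config(), out_dir = NULL) {
  cohort <- config$cohort
  if (nrow(cohort) == 0L) {
    warn("Empty cohort; nothing to do.")
    return(list(summaries = tibble(), songs = tibble(),
                posteriors = tibble(), maternal = tibble(),
                stats = tibble(), catalogue = NULL))
  }
  catalogue <- build_catalogue(config$n_catalogue,
                               seed = derive_seed(config$seed, "catalogue"))
  songs <- list()
  summaries <- list()
  for (i in seq_len(nrow(cohort))) {
    b <- cohort[i, ]
    res <- tryCatch({
      rep_seed <- derive_seed(config$seed, paste0("rep_", b$bird_id))
      rec_seed <- derive_seed(config$seed, paste0("rec_", b$bird_id))
      rep_spec <- make_repertoire(catalogue, b$mixing_prop, seed = rep_seed)
      rate <- if (b$taxon == "LL") config$rate_ll else config$rate_lm
      sim <- simulate_recording(rep_spec, config$duration_min, rate,
                                seed = rec_seed)
      labs <- classify_songs(sim, catalogue, use_audio = config$use_audio,
                             accept_threshold = config$accept_threshold,
                             full_threshold = config$full_threshold,
                             partial_threshold = config$partial_threshold)
      list(labs = mutate(labs, bird_id = b$bird_id),
           summ = summarize_bird(labs, sim$recording, b$bird_id) |>
             mutate(taxon = b$taxon, region = b$region,
                    mixing_prop = b$mixing_prop))
    }, error = function(e) {
      warn(sprintf("Skipping bird %s: %s", b$bird_id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      songs[[length(songs) + 1L]] <- res$labs
      summaries[[length(summaries) + 1L]] <- res$summ
    }
  }
  songs <- bind_rows(songs)
  summaries <- bind_rows(summaries)
  # genetics: genotype each cohort bird according to its pedigree category
  geno <- purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    b <- cohort[i, ]
    simulate_genotypes(b$pedigree_category, nightingale_loci(), n = 1L,
                       seed = derive_seed(config$seed,
                                          paste0("gen_", b$bird_id))) |>
      mutate(individual_id = b$bird_id)
  })
  posteriors <- classify_hybrids(geno)
  refs <- simulate_mtdna(seed = derive_seed(config$seed, "mtdna"))
  f1_birds <- cohort$bird_id[cohort$pedigree_category == "F1"]
  maternal <- purrr::map_dfr(f1_birds, function(id) {
    q <- mtdna_query(refs, "LL")   # F1s descend from LL mothers
    assign_maternal_lineage(q, refs$ref_LM, refs$ref_LL) |>
      mutate(individual_id = id, .before = 1L)
  })
  stats_tbl <- demo_comparisons(summaries)
  out <- list(summaries = summaries, songs = songs, posteriors = posteriors,
              maternal = maternal, stats = stats_tbl, catalogue = catalogue)
  if (!is.null(out_dir)) write_demo_outputs(out, config, out_dir)
  out
}

# The four repertoire comparisons, as identified-song proportions.
demo_comparisons <- function(summaries) {
  cmp <- function(name, a, b) {
    d <- bind_rows(mutate(a, grp = "A"), mutate(b, grp = "B"))
    if (nrow(a) == 0L || nrow(b) == 0L) return(NULL)
    d$identified <- round(d$proportion_identified * d$n_songs)
    fit <- quasibinomial_glm_f(d, .data$identified, .data$n_songs,
                               .data$grp)
    bind_cols(tibble(comparison = name, n_a = nrow(a), n_b = nrow(b)),
              glance(fit))
  }
  pick <- function(taxon, region) {
    summaries[summaries$taxon == taxon & summaries$region == region, ]
  }
  bind_rows(
    cmp("sympatric_vs_allopatric_LL", pick("LL", "sympatry"),
        pick("LL", "allopatry")),
    cmp("sympatric_LL_vs_LM", pick("LL", "sympatry"),
        pick("LM", "sympatry")),
    cmp("sympatric_vs_allopatric_LM", pick("LM", "sympatry"),
        pick("LM", "allopatry")),
    cmp("F1_vs_sympatric_LL", pick("intermediate", "sympatry"),
        pick("LL", "sympatry")))
}

write_demo_outputs <- function(out, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(out$summaries, file.path(out_dir, "birds.tsv"))
  readr::write_tsv(select(out$songs, -any_of("samples")),
                   file.path(out_dir, "songs.tsv"))
  readr::write_tsv(out$posteriors, file.path(out_dir, "posteriors.tsv"))
  if (nrow(out$maternal)) {
    readr::write_tsv(out$maternal, file.path(out_dir, "maternal.tsv"))
  }
  jsonlite::write_json(out$stats, file.path(out_dir, "stats.json"),
                       digits = NA, pretty = TRUE)
  log <- list(seed = config$seed,
              derived_seeds = list(
                catalogue = derive_seed(config$seed, "catalogue"),
                mtdna = derive_seed(config$seed, "mtdna")),
              n_catalogue = config$n_catalogue,
              n_birds = nrow(config$cohort),
              n_songs = nrow(out$songs),
              n_excluded = sum(out$songs$fragmented),
              r_version = as.character(getRversion()))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @importFrom dplyr any_of bind_cols
NULL
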