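test_that("collapse_repeats removes only adjacent repeats", {
  expect_equal(collapse_repeats(c("a", "a", "b", "b", "b", "c")),
               c("a", "b", "c"))
  expect_equal(collapse_repeats(character()), character())
  expect_equal(collapse_repeats(c("a", "b", "a")), c("a", "b", "a"))
})

test_that("element resemblance is LCS over catalogue length", {
  s20 <- sprintf("e%02d", 1:20)
  expect_equal(element_resemblance(s20, s20), 1)
  expect_equal(element_resemblance(s20[-10], s20), 0.95)
  expect_equal(element_resemblance(c("x", "y"), s20), 0)
  expect_error(element_resemblance(s20, character()), "Empty")

  # brute-force LCS oracle on random pairs
  set.seed(14)
  for (k in 1:20) {
    a <- sample(letters[1:6], sample(0:9, 1), replace = TRUE)
    b <- sample(letters[1:6], sample(1:9, 1), replace = TRUE)
    expect_equal(element_resemblance(a, b), lcs_ref(a, b) / length(b))
  }
})

test_that("organization detection separates LM, LL and spliced songs", {
  cat_ <- shared_catalogue()
  gl <- unique(unlist(cat_$types$gamma_labels))

  lm <- render_song(catalogue_type(cat_, 1))
  o <- detect_organization(lm$log$label, lm$log$part, gl)
  expect_equal(o$org, "LM_ORG")
  expect_true(o$has_catalogue_gamma)

  ll_type <- with(list(), { set.seed(15); draw_song_type(song_grammar("LL")) })
  ll <- render_song(ll_type)
  o <- detect_organization(ll$log$label, ll$log$part, gl)
  expect_equal(o$org, "LL_ORG")
  expect_false(o$has_catalogue_gamma)

  spliced <- with(list(), { set.seed(16); splice_gamma(ll_type, cat_) })
  sp <- render_song(spliced)
  o <- detect_organization(sp$log$label, sp$log$part, gl)
  expect_equal(o$org, "LL_ORG")
  expect_true(o$has_catalogue_gamma)
  # and the cascade sends it to UNCLEAR
  expect_equal(assign_category(sp$log$label, sp$log$part, NULL, cat_),
               "UNCLEAR")
})

test_that("the category cascade routes each constructed case correctly", {
  cat_ <- shared_catalogue()
  # clean catalogue rendering -> LM_CATALOGUE through the audio match
  st <- catalogue_type(cat_, 3)
  r <- render_song(st)
  m <- rank_templates(r$samples, cat_, top_k = 10)
  expect_equal(assign_category(r$log$label, r$log$part, m, cat_),
               "LM_CATALOGUE")
  # perturbed variant (resemblance in [0.75, 0.95)) -> partial
  pert <- with(list(), { set.seed(17); perturb_song_type(st) })
  res <- element_resemblance(collapsed_sequence(pert),
                             cat_$types$collapsed[[3]])
  expect_gte(res, 0.75)
  expect_lt(res, 0.95)
  rp <- render_song(pert)
  mp <- rank_templates(rp$samples, cat_, top_k = 10)
  expect_equal(assign_category(rp$log$label, rp$log$part, mp, cat_),
               "LM_PARTIAL_CATALOGUE")
  # novel LM-grammar type -> LM via organization + gamma
  nov <- with(list(), { set.seed(18); draw_novel_lm_type(cat_, id = "N9") })
  rn <- render_song(nov)
  mn <- rank_templates(rn$samples, cat_, top_k = 10)
  expect_equal(assign_category(rn$log$label, rn$log$part, mn, cat_), "LM")
  # pure LL song -> LL (sequence path suffices)
  ll <- render_song(with(list(), {
    set.seed(19)
    draw_song_type(song_grammar("LL"))
  }))
  expect_equal(assign_category(ll$log$label, ll$log$part, NULL, cat_), "LL")
})

test_that("bird summaries compute identified proportions and flags", {
  mk <- function(categories) {
    tibble::tibble(category = categories,
                   fragmented = FALSE)
  }
  s <- summarize_bird(mk(rep("LL", 10)), 2, "b1")
  expect_equal(s$proportion_identified, 0)
  expect_false(s$mixed_singer)
  expect_equal(s$repertoire_class, "pure_LL")
  expect_equal(s$song_rate, 5)

  s2 <- summarize_bird(mk(c("LM_CATALOGUE", "LL")), 1, "b2")
  expect_true(s2$mixed_singer)

  s3 <- summarize_bird(mk(c("LM_CATALOGUE", "LM", "LM_PARTIAL_CATALOGUE")),
                       1, "b3")
  expect_equal(s3$proportion_identified, 1)
  expect_equal(s3$repertoire_class, "pure_LM")

  expect_error(summarize_bird(tibble::tibble(category = "LL",
                                             fragmented = TRUE), 1),
               "excluded")
})

test_that("stricter identified criteria never increase the proportion", {
  set.seed(20)
  lev <- song_category_levels()
  for (k in 1:10) {
    labs <- tibble::tibble(category = sample(lev, 30, replace = TRUE),
                           fragmented = FALSE)
    loose <- summarize_bird(labs, 1)$proportion_identified
    strict <- summarize_bird(labs, 1, strict = TRUE)$proportion_identified
    expect_lte(strict, loose)
  }
})

test_that("labels partition non-excluded segments", {
  cat_ <- shared_catalogue()
  rep_ <- make_repertoire(cat_, mixing_prop = 0.5, n_spliced = 1, seed = 95)
  sim <- simulate_recording(rep_, duration_min = 1.5, song_rate_per_min = 8,
                            seed = 96)
  labs <- classify_songs(sim, cat_, use_audio = FALSE)
  kept <- labs[!labs$fragmented, ]
  expect_true(all(kept$category %in% song_category_levels()))
  expect_false(anyNA(kept$category))
})

test_that("mixing proportion round-trips into the identified proportion", {
  cat_ <- shared_catalogue()
  rep_ <- make_repertoire(cat_, mixing_prop = 0.62, seed = 97)
  labs <- dplyr::bind_rows(lapply(1:3, function(k) {
    sim <- simulate_recording(rep_, duration_min = 2, song_rate_per_min = 10,
                              seed = 110 + k)
    classify_songs(sim, cat_, use_audio = FALSE)
  }))
  s <- summarize_bird(labs, 6)
  n <- s$n_songs
  expect_lt(abs(s$proportion_identified - 0.62),
            3 * sqrt(0.62 * 0.38 / n))
})
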