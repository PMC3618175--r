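mkspec <- function(M, params = spectrogram_params()) {
  structure(list(mag = M, freq = seq_len(nrow(M)),
                 time = seq_len(ncol(M)) * 0.01, time_step = 0.01,
                 freq_step = 1, params = params),
            class = "song_spectrogram")
}

test_that("template extraction finds the loudest window", {
  sr <- 22050
  quiet <- 0.1 * sin(2 * pi * 2000 * seq(1 / sr, 1, by = 1 / sr))
  loud <- 0.9 * sin(2 * pi * 3000 * seq(1 / sr, 0.5, by = 1 / sr))
  x <- c(quiet, loud, quiet)
  tm <- extract_template(x, sr)
  # brute-force scan over the same hop grid
  hop <- 128L
  win <- as.integer(round(0.5 * sr / hop)) * hop
  starts <- seq(1L, length(x) - win + 1L, by = hop)
  rms <- vapply(starts, function(s) sqrt(mean(x[s + 0:(win - 1)]^2)),
                numeric(1))
  expect_equal(tm$start_s, (starts[which.max(rms)] - 1) / sr)
  # the window covers the loud burst
  expect_gte(tm$end_s, 1.0)
  expect_lte(tm$start_s, 1.5)
})

test_that("constant-amplitude input resolves ties to the first window", {
  x <- sin(2 * pi * 2000 * seq(1 / 22050, 1.2, by = 1 / 22050))
  tm <- extract_template(x, 22050)
  expect_equal(tm$start_s, 0)
  expect_error(extract_template(x[1:1000], 22050), "shorter")
})

test_that("two-phrase song types yield two non-overlapping templates", {
  cat_ <- shared_catalogue()
  two <- which(cat_$types$two_phrase)
  expect_gt(length(two), 0L)
  id <- cat_$types$song_type_id[two[1]]
  tms <- cat_$templates[cat_$templates$song_type_id == id, ]
  expect_equal(nrow(tms), 2L)
  expect_true(tms$end_s[1] <= tms$start_s[2] ||
                tms$end_s[2] <= tms$start_s[1])
})

test_that("cross-correlation equals patch Pearson correlation (oracle)", {
  set.seed(12)
  for (k in 1:4) {
    S <- matrix(runif(24 * 40), 24)
    Tm <- matrix(runif(24 * 7), 24)
    brute <- vapply(0:(40 - 7), function(l) {
      suppressWarnings(cor(as.vector(S[, l + (1:7)]), as.vector(Tm)))
    }, numeric(1))
    got <- cross_correlate(mkspec(S), mkspec(Tm))
    expect_equal(as.numeric(got), max(brute), tolerance = 1e-12)
    expect_equal(attr(got, "lag_index"), which.max(brute) - 1L)
  }
})

test_that("self-match scores exactly 1 at the source lag", {
  cat_ <- shared_catalogue()
  st <- catalogue_type(cat_, 4)
  r <- render_song(st)
  sp <- compute_spectrogram(r$samples, 22050, cat_$params)
  tm <- cat_$templates[cat_$templates$song_type_id == st$song_type_id, ]
  cc <- cross_correlate(sp, tm$spec[[1]])
  expect_equal(as.numeric(cc), 1, tolerance = 1e-10)
  expect_equal(attr(cc, "lag_s"), tm$start_s[1], tolerance = sp$time_step)
})

test_that("a template embedded in silence is located at its offset", {
  tm_mag <- matrix(runif(128 * 20, 0.2, 1), 128)
  song <- matrix(1e-6, 128, 100)
  song[, 31:50] <- tm_mag
  cc <- cross_correlate(mkspec(song), mkspec(tm_mag))
  expect_equal(attr(cc, "lag_index"), 30L)
  expect_equal(as.numeric(cc), 1, tolerance = 1e-9)
})

test_that("scores are invariant to amplitude scaling", {
  set.seed(3)
  S <- matrix(runif(30 * 50), 30)
  Tm <- matrix(runif(30 * 6), 30)
  s1 <- cross_correlate(mkspec(S), mkspec(Tm))
  s2 <- cross_correlate(mkspec(3.7 * S), mkspec(Tm))
  expect_equal(as.numeric(s1), as.numeric(s2), tolerance = 1e-12)
})

test_that("parameter mismatch and short songs are rejected", {
  S <- matrix(runif(30 * 10), 30)
  p2 <- spectrogram_params(fft_size = 512L)
  expect_error(cross_correlate(mkspec(S), mkspec(S[, 1:3], p2)),
               "parameters differ")
  expect_error(cross_correlate(mkspec(S[, 1:3]), mkspec(S)), "shorter")
})

test_that("white-noise spectrograms score near zero against templates", {
  cat_ <- shared_catalogue()
  tm <- cat_$templates$spec[[2]]
  set.seed(31)
  scores <- replicate(100, {
    sp <- compute_spectrogram(rnorm(22050), 22050, cat_$params)
    as.numeric(cross_correlate(sp, tm))
  })
  expect_true(all(abs(scores) < 0.3))
})

test_that("ranking recovers the true type and ignores catalogue order", {
  cat_ <- shared_catalogue()
  hits <- 0L
  idx <- seq(1, 25, by = 2)
  for (i in idx) {
    st <- catalogue_type(cat_, i)
    m <- rank_templates(render_song(st)$samples, cat_, top_k = 1)
    hits <- hits + (attr(m, "best_song_type_id") == st$song_type_id)
  }
  expect_gte(hits / length(idx), 0.9)

  # permutation invariance given the deterministic tie-break
  st <- catalogue_type(cat_, 2)
  song <- render_song(st)$samples
  m_all <- rank_templates(song, cat_, top_k = Inf)
  cat_shuf <- cat_
  set.seed(8)
  cat_shuf$templates <- cat_shuf$templates[sample(nrow(cat_shuf$templates)), ]
  m_shuf <- rank_templates(song, cat_shuf, top_k = Inf)
  expect_identical(m_all$song_type_id, m_shuf$song_type_id)
  # top_k = 1 agrees with full ranking
  m1 <- rank_templates(song, cat_, top_k = 1)
  expect_identical(attr(m1, "best_song_type_id"),
                   m_all$song_type_id[1])
})

test_that("pure LL songs stay below the acceptance threshold", {
  cat_ <- shared_catalogue()
  rep0 <- make_repertoire(cat_, mixing_prop = 0, seed = 91)
  sim <- simulate_recording(rep0, duration_min = 1, song_rate_per_min = 6,
                            seed = 92)
  segs <- segment_songs(sim$recording)
  best <- vapply(segs$samples, function(s) {
    attr(rank_templates(s, cat_, top_k = 1), "best_score")
  }, numeric(1))
  expect_true(all(best < 0.6))
})
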