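test_that("catalogue generation is deterministic and types are distinct", {
  c1 <- build_catalogue(8, seed = 7)
  c2 <- build_catalogue(8, seed = 7)
  expect_identical(c1$types$collapsed, c2$types$collapsed)
  expect_identical(c1$templates$start_s, c2$templates$start_s)
  expect_identical(c1$templates$spec[[3]]$mag, c2$templates$spec[[3]]$mag)
  keys <- vapply(c1$types$collapsed, paste, "", collapse = "|")
  expect_equal(anyDuplicated(keys), 0L)
  # between one and two templates per type
  expect_gte(nrow(c1$templates), 8L)
  expect_lte(nrow(c1$templates), 16L)
  expect_equal(nrow(c1$templates),
               8L + sum(c1$types$two_phrase))
})

test_that("a singleton catalogue matches its own rendering maximally", {
  c1 <- build_catalogue(1, seed = 3)
  st <- catalogue_type(c1, 1)
  r <- render_song(st)
  m <- rank_templates(r$samples, c1, top_k = 1)
  expect_equal(attr(m, "best_song_type_id"), st$song_type_id)
  expect_equal(attr(m, "best_score"), 1, tolerance = 1e-10)
})

test_that("an alphabet too small for the requested catalogue errors", {
  g <- song_grammar("LM")
  g$alphabet <- g$alphabet[!duplicated(g$alphabet$pool), ]
  g$parts <- lapply(g$parts, function(p) {
    p$n_elements <- c(1L, 1L)
    p
  })
  expect_error(build_catalogue(3, g, seed = 1), "too small")
})

test_that("rendering is seed-deterministic and jitter preserves the
           collapsed sequence", {
  gr <- song_grammar("LM")
  st <- with(list(), { set.seed(2); draw_song_type(gr, "S1") })
  r1 <- render_song(st, tempo_jitter = 0.1, noise_db = -40, seed = 5)
  r2 <- render_song(st, tempo_jitter = 0.1, noise_db = -40, seed = 5)
  expect_identical(r1$samples, r2$samples)
  r3 <- render_song(st, tempo_jitter = 0.1, seed = 9, vary_reps = TRUE)
  expect_identical(collapse_repeats(r3$log$label), collapsed_sequence(st))
})

test_that("LM and LL grammars emit their species-typical organization", {
  for (s in 1:5) {
    lm <- with(list(), { set.seed(s); draw_song_type(song_grammar("LM")) })
    expect_identical(unique(lm$elements$part),
                     c("alpha", "beta", "gamma", "omega"))
    ll <- with(list(), { set.seed(s); draw_song_type(song_grammar("LL")) })
    expect_false(any(ll$elements$part %in% c("beta", "omega")))
    # always begins with a repeated element
    expect_gte(ll$elements$reps[1], 2L)
  }
})

test_that("simulated recordings honour song counts and mixing proportions", {
  cat_ <- shared_catalogue()
  rep0 <- make_repertoire(cat_, mixing_prop = 0, seed = 21)
  sim0 <- simulate_recording(rep0, duration_min = 1, song_rate_per_min = 6,
                             seed = 22)
  expect_true(all(sim0$truth$species == "LL"))
  expect_equal(nrow(sim0$truth), 6L)

  # mixing proportion recovered within binomial error
  rep_mix <- make_repertoire(cat_, mixing_prop = 0.62, seed = 23)
  species <- unlist(lapply(1:3, function(k) {
    simulate_recording(rep_mix, duration_min = 2, song_rate_per_min = 10,
                       seed = 30 + k)$truth$species
  }))
  phat <- mean(species == "LM")
  se3 <- 3 * sqrt(0.62 * 0.38 / length(species))
  expect_lt(abs(phat - 0.62), se3)

  # infeasible packing errors
  expect_error(
    simulate_recording(rep0, duration_min = 0.2, song_rate_per_min = 60,
                       seed = 1),
    "exceeds")
})

test_that("gene-dropped genotypes match closed-form expectations", {
  loci <- nightingale_loci()
  # F1 at a fully diagnostic locus is always heterozygous
  f1 <- simulate_genotypes("F1", loci, n = 50, seed = 5)
  lu03 <- f1[f1$locus == "Lu03", ]
  expect_true(all(lu03$allele1 != lu03$allele2))
  # PureLM heterozygosity at Lu10 ~ 2 * 0.8 * 0.2
  lm <- simulate_genotypes("PureLM", loci, n = 4000, seed = 6)
  lu10 <- lm[lm$locus == "Lu10", ]
  het <- mean(lu10$allele1 != lu10$allele2)
  expect_lt(abs(het - 0.32), 3 * sqrt(0.32 * 0.68 / 4000))
  # BC2 mean heterozygous fraction at 12 diagnostic loci ~ 25%
  bc2 <- simulate_genotypes("BC2_LL", diagnostic_loci(12), n = 2000,
                            seed = 7)
  hf <- heterozygous_fraction(bc2, diagnostic_loci(12))
  expect_equal(mean(hf$het_fraction), 0.25, tolerance = 0.05)
  # invalid frequencies are rejected
  bad <- diagnostic_loci(2)
  bad$freq1_LM[1] <- 1.4
  expect_error(simulate_genotypes("F1", bad, n = 1, seed = 1), "frequencies")
})

test_that("Z-linked loci are single-copy in ZW females", {
  loci <- nightingale_loci()
  fem <- simulate_genotypes("F1", loci, n = 20, seed = 8, sex = "female_ZW")
  z <- fem[fem$locus == "ADAMTS6", ]
  expect_true(all(is.na(z$allele2)))
  auto <- fem[fem$locus == "Lu03", ]
  expect_false(anyNA(auto$allele2))
  # an F1 daughter's single Z comes from her (pure-species) father
  expect_true(all(z$allele1 %in% c("T", "C")))
})

test_that("mtDNA references differ at exactly the requested sites", {
  refs <- simulate_mtdna(seed = 9)
  s1 <- strsplit(refs$ref_LM, "")[[1]]
  s2 <- strsplit(refs$ref_LL, "")[[1]]
  expect_equal(sum(s1 != s2), 10L)
  expect_equal(nchar(refs$ref_LM), 193L)
  expect_equal(nrow(refs$sites), 10L)

  same <- simulate_mtdna(n_diagnostic = 0, seed = 10)
  res <- assign_maternal_lineage(same$ref_LM, same$ref_LM, same$ref_LL)
  expect_equal(res$species, "indeterminate")

  q <- mtdna_query(refs, "LL")
  hit <- assign_maternal_lineage(q, refs$ref_LM, refs$ref_LL)
  expect_equal(hit$species, "LL")
  expect_equal(hit$n_matched, 10L)
})

test_that("mtDNA sequences round-trip through FASTA", {
  refs <- simulate_mtdna(seed = 11)
  path <- tempfile(fileext = ".fasta")
  write_mtdna_fasta(c(LM = refs$ref_LM, LL = refs$ref_LL), path)
  back <- ape::read.FASTA(path)
  expect_equal(names(back), c("LM", "LL"))
  chars <- as.character(back)
  expect_equal(toupper(paste(chars$LM, collapse = "")), refs$ref_LM)
  unlink(path)
})
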