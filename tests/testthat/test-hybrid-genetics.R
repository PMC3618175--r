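test_that("class genotype tables match closed forms and sum to one", {
  loci <- nightingale_loci()
  lu03 <- loci[loci$locus == "Lu03", ]   # fully diagnostic
  f1 <- genotype_class_freqs(lu03, "F1")
  expect_equal(f1$prob[f1$genotype == "T/C"], 1)
  f2 <- genotype_class_freqs(lu03, "F2")
  expect_equal(f2$prob, c(0.25, 0.5, 0.25))

  lu10 <- loci[loci$locus == "Lu10", ]   # T 80% / C 20% in LM
  lm <- genotype_class_freqs(lu10, "PureLM")
  expect_equal(lm$prob, c(0.64, 0.32, 0.04))

  for (cl in hybrid_classes()) {
    for (i in seq_len(nrow(loci))) {
      for (sx in c("male_ZZ", "female_ZW")) {
        tab <- genotype_class_freqs(loci[i, ], cl, sx, pseudo_count = 0.5)
        expect_equal(sum(tab$prob), 1, tolerance = 1e-12)
      }
    }
  }
  expect_error(genotype_class_freqs(lu03, "BC7"), "should be one of")
})

test_that("gene-dropped genotype frequencies match the analytic tables", {
  loci <- nightingale_loci()
  test_loci <- loci[loci$locus %in% c("Lu03", "Lu10", "ADAMTS6"), ]
  n <- 3000
  for (cl in hybrid_classes()) {
    g <- simulate_genotypes(cl, test_loci, n = n,
                            seed = 400 + match(cl, hybrid_classes()))
    for (i in seq_len(nrow(test_loci))) {
      row <- test_loci[i, ]
      gg <- g[g$locus == row$locus, ]
      geno <- ifelse(gg$allele1 == gg$allele2,
                     paste(gg$allele1, gg$allele1, sep = "/"),
                     paste(row$allele1, row$allele2, sep = "/"))
      tab <- genotype_class_freqs(row, cl)
      obs <- table(factor(geno, levels = tab$genotype))
      keep <- tab$prob > 0
      expect_true(all(obs[!keep] == 0))
      if (sum(keep) > 1) {
        p <- stats::chisq.test(obs[keep], p = tab$prob[keep])$p.value
        expect_gt(p, 1e-4)
      }
    }
  }
})

test_that("hand-enumerated posteriors match the classifier", {
  # all-heterozygous male at 5 fully diagnostic loci, unsmoothed:
  # F1 likelihood 1, F2/BC each 0.5^5 -> posterior(F1) = 1/(1 + 3/32)
  loci5 <- diagnostic_loci(5)
  rec <- tibble::tibble(locus = loci5$locus, allele1 = "A", allele2 = "B")
  hp <- posterior_hybrid_class(rec, loci5, pseudo_count = 0)
  expect_equal(hp$posterior[["F1"]], 1 / (1 + 3 * 0.5^5),
               tolerance = 1e-12)

  # adding the two partially informative loci with F1-consistent
  # heterozygous genotypes raises the F1 posterior
  loci7 <- nightingale_loci()
  rec7 <- tibble::tibble(
    locus = loci7$locus,
    allele1 = loci7$allele1,
    allele2 = loci7$allele2)
  hp7 <- posterior_hybrid_class(rec7, loci7, pseudo_count = 0)
  expect_gt(hp7$posterior[["F1"]], hp$posterior[["F1"]])

  # homozygous-LM at all five diagnostic loci: classes requiring an LL copy
  # have zero likelihood; PureLM dominates
  rec_lm <- tibble::tibble(locus = loci5$locus, allele1 = "A", allele2 = "A")
  hp_lm <- posterior_hybrid_class(rec_lm, loci5, pseudo_count = 0)
  expect_equal(hp_lm$posterior[["F1"]], 0)
  expect_equal(hp_lm$posterior[["PureLL"]], 0)
  expect_equal(hp_lm$posterior[["BC1_LL"]], 0)
  expect_gt(hp_lm$posterior[["PureLM"]], 0.95)
  expect_equal(hp_lm$posterior[["PureLM"]],
               1 / (1 + 0.5^5 + 0.25^5), tolerance = 1e-12)

  expect_error(posterior_hybrid_class(
    tibble::tibble(locus = "Lu03", allele1 = NA_character_,
                   allele2 = NA_character_)), "missing")
})

test_that("posterior probabilities are proper and tidy() mirrors them", {
  g <- simulate_genotypes("F2", n = 5, seed = 21)
  post <- classify_hybrids(g)
  probs <- as.matrix(post[, hybrid_classes()])
  expect_true(all(probs >= 0))
  expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-12)

  hp <- posterior_hybrid_class(g[g$individual_id == g$individual_id[1], ])
  td <- tidy(hp)
  expect_equal(sum(td$posterior), 1, tolerance = 1e-12)
})

test_that("simulated classes are recovered as far as 7 loci allow", {
  # pures and F1 are near-perfectly identifiable; F2 and BC1 overlap in
  # genotype space at seven loci, so only coarser guarantees hold there
  rec <- function(cl, n, seed) {
    g <- simulate_genotypes(cl, n = n, seed = seed)
    post <- classify_hybrids(g)
    mean(post$modal_class == cl)
  }
  expect_gte(rec("PureLM", 100, 501), 0.95)
  expect_gte(rec("PureLL", 100, 502), 0.95)
  expect_gte(rec("F1", 100, 503), 0.95)
  expect_gte(rec("BC1_LM", 100, 504), 0.7)
  expect_gte(rec("BC1_LL", 100, 505), 0.7)
  # F2 errors stay inside the hybrid classes
  g <- simulate_genotypes("F2", n = 100, seed = 506)
  post <- classify_hybrids(g)
  expect_gte(mean(post$modal_class == "F2"), 0.4)
  expect_true(all(post$modal_class[post$modal_class != "F2"] %in%
                    c("F1", "BC1_LM", "BC1_LL")))
})

test_that("label swap mirrors the posterior exactly", {
  loci <- nightingale_loci()
  swapped <- loci
  swapped$freq1_LM <- loci$freq1_LL
  swapped$freq1_LL <- loci$freq1_LM
  g <- simulate_genotypes("BC1_LM", n = 8, seed = 23)
  for (id in unique(g$individual_id)) {
    rec <- g[g$individual_id == id, ]
    a <- posterior_hybrid_class(rec, loci)$posterior
    b <- posterior_hybrid_class(rec, swapped)$posterior
    expect_equal(a[["PureLM"]], b[["PureLL"]], tolerance = 1e-12)
    expect_equal(a[["BC1_LM"]], b[["BC1_LL"]], tolerance = 1e-12)
    expect_equal(a[["F1"]], b[["F1"]], tolerance = 1e-12)
    expect_equal(a[["F2"]], b[["F2"]], tolerance = 1e-12)
  }
})

test_that("backcross heterozygosity screen has its closed forms", {
  expect_equal(backcross_het_expectation(1), 0.5)
  expect_equal(backcross_het_expectation(2), 0.25)
  expect_equal(backcross_het_expectation(3), 0.125)
  expect_error(backcross_het_expectation(0), ">= 1")

  expect_equal(prob_all_homozygous(1, 5), 0.5^5)
  expect_equal(prob_all_homozygous(2, 5), 0.75^5)
  expect_error(prob_all_homozygous(2, 0), ">= 1")

  # gene-dropping oracle for P(all homozygous) of a BC2 at 5 loci
  g <- simulate_genotypes("BC2_LM", diagnostic_loci(5), n = 5000, seed = 24)
  hf <- heterozygous_fraction(g, diagnostic_loci(5))
  p_hat <- mean(hf$het_fraction == 0)
  expect_equal(p_hat, 0.75^5, tolerance = 0.03)
})

test_that("map distance multiplies and rounds as advertised", {
  expect_equal(map_distance_cm(13.8, 1.43), 19.734)
  expect_equal(map_distance_cm(13.8, 1.43, rounded = TRUE), 20)
  expect_equal(map_distance_cm(0, 1.43), 0)
  expect_equal(map_distance_cm(1, 1), 1)
})

test_that("maternal lineage assignment counts diagnostic matches", {
  refs <- simulate_mtdna(seed = 25)
  q <- strsplit(refs$ref_LM, "")[[1]]
  p <- refs$sites$position[1]
  q[p] <- refs$sites$ll_base[1]       # one site mutated toward LL
  res <- assign_maternal_lineage(paste(q, collapse = ""),
                                 refs$ref_LM, refs$ref_LL)
  expect_equal(res$species, "LM")
  expect_equal(res$n_matched, 9L)
  expect_equal(res$n_diagnostic, 10L)
  expect_error(assign_maternal_lineage("ACGT", refs$ref_LM, refs$ref_LL),
               "equal length")
})
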