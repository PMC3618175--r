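#' The six genotype categories of the hybrid classifier
#' @export
hybrid_classes <- function() {
  c("PureLM", "PureLL", "F1", "F2", "BC1_LM", "BC1_LL")
}

# Distribution of gene-copy origins (LM copies out of 2, or out of 1 for the
# single Z of a ZW female) that defines each class.
origin_distribution <- function(class, haploid = FALSE) {
  if (!haploid) {
    # probabilities over origin pairs (MM, ML, LL)
    switch(class,
      "PureLM" = c(1, 0, 0), "PureLL" = c(0, 0, 1), "F1" = c(0, 1, 0),
      "F2" = c(0.25, 0.5, 0.25), "BC1_LM" = c(0.5, 0.5, 0),
      "BC1_LL" = c(0, 0.5, 0.5),
      abort(sprintf("Unknown hybrid class '%s'.", class)))
  } else {
    # probabilities over single-copy origin (M, L)
    switch(class,
      "PureLM" = c(1, 0), "PureLL" = c(0, 1), "F1" = c(0.5, 0.5),
      "F2" = c(0.5, 0.5), "BC1_LM" = c(0.75, 0.25),
      "BC1_LL" = c(0.25, 0.75),
      abort(sprintf("Unknown hybrid class '%s'.", class)))
  }
}

smoothed_freq1 <- function(freq1, pseudo_count, ref_copies) {
  (freq1 * ref_copies + pseudo_count) / (ref_copies + 2 * pseudo_count)
}

#' Genotype probabilities of a hybrid class at one locus
#'
#' Each class is a distribution over gene-copy origins (both copies LM for
#' PureLM; exactly one LM copy for F1; 1/4-1/2-1/4 for F2; 1/2-1/2 for first
#' backcrosses), and genotype probabilities follow by drawing each copy from
#' the corresponding species allele-frequency pool. Z-linked loci are
#' diploid in ZZ males; in ZW females the single Z copy uses the marginal
#' origin distribution.
#'
#' Reference frequencies may be smoothed by adding `pseudo_count` to the
#' allele counts implied by `ref_copies` reference gene copies, which avoids
#' zero likelihoods at fixed loci.
#'
#' @param locus One row of a locus table ([nightingale_loci()] layout).
#' @param class One of [hybrid_classes()].
#' @param sex `"male_ZZ"` or `"female_ZW"`.
#' @param pseudo_count Added per allele (0 = plug-in frequencies).
#' @param ref_copies Reference gene copies behind the frequencies
#'   (2 x 20 allopatric individuals = 40).
#' @return Tibble: `genotype` (e.g. `"T/T"`, `"T/C"`, or a single symbol for
#'   a haploid Z), `prob`; probabilities sum to 1.
#' @export
genotype_class_freqs <- function(locus, class, sex = "male_ZZ",
                                 pseudo_count = 0, ref_copies = 40) {
  class <- match.arg(class, hybrid_classes())
  sex <- match.arg(sex, c("male_ZZ", "female_ZW"))
  pM <- smoothed_freq1(locus$freq1_LM, pseudo_count, ref_copies)
  pL <- smoothed_freq1(locus$freq1_LL, pseudo_count, ref_copies)
  haploid <- locus$chromosome_class == "Z" && sex == "female_ZW"
  if (haploid) {
    w <- origin_distribution(class, haploid = TRUE)
    p1 <- w[1] * pM + w[2] * pL
    return(tibble(genotype = c(locus$allele1, locus$allele2),
                  prob = c(p1, 1 - p1)))
  }
  w <- origin_distribution(class)
  p_pair <- rbind(c(pM, pM), c(pM, pL), c(pL, pL))
  hom1 <- sum(w * p_pair[, 1] * p_pair[, 2])
  het <- sum(w * (p_pair[, 1] * (1 - p_pair[, 2]) +
                    (1 - p_pair[, 1]) * p_pair[, 2]))
  hom2 <- sum(w * (1 - p_pair[, 1]) * (1 - p_pair[, 2]))
  tibble(
    genotype = c(paste(locus$allele1, locus$allele1, sep = "/"),
                 paste(locus$allele1, locus$allele2, sep = "/"),
                 paste(locus$allele2, locus$allele2, sep = "/")),
    prob = c(hom1, het, hom2))
}

# Likelihood of one observed call under one class.
call_likelihood <- function(class, locus, sex, a1, a2,
                            pseudo_count, ref_copies) {
  tab <- genotype_class_freqs(locus, class, sex, pseudo_count, ref_copies)
  if (is.na(a2)) {
    i <- match(a1, c(locus$allele1, locus$allele2))
    if (is.na(i)) abort(sprintf("Allele '%s' not in locus %s.", a1,
                                locus$locus))
    return(tab$prob[i])
  }
  het <- a1 != a2
  if (het) return(tab$prob[2L])
  i <- match(a1, c(locus$allele1, locus$allele2))
  if (is.na(i)) abort(sprintf("Allele '%s' not in locus %s.", a1,
                              locus$locus))
  tab$prob[c(1L, 3L)][i]
}

#' Posterior over the six genotype categories for one individual
#'
#' Plug-in-likelihood classifier: the posterior is proportional to
#' `prior(class)` times the product over non-missing loci of the class
#' genotype probability from [genotype_class_freqs()]. Loci are assumed
#' unlinked. Missing loci are skipped.
#'
#' @param record Long tibble with columns `locus`, `allele1`, `allele2` (and
#'   optionally `sex`) for a single individual.
#' @param loci Locus table.
#' @param prior Named numeric over [hybrid_classes()]; default uniform.
#' @param pseudo_count Allele-count smoothing (default 0.5; 0 recovers the
#'   closed-form unsmoothed likelihoods).
#' @param ref_copies Reference gene copies behind the frequencies.
#' @param sex Used when `record` has no `sex` column.
#' @return A `hybrid_posterior`: list with `posterior` (named probability
#'   vector summing to 1), `log_likelihood` (named), and `per_locus`, the
#'   tibble of per-locus log-likelihoods.
#' @export
posterior_hybrid_class <- function(record, loci = nightingale_loci(),
                                   prior = NULL, pseudo_count = 0.5,
                                   ref_copies = 40, sex = "male_ZZ") {
  classes <- hybrid_classes()
  if (is.null(prior)) {
    prior <- stats::setNames(rep(1 / length(classes), length(classes)),
                             classes)
  }
  obs <- record[!is.na(record$allele1), , drop = FALSE]
  obs <- obs[obs$locus %in% loci$locus, , drop = FALSE]
  if (nrow(obs) == 0L) abort("All loci missing; cannot classify.")
  per_locus <- purrr::map_dfr(seq_len(nrow(obs)), function(i) {
    lr <- loci[loci$locus == obs$locus[i], ]
    sx <- if ("sex" %in% names(obs)) obs$sex[i] else sex
    lik <- vapply(classes, call_likelihood, numeric(1), locus = lr,
                  sex = sx, a1 = obs$allele1[i], a2 = obs$allele2[i],
                  pseudo_count = pseudo_count, ref_copies = ref_copies)
    tibble(locus = obs$locus[i], class = classes, log_lik = log(lik))
  })
  ll <- per_locus |>
    group_by(.data$class) |>
    summarise(log_lik = sum(.data$log_lik), .groups = "drop")
  logpost <- log(prior[ll$class]) + ll$log_lik
  m <- max(logpost[is.finite(logpost)])
  post <- exp(logpost - m)
  post[!is.finite(logpost)] <- 0
  post <- post / sum(post)
  structure(list(posterior = stats::setNames(as.numeric(post), ll$class),
                 log_likelihood = stats::setNames(ll$log_lik, ll$class),
                 per_locus = per_locus),
            class = "hybrid_posterior")
}

#' @export
print.hybrid_posterior <- function(x, ...) {
  p <- sort(x$posterior, decreasing = TRUE)
  cat("<hybrid_posterior>", sprintf("%s=%.3f", names(p), p), "\n")
  invisible(x)
}

#' Classify many individuals into hybrid categories
#'
#' Maps [posterior_hybrid_class()] over a long genotype tibble and returns
#' one row per individual with the six posterior probabilities, the modal
#' class and its posterior.
#'
#' @inheritParams posterior_hybrid_class
#' @param genotypes Long tibble: `individual_id`, `locus`, `allele1`,
#'   `allele2`, optionally `sex` (e.g. [simulate_genotypes()] output).
#' @return Tibble: `individual_id`, one column per class, `modal_class`,
#'   `modal_posterior`.
#' @export
classify_hybrids <- function(genotypes, loci = nightingale_loci(),
                             prior = NULL, pseudo_count = 0.5,
                             ref_copies = 40, sex = "male_ZZ") {
  genotypes |>
    group_by(.data$individual_id) |>
    dplyr::group_modify(function(d, key) {
      hp <- posterior_hybrid_class(d, loci, prior, pseudo_count,
                                   ref_copies, sex)
      p <- hp$posterior
      bind_cols(as_tibble(as.list(p)),
                tibble(modal_class = names(p)[which.max(p)],
                       modal_posterior = max(p)))
    }) |>
    ungroup()
}

#' Expected heterozygosity of a backcross generation
#'
#' A generation-`n` backcross carries, at a fully diagnostic locus, one
#' gene copy from the recurrent pure parent and one copy heterospecific
#' with probability `0.5^n`; the expected fraction of heterozygous
#' diagnostic loci is therefore `0.5^n` (50% for BC1, 25% for BC2, 12.5%
#' for BC3).
#'
#' @param generation Backcross generation, integer >= 1.
#' @return Expected heterozygous fraction.
#' @examples
#' backcross_het_expectation(2)  # 0.25
#' @export
backcross_het_expectation <- function(generation) {
  stopifnot_scalar_number(generation, "generation")
  if (generation < 1) abort("`generation` must be >= 1.")
  0.5^generation
}

#' Probability a backcross is homozygous at all diagnostic loci
#'
#' Under locus independence, a BC(n) individual is homozygous at every one
#' of `n_loci` fully diagnostic loci with probability `(1 - 0.5^n)^n_loci` -
#' the quantity that makes an all-homozygous multilocus genotype evidence
#' against a recent backcross origin.
#'
#' @param generation Backcross generation, >= 1.
#' @param n_loci Number of diagnostic loci, >= 1.
#' @return Probability in `[0, 1]`.
#' @export
prob_all_homozygous <- function(generation, n_loci) {
  stopifnot_scalar_number(n_loci, "n_loci")
  if (n_loci < 1) abort("`n_loci` must be >= 1.")
  (1 - backcross_het_expectation(generation))^n_loci
}

#' Genetic map distance from physical separation
#'
#' @param separation_mb Physical separation, Mb (non-negative).
#' @param rate_cm_per_mb Recombination rate, cM/Mb.
#' @param rounded If `TRUE`, round to the nearest cM (the conventional
#'   shorthand, e.g. 13.8 Mb at 1.43 cM/Mb ~ 20 cM).
#' @return Map distance in cM.
#' @export
map_distance_cm <- function(separation_mb, rate_cm_per_mb, rounded = FALSE) {
  if (separation_mb < 0 || rate_cm_per_mb < 0) {
    abort("Separation and rate must be non-negative.")
  }
  d <- separation_mb * rate_cm_per_mb
  if (rounded) round(d) else d
}
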