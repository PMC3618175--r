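#' Pedigree categories recognized by the generator
#' @export
pedigree_categories <- function() {
  c("PureLM", "PureLL", "F1", "F2", "BC1_LM", "BC1_LL",
    "BC2_LM", "BC2_LL", "BC3_LM", "BC3_LL")
}

# mother/father categories for each derived class. The hybrid parent is
# always the father (F1 females are sterile under Haldane's rule), except in
# F2 which by definition is an F1 x F1 cross.
parent_categories <- function(category, maternal_species = "LL") {
  other <- if (maternal_species == "LL") "PureLM" else "PureLL"
  mat <- paste0("Pure", maternal_species)
  switch(category,
    "F1" = c(mother = mat, father = other),
    "F2" = c(mother = "F1", father = "F1"),
    "BC1_LM" = c(mother = "PureLM", father = "F1"),
    "BC1_LL" = c(mother = "PureLL", father = "F1"),
    "BC2_LM" = c(mother = "PureLM", father = "BC1_LM"),
    "BC2_LL" = c(mother = "PureLL", father = "BC1_LL"),
    "BC3_LM" = c(mother = "PureLM", father = "BC2_LM"),
    "BC3_LL" = c(mother = "PureLL", father = "BC2_LL"),
    abort(sprintf("Unknown pedigree category '%s'.", category))
  )
}

# Vectorized gene-dropping for one locus. Returns a logical matrix (TRUE =
# allele1) with 2 columns for diploid genotypes, 1 column for the single Z
# copy of a ZW female. Avian sex chromosomes: a son receives his mother's
# single Z plus one of his father's two; a daughter receives one paternal Z
# (and the W, which carries no locus).
drop_locus <- function(category, locus, n, sex, maternal_species) {
  z_linked <- locus$chromosome_class == "Z"
  haploid <- z_linked && sex == "female_ZW"
  if (category %in% c("PureLM", "PureLL")) {
    p <- if (category == "PureLM") locus$freq1_LM else locus$freq1_LL
    k <- if (haploid) 1L else 2L
    return(matrix(rbinom(n * k, 1L, p) == 1L, ncol = k))
  }
  par <- parent_categories(category, maternal_species)
  pick1 <- function(g) {
    if (ncol(g) == 1L) g[, 1L]
    else ifelse(rbinom(nrow(g), 1L, 0.5) == 1L, g[, 1L], g[, 2L])
  }
  if (!z_linked) {
    m <- pick1(drop_locus(par[["mother"]], locus, n, "female_ZW",
                          maternal_species))
    f <- pick1(drop_locus(par[["father"]], locus, n, "male_ZZ",
                          maternal_species))
    cbind(m, f)
  } else if (sex == "male_ZZ") {
    if (category == "F2") {
      # the F2 mother is an F1 female whose single Z descends from her pure
      # father; both cross directions occur (captive breeding shows both
      # viable), so the grandparental direction is drawn per individual.
      # This keeps Z-locus origins at the 1/4-1/2-1/4 class expectation.
      dir_lm <- rbinom(n, 1L, 0.5) == 1L
      m <- ifelse(dir_lm,
                  rbinom(n, 1L, locus$freq1_LM) == 1L,
                  rbinom(n, 1L, locus$freq1_LL) == 1L)
    } else {
      m <- drop_locus(par[["mother"]], locus, n, "female_ZW",
                      maternal_species)[, 1L]
    }
    f <- pick1(drop_locus(par[["father"]], locus, n, "male_ZZ",
                          maternal_species))
    cbind(m, f)
  } else {
    f <- pick1(drop_locus(par[["father"]], locus, n, "male_ZZ",
                          maternal_species))
    matrix(f, ncol = 1L)
  }
}

#' Simulate genotypes by gene-dropping through a pedigree
#'
#' Draws `n` individuals of one pedigree category at the given loci.
#' Founder gene copies are drawn from the per-species allele-frequency
#' pools; gametes of hybrid ancestors segregate fairly and loci are
#' independent. Z-linked loci are diploid in `male_ZZ` individuals and
#' single-copy in `female_ZW`.
#'
#' @param category One of [pedigree_categories()].
#' @param loci Locus table (see [nightingale_loci()], [diagnostic_loci()]).
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @param sex `"male_ZZ"` (default; all recorded singers are male) or
#'   `"female_ZW"`.
#' @param maternal_species Species of the F1 maternal line (`"LL"` matches
#'   the crosses observed in the field); determines the mtDNA haplotype and
#'   the source of a daughter's Z.
#' @return Long tibble: `individual_id`, `category`, `sex`, `locus`,
#'   `allele1`, `allele2` (`allele2` is `NA` at Z loci of ZW females).
#' @export
simulate_genotypes <- function(category, loci = nightingale_loci(), n = 1L,
                               seed = NULL, sex = "male_ZZ",
                               maternal_species = "LL") {
  category <- match.arg(category, pedigree_categories())
  sex <- match.arg(sex, c("male_ZZ", "female_ZW"))
  validate_loci(loci)
  with_seed(seed, {
    per_locus <- purrr::map(seq_len(nrow(loci)), function(i) {
      row <- loci[i, ]
      g <- drop_locus(category, row, n, sex, maternal_species)
      to_sym <- function(v) ifelse(v, row$allele1, row$allele2)
      tibble(individual_id = sprintf("%s_%04d", category, seq_len(n)),
             category = category, sex = sex, locus = row$locus,
             allele1 = to_sym(g[, 1L]),
             allele2 = if (ncol(g) == 2L) to_sym(g[, 2L]) else NA_character_)
    })
    bind_rows(per_locus) |> arrange(.data$individual_id, .data$locus)
  })
}

#' Per-individual heterozygous fraction at diagnostic loci
#'
#' The screen used to rule out later-generation backcrosses: a BC(g)
#' individual is expected to be heterozygous at a fraction `0.5^g` of fully
#' diagnostic loci, so observed heterozygosity far below that makes a
#' backcross origin unlikely.
#'
#' @param genotypes Long genotype tibble from [simulate_genotypes()] (or the
#'   same layout read from TSV).
#' @param loci Locus table; only rows with `diagnostic == TRUE` are used.
#' @return Tibble: `individual_id`, `n_loci`, `het_fraction`.
#' @export
heterozygous_fraction <- function(genotypes, loci = nightingale_loci()) {
  diag_loci <- loci$locus[loci$diagnostic]
  genotypes |>
    filter(.data$locus %in% diag_loci, !is.na(.data$allele1),
           !is.na(.data$allele2)) |>
    group_by(.data$individual_id) |>
    summarise(n_loci = n(),
              het_fraction = mean(.data$allele1 != .data$allele2),
              .groups = "drop")
}
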