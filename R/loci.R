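#' Species-informative SNP loci for nightingale hybrid identification
#'
#' The seven-locus marker panel used to classify sympatric nightingales:
#' three Z-linked and four autosomal biallelic SNPs with per-species
#' reference allele frequencies estimated from 20 allopatric individuals of
#' each species. A locus is *diagnostic* when the two species are fixed for
#' alternative alleles; five of the seven loci are diagnostic by these
#' frequencies.
#'
#' `freq1_LM` / `freq1_LL` are the frequencies of `allele1` in the Common
#' Nightingale (*L. megarhynchos*) and the Thrush Nightingale
#' (*L. luscinia*); `allele2` has the complementary frequency.
#' `position_mb` is the zebra finch genome position, informational only.
#'
#' @return Tibble: `locus`, `chromosome`, `chromosome_class`
#'   (`"Z"`/`"autosomal"`), `position_mb`, `allele1`, `allele2`,
#'   `freq1_LM`, `freq1_LL`, `diagnostic`.
#' @examples
#' nightingale_loci()
#' sum(nightingale_loci()$diagnostic)  # 5
#' @export
nightingale_loci <- function() {
  tibble(
    locus = c("ADAMTS6", "SPINZ-2", "TG5287", "Lu01", "Lu03", "Lu04", "Lu10"),
    chromosome = c("Z", "Z", "Z", "6", "4", "1A", "3"),
    chromosome_class = c("Z", "Z", "Z", "autosomal", "autosomal",
                         "autosomal", "autosomal"),
    position_mb = c(50.7, 7.5, 64.5, 18.5, 47.1, 55.0, 64.8),
    allele1 = c("T", "A", "G", "G", "T", "G", "T"),
    allele2 = c("C", "G", "A", "T", "C", "T", "C"),
    freq1_LM = c(1, 1, 1, 0.95, 1, 1, 0.80),
    freq1_LL = c(0, 0, 0, 0.025, 0, 0, 0.05)
  ) |>
    mutate(diagnostic = (.data$freq1_LM == 1 & .data$freq1_LL == 0) |
             (.data$freq1_LM == 0 & .data$freq1_LL == 1))
}

#' A panel of fully diagnostic loci
#'
#' Convenience constructor for simulation studies: `n` unlinked autosomal
#' biallelic loci fixed for `allele1` in LM and `allele2` in LL.
#'
#' @param n Number of loci.
#' @return Tibble in the [nightingale_loci()] layout.
#' @export
diagnostic_loci <- function(n = 12L) {
  tibble(
    locus = sprintf("D%02d", seq_len(n)),
    chromosome = NA_character_,
    chromosome_class = "autosomal",
    position_mb = NA_real_,
    allele1 = "A", allele2 = "B",
    freq1_LM = 1, freq1_LL = 0,
    diagnostic = TRUE
  )
}

validate_loci <- function(loci) {
  need <- c("locus", "chromosome_class", "allele1", "allele2",
            "freq1_LM", "freq1_LL")
  if (!all(need %in% names(loci))) {
    abort(paste("Locus table must have columns:",
                paste(need, collapse = ", ")))
  }
  bad <- loci$freq1_LM < 0 | loci$freq1_LM > 1 |
    loci$freq1_LL < 0 | loci$freq1_LL > 1
  if (any(bad | is.na(bad))) {
    abort("Allele frequencies must lie in [0, 1] (allele2 takes 1 - freq1).")
  }
  invisible(loci)
}
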