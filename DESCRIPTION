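Package: nightsong
Title: Detection of Mixed Singing and Hybrid-Category Inference in
    Nightingales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for studying heterospecific ("mixed")
    singing in the hybrid zone of the Thrush Nightingale (Luscinia luscinia)
    and the Common Nightingale (L. megarhynchos).  One track classifies
    segmented songs against a catalogue of Common Nightingale song types by
    spectrogram template cross-correlation and a five-category decision
    cascade; the other classifies individuals into six genotype categories
    (pure species, F1, F2, first-generation backcrosses) from
    species-informative SNPs with a plug-in-likelihood classifier, screens
    for later-generation backcrosses via expected heterozygosity, and
    assigns maternal lineage from diagnostic mtDNA sites.  A synthetic-data
    generator provides song grammars, rendered audio, pedigree genotypes and
    mtDNA haplotypes so the whole pipeline runs end-to-end without field
    data.  Includes exact Mann-Whitney U and quasibinomial GLM F-tests
    implemented from first principles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
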