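---
title: "Methods: song classification and hybrid-category inference in nightingales"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: song classification and hybrid-category inference in nightingales}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nightsong)
```

## The scientific problem

In the Central European contact zone of the Thrush Nightingale
(*Luscinia luscinia*, LL) and the Common Nightingale (*L. megarhynchos*,
LM), many LL males are *mixed singers*: they include LM song types in
their repertoires. Two proximate explanations compete — cross-species
song learning versus introgressive hybridization (mixed singers being
backcross hybrids that inherited a tendency for heterospecific song).
Distinguishing them needs two measurements on the same males: how much of
each repertoire is of LM origin, and whether each male carries any LM
alleles. `nightsong` implements both measurement tracks and a synthetic
generator that stands in for field data, so the full pipeline is
exercised end-to-end by code.

## Track 1: song classification

### Preprocessing and spectrograms

Recordings are resampled to 22.05 kHz, peak-normalized to 85% of full
scale, and denoised by magnitude spectral gating: an STFT of size 512 is
computed with a Hann window at 50% overlap, bins below −40 dBFS are
attenuated by 90 dB, and the signal is rebuilt by overlap-add. dB values
are referenced to full scale of the normalized signal. Classification
spectrograms use FFT 256, a Hamming window and 50% overlap (hop 128
samples, ~5.8 ms). Two numerical details matter at signal boundaries: the
input is padded by one hop on each side so overlap-add coverage is
constant (no edge attenuation), and re-applying the whole chain to
already-conformant audio reproduces it to better than 2% everywhere
except inside the first/last gate frame, where the onset transient of the
gate is itself re-gated.

### Segmentation

Field practice splits recordings into single songs by hand; the package
replaces this with an explicit energy rule: the 20-ms RMS envelope is
thresholded at −45 dBFS, runs separated by less than 0.3 s are merged,
and runs shorter than 0.5 s are flagged `fragmented` and excluded
downstream. These defaults assume the generator's ≥1 s inter-song gaps;
they are configurable for other material, and on real, noisier audio the
rule is a stand-in that has only been validated on synthetic recordings.

### Template matching

Each catalogue song type contributes one or two 0.5-s templates cut from
the maximum-RMS window of its reference rendering (hop-aligned; windows
within 0.1% RMS of the maximum count as tied and resolve to the earliest
window — a constant-amplitude rendering has only O(1e−4) phase-dependent
RMS variation). Types with a second repetitive phrase (a beta element
repeated ≥3 times besides the always-repetitive gamma section) get a
second, non-overlapping template. Matching slides the template along the
song's time axis only (no frequency shifting — a fixed convention) and
scores each lag by the zero-mean normalized 2-D correlation of template
and patch; only lags with the template fully inside the song are scored,
since every matched case attains its maximum at full overlap. A song
type's score is the maximum over its templates; ties resolve to the lower
template id, which also makes the ranking invariant to catalogue order.

Shared elements are a real feature of nightingale song: two types that
share their loudest phrase produce near-identical templates, so raw
template rank alone cannot always separate them (scores ~1.0 for both).
The cascade therefore retains the `top_k` (default 10) candidate types
whose score clears the acceptance threshold (default 0.6 — the value has
no field analogue because matches were human-reviewed there) and
evaluates element-sequence resemblance against *all* retained candidates,
taking the best.

### The five-category cascade

Resemblance is the longest-common-subsequence length divided by the
catalogue type's collapsed sequence length. LCS was chosen because song
types are defined by the *order* of distinct elements: a song missing a
few elements keeps a high score, while a reordering is penalized.
Repetition counts are collapsed away first — they vary between
renditions and never affect identity. Thresholds 0.95 (`LM_CATALOGUE`)
and 0.75 (`LM_PARTIAL_CATALOGUE`) follow the field protocol; whether the
original visual scoring also penalized order violations is unknowable
from the protocol text, so LCS is a documented interpretation. Songs
failing both thresholds are classified by organization: all four LM parts
(alpha, beta, gamma, omega) in order plus recognizable catalogue gamma
parts → `LM`; repeated start with no beta and no omega and no catalogue
gamma → `LL`; everything else — including the pathological "LL
organization but catalogue gamma present" — → `UNCLEAR`.

Element sequences for synthetic audio come from the synthesis log (the
generator's ground truth), playing the role of the human spectrogram
reader; gamma-part presence is read from shared gamma labels, or from
gamma-template correlation when only audio is available. This is the
declared scope of the artifact: the acceptance surface is the decision
logic, not audio-to-symbol transcription.

## Track 2: hybrid-category inference

### The six-class classifier

Each class is a distribution over the species origins of an individual's
two gene copies (one copy for the single Z of a ZW female): pure classes
put both copies in one species, F1 exactly one in each, F2 ¼/½/¼, first
backcrosses ½/½. Genotype likelihoods follow by drawing each copy from
the corresponding species' reference allele frequencies; loci are treated
as unlinked (the three Z-linked markers span ≥13.8 Mb ≈ 20 cM at
1.43 cM/Mb, and the four autosomal markers sit on different chromosomes).
The posterior multiplies per-locus likelihoods with a uniform class prior
by default (no phenotypic prior information), skipping missing loci.

This is a *plug-in* likelihood: reference frequencies are fixed (40 gene
copies per species behind them), optionally smoothed by a pseudo-count
(default 0.5 per allele) to avoid zero likelihoods at fixed loci; an
unsmoothed mode reproduces the closed-form examples exactly. The MCMC
alternative that jointly re-estimates allele frequencies from the sample
was deliberately not reimplemented — the markers are (near-)diagnostic,
so the plug-in classifier recovers the same modal classes. The cost is a
slightly lower ceiling on posterior certainty: a pure individual
homozygous at all five diagnostic loci still leaves the same-direction
BC1 class a likelihood of 0.5 per locus, capping the pure posterior near
99% (measured median 98.9% over simulated pure males) where the joint
estimator reports >99%. Simulated F1 males have median F1 posterior ~96%.

Identifiability at seven loci is limited for the intermediate classes: F2
individuals are recovered as modal F2 in only ~55% of draws (their
genotype distribution overlaps F1 and both BC1 classes), BC1 in ~86–91%.
Pure and F1 classes are recovered near-perfectly. Tests assert exactly
these graded guarantees rather than a uniform recovery rate.

### Backcross screen, map distance, mtDNA

BC2/BC3 hybrids are not classifier classes; they are screened through the
expected heterozygous fraction at fully diagnostic loci, `0.5^g`, and the
probability of full homozygosity `(1 − 0.5^g)^L` under locus
independence. Maternal lineage is assigned by majority vote over the
sites at which the two mtDNA reference haplotypes differ, reporting the
matched-site count and an explicit indeterminate state on ties.

## The synthetic-data generator

The generator defines the study conditions: two species song grammars
(LM: soft alpha intro, beta series, loud repeated gamma, terminal omega;
LL: repeated initial part, middle, terminal trill — no beta, no omega),
rendered through five glyph shapes (whistle, sweep, trill-pulse, buzz,
click) whose bands and durations were chosen once so that distinct labels
are separable by spectrogram correlation at the default noise level.
Glyphs are loudness-equalized (RMS proportional to the part amplitude) so
the maximum-amplitude template window falls on the gamma section, as in
the field protocol. Repetition counts are drawn from a truncated
geometric — the field observation is only that counts vary — with the
constraint that a repeated element never drops to a single occurrence in
a rendition (identity-bearing structure is preserved). Recordings default
to ≥1 s silent gaps (the field protocol does not report gap statistics;
this is a convention that makes energy segmentation unambiguous on clean
audio), −50 dBFS white background noise, 5% tempo jitter, and song rates
of 7.2/min (LL-like) and 9.8/min (LM-like); recordings average ~150–200
songs at field length, scaled down in tests.

Pedigree genotypes are produced by explicit gene-dropping. The hybrid
parent of every backcross is the father (F1 females are sterile under
Haldane's rule in this system), which makes Z-linked heterozygosity
expectations equal the autosomal `0.5^g`. One subtlety: an F1 mother from
a fixed-direction cross carries a Z of deterministic species origin, which
would skew F2 sons' Z-locus origins to ½/½; since both cross directions
are viable in captivity, the generator draws the grandparental direction
per F2 individual, restoring the ¼/½/¼ class expectation. mtDNA
references differ at exactly 10 of 193 positions, with an optional
per-site noise rate (default 0).

What passing tests show — and don't: the synthetic audio has clean gaps,
no overlapping singers, no reverberation or wind, and element sequences
are observable exactly. Classification accuracy here validates the
decision logic and the correlation machinery, not robustness to field
noise. Likewise the genotype simulations validate the classifier against
its own generative assumptions (unlinked loci, correct reference
frequencies), not against misspecified frequencies.

## Statistical procedures

The exact Mann–Whitney U test builds the full null distribution of U by
the counting recurrence `N(m, n, u) = N(m−1, n, u−n) + N(m, n−1, u)`
(checked in tests against complete enumeration for all group sizes ≤7; the
distribution is symmetric about mn/2 and sums to one within 1e−12). U is
reported in the min convention with both directed statistics available.
The two-sided p doubles the smaller tail and caps at 1; at group sizes
17 and 19 with U = 53 this convention gives p = 0.00034. Ties switch to midranks and a tie-corrected
normal approximation, with a warning.

The quasibinomial GLM fits a binomial logit model by IRLS (relative
deviance change <1e−10, ≤100 iterations), estimates dispersion as Pearson
χ²/df of the full model, and tests the group effect by
`F = (Δdeviance/Δdf)/dispersion`. Degenerate inputs are handled
explicitly: identical groups give F = 0, p = 1 even when the dispersion
estimate is 0; separation fits on the boundary with a warning. Simulation
shows >80% power at a logit difference of 1.5 with 9 vs 8 birds of ~150
songs, with near-nominal (slightly liberal, ~8% at α = 0.05) size under
the null — an expected property of the F approximation at 15 residual
degrees of freedom.

## Problem sizes and reproducibility

Tests run on catalogues of 8–25 song types, recordings of 1–2.5 minutes,
3,000–10,000 gene-dropped individuals, and 200-draw posterior summaries;
the demo cohort mirrors a 41-male field design at ~1 minute per bird.
These sizes keep the full suite in a few minutes while leaving every
statistical check comfortably powered. All randomness flows from explicit
seeds; a run seed fans out to per-stage seeds through a documented integer
derivation, and repeated runs are bit-identical, including written TSV and
JSON outputs.
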