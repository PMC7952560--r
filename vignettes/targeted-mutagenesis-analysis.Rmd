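---
title: "Quantifying targeted in vivo mutagenesis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying targeted in vivo mutagenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutassay)
```

This vignette is the package's own account of the statistics it implements:
the models, their assumptions, the tunable parameters, the numerical choices,
and what the synthetic-data generators do and do not emulate. The setting is
the characterisation of promoter-targeted deaminase mutagenesis systems —
platforms that recruit a mutator enzyme to a genomic locus via an orthogonal
RNA polymerase and its promoter — but every estimator here applies to
classical fluctuation assays and targeted deep sequencing generally.

## 1. Mutation rates from fluctuation assays

### The model

In a fluctuation assay, `C` parallel cultures grow from a small inoculum to
`N_t` cells and are plated on selective medium; the number of resistant
colonies per culture `r_1..r_C` is heavy-tailed, because a mutation arising
early founds a large clone (a "jackpot"). Under the Luria–Delbrück model the
number of mutation *events* per culture is Poisson with mean `m`, and each
event's clone grows to a random final size; for continuously growing,
non-dying mutants the clone-size law is `P(size >= j) = 1/j`. The resulting
mutant-count distribution has the Ma–Sandri–Sarkar (MSS) recursion

$$p_0 = e^{-m}, \qquad p_r = \frac{m}{r}\sum_{i=0}^{r-1}\frac{p_i}{r-i+1},$$

implemented in `ld_pmf()` (compiled; the recursion is quadratic in the
truncation index). The pmf is deficient at any finite truncation; the deficit
is exactly the upper-tail mass, which the likelihood uses for counts beyond
the jackpot cap.

### Estimators

* `mss_mle()` maximises `sum(log p_{r_j}(m))` over `m`. The likelihood is
  unimodal in `log m`; we bracket `m` between a P0/Lea–Coulson-derived seed
  and `10 * (mean(r) + 1)` and refine with `stats::optimize` (golden-section
  plus parabolic interpolation) at relative tolerance `1e-6`, re-expanding
  once if the maximum pins at the upper bracket. Counts above the jackpot
  cap (default 10,000) contribute through the lumped tail mass
  `1 - sum(p_0..p_cap)`, keeping jackpot likelihoods finite without
  truncating the data.
* `p0_estimate()` is `-log(\hat P_0)` from the fraction of zero-count
  cultures — the classical low-rate estimator; it errors when no culture has
  a zero count, where it is undefined.
* All-zero counts return the boundary estimate `m = 0` (a legitimate
  low-rate outcome) with the CI marked undefined, not an error.

### Confidence intervals

`confidence_interval()` uses Stewart's large-`C` approximation for the
sampling standard deviation of `log m`:

$$\sigma_{\ln m} = \frac{1.225\, m^{-0.315}}{\sqrt{C}},$$

with symmetric 95% limits `exp(log m ± 1.96 σ)` by default. Fluctuation
calculators differ in whether they also apply a skewness correction to the
limits; since the likelihood is right-skewed we expose an `asymmetric` flag
applying `exp(log m ± 1.96 σ e^{±0.315·1.96σ})`, which widens the upper
limit. The symmetric form is the default and the one whose coverage the test
suite certifies (90–98% over 500 simulated assays at `C = 24` for
`m ∈ {0.5, 2, 8}`).

### Rates, plating and comparisons

`rate_from_m()` converts to a per-division rate `μ = m / N_t` (a
per-generation variant `m/(N_t ln 2)` sits behind a flag). The partial
plating correction is **off by default**: when only a fraction `z` of each
culture is plated, the uncorrected estimate is a proxy rate, which is the
appropriate choice when rates are only used comparatively between strains
plated identically. When enabled, the standard correction multiplies `m` by
`(z - 1)/(z \log z)` (continuous-growth plating factor; → 1 as `z` → 1).
`compare_rates()` reports rate ratios both raw and rounded to two
significant figures, the convention for quoting fold increases — e.g. the
published maximal targeted loss-of-function rate over background,
`1.1e-2 / 1.6e-8 = 687,500`, quoted as 690,000-fold:

```{r}
compare_rates(mutation_rate_estimate(1.1e-2), mutation_rate_estimate(1.6e-8))
```

## 2. Positional mutation spectra from targeted sequencing

`build_pileup()` tallies per-position A/C/G/T counts from gaplessly aligned
reads, discarding every base call with Phred quality below 35 — filtering
precedes all frequency computation. Alignments with indel or clip operations
are rejected per read (this pipeline consumes alignments; it does not make
them), and overhanging reads are trimmed with a warning.

`position_frequencies()` divides each base's count by the total at that
position. Zero-coverage positions are **masked, never zero-filled**, so all
windowed means are over observed positions only; silently imputing zeros
would deflate substitutions-per-base (s.p.b.) statistics.

`moving_average()` smooths a per-position signal with the unweighted mean of
the 10 positions on either side (window half-width `w = 10` positions,
shrinking at the edges), after a single-pass 3-standard-deviation exclusion
of outliers within the window — isolated extreme positions, typically
homopolymer-adjacent artefacts, would otherwise dominate the trend. Two
readings of "standard deviations from the mean" are possible: window-local
or profile-global; window-local is the default, the global variant sits
behind `scope = "global"` for sensitivity analysis. Windows left with fewer
than three members are masked rather than padded.

`mean_spb()` averages, over a 1-based inclusive window, the frequency of the
alternative base at positions whose reference base matches the substitution
type; non-matching positions are excluded from numerator and denominator
alike. `fold_enrichment()` is the ratio of target to control windowed
s.p.b., after shifting the control onto the target's coordinates — the
default offset of 23 nt accounts for the insertion that distinguishes the
promoter-less control strain — and reports the replicate standard deviation
when paired biological replicate profiles are supplied. Raw ratios are
reported by default; a pseudocount for zero-control types is opt-in.
`background_subtract()` subtracts the control's per-type s.p.b. (sequencing
error) from the target's, clamps at zero, and renormalises to per-type
substitution fractions.

`onset_position()` estimates where mutagenesis switches on: the first
matching-reference position downstream of the transcription start whose
frequency exceeds half the downstream plateau (plateau = mean over the
distal half of the profile). With a plateau of `1e-3` s.p.b. against an
error floor of `~3e-5` the half-plateau threshold separates the two regimes
by more than an order of magnitude, so the estimate is insensitive to the
exact threshold.

Coordinates are 1-based inclusive everywhere; strand is never re-complemented
(C>T and G>A are distinct classes on the reference strand, as a
deaminase acting on the displaced strand produces them asymmetrically).

## 3. Enrichment calling from barcoded amplicons

`filter_reads()` keeps a read iff its mean Phred quality and total length
pass, and both its front and back barcode match a single well within one
mismatch (Hamming distance on equal-length barcodes); equal-best ties are
discarded as ambiguous. The exact quality/length cutoffs of the original
long-read protocol are not published; the defaults here (mean Q20, open
length range) are declared, not inferred, and are explicit arguments.

`well_distributions()` tallies per-well per-position base distributions from
gapless alignments (`align_gapless()` is a deliberately trivial
minimum-mismatch offset scan for synthetic amplicons; real campaigns should
bring alignments from a dedicated aligner). Positions a well never covers
are dropped from that well's table — the analogue of removing gap-only
columns before quantification.

`call_significant()` implements the two-criterion rule: a (position,
alternative base) is significant iff its global frequency over all pooled
filtered reads is **≥ 10%**, OR it is present in **≥ 4** wells. Both
thresholds are inclusive and the tests pin the boundary on both sides (4
vs 3 wells; 10.0% vs 9.9%). "Global frequency" is computed over pooled
reads, not as a mean of per-well frequencies — the closest reading of "10%
of reads". The within-well frequency that defines "present" is not stated
in the source protocol; the default, 0.10, is chosen symmetric with the
global criterion and is a prominent, documented knob (`presence_floor`).
`annotate_codon()` translates affected codons with the standard genetic code
into labels such as `D54N` or `Q237*`.

## 4. Growth rates

`growth_rate()` computes `ln(OD600(t1)/OD600(t0)) / (t1 - t0)` with the
default interval 4–16 h (divisor 12). This is the only dimensionally
sensible parenthesisation of the published formula (units h⁻¹), and it is
invariant to uniform OD scaling. Missing endpoints refuse interpolation.
Replicates are handled rates-first: per-replicate rates, then mean/SD
(`growth_rates()`); per-timepoint variant comparisons delegate to Welch's
t-test (`compare_od()`), which is plumbing, not method.

## 5. What the synthetic generators emulate — and what they do not

Every generator is seeded and bit-reproducible, and each emission is paired
with a ground-truth record so recovery can be asserted exactly.

**Fluctuation** (`simulate_fluctuation()`): Poisson mutation events with
`m = μ(N_t − N_0)`, clone sizes from the Lea–Coulson law
`P(size ≥ j) = 1/j` truncated at `N_t`, binomial plating. We deliberately
default to the continuous-growth clone-size law rather than synchronous
doublings: with synchronised doublings clone sizes are powers of two, and
the dyadic discretisation alone shifts `p_2` from
`e^{-m}(m/6 + m^2/8)` to `e^{-m}(m/4 + m^2/8)` — at `m = 2` a
total-variation distance ≥ 0.011 from the MSS distribution, a model
mismatch larger than the sampling noise of 10⁵ cultures. The synchronous
variant remains available (`growth_model = "synchronous"`) for studying
exactly that discrepancy. Not emulated: cell death, post-plating growth,
phenotypic lag, variable `N_t` between cultures.

**Pileups** (`simulate_pileup()`): the positional structure of
promoter-targeted deaminase mutagenesis — a C>T plateau (default `1e-3`
s.p.b.) switching on at a cytosine 9–12 nt downstream of the TSS (the onset
offset is drawn per simulation and recorded; the reference is built with a
cytosine at the drawn onset so the first mutated position is informative),
an exponentially decaying G>A component (initial `5e-4`, length constant
300 nt — the decay *form* is a modelling choice, the source data only show
that the rate falls off with distance), minority A>G/T>C plateaus (`1e-4`),
uniform sequencing error spread over the three alternatives, and a
two-point Phred mixture (Q40/Q30 around the Q35 filter — only the filter
boundary matters downstream, so no attempt is made at a realistic quality
model). Truth stores pre-error substitution counts. Not emulated: indels,
strand bias, context-dependent error, PCR jackpots, overlapping read pairs.

**Amplicon campaigns** (`simulate_amplicon_campaign()`): one driver
substitution planted in a fixed fraction of wells (default 85%, the sweep
prevalence observed in the original campaign) at high within-well frequency,
plus sparse noise substitutions each confined to ≤ 2 wells; barcodes are
generated with pairwise Hamming distance ≥ 3 so single-mismatch
demultiplexing is unambiguous. Not emulated: long-read indel error profiles,
chimeras, well-to-well contamination.

Passing recovery tests on these generators certifies the estimators under
the stated statistical model; it does not certify robustness to the real-data
pathologies listed as not emulated.

## 6. Problem sizes and numerical tolerances

The recovery studies run at the sizes the analyses are designed for:
10⁵ cultures for the pmf/total-variation check (TV < 0.01), 10⁴ cultures for
MLE recovery (|m̂ − 2| ≤ 0.1), 500 replicate assays per condition for CI
coverage, coverage 10⁵ over a 300 nt reference for spectrum recovery (planted
plateau recovered within 10%, onset exactly), and a 177-well, 30-reads-per-
well campaign for enrichment calling (driver isolated exactly). The MLE/grid
cross-check demands agreement within 10⁻³ relative; the grid oracle is a
two-stage log-spaced search independent of the bracketing path. The MSS
recursion is evaluated in compiled code; at the default jackpot cap the
likelihood remains exact for counts up to 10,000 with the tail lumped beyond.

## 7. Known limitations

* Stewart's σ approximation degrades for very small `C` or extreme `m`; the
  CI is calibrated in the regime the assays use (C ≈ 8–24, m ≈ 0.1–10).
* `mean_spb` treats positions as independent; correlated errors (e.g.
  alignment slips) violate this and are not modelled.
* The enrichment caller ignores linkage between mutations on the same read;
  haplotype analysis is out of scope.
* No support for variable `N_t` across cultures within one experiment, and
  no Bayesian fluctuation estimators.
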