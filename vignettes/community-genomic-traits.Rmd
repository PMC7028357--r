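---
title: "Community information-processing traits from metagenomes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community information-processing traits from metagenomes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metatrait)
```

This vignette documents the models, estimators, and design choices behind
`metatrait`: what each community trait measures, how the treatment
comparison is constructed, what the synthetic-community generator does and
does not emulate, and where numerical decisions were made.

## The scientific setting

Genomic traits that set the cost and rate of biochemical information
processing — genome size, GC content, rRNA operon and tRNA gene
multiplicity, and codon usage bias in ribosomal protein genes — trade off
against each other along an oligotrophy–copiotrophy continuum.
Resource-rich (copiotrophic) conditions favor machinery for fast
transcription and translation: more rRNA/tRNA genes, stronger codon bias
in highly expressed genes, larger genomes. Chronically nutrient-poor
(oligotrophic) conditions favor cheap information processing: streamlined
low-GC genomes, few rRNA operons, relaxed codon bias. Measured on shotgun
metagenomes, community-weighted versions of these traits should therefore
respond coherently to whole-ecosystem nutrient enrichment, and their
covariation should collapse onto a single axis of trophic strategy.

## Read preprocessing

* **Quality filter.** A read is retained when its *mean* Phred quality is
  at least `q_threshold` (default 25, boundary inclusive). Mean-read
  quality is the common whole-read interpretation of a "Q25" filter; the
  per-base variant would differ only for heterogeneous quality strings,
  which the downstream traits are insensitive to.
* **Rarefaction.** `rarefy()` draws a uniform subsample without
  replacement (seeded, deterministic) to a fixed depth, default 100,000
  reads. The trait stages themselves run on the *full-depth*
  quality-filtered libraries — feature counts, occurrence rates, and depth
  residuals all refer to non-subsampled data — so rarefaction is exposed
  for workflows that need equalized sampling effort (e.g. external
  annotation) rather than used internally.
* **Depth exclusion.** A sample is dropped when its total reads fall below
  `fraction` (default 0.2) times the *leave-one-out mean* of the other
  samples' depths — the literal reading of "less than 20% of the rest of
  the samples". Exclusion happens before any cross-sample statistic
  (background composition, residual regressions).

## Trait estimators

### Codon usage bias (ENC and ENC′)

For each ribosomal-protein CDS, codons are counted in frame 0 (trailing
1–2 nt dropped, codons containing N skipped, stop codons excluded). Within
each synonymous family the homozygosity estimator
`F̂ = (n·Σp² − 1)/(n − 1)` (unbiased for the probability that two randomly
drawn codons of the family coincide) feeds the class-mean combination

    ENC = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆

over the canonical degeneracy structure (9 two-fold families, Ile, 5
four-fold, 3 six-fold; Met and Trp contribute the constant 2). Six-fold
families are kept whole rather than split 2+4, matching this constant
structure. ENC′ substitutes the χ²-corrected homozygosity
`F̂꜀ = (X² + n − k)/(k(n − 1))`, where X² is the deviation of observed
within-family counts from the frequencies expected under the background
nucleotide composition (per-codon products of base frequencies, normalized
within the family). Under a uniform background the correction cancels
algebraically and ENC′ ≡ ENC; the test suite verifies this identity to
1e-9 on 1000 random count tables.

Numerical rules, chosen where the literature is silent and logged per
gene:

* A family is *usable* when observed at least twice and `F̂ > 1e-12`
  (non-positive estimates would blow up the reciprocal; the small
  tolerance keeps the uniform-background identity exact at the zero
  boundary).
* If the Ile class is unusable, `F̄₃` is imputed as `(F̄₂ + F̄₄)/2` when
  both neighbours exist; any other unusable class term falls back to the
  mean F̂ over all usable families; with no usable family the gene's value
  is undefined and excluded (and counted) in per-sample summaries.
* The combined value is clamped to [20, 61]: the finite-n estimator
  overshoots 61 under even usage (a table with 12 occurrences per family
  split evenly combines to ≈ 86 before clamping) and can rarely undershoot
  20.

The background composition is the *unweighted average across retained
samples* of per-sample nucleotide frequencies (N excluded) — one global
background, so deeply and shallowly sequenced samples count equally.
Per-sample summaries report mean and median ENC and ENC′ over genes with
defined values, and community bias as 1/mean(ENC) so that larger means
stronger bias.

### Genome size

Genome equivalents are the mean length-normalized hit count over a set of
universal single-copy marker genes, `GE = scale × mean(hits/length)`, with
`scale` set to the read length when hits are read counts (so a single-copy
genome at 1× coverage gives GE ≈ 1). Mean genome size is the bacterial
predicted-protein count divided by GE — genes per genome equivalent. The
marker set itself is an input (the detectors that produce hit tables and
feature counts are consumed, not reimplemented); the simulator ships a
30-marker synthetic set with lengths 300–1500 nt.

### GC content

GC is pooled (length-weighted) over the six-frame open reading frames of
the reads, N excluded. ORFs are maximal stop-free codon runs (≥ 60 nt,
truncated to whole codons, not ATG-anchored — read fragments rarely
contain true starts). Note a structural property of this estimator: stop
codons are AT-rich, so conditioning on stop-free runs enriches GC relative
to the raw base composition; for i.i.d. bases the expectation is available
in closed form and the simulator's ground truth uses it (see below).

### Occurrence rates and depth residuals

Rates are feature count / total (quality-filtered) reads. Count traits are
log₁₀-transformed, and `depth_residuals()` regresses log₁₀ count on log₁₀
depth across *all* retained samples pooled, returning residuals (sum 0);
identical depths degrade the design to intercept-only residuals with a
warning.

## The treatment comparison

Directions are fixed a priori from the trait predictions: every trait
higher under fertilization except the ENC/ENC′ summaries, which are
predicted lower (stronger bias). Per trait the battery reports the
one-tailed Welch t-test (Satterthwaite df), the treatment R² with its F
test, the two-sided Bonett variance test, and the variance factor
var(unfertilized)/var(fertilized); for the tRNA/rRNA counts additionally
the exact conditional Poisson rate test, with treatment counts summed and
exposure = number of samples × mean reads per metagenome (only the
exposure ratio enters the conditional binomial). KS tests compare the
pooled per-gene ENC/ENC′ distributions between treatments, exactly when
n·m ≤ 10⁴. No multiple-testing correction is applied; all raw p-values and
effect sizes are reported side by side so effect magnitude is not
collapsed into significance stars.

The Bonett test uses the kurtosis-adjusted procedure: pooled kurtosis from
fourth-power deviations about trimmed means (trim proportion
`1/(2√(n−4))`, floored at 0 for n ≤ 4), the `(n−3)/n` small-sample terms in
the standard error, and the adjustment constant `c = (n₁/(n₁−1.96)) /
(n₂/(n₂−1.96))` evaluated at the conventional 5% normal critical value.
The alternative of inverting the published confidence interval (whose
constant depends on the critical value itself) is ill-posed at n = 3–4 —
the constant diverges as the critical value approaches n — so the fixed-
constant z form is used and cross-checked against an independent
transcription of the formulas in the tests.

## The trophic axis

The five traits entering the PCA are mean genome size, GC content, log₁₀
tRNA count, log₁₀ rRNA count, and **median ENC′** (the preferred
codon-usage measure for the axis; rates or residuals can be substituted
via `trait_cols`). Columns are z-scored (n−1 sd), PC1 is extracted from
the covariance of the standardized matrix (equivalent to correlation PCA
on raw traits), and the sign is oriented so the genome-size loading is
non-negative — higher scores mean copiotrophy, and the ENC′ loading comes
out negative. Treatment separation along the axis reuses the binary-factor
R².

## The synthetic-community generator

`taxon_pool()` places taxa on a unit oligotroph→copiotroph gradient; each
trait follows the gradient with independent Gaussian jitter (sd 0.16 on
the gradient scale), giving pairwise rank correlations around 0.8 — the
co-varying structure that produces a dominant PC1. Ranges: 1.6–4k genes at
1 gene/kb (clamped 1–6k), GC 0.38–0.64, codon bias b 0.08–0.40, and
rRNA/tRNA complements specified as per-bp *densities* rising along the
gradient (0.55–5 rRNA genes/Mb; 11–55 tRNA genes/Mb). Densities, not raw
copy numbers, are the gradient variable because per-read hit rates equal
density × feature length: for strong enrichment responses of the observed
size (rates roughly doubling) to be attainable by composition change
alone, density must rise with copiotrophy even as genomes grow. The
resulting copy-number ranges (1–25 rRNA operons, 20–300 tRNA genes at the
extremes) bracket, and at the upper end exceed, those of sequenced
bacteria; the extremes carry little abundance in any realistic community
the designer produces.

`sample_dataset()` draws, per sample: a lognormal depth (CV 0.2; designated
"failed library" samples at 5% of the mean so the depth-exclusion rule has
work to do — by default 1 unfertilized + 2 fertilized of 5 + 5, leaving
the 4-vs-3 retained design); per-sample abundances from a Dirichlet around
the treatment abundances (precision 25 — see calibration below); reads as
i.i.d. bases at the taxon's GC, allocated to taxa proportional to
abundance × genome size; constant-quality strings with a 10% low-quality
fraction to exercise the Q25 filter; Poisson marker/16S/tRNA/protein
counts at the annotation level (detector outputs are counts, so the
generator emits counts); and per-taxon ribosomal-protein CDS (54 genes per
genome equivalent, 300 aa each) from the preferred-codon scheme, in which
the family's designated codon has probability `b + (1−b)/k` and the others
`(1−b)/k` each. Everything is reproducible from a single seed (read
generation uses a fast xorshift128+ stream keyed from R's seeded RNG).

`expected_traits()` gives the closed-form ground truth: genome size
Σa·genes (read allocation ∝ a·bp and coverage normalization cancel the bp
weighting), GC as the DNA-share-weighted *ORF-conditioned* GC (raw base GC
corrected for the exclusion of AT-rich stop codons; `gc_dna` keeps the
uncorrected value), rRNA/tRNA per-read rates = feature length ×
Σa·copies / Σa·bp, and mean ENC = Σa·ENC∞(b) with ENC∞ the large-length
expectation under the codon scheme. Known approximations: ORF *yield*
differs slightly between GC-poor and GC-rich taxa (GC-rich sequence has
fewer stops, hence longer runs), which the GC ground truth ignores — an
effect under 1.5% relative, inside the 3% recovery tolerance — and the
finite gene length (300 aa ≈ 16 codons per family) adds a small convexity
bias to mean ENC, about +1–2% relative to ENC∞.

`fertilization_design()` turns target effect sizes into abundance vectors.
The unfertilized baseline is the minimum-KL tilt of an oligotroph-leaning
prior that anchors community DNA GC at 0.49; the fertilized community is
the maximum-entropy (minimum-KL) reweighting of the baseline satisfying
all five expected-trait targets exactly, found by damped Newton on the
convex dual (residual < 1e-11). Default effects mirror a strong
whole-ecosystem enrichment: genome size ×1.25, GC +5 points, rRNA rate
×2.19, tRNA rate ×1.93, mean ENC ×0.933. Targets outside the convex hull
of a particular pool's trait combinations (about 3% of pool seeds at the
default effects) raise a configuration error naming the fix. The Dirichlet
precision 25 was fixed once so that treatment explains roughly half to
nine-tenths of per-trait variance in simulated experiments — the range a
strong enrichment response shows — and not revisited.

### What the simulator does *not* emulate

Reads are i.i.d. bases at a taxon-level GC: there are no genes, operon
structures, k-mer statistics, sequencing error profiles, chimeras, or
strain variation, and rRNA/tRNA detection is bypassed entirely (counts are
generated, not detected). Passing tests therefore demonstrate that the
*estimators and statistics* behave correctly on data matching their
assumptions, not that upstream detectors (HMM search, tRNA covariance
models, taxonomic annotation) are accurate — those tools' outputs are this
package's inputs in real use.

## Problem sizes used by the test suite

Unit tests run on small constructed cases and oracle comparisons. The
acceptance-style checks use: parameter recovery at 10⁶ reads/sample with
10 replicate samples per treatment at exact treatment abundances (the
treatment estimate is the replicate average, which brings the Poisson
sampling error of the rate traits well below the 3% recovery band); 200
simulated
experiments at mean depth 2×10⁴ reads/sample for directional recovery at
the 4-vs-3 retained design; and 500 null-configuration runs at 10⁴
reads/sample for the one-tailed size check. The scaled-down depths make
the directional checks conservative — Poisson count noise at 10⁴–10⁵
total reads is substantially larger than at study-scale libraries, while
the biological (compositional) variance component is depth-independent.

## Known limitations

* ENC is length-sensitive below ~100 codons; per-gene `n_codons` is
  recorded so length effects can be audited, but no correction is applied.
* The exact conditional Poisson test treats treatment totals as a single
  pooled count; overdispersion across replicate samples (present in the
  simulator through the Dirichlet layer) makes it anticonservative
  relative to the Welch test on per-sample rates — both are reported.
* The background composition is global (averaged over retained samples),
  so ENC′ does not correct for between-sample compositional differences.
* `find_orfs()` reports *all* six-frame runs; overlapping ORFs are pooled
  into GC with multiplicity, which is the straightforward reading of
  "GC content of ORFs" but weights stop-sparse regions more than a
  single-frame caller would.
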