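---
title: "Methods: column-wise trait association scans and windowed population genomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: column-wise trait association scans and windowed population genomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whalescan)
```

## The problem

Cetaceans span roughly three orders of magnitude in adult body mass, from
~50 kg porpoises to >100 t blue whales, and candidate growth-regulating loci
such as the insulin-like growth factor 1 gene carry noncoding variants that
segregate with size across species. `whalescan` implements two analysis
stages around this question:

1. **A column-wise association scan** over a species-level multiple sequence
   alignment of a gene region: for every alignment column, test whether the
   nucleotide carried by each species predicts its (log) adult body mass,
   control the false discovery rate by trait-label permutation, and classify
   the significant columns into clade-sharing "site types".
2. **A windowed population-genomic stage** over per-site diploid genotype
   calls: depth filtering, heterozygosity in nonoverlapping windows, runs of
   homozygosity (ROH) with the inbreeding coefficient Froh, pseudodiploid
   track construction from two individuals, and export of PSMC input.

A synthetic-data generator produces alignments, trait tables and genotype
tracks with known planted signal, so every stage is testable at desk scale
without external data.

## The per-column model

For column $j$ let $y_i$ be the natural-log body mass (kg) of species $i$
and $a_{ij}$ its nucleotide. Species whose character is a gap, `N`, or an
IUPAC ambiguity code are excluded from that column: a gap is absence of
evidence, not a fifth allele. Two linear models are fitted:

* **allele only:** $y \sim \mathrm{allele}$
* **allele + habitat:** $y \sim \mathrm{habitat} + \mathrm{allele}$, with
  habitat the aquatic/terrestrial indicator.

The reported p-value is the partial F test of the allele factor against the
reduced model (intercept, or intercept + habitat). This choice is
well-defined for multi-allelic columns and reduces to the squared
coefficient t test for biallelic columns without the covariate. Natural log
is used for mass; the F statistic is invariant to the logarithm base, so
this is a reproducibility convention, not a modelling choice (the test
suite asserts invariance to 10 decimal digits).

Degenerate columns are flagged rather than silently dropped:
`monomorphic_skipped` (fewer than two allele classes), `collinear_skipped`
(allele factor has zero estimable degrees of freedom given the covariate),
`insufficient_df_skipped` (no residual degrees of freedom),
`singleton_class` (tested, but some allele is carried by one species), and
`zero_residual` (perfect fit; p reported as exactly 0 rather than a clamped
epsilon). The set of tested columns depends only on the alignment and the
habitat labels — never on the trait values — so permuted scans retest
exactly the same columns.

### Implementation

Because the column designs are fixed under trait permutation, the scan
engine precomputes, once per alignment, an orthonormal basis of each
column's reduced-model space and of the allele factor's complement within
the full model. A whole-alignment scan for any (real or permuted) response
then reduces to a handful of matrix products, which is what makes
2 × 1,000-permutation runs over tens of thousands of columns run in
seconds. Each column's statistic is checked against `stats::lm`/`anova` in
the unit tests. Rank decisions use an absolute tolerance of `1e-8` on the
R diagonal of the QR decomposition; since designs are 0/1 indicators, any
genuine direction has norm well above that.

## Permutation FDR

For a p-value threshold $t$, the false discovery rate is estimated as the
paper-standard permutation ratio

$$\widehat{\mathrm{FDR}}(t) =
  \frac{\overline{\#\{p_{\mathrm{perm}} \le t\}}}{\#\{p \le t\}},$$

where the numerator averages hit counts over scans with body-mass values
permuted across species — either freely, or separately within the aquatic
and terrestrial groups (stratified), which preserves the grossly different
mass distributions of the two habitats and is the appropriate null when
habitat is a covariate. Defaults follow the conventional stability check of
two independent runs of 1,000 permutations, reported separately. When no
original hits exist the FDR is undefined and reported as `NA`, never 0.
Multiple testing is handled exclusively by this permutation FDR; no
Benjamini–Hochberg correction is layered on top.

**Choosing thresholds.** With a strongly multimodal trait (giant whales sit
several log-units above everything else), a fixed "round-number" threshold
is dominated by background columns whose one- or two-species minor class
happens to coincide with the largest permuted masses; such coincidences
arise at rate $1/\binom{n}{2}$ per two-species column and inflate both
numerator and denominator. The stable procedure — and the one a real scan
uses — evaluates the FDR *at the attained p of the pattern sites*: all
sites realising the same species bipartition share a single p-value, and
partial coincidences cannot reach it. The planted-recovery tests and the
acceptance script follow this protocol.

## Site types

A `clade_pattern` names a species bipartition. A column is assigned a type
when every group-A species shares one non-missing allele, every group-B
species shares a different one, and species outside both groups are
ignored; the call depends only on the partition, not on which nucleotides
realise it. In the default configuration, `type1` separates the three giant
whales (blue, minke, sperm) from all other artiodactyls, and `type2`
separates the four largest whales plus the terrestrial artiodactyls from
the smaller cetaceans. Patterns are tried in configuration order with first
match winning (the two default partitions cannot both match one column, so
precedence is a safety rule). Missing data inside a pattern group yields
"no call" with a note rather than a guess.

An advisory low-complexity flag automates the exclusion of alignment
artifacts: a column is flagged when, within a ±5-column window, the gap
fraction exceeds 0.3, or the reference row's gap-free subsequence has at
most 2 distinct characters, or a mono-/di-nucleotide repeat covers more
than 80% of it. The flag annotates; it never removes a column. These
parameters are heuristics for "the alignment is ambiguous here" and should
be reviewed against the data at hand.

## Coordinates

Alignment columns are 1-based; genomic coordinates are 1-based inclusive
internally, with BED output converted to 0-based half-open. The
column↔coordinate map is anchored on a user-chosen reference row and
orientation (reverse orientation supports genes on the minus strand, where
coordinates decrease as columns increase); columns where the reference row
carries a gap are "unmapped" rather than attributed to a neighbouring base,
because a site with no reference base has no defensible single coordinate.

## Windowed heterozygosity, ROH, Froh

Heterozygosity is the number of heterozygous calls divided by all called
genotypes in nonoverlapping windows (default 1 Mb) tiling each scaffold;
the final short window is kept and flagged, and a window with no calls
reports `NA`. Depth filtering retains sites within the boundary-inclusive
interval $[\bar d/3,\ 2\bar d]$, with the mean computed once on the
unfiltered track so the filter is idempotent.

ROH are called on smaller tiles (default 20 kb): a window qualifies when
its het score is at or below the threshold (default 0.025), and at least 25
consecutive qualifying windows form a run. The window score defaults to the
within-window het fraction but is configurable (`het_per_kb`), because
published threshold conventions depend on whether the denominator counts
all called sites or only variant sites: on an all-sites track with per-site
heterozygosity ~10⁻³, a 2.5% threshold only separates signal from
background when the background score is variant-dense. Windows with zero
calls break runs by default — absence of calls is not evidence of
homozygosity — with an explicit option to let them qualify.
$F_\mathrm{ROH}$ is the summed length of runs at or above 500 kb divided by
the assessed length; the pipeline reports it against both the assessed and
the total scaffold length, since published values differ in this
denominator.

## Pseudodiploid and PSMC input

A pseudodiploid track samples, at every site called in both input
individuals, one allele uniformly from each; the composite site is
heterozygous exactly when the draws differ. Its coalescence profile dates
the cessation of gene flow between the two source populations. Sites called
in only one input are excluded. The psmcfa export bins the track at 100 bp:
`K` if the bin contains a heterozygous call, else `T` if at least half the
bin's positions are called, else `N` (the called-fraction cutoff is a
parameter). PSMC itself is an external tool; the conventional run
parameters (generation time 30.8 yr, mutation rate 1.58×10⁻⁸ per bp per
generation, maximum coalescent parameter 15) are recorded in the pipeline's
output metadata only.

## The synthetic-data generator

A single root seed deterministically derives independent streams for the
trait, alignment and track generators, so adding planted sites never
perturbs the background draws (tested by byte comparison).

* **Traits.** 29 artiodactyl species by default, 11 aquatic and 18
  terrestrial, with log-mass drawn per clade: giant whales
  ($\mu = 10.5$ ln kg ≈ 36 t), orca (8.3 ≈ 4 t), small cetaceans (5.0 ≈
  150 kg), terrestrial artiodactyls (6.0 ≈ 400 kg), $\sigma = 0.6$. These
  means put the simulated masses on the real span from tens of kg to
  >100 t.
* **Alignment.** Columns are i.i.d.: a major allele with a minor allele
  assigned to each species independently at frequency 0.1, gaps at 0.02
  per cell, optional tandem-repeat low-complexity blocks with elevated gap
  rate, and planted pattern columns written last with no gaps. The i.i.d.
  background deliberately lacks phylogenetic autocorrelation; real
  alignments concentrate minor alleles on clades, so random
  species-subsets that mimic the giant whales are *more* common here than
  in real data, making the synthetic FDR conditions conservative.
* **Track.** Callable sites at a configurable fraction (default 0.8), het
  probability 10⁻³ per callable site (or the planted segment's residual
  rate inside ROH), and negative-binomial depth (mean 40, size 10), whose
  overdispersion is the realistic stress for the depth filter.

What passing tests on these fixtures do **not** show: robustness to
phylogenetic autocorrelation (the scan's null is exchangeability of trait
labels, not a tree-aware null — phylogenetic regression is explicitly out
of scope), to alignment error beyond the planted low-complexity blocks, or
to genotype-calling artefacts upstream of the track.

## Problem sizes used in the checks

The test suite runs the full stack at deliberate scales: the planted
recovery scenario uses 12 planted sites among 20,000 columns × 29 species
with 2 × 1,000 permutations per model; null calibration uses 10 replicates
of 5,000 columns with 200 permutations; permutation-equivalence compares
50,000 sampled permutations against exhaustive enumeration (7! = 5,040,
and 3!·4! = 144 stratified) for 7 species; coordinate round-trips cover
1,000 random gapped alignments. The single-clade (equal means)
configuration used for null calibration makes the response i.i.d.
Gaussian, under which F-test p-values are exactly uniform; note that the
per-seed FDR ratio at a mean hit count of ~5 is still a small-count ratio
and scatters widely around 1 — only its expectation is pinned.

## Known limitations

* The scan's permutation null assumes species exchangeability; shared
  ancestry can inflate apparent association for clade-aligned columns, and
  the stratified option only conditions on habitat, not on the tree.
* Site typing requires allele uniformity within pattern groups; a single
  gap in a pattern species produces "no call" rather than an imputed call.
* The ROH caller quantises run boundaries to whole windows; planted
  segments are recovered within one window of their true edges, not
  exactly.
* Pseudodiploid depth is the rounded mean of the two inputs, a convention
  for downstream filters rather than a model of merged coverage.
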