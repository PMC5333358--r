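---
title: "Models and methods for spatial intra-tumour heterogeneity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for spatial intra-tumour heterogeneity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatialith)
```

## The setting

A solid tumour is not genetically uniform: sub-lineages occupy different
regions, and a single biopsy samples only one of them. Multi-region
("multi-sector") sequencing designs take several spatially separated
biopsies — often a centimetre or more apart — and sequence each, yielding
per-sector read counts at every somatic variant site. This package provides
the downstream analyses such a design supports, together with generative
models (a spatial growth simulator and a synthetic-data generator) that
make every analysis testable without access to patient data.

Throughout, the universal input is a `mutation_table`: per-sector reference
and alternate read counts at each somatic variant, with 1-based positions
(converted to 0-based half-open coordinates only when writing BED). Sector
metadata carries a 3D position in millimetres and a tumour purity in
(0, 1] — the fraction of tumour cells in the biopsy, which dilutes observed
variant allele frequencies (VAF).

## Sector phylogenies

Detection converts counts to presence/absence: a mutation is present in a
sector when its alternate read count is at least `min_alt` (default 3
reads, a caller-like rule chosen over a VAF cut because it behaves sanely
when depth varies; configurable everywhere it is used). Pairwise distances
between sectors are unnormalised Hamming counts — the number of mutations
whose presence differs — so branch lengths are in mutation units.
Neighbour joining (Saitou–Nei, via \pkg{ape}) turns the distance matrix
into an unrooted tree; NJ is consistent on additive inputs, which the test
suite exploits by rebuilding trees from their own cophenetic distances.
Negative estimated branch lengths, an artefact NJ permits, are clamped to
zero and counted in an attribute.

Confidence comes from bootstrapping mutations: each replicate resamples
presence-matrix columns with replacement and rebuilds the tree; the support
of a bipartition is the fraction of replicate trees containing it, and the
majority-rule (> 0.5) consensus summarises them. Two numerical choices are
worth stating. First, when the number of mutations $m$ satisfies
$m^m \le 4000$ the bootstrap distribution is enumerated exactly over all
$m^m$ equally likely resamples instead of sampled — small cases become
deterministic and seed-free. Second, a replicate in which every sector is
identical (all distances zero) contributes a star tree: it counts in the
denominator and supports no split. The default of 100 replicates is the
field's convention; the character resampling is over mutations because
sectors, not mutations, are the taxa here. Trees are unrooted by default; a
normal sample can be modelled as an all-zero row and used for display
rooting, but no analysis below needs a root.

## Weir–Cockerham Fst from read counts, and isolation by distance

Genetic differentiation between two sectors at one site is estimated with
the Weir–Cockerham (1984) variance-components estimator, treating the reads
as haploid allele samples. Read counts are not diploid genotypes — each
read is one sampled chromosome — so the genotypic heterozygosity term of
the original estimator has no analogue and is dropped. With depths
$n_1, n_2$, variant frequencies $p_1, p_2$ and weighted mean $\bar p$:

$$\mathrm{MSP} = \sum_i n_i (p_i - \bar p)^2, \qquad
  \mathrm{MSG} = \frac{\sum_i n_i p_i (1 - p_i)}{n_1 + n_2 - 2}, \qquad
  n_c = (n_1 + n_2) - \frac{n_1^2 + n_2^2}{n_1 + n_2},$$

$$\hat\theta = \frac{\mathrm{MSP} - \mathrm{MSG}}
                   {\mathrm{MSP} + (n_c - 1)\,\mathrm{MSG}}.$$

A fixed difference with equal depths gives exactly 1; identical
frequencies give a small negative value (the estimator is negatively
biased at zero differentiation). Negative values are *retained* in all
downstream pooling: truncating at zero would inflate low-Fst strata and
bias the distance regression. Sites monomorphic across the pooled pair
carry no information and are excluded, with a count reported.

Purity differences between sectors would masquerade as differentiation, so
frequencies are recalibrated first: $f_\mathrm{adj} = \min(f/\rho,\, 1)$
for purity $\rho$ (the inverse of proportional dilution by normal cells,
capped at 1), then alternate counts are redrawn as
$\mathrm{Binomial}(d,\, f_\mathrm{adj})$ at a common target depth $d$ — by
default the minimum positive observed depth — so every sector contributes
the same number of resampled reads. The exact recalibration rule is a
design choice of this package (declared, configurable, and tested for
self-consistency: purity 1 at the observed depth reproduces input
frequencies in expectation).

Isolation by distance is then tested by pooling *every* per-site, per-pair
$\hat\theta$ with the pair's Euclidean distance and fitting ordinary least
squares (`lm`), reporting slope, intercept and the classical two-sided
slope p-value. Pooled records from the same pair are correlated; treating
them as independent is a deliberate simplification that matches how such
pooled regressions are usually run, and a `pair_mean` option that averages
within pairs first is provided for sensitivity analysis. Per-distance
boxplot summaries use the standard linear-interpolation quartiles and the
whisker rule upper = min(max x, Q3 + 1.5·IQR), lower = max(min x,
Q1 − 1.5·IQR).

## The spatial growth model

The simulator realises range expansion on a 3D cubic lattice with the
six-neighbour (von Neumann) neighbourhood. A founder cell is seeded at the
centre; at each event one cell with at least one free neighbour is chosen
uniformly at random (selection, when enabled, multiplies a cell's weight
by $(1+s)^{\#\mathrm{drivers}}$) and divides: the two daughters are placed
at the parental site and a uniformly chosen free neighbour site. Each
daughter genome independently gains $\mathrm{Poisson}(\mu)$ new mutations,
$\mu = 0.5$ per genome per division by default, under the infinite-sites
assumption (every mutation id is globally unique; no back-mutation). Cells
without free space simply cannot divide — there is no pushing — and with
`death_prob` an attempted division removes the cell instead. Neutral
growth to $N$ cells therefore performs exactly $N-1$ division events, an
identity the tests assert. An optional `founder_mutations` count seeds the
founding clone with pre-expansion (truncal) mutations; without it the
trunk of a simulated tumour is typically empty, because both daughters of
the founder usually leave surviving descendants.

Where the division rule is underdetermined — which cell divides, how ties
among free sites break, what shape a biopsy has — the package takes the
simplest consistent choices: uniform choice among frontier cells, uniform
free-site tie-break, and spherical (lattice-ball) sectors; all are seeded
and deterministic given the seed. Sector sampling captures every living
cell within the radius; a mutation's within-sector frequency is its
carrier fraction, and sectors convert to a `mutation_table` with depth =
cells sampled, so the entire analysis stack applies unchanged to simulated
data. Converting simulated carrier fractions to presence uses a 5 %
within-sector frequency threshold (`ceiling(0.05 × cells)` alt carriers),
mimicking sequencing detection limits. The `linear_transect` helper places
evenly spaced sector centres along an axis through the founder, clipped to
the occupied span, mimicking a linear biopsy grid.

At the scales used in the tests and the acceptance script ($10^4$ cells,
6 sectors of radius 2, 20 replicates) one replicate takes well under a
second in pure R; these sizes give stable qualitative behaviour (positive
IBD slope, bipartite end-sector clades) without needing larger populations.

## Synthetic multi-sector data

The generator emulates the statistical structure the analyses assume,
without simulating growth: a truncal set carried by all sectors, two
spatially contiguous clades split across the centre of a linear sector
grid (10 mm spacing by default), and private mutations per sector. Observed
counts follow the diploid, copy-number-neutral heterozygous model: expected
VAF = purity × CCF / 2, with depth Poisson around `mean_depth` and alt
counts binomial. Purity is uniform on (0.5, 0.9) by default — the
high-purity regime of hepatocellular carcinoma, bracketing a mean of
about 0.7 — overridable per sector. The ground truth (mutation classes,
CCF matrix, true tree) is returned alongside, which is what makes the
generator a test oracle.

What this emulates and what it does not: it reproduces presence structure,
purity dilution and binomial read noise, but not copy-number alteration,
subclonal CCF gradients, trinucleotide context, sequencing artefacts or
mapping error. Tests passing on these data therefore validate the
*algorithms* under their stated models, not robustness to every real-data
pathology. The real cohorts this design mirrors are controlled-access, so
no real reference dataset ships with the package.

## Rarefaction, ITH ranking, and the driver VAF test

For $N$ sectors, $X_n$ is the expected number of distinct detected
mutations in a random subsample of $n$ sectors (drawn without
replacement). When $\binom{N}{n} \le 1000$ the mean is computed by
exhaustive enumeration — exact and seed-free; otherwise by Monte Carlo
with 1000 resamples by default. The fold curve $X_n/X_1$ starts at 1, and
its value at $n = 2$ is the ranking statistic: 1 means a second biopsy
adds nothing, 2 (the maximum for equal-sized sectors) means it doubles the
observed variability. Detection uses the same `min_alt` rule as the
phylogeny module, so trees and rarefaction describe the same data.

The driver-versus-background comparison splits each VAF set at a threshold
(default 0.15, strictly greater counts as high) and applies Pearson's
chi-square without continuity correction to the 2×2 table; degenerate
margins raise an error naming the margin.

## Integration hotspots

Integration-site lists are scanned with 20 kb windows advancing by 10 kb,
anchored at coordinate 0 on each chromosome and clipped at its end (the
final short window is emitted; anchoring is a declared choice since edge
handling is underdetermined). A 1-based site at position $p$ falls in
window $[s, e)$ iff $s \le p-1 < e$; every interior site is counted by
exactly window/step = 2 windows. A window is a hotspot when its count
strictly exceeds 3. Sites are counted per occurrence by default (recurrent
integration at one base in several samples counts multiply), with a
`unique_positions` switch. The genome fraction reported is
n_windows × 20 kb / genome length — deliberately without merging the
overlapping halves of adjacent hotspot windows, which is the arithmetic
that per-window summaries use; a merged-interval variant is available. The
default denominator is a round 3.0 Gb human genome, overridable with exact
assembly lengths. Sites can also be projected onto a sector phylogeny:
each site maps to the edge whose descendant sectors exactly match the
sectors carrying it, all-sector sites go to the trunk ordered by genomic
coordinate, and unmatched patterns land in an explicit homoplasy bucket.

## Signature refitting

An observed 96-context count vector is normalised and projected onto a
column-stochastic signature matrix by nonnegative least squares
(\pkg{pracma}'s Lawson–Hanson solver): exposures are mixture weights and
cannot physically be negative, and NNLS also yields the sparse solutions
expected when few processes are active. Plain unconstrained least squares
is available behind `method = "ols"` for comparison, since a "linear
model" alone does not pin the constraint down. Exposures are reported both
raw (count scale) and normalised to sum 1; the fit quality is
`fraction_explained` = 1 − RSS/TSS, clamped to [0, 1]. The reference
matrix is always an input file — catalogues change and are licensed
separately — and the tests use synthetic matrices plus the multinomial
generator as an oracle (mixtures at $10^6$ draws refit to within ±0.02).

## Seeds and determinism

A single global seed drives everything. Each stochastic stage derives a
child seed as a deterministic hash of (seed, stage label), so inserting or
reordering stages never shifts another stage's random stream, and two runs
with the same configuration are byte-identical. All derived seeds stay
within 32-bit integer range.

## Known limitations

- Fst treats pooled per-site records as independent; spatial and linkage
  autocorrelation are not modelled (no block jackknife).
- The recalibration rule (divide by purity, cap, re-binomialise at the
  minimum depth) is one reasonable inverse of purity dilution, not the
  only one.
- The simulator is neutral by default and has no explicit metastasis,
  nutrient limitation or off-lattice geometry.
- Rarefaction does not extrapolate beyond the observed number of sectors
  (no Chao-type richness estimation).
- Copy-number variation is outside every model here; sites are assumed
  diploid and heterozygous.
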