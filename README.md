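# spatialith

Spatial intra-tumour heterogeneity (ITH) analysis for multi-region tumour
sequencing, plus a 3D lattice range-expansion tumour simulator.

Multi-region ("multi-sector") sequencing takes several spatially separated
biopsies from one tumour and sequences each. `spatialith` is for analysts of
such designs who want to ask: how do the sectors relate genealogically, does
genetic differentiation grow with physical distance (isolation by distance,
IBD), how much somatic variability does a single biopsy miss, where does
viral integration cluster in the genome, and which mutational processes
shaped the spectrum? Because real multi-region cohorts are usually
controlled-access, the package also ships a synthetic-data generator and a
spatial growth simulator so that every analysis is exercisable end to end
without any download.

## What it computes

- **Sector phylogenies.** Presence/absence of somatic variants (alt reads ≥
  a detection threshold) → pairwise Hamming distances → neighbour-joining
  tree; confidence by bootstrap over mutation columns with majority-rule
  consensus. Small cases are enumerated exactly over all *m^m* resamples.
- **Fst and IBD.** Weir–Cockerham's two-population θ, treating reads as
  haploid allele samples: with read depths *n₁, n₂* and variant-read
  frequencies *p₁, p₂*,

  θ = (MSP − MSG) / (MSP + (n_c − 1)·MSG),

  where MSP = Σ nᵢ(pᵢ − p̄)², MSG = Σ nᵢpᵢ(1 − pᵢ)/(n₁ + n₂ − 2) and
  n_c = n₁ + n₂ − (n₁² + n₂²)/(n₁ + n₂). Observed frequencies are first
  purity-corrected (f/purity, capped at 1) and re-binomialised at a common
  depth. All per-site, per-pair θ values are pooled and regressed on the
  pair's physical distance (OLS); a positive slope is the IBD signature.
- **Rarefaction ITH ranking.** X_n = mean count of distinct mutations
  detected in n randomly drawn sectors; the fold curve X_n/X₁ and its value
  at n = 2 rank how much variability a single biopsy misses.
- **Integration hotspots.** 20 kb windows sliding by 10 kb; a window with
  more than 3 integration sites is a hotspot; genome fraction reported as
  n_windows × 20 kb / genome length.
- **Signature refitting.** Nonnegative least squares of a 96-context
  spectrum on a column-stochastic signature matrix.
- **Growth simulation.** A founder cell on a 3D cubic lattice divides into
  the six axial directions where space is free; each daughter genome gains
  Poisson(0.5) unique mutations per division; optional death and
  driver-mutation selection. Sector sampling mimics a linear biopsy grid.

## Worked example

```r
library(spatialith)

tum <- generate_tumour(6, seed = 11)        # 6 sectors, two clades
tum$table
#> mutation_table: 320 variants x 6 sectors
#>   sectors: S1, S2, S3, S4, S5, S6
#>   mean depth: 100.1

pm   <- presence_matrix(tum$table, min_alt = 3)
boot <- bootstrap_consensus(pm, n_replicates = 100, seed = 11)
boot
#> Bootstrap consensus over 100 replicates (resample)
#> Non-trivial splits observed:
#>         split size support
#> 1 S3|S4|S5|S6    4       1
#> 2    S4|S5|S6    3       1
#> 3       S5|S6    2       1
```

The generating clades were {S1,S2,S3} vs {S4,S5,S6}; the split `S4|S5|S6`
is recovered with bootstrap support 1.0 (the other splits resolve
within-clade structure contributed by private mutations).

```r
tab <- purity_recalibrate(tum$table,
                          setNames(tum$truth$purity, tum$meta$sector_id),
                          seed = 11)
fit <- ibd_regression(fst_records(tab, tum$meta))
fit
#> Isolation-by-distance fit (3300 pooled Fst records, site pooling)
#>   slope     +0.00424 per mm
#>   intercept +0.131
#>   p-value   2.88e-36
```

Fst rises by ≈0.004 per millimetre of sector separation — sectors further
apart are genetically more different.

```r
curve <- rarefaction(tum$table, min_alt = 3)
ith_slope(curve)
#> [1] 1.294118
```

A second biopsy reveals on average 29% more somatic mutations than one.

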