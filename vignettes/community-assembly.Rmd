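---
title: "Null-model analysis of community assembly along elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model analysis of community assembly along elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elevassembly)
```

## The problem

Elevation gradients compress large environmental changes into small
horizontal distances, which makes them a natural instrument for separating
the forces that assemble microbial communities: **selection** (environmental
filtering by habitat preference), **dispersal** (organism exchange between
sites, either limiting or homogenizing), and **ecological drift**
(demographic stochasticity). `elevassembly` implements the statistical chain
used for such studies on OTU count tables from taxon-targeted amplicon
sequencing: diversity and beta-diversity description, matrix-correlation
inference, a two-step null-model partition of assembly processes, indicator
species detection per elevation zone, and phylogenetic-signal tests of
elevational habitat preference. A synthetic-community generator reproduces
the two study designs the package targets — a mountain transect spanning
400–1,200 m and a low-relief two-watershed design spanning ~50 m — so every
stage is testable end to end without sequencing data.

## The assembly partition

For samples $j,k$ the between-community mean nearest-taxon distance is

$$\beta\mathrm{MNTD}(j,k) = \tfrac12\Big(\sum_i f_{ij}\min_{i'\in k} d(i,i')
 + \sum_{i'} f_{i'k}\min_{i\in j} d(i,i')\Big),$$

with $f$ relative abundances and $d$ patristic distance. `bnti()` shuffles
tip labels across the whole tree (the standard randomization for this
framework) and standardizes the observation against the null mean and
standard deviation; $\beta$NTI beyond $\pm 2$ indicates selection (variable
when positive, homogeneous when negative). For the remaining pairs,
`raup_crick_bray()` compares the observed Bray–Curtis dissimilarity against
nulls that preserve each sample's richness and depth, drawing species by
occupancy and allocating reads by regional relative abundance; the rank,
rescaled to $[-1,1]$, flags dispersal limitation ($>0.95$) or homogenizing
dispersal ($<-0.95$), and everything else is drift
(`classify_processes()`, thresholds configurable, defaults $\pm 2$ and
$\pm 0.95$).

Two implementation choices matter here. First, one seeded stream generates
a *shared* set of tip relabelings used for every sample pair, rather than
per-pair substreams: the whole matrix is a deterministic function of one
seed regardless of evaluation order, and sharing nulls across pairs is the
framework's usual (and much cheaper) practice. Second,
`raup_crick_bray(reference = )` lets occupancy and regional abundance come
from a larger reference table. This matters for calibration work: when the
null's parameters are estimated from the very samples being tested, their
sampling noise is shared between the observation and the null and RC drifts
outward; with an independent reference the self-consistency calibration
(|RC| > 0.95 for ≈5% of pairs generated by the null process itself) holds.

## Beta diversity, matrix tests, indicators, phylogenetic signal

Bray–Curtis (vegan), unweighted UniFrac (picante, on the pruned rooted
tree), and the Sørensen partition into turnover
$\beta_\mathrm{sim}=\min(b,c)/(a+\min(b,c))$ and nestedness
$\beta_\mathrm{sne}=\beta_\mathrm{sor}-\beta_\mathrm{sim}$ are exposed as
labeled `dist` objects; the partition identity is enforced entrywise. On a
star phylogeny unweighted UniFrac reduces to the binary Jaccard index —
`(b+c)/(a+b+c)`, not Sørensen — and the test suite asserts that closed-form
limit.

ANOSIM wraps vegan (one-sided, 9,999 permutations by default, midranks).
The Mantel family is implemented in the package because its conventions are
pinned: two-sided by default (environmental correlations carry sign),
add-one p estimator $(1+\#\{|r^*|\ge|r|\})/(1+n)$, joint row/column
permutation of the second matrix, and a correlogram with equal-width
distance classes (Sturges' rule on the pair count), class-membership
indicator correlations with the sign flipped so that positive $r$ means
"more similar than average in this class", and Holm correction. vegan's
Mantel is kept as an independent cross-check in the tests.

`indval()` computes specificity $A$, fidelity $B$ and
$\mathrm{IndVal}=\sqrt{AB}$ per OTU with best-group assignment and
label-permutation significance. IndVal is deliberately *not* invariant to
per-sample rescaling (specificity uses group mean abundances), so the
pipeline feeds it normalized tables. Preferred elevation is the
abundance-weighted mean of detection-site elevations; it is bounded by the
detection range, so on a transect it compresses optima lying outside the
sampled span toward the edges — correlation with the true optimum stays
high, but the slope is attenuated. `bootstrap_pd_null()` draws *sets* of
pairwise patristic distances from the community pool, matching the observed
pair count: a 95% interval for an observed mean requires a sampling
distribution of means, so single-distance draws would be the wrong unit
(the draw unit and statistic are arguments). Clade divergence contrasts
default to the maximal monophyletic groups whose tips are all labeled, with
permutation t-statistics over clade-level mean distances and Bonferroni
correction; user-supplied clade cuts are accepted because real analyses
often delimit clades by inspection.

## The synthetic generator

`simulate_dataset()` layers three standard models:

1. **Yule phylogeny** (`simulate_tree`): waiting time
   $\mathrm{Exp}(k\,\lambda)$ between splits at $k$ lineages, uniform choice
   of the splitting lineage, one final interval so terminal branches are
   positive. No extinction — nothing downstream tests it.
2. **Brownian elevation optima** (`evolve_optima`): child = parent +
   $N(0, \sigma_{BM}^2\,\ell)$, so habitat preference is phylogenetically
   conserved with covariance equal to shared path length.
3. **Sampling** (`assemble_communities`): regional log-normal abundances
   $A_i$, Gaussian habitat filter
   $w_{is}=A_i\exp(-(e_s-\mathrm{opt}_i)^2/2\sigma_f^2)$, optional dispersal
   mixing $(1-m)\,w_s + m\,\bar w_{\mathrm{pool}}$ applied to *expected*
   weights (so multinomial depth stays exact), then a multinomial draw per
   sample.

Defaults (chosen once, as study conditions): a regional pool of 300 OTUs,
$\lambda=1$, $\sigma_{BM}=150$ m (tree height $\approx\log n$, so tip optima
spread ≈350 m around the 800 m root optimum and span a 400–1,200 m
transect), log-normal(0, 1) pool, and **150 reads per sample**. The shallow
depth is deliberate: taxon-targeted amplicon libraries of this kind are
sparse (the motivating survey discarded samples below its first-quartile
depth of 18 reads, and per-sample richness sits far below the regional
pool). This sparse-sampling regime is also where the Raup–Crick null is
consistent with neutral multinomial sampling; at depths where nearly every
pool member is observed in every sample, the richness-constrained null
diverges systematically from multinomial sampling and neutral data stop
looking like drift.

Regime presets fix the knobs: *selection* ($\sigma_f=100$ m, $m=0$),
*neutral* ($\sigma_f=\infty$, $m=0$), *dispersal* ($\sigma_f=200$ m,
$m=0.9$). For the dispersal regime the mixing pools merge the Low and
Middle zones, with High separate: downslope transport of soil and water
homogenizes the lower mountain while the summit stays isolated, which is
the pattern the zone-pair summary is designed to detect. (Zone-based pools
and a single whole-site pool are also available.)

The sampling designs replicate the reference survey layouts: 9 stations at
1,200→400 m with replicate pattern (3,3,2,2,3,3,2,3,3) and the per-sample
pH/temperature/soil-organic-matter records, and 10 single-replicate sites
at 609–657 m in two watersheds. Coordinates are not part of the reference survey
table, so sites are placed on transects scaled to the reference design
summaries (mean pairwise geodesic distance 1,361 m and 353 m respectively);
the mountain transect switchbacks laterally so that horizontal distance is
strongly but not perfectly collinear with elevation change — on a perfectly
straight, evenly spaced transect the partial Mantel test of elevation given
distance would be degenerate by construction.

### What the generator does not emulate

Real amplicon data add PCR and sequencing error, chimeras, clustering
artifacts, compositional biases between libraries, spatially autocorrelated
environments beyond elevation, and non-ultrametric trees estimated with
error. Passing tests therefore demonstrate the *statistical machinery* —
calibration of the nulls under their own assumptions and recovery of
planted structure — not robustness to those failure modes. Root-to-tip
contrasts in particular are only informative on non-ultrametric trees; on
the generator's ultrametric trees they are all ties by construction, and the
function returns p = 1 (or noise-level statistics) there.

## Numerical conventions and degenerate inputs

* Permutation p-values always use the add-one estimator; they can never be 0.
* Quantiles (the depth filter's `"q1"`, CSS scaling) use the
  linear-interpolation type-7 definition — a printed cutoff like "first
  quartile = 18" depends on this choice.
* Strictly-less-than depth filtering: a sample exactly at the threshold is
  kept.
* Samples at exactly the 500 m / 1,000 m zone boundaries are Middle.
* Degenerate nulls (sd = 0 in βNTI) yield `NA` with a warning and are
  excluded from zone fractions but counted; an all-empty sample is an error
  everywhere rather than a silent zero.
* Partial correlations with a collinear covariate return 0 by convention
  rather than 0/0.
* Midpoint rooting is applied to unrooted input trees and flagged on the
  returned object; rooting choice affects UniFrac and root-to-tip, so the
  flag is preserved for provenance.
* CSS follows the cumulative-sum-scaling recipe (per-sample sum of counts
  at or below the chosen quantile of nonzero counts, rescaled by the median
  factor); TSS (plain relative abundance) is available because the two are
  often conflated in methods descriptions, and the method used is recorded
  on the table.

## Problem sizes

The shipped analyses and tests run on 10–24 samples, 150–300 OTUs, 299–999
null randomizations and 999–9,999 permutations; null-model calibration uses
210 pairs (βNTI) and 435 pairs (RC) with 1,000-replicate uniformity checks
for the permutation tests. These sizes give stable rates (binomial standard
errors well inside the asserted bands) while keeping a full run in the
minutes range on one core.

## Worked example

```{r example, eval = FALSE}
ds <- simulate_dataset("wm", "selection", seed = 1)
vd <- validate_dataset(ds$table, ds$metadata, ds$tree)
bn <- bnti(vd$table, vd$tree, n_null = 999, seed = 2)
rc <- raup_crick_bray(vd$table, n_null = 999, seed = 3)
cls <- classify_processes(bn, rc)
zones <- setNames(as.character(assign_zones(vd$metadata$elevation)),
                  vd$metadata$sample_id)
zone_summary(cls, zones)
```

The numbered drivers under `analysis/` run the same chain over all three
regimes and write their tables under `results/`; `scripts/acceptance.R`
recomputes the headline quantities from scratch with a caller-supplied
seed.

## Known limitations

* The Raup–Crick loop is pure R and quadratic in samples times nulls; at a
  few hundred samples it needs patience or fewer nulls.
* IndVal searches single groups only by default (the zone-combination
  search of multipatt-style tools is out of scope here).
* Conspecific matching between datasets is by exact OTU id; sequence-level
  clustering against an external survey is upstream of this package.
* Only unweighted UniFrac is provided; weighted variants and ordination are
  better served by vegan/phyloseq directly.
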