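---
title: "Methods: gridded diversity hotspots and conservation gaps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded diversity hotspots and conservation gaps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylohotspot)
```

## The analysis

phylohotspot implements a grid-based biodiversity hotspot and conservation
gap analysis. The inputs are a species-by-cell presence/absence matrix on a
regular grid of equal-area cells, a rooted, dated phylogeny covering the
species, a per-cell table of land and nature-reserve area, and optionally a
species-to-genus/family taxonomy. From these it computes four per-cell
diversity metrics, flags the top-percentile cells per metric as hotspots,
accounts for how the four hotspot maps overlap, groups hotspot cells into
contiguous regions, and classifies each hotspot cell's protection status
from its reserve coverage.

## The four metrics

Write $S$ for the number of species recorded in a cell and $R_j$ for the
range size of species $j$ — the number of grid cells (on the analysis grid,
after small-cell exclusion) in which it is recorded.

**Species richness.** $\mathrm{SR} = S$, the column sum of the incidence
matrix.

**Corrected weighted endemism.** Weighted endemism
$\mathrm{WE} = \sum_{j \in \text{cell}} 1/R_j$ up-weights range-restricted
species; summed over all cells every species contributes exactly 1, a
conservation identity the tests verify to $10^{-9}$. Because WE is strongly
coupled to richness, the corrected form divides by $S$ and is reported as a
percentage:
$$\mathrm{CWE} = \frac{\sum_{j} 1/R_j}{S} \times 100\%.$$
CWE is the mean range-restriction of the cell's species: 100% when every
species in the cell occurs nowhere else, $100/N$% when all species are
ubiquitous over $N$ cells.

**Relative phylogenetic diversity.** Faith's PD of a cell is the total
branch length spanned by the cell's species. PD correlates almost linearly
with $S$ at high richness, so it is standardized by the log of richness:
$$\mathrm{PD_{rel}} = \mathrm{PD} / \log_{10} S.$$
For $S = 1$ the divisor is zero; such cells are flagged
`pdrel_undefined_s1` and excluded from PD_rel hotspot ranking by default
(the alternative `pdrel_s1 = "zero"` reports 0, covering the other
plausible reading; neither imputes a value silently). Note the crossover at
$S = 10$: $\mathrm{PD_{rel}} > \mathrm{PD}$ for $2 \le S < 10$ and
$\mathrm{PD_{rel}} \le \mathrm{PD}$ beyond.

**Phylogenetic endemism.** Each branch $c$ on the union of root-paths of
the cell's species contributes its length $L_c$ discounted by its clade
range $R_c$, the number of cells occupied by at least one descendant of the
branch (overlapping cells counted once):
$$\mathrm{PE} = \sum_{c \in C} L_c / R_c.$$
Summed over all cells each branch contributes $L_c \cdot R_c/R_c = L_c$, so
total PE equals the PD of all recorded taxa — the second exact identity the
tests assert.

### Rooting convention

PD here sums the branches connecting the cell's taxa **to the root**, so
the stem above the taxa's most recent common ancestor is included and a
single-species cell has PD equal to its root-path length. This choice is
deliberate: it is the path-set definition PE uses, and it is what makes the
PE conservation identity exact. `faith_pd(..., rooted = FALSE)` exposes the
classical unrooted variant (branches strictly between taxa; 0 for one
taxon) for comparison; it propagates through
`relative_phylogenetic_diversity()` and `diversity_table()` via `rooted =
FALSE`. PE itself is always computed on root-paths.

### Degenerate inputs

Empty cells are flagged `empty` with `SR = 0`, `CWE = PD = PD_rel = NA`.
Two exceptions are exact mathematics rather than imputations: `WE = 0` (an
empty sum; required for the WE identity over all cells) and `PE = 0`.
Zero-length branches are retained for topology and contribute 0. Polytomies
are kept as-is; supertrees pruned from taxonomic backbones are
polytomy-rich and arbitrary resolution would manufacture branch lengths.
Reserve areas exceeding a cell's land area (digitisation slivers) are
clamped with a warning rather than rejected.

## Branch-length age smoothing

`bladj_smooth()` implements BLADJ-style even interpolation for trees whose
topology is known but whose internal node ages are only partly constrained:
fixed ages (root required, leaves defaulting to 0) are honoured, and along
each root-to-leaf path the unconstrained nodes between two consecutive
constrained ones are spaced at equal age steps; branch lengths are then
parent age minus child age. Off a pure chain a node lies on several paths;
interpolation visits tips in cladewise appearance order and the first path
to assign a node wins, which is deterministic and matches the
even-placement intent of Phylocom's BLADJ without claiming
bit-compatibility. Constraint violations (a fixed node older than its
nearest fixed ancestor) are errors, never silently adjusted.

## Hotspot selection

"Top $p$" is read as the top fraction of grid **cells** ranked by the
metric: the `ceiling(p * n_eligible)` highest-valued eligible cells, where
eligible means the metric is defined (so `pdrel_undefined_s1` cells never
rank for PD_rel). Cells tied with the cutoff value are all included —
selection must not depend on input order — which is why a selected set can
slightly exceed the nominal count. Selection is monotone in $p$. The
alternative reading, a threshold at the top fraction of the observed value
*range*, is available as `mode = "range"` for sensitivity analysis; with
strongly right-skewed metrics like WE it selects far fewer cells, and the
two modes should not be compared casually.

Published pairwise "overlap" percentages between hotspot maps rarely state
a denominator, so `overlap_summary()` reports both conventions explicitly —
Jaccard $|A \cap B| / |A \cup B|$ and $|A \cap B| / \min(|A|, |B|)$ — and
species-composition similarity as Sørensen (default convention) alongside
Jaccard. Nothing downstream depends on which one a reader prefers.

Contiguous regions are maximal connected components of the hotspot union
under queen adjacency by default (diagonal mountain chains are common;
`adjacency = "rook"` is the stricter alternative). Region ids are assigned
by decreasing size with ties broken by smallest member cell id, so labels
are reproducible.

## Gap classification

Coverage is `reserve_area / land_area` per cell. A hotspot cell is
`uncovered` at exactly 0, `under_protected` strictly between 0 and the
threshold, and `protected` at or above it; the default threshold is 0.10,
the conventional 10% protection target. Whether exactly-at-threshold counts
as protected is genuinely ambiguous in the way the rule is usually phrased
("less than 10%" for gaps, "more than 10%" for protected); we default to
protected and expose `strict_protected = TRUE` for the other reading. Gap
fraction is monotone non-decreasing in the threshold. Per-n-metric gap
fractions (the share of cells selected by exactly $n$ metrics that are
gaps) are area-weighted.

## The synthetic-data generator

Real inputs of this kind — a national distribution atlas rasterized to
50 km cells, a dated supertree, a digitized reserve map — are typically
proprietary. The generator produces inputs with the statistical structure
the analysis assumes so the whole pipeline is testable:

* a rectangular grid of 2,500 km² cells (50 km × 50 km) in which a
  configurable fraction of border cells (default 0.3) gets a land area
  drawn uniformly below the full cell, exercising the 1,250 km² exclusion
  rule;
* an ultrametric Yule phylogeny (`ape::rphylo`, pure birth);
* species range sizes drawn from a lognormal, default median 10 cells with
  `sdlog = 1.2` — right-skewed, most species narrow-ranged, as range-size
  distributions of large floras are;
* spatially cohesive ranges grown by seeded breadth-first accretion on rook
  adjacency from a start cell, the simplest mechanism that yields
  contiguous county-map-like ranges; starts are biased toward configurable
  endemism-center cells for the narrowest quantile of species and toward
  the high end of a monotone row-axis richness gradient (the latitudinal
  trend) otherwise, with optional planted single-cell endemics and an
  optional planted high-richness block so tests can verify pattern
  recovery;
* zero-inflated Beta reserve coverage, default `Beta(0.9, 4.5)` with zero
  probability 0.35, giving mean coverage near 11% of land — the order of a
  real national reserve network.

Identical configuration and seed give bit-identical outputs; the generator
restores the caller's RNG state. Grid and occurrence draws use separate
streams (seed and seed + 1) so changing one does not reshuffle the other.

What the generator does **not** emulate: climate-driven niches and the
resulting spatial autocorrelation of composition, phylogenetic signal in
range size or range location (ranges are assigned independently of the
tree), coastline geometry, and taxonomic structure above species. Passing
recovery tests therefore demonstrate that the pipeline's bookkeeping and
ranking are correct on data with known structure — not that any particular
real landscape would yield similar hotspot maps.

## Problem sizes and tolerances

The conservation identities are exact mathematics and are asserted to
$10^{-9}$ on a 200-species × 500-cell instance. Oracle-equivalence tests
compare every metric against an independent brute-force implementation
(explicit root-path enumeration and from-scratch set unions) on 100 random
instances of up to 10 species × 20 cells, plus all 255 subsets of an
8-leaf tree for PD; `picante::pd` serves as an additional external
cross-check. Pattern-recovery runs use a 40 × 40 grid with 300 species —
large enough for stable top-decile sets, small enough to keep the full
suite under a minute of compute. The planted-recovery test fixes its seed;
it is a property of the stated study conditions, not of a particular draw,
but is asserted reproducibly.

## Known limitations

* PE and PD are computed on the rooted convention throughout; users wanting
  unrooted PE (rare) must compute it themselves from `clade_ranges()`.
* The value-range hotspot mode and the strict gap boundary are provided for
  sensitivity analysis, not validated against any published map.
* Reserve coverage is consumed as per-cell areas; polygon intersection is
  upstream GIS work and out of scope.
* BLADJ smoothing matches Phylocom's behaviour on chains exactly and its
  intent elsewhere; it is not a drop-in bit-identical replacement.
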