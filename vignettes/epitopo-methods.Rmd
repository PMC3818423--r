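---
title: "Quantifying epithelial organization: models, parameters and design choices"
author: "epitopo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying epithelial organization: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epitopo` compares two groups of segmented epithelial images and asks two
questions: do the groups differ in their polygon (cell-side) distribution,
and do they differ in overall organization as captured by geometric and
network characteristics? This vignette records the model behind each stage,
the parameters that matter, and the design decisions that were genuinely
open — in enough detail that a maintainer can judge every numerical choice.

## The tissue model and what the generator emulates

Proliferating epithelial monolayers, viewed apically, form a confluent
polygonal mosaic. Their side distribution is stereotyped — roughly 3%
four-sided, 28% five-sided, 46% six-sided and 20% seven-sided cells — and
changes only subtly between nearby developmental stages, while the pupal
endpoint is a near-perfect hexagonal lattice.

The synthetic generator reproduces this regime with the simplest mechanism
that spans it: seed points are sampled uniformly with a hardcore
(minimum-separation) constraint of half the mean spacing, relaxed by a
configurable number of Lloyd (centroidal Voronoi) iterations, and every
pixel is assigned to its nearest seed. Cells are separated by 1-px
background boundaries; the outer pixel frame is background; the ROI is the
set of cells not touching the border (border cells only contribute as
neighbours, mirroring standard practice). Defaults are 515 cells in a
512×512 frame — about the cell count per image of a typical wing-disc
field — and `lloyd_iterations = 2`, which lands the interior polygon-class
frequencies at ≈2%/23%/46%/24% for classes 4–7, inside the published
proliferating-epithelium regime. The regularity knob is monotone: more
Lloyd iterations → more hexagons (tested property).

`polygon_shift` creates the second condition. A positive shift interpolates
the seed points toward a further-relaxed configuration (four extra Lloyd
iterations), converting pentagon mass into hexagon mass smoothly; a negative
shift interpolates toward a fresh uniform sample, de-ordering the mosaic.
The default two-condition study uses shift 0 versus **0.3**, calibrated once
at the default image size on the polygon distribution alone: it is the
smallest grid value at which the 15-vs-16-image MANOVA is reliably
significant (p typically 10⁻⁴–10⁻²) while the mosaics stay visually
indistinguishable — the "small but significant" situation the method exists
for. A shift of 0.2 leaves the comparison borderline (p crossing 0.05 on
some seeds), and shift 1 is gross enough for >90% power even on small test
images; the power grid is exercised in the test suite.

What the generator does **not** emulate: membrane thickness and staining
noise (boundaries are ideal 1-px lines), curved or irregular cell sides
(Voronoi cells are convex polygons, so convex-hull ratios sit near 1 by
construction), cell divisions, apoptosis and local rearrangements (there is
no dynamics), and segmentation errors. Passing tests therefore demonstrate
the correctness of the *measurement and statistics machinery* on
ground-truth mosaics, not robustness to imaging artifacts.

Determinism: the same `(spec, seed)` yields a bit-identical label image.
Nearest-seed ties are broken by lowest seed index; where the 1-px boundary
severs a thin Voronoi wedge tip, the repair step keeps each label's largest
4-connected component and clears stray pixels to background, so the label
integrity invariants (labels 1..n, each one 4-connected region) hold.

## Per-cell geometry

Axis lengths are those of the ellipse with the same normalized second
central moments as the pixel region (the regionprops convention, with the
1/12 pixel-extent correction, so a 20×10 rectangle has axis ratio exactly
2). The convex-hull ratio divides pixel area by the area of the convex hull
of the pixel *corners*; the hull then contains every pixel square entirely,
making the ratio ≤ 1 with equality exactly for convex pixel polygons.
"Relation neighbours" features divide the cell's value by the mean over its
contact-graph neighbours — a cell resembling its neighbourhood scores 1.
The other orientation (neighbour mean over cell value) would carry the same
information; one was fixed and documented.

## The contact network and the neighbour radius

Two cells are adjacent when dilating one region by a disc of radius `r`
overlaps the other — equivalently, when their minimal pixel-to-pixel
distance is ≤ `r`. The default `r = 4` px is the field's standard operating
point for segmented micrographs, whose membrane boundaries are a few pixels
thick. On the generator's ideal 1-px boundaries, `r = 4` occasionally
bridges across thin wedges of very irregular (unrelaxed) mosaics, slightly
inflating degrees; `r = 3` is the radius matched to a 1-px boundary
staircase (it covers the √5–2√2 px gaps of diagonal contacts but cannot
reach across another cell). The Voronoi-recovery tests therefore run at
`r = 3` on a fine 1024² grid, where the contact graph reproduces the
Delaunay triangulation of the generator seeds for >95% of interior cells
and the polygon-class histogram to ±1 cell per class. At the default
relaxation the two radii give nearly identical distributions, and `r = 4`
remains the pipeline default.

Edge weights count background pixels within distance `r` of both regions
(a shared-boundary-length proxy). Weights feed **only** the node strength;
every path-based metric (eccentricity, betweenness, shortest-path lengths,
radius, diameter, efficiency) is unweighted, matching the standard
definition of betweenness as a fraction of shortest paths. Per-node metrics
are computed on the full graph so out-of-ROI neighbours contribute; the 12
whole-image metrics use the subgraph induced by ROI cells (largest
component, with a warning, in the rare disconnected case). Betweenness is
normalized by (n−1)(n−2)/2. Local clustering of degree-<2 nodes is defined
as 0. On regular graphs the degree–degree correlation is undefined and
reported as 0. Two of the 40 characteristics — the degree–degree Pearson
correlation and Newman's assortativity — are numerically equal on
unweighted graphs; both are kept for fidelity to the classic 40-entry
vector, and the selection machinery tolerates the collinearity (see below).
Modularity uses greedy agglomerative community detection on a canonical
vertex ordering (by centroid), so relabelling cells cannot change any image
feature.

## Correlation assay

Cell similarity is the Pearson correlation of two cells' 14 min-max
normalized characteristics (the formula with population standard deviations
and the 1/p factor reduces algebraically to Pearson's r). Values are ≤ 1;
negative values are possible in principle and simply never pass the high
thresholds of interest, so the classic "between 0 and 1" reading is treated
as an empirical observation, not enforced by clipping. The edge rule is
`corr ≥ threshold` (boundary ties included; they are measure-zero). The
threshold sweep exploits that the largest-component size is non-increasing
in the threshold and bisects to a requested component-size window; the
historical operating point (a ~1700-cell component at threshold 0.9975 on
~16,000 pooled cells) is reachable only with the original images, so the
package reports whatever window the caller requests. Assortment of polygon
classes over links, and mixing of conditions, are both tested by permuting
node attributes (≥1000 shuffles, seeded).

## Polygon distribution and MANOVA

Frequencies are computed over ROI cells; classes 4–8 enter a one-way
two-group MANOVA (classes 3, 9, 10 are discarded as absent from many
images — which also keeps the responses away from exact simplex
collinearity). Wilks' Λ with Rao's F is reported; for two groups all four
classic MANOVA statistics are equivalent, and the F is exact under
normality. Frequencies are used untransformed (no arcsine), matching how
such distributions are conventionally plotted and compared; the permutation
cross-check in the test suite confirms the parametric p within Monte-Carlo
error in the regime used. The within-group residual rank is checked and a
singular covariance produces an explicit error advising class pooling.

## PCA descriptor and feature selection

Images are projected on the two leading eigenvectors of the covariance of
the selected (min-max normalized) features; the sign convention makes the
largest-magnitude loading positive. Separation is scored by
`trace(B)/trace(W)` of the 2-D scores, where B and W are the between- and
within-group scatter matrices (they sum to the total scatter — a tested
identity). The classic Calinski-Harabasz factor (N−k)/(k−1) is deliberately
omitted: with N = 31 and k = 2 it would scale every value by 29, while the
descriptor range observed in this kind of analysis (≈0.1–1.8) matches the
unscaled trace ratio. This is the single most consequential
reverse-engineering choice in the package and is fixed here.

Normalization is min-max to [0, 1] per characteristic (constant columns map
to 0 with a warning, and are excluded from selection since they admit no
2-D projection; the same applies to exactly collinear candidate pairs such
as the duplicated degree-correlation features, which are skipped as
rank-deficient rather than scored).

The beam search evaluates all C(40, 2) = 780 pairs and keeps the 10 best;
each kept pair is extended by every unused feature, keeping 5 per pair (50
trios); then 2 per trio (100 quartets); from there one feature is added per
branch per iteration. The full quotas are kept through the quartet stage —
this is what makes the 10/50/100 bookkeeping exact — and the
stop-on-decrease rule applies from the one-at-a-time phase on, per branch;
the global stop is at 7 features. Since a later extension can only lose to
an earlier subset, the returned result is the argmax over *everything
evaluated*, with the full per-iteration trace attached. Ties in candidate
ranking are broken by lexicographic feature-index order, making the search
fully deterministic. The inner loop (≈17,000 small eigenproblems per run)
is implemented in compiled code against the precomputed 40×40 covariance;
a test pins the fast path to the direct R scatter computation at 1e-9, and
on 8-feature tables the beam search attains the exhaustive-enumeration
optimum in ≥90% of random tables (the gap, when present, is the price of
the fixed beam width and is measured, not hidden).

## Randomization null

Each loop reassigns the images into mixA (half of each condition, rounded
up — 8+8 for a 15+16 study) and mixB (the rest, 8+7), then re-runs the
*entire* selection search and the MANOVA. The real-label descriptor's
percentile among loops, the count of loops beating it, and the
p-vs-descriptor scatter (with the p = 0.05 line and the real pair flagged)
make up the independence report. The acceptance script uses 400 loops — a
scaled version of the classic 4,000-loop design chosen to keep a full
reproduction run in minutes; the loop count is a parameter and the series
is seeded and fully reproducible.

## Numerical choices and degenerate inputs

* Coordinates are (row, col), 0-based at the top-left corner, half-open
  pixel extents; pixel centres at half-integers.
* Nearest-seed ties: lowest seed index. Candidate-ranking ties:
  lexicographic. RNG: every stage derives its stream from one integer seed.
* Overcrowded specs (fewer than ~9 px per cell, or hardcore sampling
  failure) raise an explicit "overcrowded" error; degenerate cell vectors
  (zero variance) and empty label images also error rather than propagate
  NaN.
* An in-ROI cell with no neighbours is treated as an upstream segmentation
  fault (error), since every confluent tissue cell has contacts.
* `manova_polygons` requires ≥6 images per group for the 5-class response;
  `pca_descriptor` errors when all points of each group coincide.

## Problem sizes used by the test suite

Tests run on scaled mosaics chosen to exercise the identical code paths at
interactive cost: "tiny" images (64 cells, 80² px) for calibration-style
loops — including the 500-replicate null calibration of the MANOVA type-I
error — and "mid" images (150 cells, 192² px) where per-image frequency
noise matters, e.g. the power checks. The Voronoi-recovery oracle runs once
at 500 cells on a 1024² grid. Selection-search properties use 31×40 tables
directly, and the planted-feature recovery uses 50 seeded tables. These
sizes are the package's own testing choices; the defaults users see remain
515-cell images.

## Known limitations

* The 40-characteristic vector follows the field's classic list by name;
  where original formula definitions were not recoverable, the standard
  graph-theory definitions were adopted and documented (strength = weighted
  degree; unweighted paths; Newman modularity of a greedy partition).
  Features 34 and 37 are numerically identical here as a consequence.
* The dilation-radius adjacency is sensitive to boundary thickness; users
  with thick membranes should keep `r = 4`, users with skeletonized 1-px
  boundaries get the most faithful topology near `r = 3`.
* The descriptor compares exactly two groups; no multi-class variant and no
  cross-validation of the selection are provided (the selection is a
  descriptive optimum, guarded by the randomization null, not a classifier).
* On coarse grids (< ~20 px per cell diameter) sub-pixel Voronoi facets are
  unrepresentable and topology recovery degrades gracefully but measurably.
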