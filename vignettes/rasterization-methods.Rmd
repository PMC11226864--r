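---
title: "Rasterization preprocessing for spatial omics: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rasterization preprocessing for spatial omics: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spixel)
```

## The problem

Imaging-based spatial omics platforms (MERFISH, Xenium, CODEX and kin)
measure gene expression or protein markers in hundreds of thousands to
millions of individual cells together with their spatial positions.  Most
spatial statistics — spatially variable gene (SVG) detection, neighbourhood
and co-localization analysis — have runtime and memory that grow with the
number of spatial points, which makes them impractical at that scale.

`spixel` trades spatial precision for tractability by *rasterizing*: the
tissue is tiled with equally sized square or hexagonal pixels at a chosen
resolution and each cell's measurements are aggregated into its pixel.
Downstream analyses then operate on thousands of pixels instead of millions
of cells.  The package also implements two analyses designed around
rasterized data: a Moran's I permutation detector for SVGs with
rotation-permutation consensus voting, and a balls-in-boxes co-enrichment
analysis of cell-type pairs.

## Rasterization model

A dataset is `n` cells with coordinates in micrometres, a features-by-cells
matrix (counts or normalized expression) and optionally a categorical label
per cell.  A `pixel_grid` is anchored at the lower-left corner of the
coordinate bounding box and tiles it completely; `resolution` is the side
length of a square pixel or the distance between opposite edges of a
(flat-top) hexagonal pixel, so finer resolution means smaller pixels.

Aggregation is a sparse matrix product between the feature matrix and a
cells-by-pixels membership indicator, which makes the result independent of
cell ordering and keeps sparse inputs sparse.  Two aggregators are
exposed:

* **mean** (default for expression).  The mean makes pixel values
  insensitive to cell density: a gene uniformly expressed by all cells gets
  the same pixel value in dense and sparse regions, and in pixels that only
  partially overlap the tissue.  With sums, density gradients and tissue
  edges would masquerade as expression patterns and inflate false positives
  in SVG analysis.
* **sum** (default for labels).  Label rasterization one-hot encodes the
  labels into a categories-by-cells model matrix and sums it per pixel,
  giving cell counts per category; the downstream relative-enrichment
  metric normalizes density itself.  Sums conserve totals exactly, which
  the tests exploit as an invariant.

Empty pixels are dropped rather than emitted as zeros — an empty pixel
carries no evidence under mean aggregation, and dropping it keeps outputs
sparse.

### Geometry choices

Several geometric details are under-determined by the problem and were
fixed once:

* **Anchoring.**  The grid origin is `(min x, min y)` of the input.  Any
  fixed rule works; this one is deterministic and needs no extra state.
* **Binning convention.**  Half-open `[lo, hi)` intervals per axis, with
  the global maximum edge closed so boundary cells are never dropped — the
  standard histogram convention.
* **Hexagon orientation.**  Flat-top hexagons with a centroid at the
  origin; cells are assigned by cube-coordinate rounding of fractional
  axial coordinates, which is exactly nearest-centroid assignment (the
  hexagonal tessellation is the Voronoi diagram of its centroids — the
  test suite checks this equivalence against brute force).
* **Rotation permutations.**  Pixel values near grid boundaries depend on
  where exactly the boundaries fall.  `permute_rasterize()` controls for
  this by rotating the *dataset* about its bounding-box centroid (the grid
  stays axis-aligned, which is geometrically equivalent to rotating the
  grid and simpler) at angles evenly spaced over one rotational symmetry
  period — 90 degrees for squares, 60 for hexagons; angles beyond the
  period duplicate tilings.

## SVG detection on rasters

`svg_test()` scores each feature with Moran's I over row-standardized
k-nearest-neighbour weights (`k = 6` by default, the immediate neighbour
shell of a square pixel) on pixel centroids.  Mean-aggregated values are
log1p-transformed first (`normalize = FALSE` gives raw values).
Significance comes from a one-sided permutation test for positive
autocorrelation with the add-one estimator
`p = (1 + #{I_perm >= I_obs}) / (1 + n_perm)`; one shared sequence of
pixel relabelings is applied to all features, and the permutation loop runs
in compiled code with features processed in cache-resident blocks.
P-values are Benjamini–Hochberg adjusted (the field-standard choice where
only "adjusted p-value" is specified) and a feature is called an SVG at
`p_adjusted <= 0.05` by default.  The test is one-sided because the SVG
definition targets coherent spatial structure, not regular dispersion.
Constant features have undefined Moran's I; they are reported as `NaN`,
excluded from the adjustment, and never called.

The permutation count bounds attainable p-values below by
`1/(1 + n_perm)`; with 1000 features, Benjamini–Hochberg at 0.05 needs
p-values around `0.05 * k / 1000` for `k` discoveries, so `n_perm` under a
few hundred leaves real positives unable to clear the threshold.  The
package default is 999; the reference benchmarks use 499 as a
runtime/granularity compromise.

**Voting.**  False positives on rasterized data are typically hotspot
artifacts: a small clump of expressing cells reads as spatial structure
only when a pixel boundary happens to split it.  Because such calls are
orientation-dependent, combining calls across rotation permutations with
`vote_consensus()` suppresses them: a feature needs at least
`required_votes` positive calls among the rotated runs.  Raising the
threshold can only remove positives, so the true negative rate weakly
increases while sensitivity can only weakly decrease; the acceptance suite
reproduces this trade-off on simulations with injected clump artifacts.

## Cell-type co-enrichment

Label rasters put cell-type counts in boxes (pixels), which opens the
classic occupancy machinery.  For type `t` and pixel `q`, the relative
enrichment is observed over expected count,

    RE[t, q] = n[t, q] / (n[., q] * N_t / N),

which corrects for both local density and global type abundance; `RE = 1`
means the type is at its tissue-wide proportion.  RE is binarized at a
threshold (default 1 — "above expectation"; the threshold is exposed
because sharper definitions of enrichment are sometimes wanted) and each
pair of types is summarized by the 2x2 table of `N` pixels, margins `mA`,
`mB` and joint count `X`.

Affinity is the log-odds parameter `alpha` of the Fisher noncentral
hypergeometric model for `X` given the margins.  The MLE solves
`E[X | alpha] = X_obs`; the expectation is strictly increasing in `alpha`,
so a bracketed root finder on `[-cap, cap]` converges reliably (tolerance
1e-9, evaluated in log space for numerical stability).  Tables at the
support boundary (complete joint presence or absence) have an infinite
MLE and are reported at the symmetric cap `+-10`; a fixed documented cap
is simpler than confidence-interval-based capping and keeps downstream
clustering finite.  Degenerate margins (a type enriched everywhere or
nowhere) leave `alpha` unidentifiable: those pairs carry `NA` and are
excluded from multiple testing.  Significance uses the two-sided Fisher
exact test by the minimum-likelihood rule with a `1e-7` relative slack for
floating-point ties, and Benjamini–Hochberg across the non-degenerate
pairs.  `cluster_alpha()` offers average-linkage hierarchical clustering
on the distance `max(alpha) - alpha` to group types that form structures
together (neither linkage nor distance is canonical here; average linkage
on a max-shifted similarity is the conventional default).

Resolution acts as a length-scale dial: types that touch only along an
interface co-occur in pixels comparable to the interface scale, while
types arranged in nested structures co-occur once pixels span the whole
structure.  The simulation below makes this concrete.

## The simulators

Both generators are first-class, tested package code; they define the
reference conditions for validating the pipelines.

**Circular SVG patterns** (`simulate_svg()`).  4992 points uniform on a
6000 x 6000 um field; 100 SVGs and 900 noise genes; each SVG carries one
circular high-expression region of radius 1500 (large), 750 (medium) or
150 um (small), placed uniformly so the circle fits in the field.  Counts
are Poisson with log-mean `log(0.5) + 5` inside the circle and `log(0.5)`
outside.  The baseline of 0.5 counts/cell matches sparse per-gene counts
typical of imaging-based panels.  The effect size is the one genuinely
free parameter of the generator; it was calibrated once — before the
validation experiments were wired up — to the design goal that detection
at resolutions finer than the pattern radius be near-perfect for *all*
presets.  That goal binds for
the small preset, where a 150 um circle holds only ~10 of 4992 cells
(0.2% of the field): across log-effects {2, 3, 4, 5}, values below 5 leave
the small pattern essentially invisible to a global autocorrelation
statistic at any resolution, while 5 (a ~150-fold mean shift, i.e. an
essentially on/off marker) retains power at resolutions below the pattern
radius and reproduces the decline-and-extinction shape that the benchmark
below verifies.  It was then frozen.

**Nested cell types** (`simulate_celltypes()`).  Four pattern centers on a
2x2 layout in a 1600 x 1600 um field; types B and C uniformly intermixed
in circles of radius 100 um; type A in surrounding annuli out to 300 um;
type D everywhere else.  Cells are placed at a single common density
(0.004 cells/um^2, about one cell per 16 um square — a typical
imaging-platform cell density), so per-type counts are proportional to the
area each niche occupies, as in a real tissue partitioned into niches.
Giving every type the *same* count instead would put B and C at ~16x the
density of A, and no pixel overlapping the core could then be A-enriched
under `RE >= 1` — the scale effect the arrangement exists to show would be
geometrically impossible.  The default centers are jittered by +-50 um
(seeded): exact multiples of round resolutions put the inner circle in
perfect registration with 100 um pixel boundaries, a measure-zero geometry
in which the core tiles exactly into a 2x2 pixel block and the A-B
interface vanishes.  Real niches are never grid-aligned.

What the simulators deliberately omit: negative-binomial overdispersion,
segmentation errors, density gradients, irregular tissue boundaries, and
expression patterns other than discs.  Passing benchmarks therefore show
that the machinery is correct and that resolution interacts with pattern
scale as theory predicts — not that real-tissue error modes are handled.

## Reference benchmark configuration

The validation experiments (test suite and `scripts/acceptance.R`) use
these problem sizes, chosen as the package's reference configuration:

* Wide-pattern benchmark: large and medium presets, resolutions spanning
  60–600 um (the full grid `{60, 120, 240, 360, 480, 600}` in the
  acceptance script; the spot checks `{60, 240, 600}` in the test suite),
  10 rotation angles per resolution, 499 detector permutations, BH at
  0.05, unanimous-vote consensus across the rotations (the strict end of
  the voting trade-off, which is the package's designed operating mode);
  the minimum across resolutions is reported, with per-rotation means
  alongside.  Expected: TPR 1.00, PPV >= 0.95, TNR >= 0.99 — every pixel
  size stays below the pattern radius.
* Small-pattern benchmark: same pipeline at resolutions
  `{120, 240, 300, 360}`; power holds near 120 um, declines monotonically
  from 240 um and reaches zero at 360 um, where whole patterns aggregate
  into single pixels whose high and low expressing cells average out.
  The consensus matters here: at coarse resolutions a sub-pixel pattern
  that happens to straddle a pixel corner at one orientation can produce a
  burst of borderline calls at that orientation only; such bursts do not
  reproduce across rotations and the vote removes them.
* Co-enrichment: resolutions `{50, 100, 200}` um; B–C co-enriched at all
  three; A–B and A–C indistinguishable from independence at 50 um and
  significantly co-enriched at 100 and 200 um.
* Oracle suite: pmf, MLE and exact p-value checked against direct
  enumeration / likelihood maximization on every contingency table with
  `N <= 30` (44,515 tables), tolerance 1e-6.
* Null calibration: with zero injected effect the positive-call fraction
  averages below 0.06 over 20 seeds, and affinity p-values are
  super-uniform under 10,000 fixed-margin permutations.

## Numerical and degenerate-input policy

* All pmf/likelihood work in log space with log-sum-exp; the MLE root is
  bracketed, tolerance 1e-9.
* Moran's I of a constant vector is `NaN` (zero variance), never an error.
* Permutation ties count as exceedances (with a 1e-12 relative tolerance),
  keeping p-values conservative.
* k-NN ties are broken by index, making weight matrices deterministic.
* A point exactly on the grid's outer boundary belongs to the last pixel;
  a point outside the grid extent is an error, not a silent drop.
* Cells with explicitly missing (`NA`) labels are excluded from label
  rasterization on request (`na_action = "exclude"`, with a message) but
  always participate in expression rasterization.

## Limitations

* Resolution is a user hyperparameter; patterns smaller than a pixel are
  invisible by construction, so the resolution should be chosen below the
  scale of the biology of interest.
* The Moran's I detector is a deliberately simple, self-contained backend
  behind a narrow interface (statistic + p-value per feature on a raster);
  it favours broad coherent patterns and has limited power for patterns
  occupying a tiny fraction of the tissue.  Any external SVG tool can be
  substituted on the same rasters.
* Coordinates are assumed to share one frame; aligning sections is out of
  scope (joint rasterization assumes pre-aligned input).
* Rasterization is in-memory; larger-than-memory chunked backends are not
  provided.
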