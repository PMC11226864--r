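# spixel

Rasterization preprocessing for single-cell resolution spatial omics.

Imaging-based spatial omics assays (MERFISH, Xenium, CODEX, ...) deliver
gene-expression or protein measurements for 10^5–10^6 individual cells with
micrometre coordinates.  Most spatial statistics scale with the number of
spatial points and become impractical at that size.  `spixel` aggregates
cells into equally sized square or hexagonal pixels at a chosen resolution
— the mean of member cells' expression per pixel (so cell density is not a
confounder), or one-hot cell-type counts per pixel — and provides two
analyses built around rasterized data:

* **Spatially variable gene (SVG) detection.**  Per gene, Moran's I over
  row-standardized k-nearest-neighbour weights on pixel centroids,

      I = (p / S0) * (z' W z) / (z' z),

  with a one-sided permutation p-value
  `p = (1 + #{I_perm >= I_obs}) / (1 + n_perm)` and Benjamini–Hochberg
  control across genes.  Because pixel values near grid boundaries depend
  on where the boundaries fall, the dataset can be rasterized under
  several rotation angles and per-rotation calls combined by voting: a
  gene is a consensus SVG only if called in at least `required_votes`
  rotations, which suppresses grid-orientation artifacts.

* **Cell-type co-enrichment.**  Rasterized cell-type counts form a classic
  balls-in-boxes problem.  Per type and pixel, the relative enrichment
  `RE = observed / expected` (expected = pixel cell count x global type
  proportion) is binarized at a threshold (default `RE >= 1`), and each
  pair of types is summarized by the 2x2 table (N pixels, margins mA, mB,
  joint count X).  The affinity `alpha` is the log-odds parameter of the
  Fisher noncentral hypergeometric model,

      P(X = x | alpha)  ∝  C(mA, x) C(N - mA, mB - x) e^(alpha x),

  estimated by solving `E[X | alpha] = X_obs`; positive `alpha` means
  co-enrichment, negative means depletion, with a two-sided Fisher exact
  p-value and BH adjustment across pairs.  The rasterization resolution
  acts as the length scale at which co-occurrence is interrogated.

The package also ships simulators with ground truth — circular
high-expression SVG patterns of configurable radius among noise genes, and
a four-type nested arrangement (two types intermixed in cores, one in
surrounding annuli, one in the background) — used by the validation suite.

## Worked example

Simulate the small-bandwidth SVG benchmark (150 um circular patterns, 100
SVGs + 900 noise genes, 4992 cells on a 6 mm field), rasterize at 100 um
and test:

```r
library(spixel)

sim <- simulate_svg("small", seed = 7)
sim
#> svg_sim: 4992 points, 100 SVGs (radius 150 um) + 900 noise genes
#>   field 6000 x 6000 um, effect 5, baseline 0.5, seed 7

r <- rasterize_expression(sim$dataset, resolution = 100)
r
#> spatial_raster (expression): 1000 features x 2690 pixels
#>   square grid, resolution 100 um, rotation 0 deg, agg = mean
#>   4992 cells in 2690 occupied pixels (1.9 cells/pixel)

fit <- svg_test(r, n_perm = 499, seed = 7)
classification_metrics(fit$is_svg, sim$truth$is_svg)
#> TP=95 FP=7 TN=893 FN=5 | TPR=0.950 PPV=0.931 TNR=0.992
```

At 100 um pixels (below the 150 um pattern radius) the detector recovers
95% of the true SVGs at ~93% precision.  Coarsening to 360 um — more than
twice the pattern radius — averages the few high-expressing cells of each
circle with their low-expressing pixel-mates and the signal disappears;
with rotation voting (10 angles, unanimity) nothing is called:

```r
rasters <- permute_rasterize(sim$dataset, 360, n_angles = 10)
fits <- lapply(seq_along(rasters), function(i)
  svg_test(rasters[[i]], n_perm = 499, seed = 7000 + i))
cons <- vote_consensus(fits, required_votes = 10)
sum(cons$consensus_is_svg)
#> [1] 0
```

Cell-type co-enrichment across length scales, on the nested four-type
arrangement (B and C intermixed in 100 um cores, A in 100–300 um annuli,
D outside):

```r
aff <- coenrichment_benchmark(c(50, 200), seed = 1)
subset(aff, type_i == "A" & type_j == "B",
       c(resolution, X, alpha_hat, p_adjusted, significant))
#>   resolution  X alpha_hat p_adjusted significant
#> 1         50 26    -0.107   8.43e-01       FALSE
#> 7        200 16    10.000   2.46e-06        TRUE
```

At 50 um pixels the annulus type A and core type B rarely share a pixel
and their affinity is indistinguishable from independence; at 200 um a
pixel spans the whole structure and the pair is strongly co-enriched —
resolution selects the interaction length scale.

The CLI mirrors these steps (`inst/cli/spixel`):

```sh
spixel simulate svg --preset small --seed 7 --out sim/
spixel rasterize --coords sim/coords.csv --matrix sim/matrix.mtx \
       --resolution 100 --out raster/
spixel svg --raster raster/ --n-perm 499 --seed 7 --out svgs.csv
```

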