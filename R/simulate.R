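#' Simulate spatial expression data with circular SVG patterns
#'
#' Generates a synthetic single-cell resolution dataset for benchmarking
#' spatially-variable-gene detection: `n_points` cells placed uniformly on
#' a square field, `n_svg` spatially variable genes each carrying one
#' circular high-expression region (its own random center, fixed radius)
#' and `n_noise` genes with no spatial structure.  Counts are Poisson with
#' log-mean `log(baseline_mean) + effect_size` inside a gene's circle and
#' `log(baseline_mean)` outside, so the inside/outside mean ratio is
#' `exp(effect_size)`.  Circle centers are drawn so the circle lies fully
#' inside the field.
#'
#' The defaults (4992 points, 100 SVGs, 900 noise genes, radii of 1500, 750
#' or 150 um on a 6000 um field) match the benchmark conditions this
#' package's acceptance experiments use: pattern bandwidth is controlled by
#' `radius` while everything else stays fixed.
#'
#' @param radius circle radius in um, or a preset name: `"large"` (1500),
#'   `"medium"` (750), `"small"` (150).
#' @param n_points number of cells (default 4992).
#' @param n_svg,n_noise number of spatially variable / noise genes
#'   (defaults 100 and 900).
#' @param effect_size log-scale mean shift inside the circle (default 5).
#' @param baseline_mean Poisson mean per cell outside patterns
#'   (default 0.5).
#' @param field_size field side length in um (default 6000); `radius` must
#'   be below half of it.
#' @param seed integer seed; output is reproducible bit-for-bit.
#' @return List of class `svg_sim`: `dataset` (a [spatial_dataset()] with a
#'   sparse count matrix) and `truth` (data frame with per-gene `gene`,
#'   `is_svg`, circle `center_x`, `center_y`, `radius`).
#' @examples
#' sim <- simulate_svg("small", n_points = 500, n_svg = 5, n_noise = 20,
#'                     field_size = 2000, seed = 7)
#' sim$dataset
#' @export
simulate_svg <- function(radius = c("large", "medium", "small"),
                         n_points = 4992, n_svg = 100, n_noise = 900,
                         effect_size = 5, baseline_mean = 0.5,
                         field_size = 6000, seed = 1) {
  if (is.character(radius))
    radius <- switch(match.arg(radius), large = 1500, medium = 750,
                     small = 150)
  if (radius <= 0 || radius >= field_size / 2)
    stop("`radius` must be in (0, field_size / 2)")
  if (n_points < 1 || n_svg < 0 || n_noise < 0 || n_svg + n_noise < 1)
    stop("invalid gene/point counts")
  if (baseline_mean <= 0) stop("`baseline_mean` must be positive")
  set.seed(as.integer(seed %% .Machine$integer.max))

  xy <- cbind(x = runif(n_points, 0, field_size),
              y = runif(n_points, 0, field_size))
  f <- n_svg + n_noise
  genes <- c(sprintf("svg%03d", seq_len(n_svg)),
             sprintf("noise%03d", seq_len(n_noise)))

  centers <- cbind(runif(n_svg, radius, field_size - radius),
                   runif(n_svg, radius, field_size - radius))
  counts <- matrix(0L, f, n_points)
  if (n_svg > 0) {
    for (g in seq_len(n_svg)) {
      inside <- (xy[, 1] - centers[g, 1])^2 +
        (xy[, 2] - centers[g, 2])^2 <= radius^2
      lam <- baseline_mean * exp(effect_size * inside)
      counts[g, ] <- rpois(n_points, lam)
    }
  }
  if (n_noise > 0)
    counts[n_svg + seq_len(n_noise), ] <-
      rpois(n_noise * n_points, baseline_mean)
  rownames(counts) <- genes

  truth <- data.frame(
    gene = genes,
    is_svg = rep(c(TRUE, FALSE), c(n_svg, n_noise)),
    center_x = c(centers[, 1], rep(NA_real_, n_noise)),
    center_y = c(centers[, 2], rep(NA_real_, n_noise)),
    radius = c(rep(radius, n_svg), rep(NA_real_, n_noise)),
    stringsAsFactors = FALSE)

  structure(
    list(dataset = spatial_dataset(xy, Matrix::Matrix(counts, sparse = TRUE)),
         truth = truth,
         config = list(radius = radius, n_points = n_points, n_svg = n_svg,
                       n_noise = n_noise, effect_size = effect_size,
                       baseline_mean = baseline_mean,
                       field_size = field_size, seed = seed)),
    class = "svg_sim")
}

#' @export
print.svg_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "svg_sim: %d points, %d SVGs (radius %g um) + %d noise genes\n",
    cfg$n_points, cfg$n_svg, cfg$radius, cfg$n_noise))
  cat(sprintf("  field %g x %g um, effect %g, baseline %g, seed %d\n",
              cfg$field_size, cfg$field_size, cfg$effect_size,
              cfg$baseline_mean, cfg$seed))
  invisible(x)
}

#' Simulate a nested four-cell-type arrangement
#'
#' Generates a labels-only dataset mimicking cell-type co-localization at
#' two length scales: types B and C are uniformly intermixed inside
#' circles of radius `inner_radius`; type A surrounds them in annuli
#' (doughnuts) from `inner_radius` to `outer_radius`; type D fills the rest
#' of the field.  Pattern centers sit on a 2 x 2 layout by default and must
#' be at least `2 * outer_radius` apart.
#'
#' Cells are placed at one common spatial density everywhere (`density`,
#' cells per square um), so per-type counts default to being proportional
#' to the area each type occupies - as in a tissue of uniform cell density
#' partitioned into niches.  Pass `n_cells` (named vector for A, B, C, D)
#' to override the counts directly.
#'
#' @param inner_radius,outer_radius pattern radii in um (defaults 100 and
#'   300).
#' @param field_size field side length in um (default 1600).
#' @param centers optional k x 2 matrix of pattern centers; default is a
#'   2 x 2 layout at 1/4 and 3/4 of the field, jittered by
#'   `center_jitter` so the patterns sit in general position relative to
#'   any rasterization grid (tissue niches are never grid-aligned).
#' @param center_jitter uniform jitter half-width in um applied to the
#'   default center layout (default `inner_radius / 2`); ignored when
#'   `centers` is supplied.
#' @param density cells per square um (default 0.004, about one cell per
#'   16 um x 16 um).
#' @param n_cells optional named integer vector `c(A=, B=, C=, D=)`
#'   overriding the per-type counts.
#' @param seed integer seed.
#' @return A [spatial_dataset()] with labels `A`-`D` and no feature matrix.
#' @examples
#' ds <- simulate_celltypes(seed = 3)
#' table(ds$labels)
#' @export
simulate_celltypes <- function(inner_radius = 100, outer_radius = 300,
                               field_size = 1600, centers = NULL,
                               center_jitter = inner_radius / 2,
                               density = 0.004, n_cells = NULL, seed = 1) {
  if (inner_radius <= 0 || inner_radius >= outer_radius)
    stop("need 0 < inner_radius < outer_radius")
  set.seed(as.integer(seed %% .Machine$integer.max))
  if (is.null(centers)) {
    q <- field_size / 4
    centers <- cbind(c(q, 3 * q, q, 3 * q), c(q, q, 3 * q, 3 * q)) +
      matrix(runif(8, -center_jitter, center_jitter), 4, 2)
  }
  centers <- as.matrix(centers)
  if (nrow(centers) > 1) {
    dmin <- min(dist(centers))
    if (dmin < 2 * outer_radius)
      stop("centers too close: minimum spacing ", round(dmin, 1),
           " um < 2 * outer_radius")
  }
  if (any(centers < outer_radius) || any(centers > field_size - outer_radius))
    stop("outer circles must lie fully inside the field")
  k <- nrow(centers)
  a_inner <- k * pi * inner_radius^2
  a_ann <- k * pi * (outer_radius^2 - inner_radius^2)
  a_out <- field_size^2 - k * pi * outer_radius^2
  if (is.null(n_cells)) {
    n_cells <- c(A = round(density * a_ann),
                 B = round(density * a_inner / 2),
                 C = round(density * a_inner / 2),
                 D = round(density * a_out))
  } else {
    if (!all(c("A", "B", "C", "D") %in% names(n_cells)))
      stop("`n_cells` must be named with A, B, C, D")
    n_cells <- n_cells[c("A", "B", "C", "D")]
  }

  in_disk <- function(n, rmin, rmax) {
    # uniform in annulus/disk of chosen center
    ci <- sample.int(k, n, replace = TRUE)
    r <- sqrt(runif(n, rmin^2, rmax^2))
    th <- runif(n, 0, 2 * pi)
    cbind(centers[ci, 1] + r * cos(th), centers[ci, 2] + r * sin(th))
  }
  xyB <- in_disk(n_cells[["B"]], 0, inner_radius)
  xyC <- in_disk(n_cells[["C"]], 0, inner_radius)
  xyA <- in_disk(n_cells[["A"]], inner_radius, outer_radius)
  # D: uniform on the field outside all outer circles, by rejection
  xyD <- matrix(numeric(0), 0, 2)
  need <- n_cells[["D"]]
  while (nrow(xyD) < need) {
    m <- ceiling((need - nrow(xyD)) / max(1e-3, a_out / field_size^2)) + 16
    cand <- cbind(runif(m, 0, field_size), runif(m, 0, field_size))
    d2 <- vapply(seq_len(k), function(i)
      (cand[, 1] - centers[i, 1])^2 + (cand[, 2] - centers[i, 2])^2,
      numeric(m))
    ok <- rowSums(d2 < outer_radius^2) == 0
    xyD <- rbind(xyD, cand[ok, , drop = FALSE])
  }
  xyD <- xyD[seq_len(need), , drop = FALSE]

  xy <- rbind(xyA, xyB, xyC, xyD)
  labels <- rep(c("A", "B", "C", "D"),
                c(nrow(xyA), nrow(xyB), nrow(xyC), nrow(xyD)))
  ds <- spatial_dataset(xy, labels = labels)
  ds$sim_config <- list(inner_radius = inner_radius,
                        outer_radius = outer_radius,
                        field_size = field_size, centers = centers,
                        density = density, n_cells = n_cells, seed = seed)
  ds
}
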