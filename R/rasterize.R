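#' Rasterize expression values into pixels
#'
#' Aggregates the features x cells matrix of a [spatial_dataset()] into a
#' features x pixels matrix over a square or hexagonal grid.  The mean is
#' the default aggregation so that variability in cell density does not act
#' as a confounder in downstream analyses (a pixel full of cells uniformly
#' expressing a gene gets the same value as a sparse one); `sum` conserves
#' per-feature totals exactly and is available for count-style workflows.
#' Pixels containing no cells are dropped from the output.  Sparse input
#' matrices stay sparse.
#'
#' @param ds a [spatial_dataset()] with a `features` matrix.
#' @param resolution pixel size in um (square side length / hexagon
#'   edge-to-edge distance).
#' @param shape `"square"` (default) or `"hexagon"`.
#' @param agg aggregation function, `"mean"` (default) or `"sum"`.
#' @param grid optional pre-built [build_grid()] object, e.g. a shared grid
#'   across datasets or cell-type subsets; by default a grid is built on
#'   this dataset's bounding box.
#' @return Object of class `spatial_raster` with elements `values`
#'   (features x pixels), `pixel_centroids`, `pixel_cell_count`,
#'   `pixel_ids`, `agg`, `kind` and `provenance` (shape, resolution,
#'   rotation angle, cell count).
#' @examples
#' ds <- spatial_dataset(cbind(runif(200, 0, 500), runif(200, 0, 500)),
#'                       matrix(rpois(10 * 200, 2), 10, 200))
#' rx <- rasterize_expression(ds, resolution = 100)
#' rx
#' @export
rasterize_expression <- function(ds, resolution, shape = c("square", "hexagon"),
                                 agg = c("mean", "sum"), grid = NULL) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.null(ds$features))
    stop("dataset has no `features` matrix to rasterize")
  agg <- check_agg(agg)
  shape <- match.arg(shape)
  rasterize_matrix(ds$features, ds, resolution, shape, agg, grid,
                   kind = "expression")
}

check_agg <- function(agg) {
  if (length(agg) == 1L && !agg %in% c("mean", "sum"))
    stop("invalid parameter: `agg` must be \"mean\" or \"sum\"")
  match.arg(agg, c("mean", "sum"))
}

# shared aggregation path: values is features(or categories) x cells
rasterize_matrix <- function(values, ds, resolution, shape, agg, grid,
                             kind, keep = NULL) {
  coords <- ds$coords
  if (!is.null(keep)) {
    coords <- coords[keep, , drop = FALSE]
    values <- values[, keep, drop = FALSE]
  }
  if (is.null(grid)) grid <- build_grid(coords, resolution, shape)
  ids <- assign_pixels(coords, grid)
  occ <- order_pixel_ids(unique(ids))
  pix <- match(ids, occ)
  n <- nrow(coords)
  p <- length(occ)
  # cells x pixels membership indicator; aggregation is a sparse product,
  # so the result is independent of cell ordering by construction
  M <- Matrix::sparseMatrix(i = seq_len(n), j = pix, x = 1,
                            dims = c(n, p))
  cnt <- as.integer(Matrix::colSums(M))
  vals <- values %*% M
  if (agg == "mean")
    vals <- vals %*% Matrix::Diagonal(p, 1 / cnt)
  if (!is(values, "sparseMatrix")) {
    vals <- as.matrix(vals)
  } else {
    vals <- as(vals, "CsparseMatrix")
  }
  dimnames(vals) <- list(rownames(values), occ)
  structure(
    list(values = vals,
         pixel_centroids = grid_centroids(grid, occ),
         pixel_cell_count = cnt,
         pixel_ids = occ,
         agg = agg, kind = kind, grid = grid,
         provenance = list(shape = grid$shape, resolution = grid$resolution,
                           rotation_angle = 0, n_cells = n)),
    class = "spatial_raster")
}

#' Rasterize cell-type labels into per-pixel counts
#'
#' Converts categorical per-cell labels to a one-hot model matrix
#' (categories x cells) and aggregates it like a features-by-observations
#' matrix, by sums by default, giving the number of cells of each category
#' in each pixel.  Category order is the sorted unique label set.
#'
#' @inheritParams rasterize_expression
#' @param agg `"sum"` (default) or `"mean"` (per-pixel category fractions).
#' @param na_action what to do with cells whose label is `NA`: `"error"`
#'   (default) or `"exclude"`, which drops them from label rasterization
#'   with a message (they still count for expression rasterization).
#' @return `spatial_raster` of kind `"labels"`: `values[c, q]` is the count
#'   of cells of category `c` in pixel `q` (under `agg = "sum"`).
#' @export
rasterize_labels <- function(ds, resolution, shape = c("square", "hexagon"),
                             agg = c("sum", "mean"), grid = NULL,
                             na_action = c("error", "exclude")) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.null(ds$labels)) stop("dataset has no `labels`")
  na_action <- match.arg(na_action)
  if (length(agg) == 1L) check_agg(agg)
  agg <- match.arg(agg)
  shape <- match.arg(shape)
  keep <- NULL
  if (anyNA(ds$labels)) {
    if (na_action == "error")
      stop("labels contain NA; use na_action = \"exclude\" to drop ",
           "those cells from label rasterization")
    keep <- !is.na(ds$labels)
    message("excluding ", sum(!keep), " cells with missing labels")
  }
  lv <- sort(levels(droplevels(
    if (is.null(keep)) ds$labels else ds$labels[keep])))
  lab <- factor(as.character(ds$labels), levels = lv)
  onehot <- Matrix::sparseMatrix(
    i = as.integer(lab)[!is.na(lab)],
    j = which(!is.na(lab)),
    x = 1, dims = c(length(lv), ds$n_cells),
    dimnames = list(lv, ds$cell_ids))
  r <- rasterize_matrix(onehot, ds, resolution, shape, agg, grid,
                        kind = "labels", keep = keep)
  r
}

#' Rasterize expression for one cell-type subset
#'
#' Restricts to the cells carrying a given label before rasterization, e.g.
#' for cluster-specific spatially-variable-gene analysis.  By default the
#' grid is rebuilt on the subset's bounding box; pass `grid` to rasterize
#' several subsets onto one common frame.
#'
#' @inheritParams rasterize_expression
#' @param label_value a label occurring in `ds$labels`.
#' @export
rasterize_subset <- function(ds, label_value, resolution,
                             shape = c("square", "hexagon"),
                             agg = c("mean", "sum"), grid = NULL) {
  stopifnot(inherits(ds, "spatial_dataset"))
  if (is.null(ds$labels)) stop("dataset has no `labels`")
  keep <- !is.na(ds$labels) & ds$labels == label_value
  if (!any(keep))
    stop("unknown label: \"", label_value, "\" does not occur in the data")
  rasterize_expression(subset_dataset(ds, keep), resolution, shape, agg,
                       grid = grid)
}

#' Rasterize several datasets onto one shared grid
#'
#' Builds a single grid on the union bounding box of all datasets (already
#' in a common coordinate frame) and rasterizes each dataset onto it, so
#' that pixel ids and centroids are directly comparable across sections.  A
#' pixel may be occupied in one section and absent in another.
#'
#' @param datasets list of two or more [spatial_dataset()] objects.
#' @inheritParams rasterize_expression
#' @return List of `spatial_raster` objects sharing one grid.
#' @export
rasterize_joint <- function(datasets, resolution,
                            shape = c("square", "hexagon"),
                            agg = c("mean", "sum")) {
  if (!is.list(datasets) || length(datasets) < 2L)
    stop("`datasets` must be a list of at least two spatial_dataset objects")
  shape <- match.arg(shape)
  agg <- check_agg(agg)
  all_xy <- do.call(rbind, lapply(datasets, function(d) d$coords))
  grid <- build_grid(all_xy, resolution, shape)
  lapply(datasets, rasterize_expression, resolution = resolution,
         shape = shape, agg = agg, grid = grid)
}

#' @export
print.spatial_raster <- function(x, ...) {
  cat(sprintf("spatial_raster (%s): %d features x %d pixels\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat(sprintf("  %s grid, resolution %g um, rotation %g deg, agg = %s\n",
              x$provenance$shape, x$provenance$resolution,
              x$provenance$rotation_angle, x$agg))
  cat(sprintf("  %d cells in %d occupied pixels (%.1f cells/pixel)\n",
              x$provenance$n_cells, length(x$pixel_ids),
              x$provenance$n_cells / length(x$pixel_ids)))
  invisible(x)
}

#' @export
summary.spatial_raster <- function(object, ...) {
  print(object)
  cat("  cells per pixel:",
      paste(names(summary(object$pixel_cell_count)),
            signif(summary(object$pixel_cell_count), 3),
            sep = "=", collapse = " "), "\n")
  invisible(object)
}

#' Quick-look plot of a rasterized layer
#'
#' Debug helper: draws pixel centroids colored by one feature (or by total
#' signal) using filled squares.
#'
#' @param x a `spatial_raster`.
#' @param feature feature name or index; default sums over all features.
#' @param ... passed to [graphics::plot()].
#' @export
plot.spatial_raster <- function(x, feature = NULL, ...) {
  v <- if (is.null(feature)) Matrix::colSums(x$values) else
    as.numeric(x$values[feature, ])
  pal <- hcl.colors(64, "Viridis")
  idx <- pmin(64L, 1L + as.integer(63 * (v - min(v)) /
                                     max(1e-12, diff(range(v)))))
  plot(x$pixel_centroids, col = pal[idx], pch = 15,
       cex = 0.9, asp = 1, xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}
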