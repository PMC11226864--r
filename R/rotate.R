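#' Rotate coordinates about a center
#'
#' Standard 2-D rotation.  Rotation is an isometry: pairwise distances are
#' preserved (up to floating-point error), so rotating a dataset before
#' rasterization changes only how the grid cuts through it.
#'
#' @param coords numeric n x 2 matrix.
#' @param angle_degrees rotation angle, counter-clockwise, in degrees.
#' @param center length-2 rotation center; defaults to the bounding-box
#'   centroid of `coords`, which keeps the rotated cloud compact.
#' @return Rotated n x 2 matrix.
#' @export
rotate_coords <- function(coords, angle_degrees, center = NULL) {
  coords <- as.matrix(coords)
  if (is.null(center))
    center <- c(mean(range(coords[, 1])), mean(range(coords[, 2])))
  th <- angle_degrees * pi / 180
  # row-vector convention: (x, y) %*% R rotates counter-clockwise
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  out <- sweep(coords, 2, center) %*% R
  out <- sweep(out, 2, center, "+")
  dimnames(out) <- dimnames(coords)
  out
}

#' Evenly spaced rotation angles for grid-permutation
#'
#' Returns `n_angles` rotation angles evenly spaced over one rotational
#' symmetry period of the grid: `[0, 90)` degrees for square grids and
#' `[0, 60)` degrees for hexagonal grids.  Angles beyond the symmetry
#' period would duplicate tilings, so the range is capped there.
#'
#' @param n_angles number of angles (>= 1).
#' @param shape `"square"` or `"hexagon"`.
#' @return Numeric vector of angles in degrees, starting at 0.
#' @examples
#' make_angles(10, "square")  # 0, 9, ..., 81
#' @export
make_angles <- function(n_angles, shape = c("square", "hexagon")) {
  shape <- match.arg(shape)
  if (!is.numeric(n_angles) || n_angles < 1)
    stop("`n_angles` must be >= 1")
  sym <- if (shape == "square") 90 else 60
  (seq_len(n_angles) - 1) * sym / n_angles
}

#' Rasterize a dataset under several rotation angles
#'
#' Rasterized values can be sensitive to edge effects from where exactly the
#' grid boundaries fall.  This permutation scheme controls for that by
#' rotating the dataset (about its bounding-box centroid) at several angles
#' before rasterization; downstream per-angle results can then be combined,
#' e.g. with [vote_consensus()].  The grid itself stays axis-aligned and is
#' rebuilt on each rotated cloud's bounding box, which is geometrically
#' equivalent to rotating the grid.
#'
#' @inheritParams rasterize_expression
#' @param n_angles number of evenly spaced rotation angles (see
#'   [make_angles()]).
#' @param kind rasterize the `"expression"` matrix (default) or `"labels"`.
#' @return List of `spatial_raster`, one per angle, each recording its
#'   rotation angle in `provenance`.
#' @export
permute_rasterize <- function(ds, resolution, shape = c("square", "hexagon"),
                              agg = c("mean", "sum"), n_angles = 10,
                              kind = c("expression", "labels")) {
  stopifnot(inherits(ds, "spatial_dataset"))
  shape <- match.arg(shape)
  kind <- match.arg(kind)
  agg <- if (kind == "expression") check_agg(agg) else
    match.arg(agg, c("sum", "mean"))
  angles <- make_angles(n_angles, shape)
  center <- c(mean(range(ds$coords[, 1])), mean(range(ds$coords[, 2])))
  lapply(angles, function(a) {
    rds <- ds
    rds$coords <- rotate_coords(ds$coords, a, center)
    r <- if (kind == "expression")
      rasterize_expression(rds, resolution, shape, agg)
    else rasterize_labels(rds, resolution, shape, agg)
    r$provenance$rotation_angle <- a
    r
  })
}
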