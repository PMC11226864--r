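#' Build a pixel grid over a set of coordinates
#'
#' Constructs a square or hexagonal tessellation that spans the bounding box
#' of the input coordinates.  The grid is anchored at the lower-left corner
#' of the bounding box (`origin = (min x, min y)`), which makes grids
#' deterministic for identical inputs without any extra state.
#'
#' `resolution` follows the pixel-size convention used throughout the
#' package: the side length for square pixels and the distance between
#' opposite edges (twice the apothem) for hexagonal pixels, so that finer
#' resolution means smaller pixels.  Hexagons are flat-topped, with a
#' hexagon centroid placed at the origin.
#'
#' @param coords numeric n x 2 matrix of (x, y) positions in um.
#' @param resolution positive pixel size in um (see Details).
#' @param shape `"square"` or `"hexagon"`.
#' @return An object of class `pixel_grid`.
#' @examples
#' g <- build_grid(cbind(c(0, 100), c(0, 100)), 50, "square")
#' grid_centroids(g)
#' @seealso [assign_pixels()], [grid_centroids()]
#' @export
build_grid <- function(coords, resolution, shape = c("square", "hexagon")) {
  shape <- match.arg(shape)
  coords <- as.matrix(coords)
  if (nrow(coords) == 0L) stop("empty input: no coordinates to grid")
  if (!is.numeric(resolution) || length(resolution) != 1L ||
      !is.finite(resolution) || resolution <= 0)
    stop("invalid parameter: `resolution` must be a positive number")
  origin <- c(min(coords[, 1]), min(coords[, 2]))
  extent <- c(xmin = origin[1], xmax = max(coords[, 1]),
              ymin = origin[2], ymax = max(coords[, 2]))
  g <- list(shape = shape, resolution = resolution, origin = origin,
            extent = extent)
  if (shape == "square") {
    span <- c(extent["xmax"] - origin[1], extent["ymax"] - origin[2])
    # at least one pixel per axis even for degenerate (point/line) input
    g$nx <- max(1L, as.integer(ceiling(span[1] / resolution - 1e-9)))
    g$ny <- max(1L, as.integer(ceiling(span[2] / resolution - 1e-9)))
  } else {
    g$hex_size <- resolution / sqrt(3) # circumradius of flat-top hexagon
  }
  class(g) <- "pixel_grid"
  g
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf("pixel_grid: %s, resolution %g um, origin (%.2f, %.2f)\n",
              x$shape, x$resolution, x$origin[1], x$origin[2]))
  if (x$shape == "square")
    cat("  candidate pixels:", x$nx, "x", x$ny, "\n")
  invisible(x)
}

#' Assign coordinates to pixels
#'
#' Maps each point to exactly one pixel of a grid.  Square grids use
#' half-open `[lo, hi)` intervals per axis with the global maximum edge
#' closed (so points exactly on the outer boundary fall in the last pixel,
#' not a new one).  Hexagonal grids assign each point to the nearest hexagon
#' centroid via axial-coordinate (cube) rounding, which is deterministic for
#' boundary points.
#'
#' @param coords numeric n x 2 matrix of (x, y) positions in um.
#' @param grid a [build_grid()] object covering the coordinates.
#' @return Character vector of pixel ids (`"i_j"` integer grid indices for
#'   squares, axial `"q_r"` indices for hexagons).
#' @export
assign_pixels <- function(coords, grid) {
  stopifnot(inherits(grid, "pixel_grid"))
  coords <- as.matrix(coords)
  res <- grid$resolution
  x <- coords[, 1] - grid$origin[1]
  y <- coords[, 2] - grid$origin[2]
  if (grid$shape == "square") {
    tol <- 1e-9 * max(1, res)
    if (any(x < -tol | y < -tol | x > grid$nx * res + tol |
            y > grid$ny * res + tol))
      stop("out of bounds: coordinates outside the grid extent")
    i <- pmin(grid$nx - 1L, pmax(0L, floor(x / res)))
    j <- pmin(grid$ny - 1L, pmax(0L, floor(y / res)))
    paste0(i, "_", j)
  } else {
    s <- grid$hex_size
    pad <- 2 * s + 1e-9 * max(1, res)
    if (any(x < -pad | y < -pad |
            x > (grid$extent["xmax"] - grid$origin[1]) + pad |
            y > (grid$extent["ymax"] - grid$origin[2]) + pad))
      stop("out of bounds: coordinates outside the grid extent")
    qf <- (2 / 3) * x / s
    rf <- (-x / 3 + sqrt(3) / 3 * y) / s
    ax <- hex_round(qf, rf)
    paste0(ax$q, "_", ax$r)
  }
}

# cube rounding of fractional axial coordinates (q, r); deterministic
hex_round <- function(qf, rf) {
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fix_x <- dx > dy & dx > dz
  fix_y <- !fix_x & dy > dz
  fix_z <- !fix_x & !fix_y
  rx[fix_x] <- -ry[fix_x] - rz[fix_x]
  ry[fix_y] <- -rx[fix_y] - rz[fix_y]
  rz[fix_z] <- -rx[fix_z] - ry[fix_z]
  list(q = as.integer(rx), r = as.integer(rz))
}

#' Centroids of grid pixels
#'
#' @param grid a [build_grid()] object.
#' @param ids optional character vector of pixel ids; when omitted, all
#'   candidate pixels intersecting the bounding box are enumerated.
#' @return Matrix with columns `x`, `y` (um), rownames = pixel ids.
#' @export
grid_centroids <- function(grid, ids = NULL) {
  stopifnot(inherits(grid, "pixel_grid"))
  res <- grid$resolution
  if (is.null(ids)) {
    if (grid$shape == "square") {
      ij <- expand.grid(i = 0:(grid$nx - 1L), j = 0:(grid$ny - 1L))
      ids <- paste0(ij$i, "_", ij$j)
    } else {
      s <- grid$hex_size
      w <- grid$extent["xmax"] - grid$origin[1]
      h <- grid$extent["ymax"] - grid$origin[2]
      qr <- -1L + 0:(as.integer(ceiling(w / (1.5 * s))) + 2L)
      ids <- unlist(lapply(qr, function(q) {
        rr <- as.integer(floor(-q / 2 - 1)):
          as.integer(ceiling(h / (s * sqrt(3)) - q / 2 + 1))
        paste0(q, "_", rr)
      }))
      cen <- hex_centroid(ids, grid)
      keep <- cen[, 1] >= grid$origin[1] - res / 2 &
        cen[, 1] <= grid$extent["xmax"] + res / 2 &
        cen[, 2] >= grid$origin[2] - res / 2 &
        cen[, 2] <= grid$extent["ymax"] + res / 2
      ids <- ids[keep]
    }
  }
  out <- if (grid$shape == "square") {
    ij <- id_to_pair(ids)
    cbind(x = grid$origin[1] + (ij[, 1] + 0.5) * res,
          y = grid$origin[2] + (ij[, 2] + 0.5) * res)
  } else hex_centroid(ids, grid)
  rownames(out) <- ids
  out
}

hex_centroid <- function(ids, grid) {
  qr <- id_to_pair(ids)
  s <- grid$hex_size
  cbind(x = grid$origin[1] + s * 1.5 * qr[, 1],
        y = grid$origin[2] + s * sqrt(3) * (qr[, 2] + qr[, 1] / 2))
}

id_to_pair <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  matrix(as.integer(unlist(parts)), ncol = 2, byrow = TRUE)
}

# deterministic ordering of pixel ids: by second index, then first
order_pixel_ids <- function(ids) {
  pr <- id_to_pair(ids)
  ids[order(pr[, 2], pr[, 1])]
}
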