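#' Assemble a single-cell resolution spatial dataset
#'
#' Bundles per-cell spatial coordinates (in micrometres) with an optional
#' features-by-cells measurement matrix and optional categorical per-cell
#' labels (cell types or clusters).  This is the common input container for
#' all rasterization functions.
#'
#' @param coords numeric matrix or data frame with `n` rows and 2 columns
#'   (x, y positions in um).  Must be finite.
#' @param features optional features x cells non-negative matrix (dense
#'   `matrix` or any `Matrix` sparse class; sparse input is kept sparse).
#' @param feature_names optional character vector of feature (gene) names;
#'   defaults to the rownames of `features` or `gene1..geneF`.
#' @param cell_ids optional character vector of cell identifiers; defaults
#'   to rownames of `coords` or `cell1..cellN`.
#' @param labels optional per-cell categorical labels (character or factor,
#'   length `n`).  `NA` marks cells with explicitly missing labels; such
#'   cells can be excluded from label rasterization (see
#'   [rasterize_labels()]) but still contribute to expression rasterization.
#'
#' @return An object of class `spatial_dataset` with elements `coords`,
#'   `features`, `feature_names`, `cell_ids`, `labels`, `n_cells`.
#' @examples
#' xy <- cbind(runif(50, 0, 100), runif(50, 0, 100))
#' expr <- matrix(rpois(5 * 50, 1), 5, 50)
#' ds <- spatial_dataset(xy, expr, labels = sample(c("A", "B"), 50, TRUE))
#' ds
#' @export
spatial_dataset <- function(coords, features = NULL, feature_names = NULL,
                            cell_ids = NULL, labels = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 2L)
    stop("`coords` must be a numeric n x 2 matrix of (x, y) positions")
  n <- nrow(coords)
  if (n < 1L) stop("empty input: need at least one cell")
  if (!all(is.finite(coords))) stop("`coords` must be finite")
  colnames(coords) <- c("x", "y")

  if (is.null(cell_ids)) {
    cell_ids <- rownames(coords)
    if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(n))
  }
  cell_ids <- as.character(cell_ids)
  if (length(cell_ids) != n) stop("`cell_ids` must have one entry per cell")
  if (anyDuplicated(cell_ids)) stop("`cell_ids` must be unique")
  rownames(coords) <- cell_ids

  if (!is.null(features)) {
    if (is.data.frame(features)) features <- as.matrix(features)
    if (!is(features, "Matrix") && !is.matrix(features))
      stop("`features` must be a matrix or Matrix")
    if (ncol(features) != n)
      stop("`features` must be features x cells (", n, " columns)")
    if (min0(features) < 0) stop("`features` has negative entries")
    if (is.null(feature_names)) {
      feature_names <- rownames(features)
      if (is.null(feature_names))
        feature_names <- paste0("gene", seq_len(nrow(features)))
    }
    if (length(feature_names) != nrow(features))
      stop("`feature_names` length must match nrow(features)")
    rownames(features) <- feature_names
    colnames(features) <- cell_ids
  }

  if (!is.null(labels)) {
    if (length(labels) != n) stop("`labels` must have one value per cell")
    labels <- if (is.factor(labels)) factor(labels) else
      factor(as.character(labels))
    names(labels) <- cell_ids
  }

  structure(
    list(coords = coords, features = features,
         feature_names = feature_names, cell_ids = cell_ids,
         labels = labels, n_cells = n),
    class = "spatial_dataset")
}

# minimum that works for both base and Matrix classes without densifying
min0 <- function(m) {
  if (is(m, "sparseMatrix")) {
    x <- m@x
    if (length(x) == 0L) 0 else min(0, min(x))
  } else min(m)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset:", x$n_cells, "cells\n")
  bb <- apply(x$coords, 2, range)
  cat(sprintf("  extent: x [%.1f, %.1f] um, y [%.1f, %.1f] um\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2]))
  if (!is.null(x$features))
    cat("  features:", nrow(x$features), "x", ncol(x$features),
        if (is(x$features, "sparseMatrix")) "(sparse)\n" else "(dense)\n")
  if (!is.null(x$labels)) {
    tb <- table(x$labels, useNA = "ifany")
    cat("  labels:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.spatial_dataset <- function(x, color_by = c("label", "none"), cex = 0.3,
                                 ...) {
  color_by <- match.arg(color_by)
  col <- "grey30"
  if (color_by == "label" && !is.null(x$labels)) {
    pal <- hcl.colors(max(2L, nlevels(x$labels)), "Dark 3")
    col <- pal[as.integer(x$labels)]
  }
  plot(x$coords, col = col, pch = 16, cex = cex, asp = 1,
       xlab = "x (um)", ylab = "y (um)", ...)
  invisible(x)
}

subset_dataset <- function(ds, keep) {
  spatial_dataset(ds$coords[keep, , drop = FALSE],
                  if (!is.null(ds$features)) ds$features[, keep, drop = FALSE],
                  feature_names = ds$feature_names,
                  cell_ids = ds$cell_ids[keep],
                  labels = if (!is.null(ds$labels)) ds$labels[keep])
}
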