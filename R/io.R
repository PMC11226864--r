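#' Read a spatial dataset from standard files
#'
#' Loads per-cell coordinates (CSV/TSV with header `cell_id, x, y`), an
#' optional expression matrix - either MatrixMarket `.mtx` with `features`
#' and `cells` index files, or a dense CSV with feature names in the first
#' column and cell ids in the header - and optional labels (CSV with
#' header `cell_id, label`).  Matrix orientation for `.mtx` input is
#' auto-detected from the index file lengths and transposed to
#' features x cells when needed.  Cell ids must agree across files.
#'
#' @param coords_path coordinates file.
#' @param matrix_path optional `.mtx` or dense CSV expression matrix.
#' @param features_path,cells_path index files for `.mtx` input (default:
#'   `features.tsv` / `cells.tsv` next to the matrix).
#' @param labels_path optional labels file.
#' @return A [spatial_dataset()].
#' @export
read_dataset <- function(coords_path, matrix_path = NULL,
                         features_path = NULL, cells_path = NULL,
                         labels_path = NULL) {
  co <- read_table_auto(coords_path)
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(co)))
    stop("coordinates file must have columns: ", paste(need, collapse = ", "))
  cell_ids <- as.character(co$cell_id)
  coords <- cbind(x = as.numeric(co$x), y = as.numeric(co$y))

  features <- NULL; feature_names <- NULL
  if (!is.null(matrix_path)) {
    if (grepl("\\.mtx$", matrix_path)) {
      if (is.null(features_path))
        features_path <- file.path(dirname(matrix_path), "features.tsv")
      if (is.null(cells_path))
        cells_path <- file.path(dirname(matrix_path), "cells.tsv")
      feature_names <- readLines(features_path)
      mat_cells <- readLines(cells_path)
      m <- as(Matrix::readMM(matrix_path), "CsparseMatrix")
      if (nrow(m) == length(feature_names) &&
          ncol(m) == length(mat_cells)) {
        # features x cells already
      } else if (nrow(m) == length(mat_cells) &&
                 ncol(m) == length(feature_names)) {
        m <- Matrix::t(m)
      } else {
        stop("malformed MTX: dimensions match neither orientation of the ",
             "index files")
      }
      if (!setequal(mat_cells, cell_ids))
        stop("cell ids in matrix and coordinates files disagree")
      features <- m[, match(cell_ids, mat_cells), drop = FALSE]
    } else {
      d <- read_table_auto(matrix_path)
      feature_names <- as.character(d[[1]])
      features <- as.matrix(d[, -1, drop = FALSE])
      if (!setequal(colnames(features), cell_ids))
        stop("cell ids in matrix and coordinates files disagree")
      features <- features[, match(cell_ids, colnames(features)),
                           drop = FALSE]
    }
    if (min0(features) < 0) stop("expression matrix has negative values")
  }

  labels <- NULL
  if (!is.null(labels_path)) {
    if (!file.exists(labels_path))
      stop("labels file not found: ", labels_path)
    lb <- read_table_auto(labels_path)
    if (!all(c("cell_id", "label") %in% names(lb)))
      stop("labels file must have columns: cell_id, label")
    idx <- match(cell_ids, as.character(lb$cell_id))
    if (anyNA(idx))
      stop("labels file is missing entries for some cells")
    labels <- as.character(lb$label)[idx]
  }
  spatial_dataset(coords, features, feature_names = feature_names,
                  cell_ids = cell_ids, labels = labels)
}

read_table_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(tsv|txt)$", path)) read.delim(path, check.names = FALSE)
  else read.csv(path, check.names = FALSE)
}

#' Write a spatial dataset in the standard layout
#'
#' Writes `coords.csv`, `matrix.mtx` + `features.tsv` + `cells.tsv` (when a
#' feature matrix is present) and `labels.csv` (when labels are present)
#' into a directory.  [read_dataset()] round-trips the result losslessly.
#'
#' @param ds a [spatial_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "spatial_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(cell_id = ds$cell_ids, x = ds$coords[, 1],
                       y = ds$coords[, 2]),
            file.path(dir, "coords.csv"), row.names = FALSE)
  if (!is.null(ds$features)) {
    Matrix::writeMM(as(as(ds$features, "CsparseMatrix"), "generalMatrix"),
                    file.path(dir, "matrix.mtx"))
    writeLines(rownames(ds$features), file.path(dir, "features.tsv"))
    writeLines(ds$cell_ids, file.path(dir, "cells.tsv"))
  }
  if (!is.null(ds$labels))
    write.csv(data.frame(cell_id = ds$cell_ids,
                         label = as.character(ds$labels)),
              file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a raster in the standard layout
#'
#' Writes `pixels.csv` (pixel id, centroid, cell count), `matrix.mtx`,
#' `features.tsv`, `pixels.tsv` and `provenance.json` (shape, resolution,
#' rotation angle, aggregation) to a directory.  Values round-trip at full
#' double precision; sum-aggregated integer matrices round-trip as exact
#' integers.
#'
#' @param r a `spatial_raster`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_raster <- function(r, dir) {
  stopifnot(inherits(r, "spatial_raster"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(pixel_id = r$pixel_ids,
                       centroid_x = r$pixel_centroids[, 1],
                       centroid_y = r$pixel_centroids[, 2],
                       cell_count = r$pixel_cell_count),
            file.path(dir, "pixels.csv"), row.names = FALSE)
  Matrix::writeMM(as(as(r$values, "CsparseMatrix"), "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(r$values), file.path(dir, "features.tsv"))
  writeLines(r$pixel_ids, file.path(dir, "pixels.tsv"))
  prov <- c(r$provenance, list(agg = r$agg, kind = r$kind))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read back a raster written by [write_raster()]
#'
#' @param dir directory containing the standard raster layout.
#' @return A `spatial_raster`.
#' @export
read_raster <- function(dir) {
  px <- read.csv(file.path(dir, "pixels.csv"))
  vals <- as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  dimnames(vals) <- list(readLines(file.path(dir, "features.tsv")),
                         readLines(file.path(dir, "pixels.tsv")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"),
                              simplifyVector = TRUE)
  cen <- cbind(x = px$centroid_x, y = px$centroid_y)
  rownames(cen) <- px$pixel_id
  structure(
    list(values = vals, pixel_centroids = cen,
         pixel_cell_count = as.integer(px$cell_count),
         pixel_ids = as.character(px$pixel_id),
         agg = prov$agg, kind = prov$kind, grid = NULL,
         provenance = prov[c("shape", "resolution", "rotation_angle",
                             "n_cells")]),
    class = "spatial_raster")
}
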