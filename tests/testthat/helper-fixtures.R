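# small in-code fixtures shared across test files

random_dataset <- function(n = 200, f = 12, side = 500, seed = 1,
                           labels = NULL, sparse = FALSE) {
  set.seed(seed)
  xy <- cbind(runif(n, 0, side), runif(n, 0, side))
  feats <- matrix(rpois(f * n, 2), f, n)
  if (sparse) feats <- Matrix::Matrix(feats, sparse = TRUE)
  spatial_dataset(xy, feats, labels = labels)
}

# brute-force square-pixel containment: scan every candidate rectangle
brute_square_assign <- function(coords, grid) {
  res <- grid$resolution
  x0 <- grid$origin[1]; y0 <- grid$origin[2]
  vapply(seq_len(nrow(coords)), function(r) {
    x <- coords[r, 1]; y <- coords[r, 2]
    hit <- NA_character_
    for (i in 0:(grid$nx - 1L)) for (j in 0:(grid$ny - 1L)) {
      in_x <- x >= x0 + i * res &
        (x < x0 + (i + 1) * res || i == grid$nx - 1L)
      in_y <- y >= y0 + j * res &
        (y < y0 + (j + 1) * res || j == grid$ny - 1L)
      if (in_x && in_y) { hit <- paste0(i, "_", j); break }
    }
    hit
  }, character(1))
}

# brute-force hexagon containment: nearest centroid over a generous
# candidate lattice (hexagonal tessellation = Voronoi of its centroids)
brute_hex_assign <- function(coords, grid) {
  s <- grid$hex_size
  w <- grid$extent["xmax"] - grid$origin[1]
  h <- grid$extent["ymax"] - grid$origin[2]
  qs <- (-3L):(as.integer(ceiling(w / (1.5 * s))) + 3L)
  cand <- do.call(rbind, lapply(qs, function(q) {
    rs <- (as.integer(floor(-q / 2 - h / (s * sqrt(3)) - 3))):
      (as.integer(ceiling(h / (s * sqrt(3)) - q / 2 + 3)))
    cbind(q, rs)
  }))
  cx <- grid$origin[1] + s * 1.5 * cand[, 1]
  cy <- grid$origin[2] + s * sqrt(3) * (cand[, 2] + cand[, 1] / 2)
  vapply(seq_len(nrow(coords)), function(r) {
    d2 <- (cx - coords[r, 1])^2 + (cy - coords[r, 2])^2
    k <- which.min(d2)
    paste0(cand[k, 1], "_", cand[k, 2])
  }, character(1))
}

# dense group-by recomputation of rasterized values
brute_aggregate <- function(features, pix, agg) {
  features <- as.matrix(features)
  ids <- sort(unique(pix))
  out <- sapply(ids, function(q) {
    cols <- features[, pix == q, drop = FALSE]
    if (agg == "sum") rowSums(cols) else rowMeans(cols)
  })
  colnames(out) <- ids
  out
}
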