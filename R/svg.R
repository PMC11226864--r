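#' Moran's I spatial autocorrelation statistic
#'
#' Computes Moran's I of one value vector under a supplied spatial weight
#' matrix: `I = (n / S0) * (z' W z) / (z' z)` with `z` the centered values
#' and `S0` the sum of all weights.  With row-standardized weights and a
#' zero diagonal (as produced by [knn_weights()]), I close to 1 indicates
#' coherent spatial structure, values near `-1/(n-1)` indicate none, and a
#' perfect checkerboard under rook adjacency reaches -1.
#'
#' @param values numeric vector of length p (one value per location).
#' @param weights p x p non-negative spatial weight matrix (dense or
#'   sparse), conventionally row-standardized with zero diagonal.
#' @return Moran's I, or `NaN` for constant input.
#' @export
morans_i <- function(values, weights) {
  p <- length(values)
  if (p < 3L) stop("need at least 3 locations")
  if (nrow(weights) != p || ncol(weights) != p)
    stop("dimension mismatch between `values` and `weights`")
  z <- values - mean(values)
  den <- sum(z^2)
  if (den == 0) return(NaN)
  s0 <- sum(weights)
  num <- as.numeric(z %*% (weights %*% z))
  (p / s0) * num / den
}

#' k-nearest-neighbour spatial weights
#'
#' Row-standardized k-NN weight matrix over point locations: each location
#' gets weight `1/k` on its `k` nearest neighbours (Euclidean distance, ties
#' broken by index for determinism), zero elsewhere and on the diagonal.
#' Distances are computed block-wise so no full p x p distance matrix is
#' ever held.
#'
#' @param centroids p x 2 matrix of locations.
#' @param k number of neighbours, `1 <= k < p`.
#' @return Sparse `dgCMatrix` of weights.
#' @export
knn_weights <- function(centroids, k = 6) {
  centroids <- as.matrix(centroids)
  p <- nrow(centroids)
  if (k < 1 || k >= p) stop("need 1 <= k < number of locations")
  block <- max(1L, min(p, as.integer(2e7 / p)))
  nn <- matrix(0L, p, k)
  d2all <- rowSums(centroids^2)
  for (start in seq(1L, p, by = block)) {
    idx <- start:min(p, start + block - 1L)
    # squared distances block x p
    d2 <- outer(d2all[idx], d2all, "+") -
      2 * tcrossprod(centroids[idx, , drop = FALSE], centroids)
    for (r in seq_along(idx)) {
      d <- d2[r, ]
      d[idx[r]] <- Inf
      nn[idx[r], ] <- order(d)[seq_len(k)]
    }
  }
  Matrix::sparseMatrix(i = rep(seq_len(p), each = k), j = as.vector(t(nn)),
                       x = 1 / k, dims = c(p, p))
}

#' Permutation test for spatially variable genes on a raster
#'
#' Scores every feature of a rasterized dataset with Moran's I over
#' row-standardized k-nearest-neighbour weights on the pixel centroids, and
#' attaches a one-sided permutation p-value for positive spatial
#' autocorrelation: `p = (1 + #{I_perm >= I_obs}) / (1 + n_perm)`, with the
#' same `n_perm` random relabelings of pixels shared across features.
#' P-values are Benjamini-Hochberg adjusted across features and a feature
#' is called spatially variable when its adjusted p-value is at most `fdr`.
#' Mean-aggregated expression is log1p-transformed before testing by
#' default; constant features get a `NaN` statistic and are never called.
#'
#' @param raster a `spatial_raster` (kind `"expression"`).
#' @param k_neighbors neighbours for the weight matrix (default 6).
#' @param n_perm number of permutations (>= 99; default 999).  The smallest
#'   attainable p-value is `1/(1 + n_perm)`.
#' @param fdr adjusted-p-value call threshold (default 0.05).
#' @param seed integer seed; results are deterministic given the seed.
#' @param normalize log1p-transform mean-aggregated values first (default
#'   `TRUE`); set `FALSE` to test raw values.
#' @return Data frame of class `svg_result`, one row per feature:
#'   `gene`, `statistic` (Moran's I), `p_value`, `p_adjusted`, `is_svg`,
#'   `rank` (1 = strongest statistic).
#' @export
svg_test <- function(raster, k_neighbors = 6, n_perm = 999, fdr = 0.05,
                     seed = 1, normalize = TRUE) {
  stopifnot(inherits(raster, "spatial_raster"))
  p <- length(raster$pixel_ids)
  if (p <= k_neighbors + 1)
    stop("raster has too few pixels (", p, ") for k = ", k_neighbors)
  if (n_perm < 99) stop("`n_perm` must be at least 99")
  vals <- as.matrix(raster$values)
  if (normalize && raster$agg == "mean") vals <- log1p(vals)
  f <- nrow(vals)
  genes <- rownames(vals)
  if (is.null(genes)) genes <- paste0("gene", seq_len(f))

  W <- knn_weights(raster$pixel_centroids, k_neighbors)
  Zt <- vals - rowMeans(vals)       # center each feature across pixels
  den <- rowSums(Zt^2)
  const <- den <= 1e-12 * pmax(1, rowSums(vals^2))

  set.seed(as.integer(seed %% .Machine$integer.max))
  perms <- vapply(seq_len(n_perm), function(i) sample.int(p) - 1L,
                  integer(p))
  res <- moran_perm_exceed(W, Zt, perms)
  stat <- ifelse(const, NaN, res$obs_num / den)
  pval <- ifelse(const, NA_real_, (1 + res$exceed) / (1 + n_perm))
  padj <- rep(NA_real_, f)
  padj[!const] <- p.adjust(pval[!const], method = "BH")
  is_svg <- !is.na(padj) & padj <= fdr
  # ranks: descending statistic, NaN (constant) features last, ties by order
  rk <- integer(f)
  rk[order(-ifelse(is.nan(stat), -Inf, stat), seq_len(f))] <- seq_len(f)

  structure(
    data.frame(gene = genes, statistic = stat, p_value = pval,
               p_adjusted = padj, is_svg = is_svg, rank = rk,
               row.names = genes, stringsAsFactors = FALSE),
    class = c("svg_result", "data.frame"),
    k_neighbors = k_neighbors, n_perm = n_perm, fdr = fdr, seed = seed,
    n_pixels = p)
}

#' @export
print.svg_result <- function(x, ...) {
  cat(sprintf(
    "svg_result: %d features on %d pixels (k = %d, %d permutations)\n",
    nrow(x), attr(x, "n_pixels"), attr(x, "k_neighbors"), attr(x, "n_perm")))
  cat(sprintf("  %d called spatially variable at FDR %.3g\n",
              sum(x$is_svg), attr(x, "fdr")))
  print.data.frame(head(x[order(x$rank), ], 5))
  if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more features\n")
  invisible(x)
}

#' Consensus voting across rotation permutations
#'
#' Combines spatially-variable calls from several rotation-permuted runs:
#' a feature's votes are the number of runs in which it was called, and the
#' consensus call requires at least `required_votes` of them.  Raising the
#' required votes can only remove positives (calls are monotone in the
#' threshold), which suppresses grid-orientation artifacts that are not
#' reproduced across rotations.
#'
#' @param results list of [svg_test()] results over the same feature set.
#' @param required_votes minimum number of runs calling a feature
#'   (`1 <= required_votes <= length(results)`).
#' @return Data frame of class `vote_consensus`: `gene`, `votes`,
#'   `consensus_is_svg`.
#' @export
vote_consensus <- function(results, required_votes) {
  n <- length(results)
  if (n < 1L) stop("`results` must be a non-empty list")
  if (required_votes < 1 || required_votes > n)
    stop("`required_votes` must be between 1 and ", n)
  genes <- results[[1]]$gene
  calls <- vapply(results, function(r) {
    if (!identical(sort(r$gene), sort(genes)))
      stop("all results must cover the same feature set")
    r$is_svg[match(genes, r$gene)]
  }, logical(length(genes)))
  votes <- rowSums(calls)
  structure(
    data.frame(gene = genes, votes = as.integer(votes),
               consensus_is_svg = votes >= required_votes,
               row.names = genes, stringsAsFactors = FALSE),
    class = c("vote_consensus", "data.frame"),
    n_results = n, required_votes = required_votes)
}

#' Binary classification metrics against ground truth
#'
#' Confusion counts plus true positive rate (sensitivity), positive
#' predictive value (precision) and true negative rate (specificity).
#' Ratios whose denominator is zero are reported as `NaN` and should be
#' omitted from summaries.
#'
#' @param predicted,truth logical vectors of equal length.
#' @return List of class `classification_metrics` with `TP`, `FP`, `TN`,
#'   `FN`, `TPR`, `PPV`, `TNR`.
#' @export
classification_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth))
    stop("`predicted` and `truth` must have equal length")
  if (length(predicted) < 1L) stop("empty input")
  predicted <- as.logical(predicted); truth <- as.logical(truth)
  tp <- sum(predicted & truth); fp <- sum(predicted & !truth)
  tn <- sum(!predicted & !truth); fn <- sum(!predicted & truth)
  rate <- function(a, b) if (a + b == 0) NaN else a / (a + b)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 TPR = rate(tp, fn), PPV = rate(tp, fp), TNR = rate(tn, fp)),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("TP=%d FP=%d TN=%d FN=%d | TPR=%.3f PPV=%.3f TNR=%.3f\n",
              x$TP, x$FP, x$TN, x$FN, x$TPR, x$PPV, x$TNR))
  invisible(x)
}
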