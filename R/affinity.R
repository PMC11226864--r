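#' Relative enrichment of cell types per pixel
#'
#' For a label raster (cell-type counts per pixel), computes the ratio of
#' observed to expected counts, where the expected count of type `t` in
#' pixel `q` is `pixel_cell_count[q] * N_t / N` (pixel size times the global
#' type proportion).  This accounts for variability in both cell density
#' and cell-type abundance: a type at its global proportion scores 1
#' everywhere.  Types absent from the data are dropped with a warning.
#'
#' @param raster a `spatial_raster` of kind `"labels"` aggregated with
#'   `sum` (see [rasterize_labels()]).
#' @return Object of class `enrichment_matrix`: list with `RE` (types x
#'   pixels), the original `counts`, `type_totals`, `pixel_cell_count` and
#'   `pixel_centroids`.
#' @export
relative_enrichment <- function(raster) {
  stopifnot(inherits(raster, "spatial_raster"))
  if (raster$kind != "labels" || raster$agg != "sum")
    stop("`raster` must be a sum-aggregated label raster")
  counts <- as.matrix(raster$values)
  if (all(counts == 0)) stop("all-zero label raster")
  nt <- rowSums(counts)
  if (any(nt == 0)) {
    warning("dropping types with zero cells: ",
            paste(rownames(counts)[nt == 0], collapse = ", "))
    counts <- counts[nt > 0, , drop = FALSE]
    nt <- nt[nt > 0]
  }
  n <- sum(nt)
  expected <- outer(nt / n, raster$pixel_cell_count)
  structure(list(RE = counts / expected, counts = counts, type_totals = nt,
                 pixel_cell_count = raster$pixel_cell_count,
                 pixel_centroids = raster$pixel_centroids),
            class = "enrichment_matrix")
}

#' @export
print.enrichment_matrix <- function(x, ...) {
  cat("enrichment_matrix:", nrow(x$RE), "types x", ncol(x$RE), "pixels\n")
  cat("  type totals:",
      paste(names(x$type_totals), x$type_totals, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Binarize relative enrichment
#'
#' A type is "enriched" in a pixel when its relative enrichment meets the
#' threshold (default 1, i.e. above its expectation under spatial
#' homogeneity).
#'
#' @param re an [relative_enrichment()] result, or a plain RE matrix.
#' @param threshold positive RE cutoff (default 1.0).
#' @return Logical types x pixels matrix.
#' @export
binarize <- function(re, threshold = 1.0) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("`threshold` must be positive")
  m <- if (inherits(re, "enrichment_matrix")) re$RE else as.matrix(re)
  m >= threshold
}

support_range <- function(N, mA, mB)
  c(max(0L, mA + mB - N), min(mA, mB))

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Fisher noncentral hypergeometric probability mass
#'
#' Probability of observing `x` joint presences among `N` pixels with
#' margins `mA` and `mB` under log-odds affinity `alpha`:
#' `P(X = x) = C(mA, x) C(N - mA, mB - x) exp(alpha x) / Z` with `Z`
#' summing the numerator over the support
#' `max(0, mA + mB - N) <= x <= min(mA, mB)`.  Computed in log space;
#' `alpha = 0` reduces to the central hypergeometric distribution.
#'
#' @param x integer (vectorized) number of joint presences.
#' @param N,mA,mB total boxes and per-type margins.
#' @param alpha finite log-odds affinity.
#' @return Probabilities (0 outside the support).
#' @export
fnchg_pmf <- function(x, N, mA, mB, alpha = 0) {
  if (!is.finite(alpha)) stop("`alpha` must be finite")
  sr <- support_range(N, mA, mB)
  if (sr[1] > sr[2]) stop("no attainable table for these margins")
  u <- sr[1]:sr[2]
  lw <- lchoose(mA, u) + lchoose(N - mA, mB - u) + alpha * u
  lz <- logsumexp(lw)
  out <- numeric(length(x))
  ok <- x >= sr[1] & x <= sr[2] & x == round(x)
  out[ok] <- exp(lchoose(mA, x[ok]) + lchoose(N - mA, mB - x[ok]) +
                   alpha * x[ok] - lz)
  out
}

fnchg_mean <- function(N, mA, mB, alpha) {
  sr <- support_range(N, mA, mB)
  u <- sr[1]:sr[2]
  sum(u * fnchg_pmf(u, N, mA, mB, alpha))
}

#' Maximum likelihood affinity for a 2x2 co-occurrence table
#'
#' Estimates the log-odds affinity `alpha` of the Fisher noncentral
#' hypergeometric model from the observed joint-presence count.  The MLE
#' solves the moment equation `E[X | alpha] = x`; the expectation is
#' strictly increasing in `alpha`, so the root is found by bracketed 1-D
#' root finding.  Observations at the support boundary (complete
#' co-occurrence or complete avoidance) have no finite MLE and are mapped
#' to `+cap` / `-cap`; degenerate margins (`mA` or `mB` in `{0, N}`) leave
#' alpha unidentifiable and return `NA`.
#'
#' @param x observed joint-presence count.
#' @param N,mA,mB total boxes and margins.
#' @param cap symmetric cap for boundary tables (default 10).
#' @return `alpha` estimate (positive = co-enrichment, negative =
#'   depletion), or `NA` for degenerate margins.
#' @export
alpha_mle <- function(x, N, mA, mB, cap = 10) {
  if (mA <= 0 || mA >= N || mB <= 0 || mB >= N) return(NA_real_)
  sr <- support_range(N, mA, mB)
  if (x < sr[1] || x > sr[2]) stop("x outside the table support")
  if (x == sr[1]) return(-cap)
  if (x == sr[2]) return(cap)
  fn <- function(a) fnchg_mean(N, mA, mB, a) - x
  lo <- fn(-cap); hi <- fn(cap)
  if (lo >= 0) return(-cap)
  if (hi <= 0) return(cap)
  uniroot(fn, c(-cap, cap), f.lower = lo, f.upper = hi,
          tol = 1e-9)$root
}

#' Two-sided exact p-value for co-occurrence
#'
#' Fisher exact test of no affinity (`alpha = 0`) by the minimum-likelihood
#' rule: the p-value sums central hypergeometric probabilities of all
#' outcomes no more probable than the observed one (with a small relative
#' slack for floating-point ties).  Degenerate margins give p = 1.
#'
#' @inheritParams alpha_mle
#' @return p-value in \[0, 1\].
#' @export
affinity_pvalue <- function(x, N, mA, mB) {
  if (mA <= 0 || mA >= N || mB <= 0 || mB >= N) return(1)
  sr <- support_range(N, mA, mB)
  if (x < sr[1] || x > sr[2]) stop("x outside the table support")
  u <- sr[1]:sr[2]
  d <- dhyper(u, mA, N - mA, mB)
  min(1, sum(d[d <= d[u == x] * (1 + 1e-7)]))
}

#' Pairwise co-enrichment affinity across cell types
#'
#' Treats each type's binarized enrichment pattern as balls in boxes and,
#' for every unordered pair of types, builds the 2x2 table (`N` pixels,
#' margins `mA`, `mB`, joint count `X`), estimates the affinity
#' [alpha_mle()] and the exact two-sided [affinity_pvalue()], and adjusts
#' p-values with Benjamini-Hochberg across all non-degenerate pairs.  The
#' result is symmetric in the pair.
#'
#' @param binary logical types x pixels matrix (see [binarize()]), with at
#'   least two types as rownames.
#' @param fdr significance threshold on adjusted p-values (default 0.05).
#' @param cap cap for boundary alpha estimates (default 10).
#' @return Data frame of class `affinity_result`: `type_i`, `type_j`, `N`,
#'   `mA`, `mB`, `X`, `alpha_hat`, `p_value`, `p_adjusted`, `significant`,
#'   `direction` (`"co-enriched"`, `"depleted"` or `"none"`).
#' @export
pairwise_affinity <- function(binary, fdr = 0.05, cap = 10) {
  binary <- as.matrix(binary)
  if (nrow(binary) < 2L) stop("need at least two types")
  storage.mode(binary) <- "logical"
  types <- rownames(binary)
  if (is.null(types)) types <- paste0("type", seq_len(nrow(binary)))
  N <- ncol(binary)
  m <- rowSums(binary)
  pr <- t(utils::combn(nrow(binary), 2))
  out <- data.frame(
    type_i = types[pr[, 1]], type_j = types[pr[, 2]],
    N = N, mA = m[pr[, 1]], mB = m[pr[, 2]],
    X = vapply(seq_len(nrow(pr)), function(r)
      sum(binary[pr[r, 1], ] & binary[pr[r, 2], ]), numeric(1)),
    stringsAsFactors = FALSE)
  out$alpha_hat <- vapply(seq_len(nrow(out)), function(r)
    alpha_mle(out$X[r], N, out$mA[r], out$mB[r], cap), numeric(1))
  out$p_value <- vapply(seq_len(nrow(out)), function(r)
    if (is.na(out$alpha_hat[r])) NA_real_ else
      affinity_pvalue(out$X[r], N, out$mA[r], out$mB[r]), numeric(1))
  out$p_adjusted <- NA_real_
  ok <- !is.na(out$p_value)
  out$p_adjusted[ok] <- p.adjust(out$p_value[ok], method = "BH")
  out$significant <- ok & out$p_adjusted <= fdr
  out$direction <- ifelse(!out$significant, "none",
                          ifelse(out$alpha_hat > 0, "co-enriched",
                                 "depleted"))
  structure(out, class = c("affinity_result", "data.frame"), fdr = fdr,
            cap = cap)
}

#' @export
print.affinity_result <- function(x, ...) {
  cat("affinity_result:", nrow(x), "type pairs over", x$N[1], "pixels\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Symmetric alpha matrix from an affinity result
#'
#' @param result a [pairwise_affinity()] data frame.
#' @param diag_value value for the diagonal (default: the cap used).
#' @return Symmetric types x types matrix of alpha estimates.
#' @export
alpha_matrix <- function(result, diag_value = attr(result, "cap")) {
  types <- sort(unique(c(result$type_i, result$type_j)))
  m <- matrix(NA_real_, length(types), length(types),
              dimnames = list(types, types))
  diag(m) <- if (is.null(diag_value)) 10 else diag_value
  for (r in seq_len(nrow(result))) {
    m[result$type_i[r], result$type_j[r]] <- result$alpha_hat[r]
    m[result$type_j[r], result$type_i[r]] <- result$alpha_hat[r]
  }
  m
}

#' Hierarchically cluster cell types by affinity
#'
#' Average-linkage hierarchical clustering of types on the distance
#' `max(alpha) - alpha`, so strongly co-enriched types merge first.  Useful
#' for finding groups of types that form spatial structures together.
#'
#' @param alpha_mat symmetric types x types alpha matrix (capped values are
#'   treated as finite); see [alpha_matrix()].
#' @param k optional number of flat groups to cut the dendrogram into.
#' @return List with the `hclust` object, the leaf `order` (type names)
#'   and, when `k` is given, integer `groups`.
#' @export
cluster_alpha <- function(alpha_mat, k = NULL) {
  alpha_mat <- as.matrix(alpha_mat)
  if (nrow(alpha_mat) != ncol(alpha_mat) ||
      !isTRUE(all.equal(alpha_mat, t(alpha_mat), tolerance = 1e-8)))
    stop("`alpha_mat` must be symmetric")
  d <- max(alpha_mat) - alpha_mat
  diag(d) <- 0
  hc <- hclust(as.dist(d), method = "average")
  out <- list(hclust = hc, order = rownames(alpha_mat)[hc$order])
  if (!is.null(k)) out$groups <- cutree(hc, k = k)
  out
}
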