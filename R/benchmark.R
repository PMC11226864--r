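#' Rotation-voting SVG detection benchmark on simulated data
#'
#' End-to-end benchmark of the full rasterized spatially-variable-gene
#' pipeline: simulates circular-pattern data ([simulate_svg()]), rasterizes
#' it at each requested resolution under `n_angles` rotation permutations
#' ([permute_rasterize()]), runs the Moran's I permutation detector
#' ([svg_test()]) on every rotated raster, combines the per-rotation calls
#' with [vote_consensus()] and scores the consensus against the simulation
#' ground truth ([classification_metrics()]).  The default requires a
#' unanimous vote (`required_votes = n_angles`), the strictest end of the
#' voting trade-off, which suppresses calls that appear only at particular
#' grid orientations.  Per-rotation means of the metrics are returned
#' alongside (columns `TPR_rot`, `PPV_rot`, `TNR_rot`; undefined ratios
#' omitted from the average).
#'
#' @param radius pattern radius in um or preset name (see [simulate_svg()]).
#' @param resolutions numeric vector of rasterization resolutions in um.
#' @param n_angles rotation permutations per resolution (default 10).
#' @param required_votes votes needed for a consensus call (default
#'   `n_angles`, i.e. unanimity).
#' @param n_perm permutations inside the detector (default 499).
#' @param fdr adjusted-p-value call threshold (default 0.05).
#' @param seed integer seed driving the simulation and the detector.
#' @param sim_args optional list of further arguments to [simulate_svg()].
#' @return Data frame with one row per resolution: `resolution`, consensus
#'   `TPR`, `PPV`, `TNR`, per-rotation means `TPR_rot`, `PPV_rot`,
#'   `TNR_rot`, and `n_pixels` (mean occupied pixels).
#' @seealso [coenrichment_benchmark()]
#' @export
svg_benchmark <- function(radius, resolutions, n_angles = 10,
                          required_votes = n_angles, n_perm = 499,
                          fdr = 0.05, seed = 1, sim_args = list()) {
  sim <- do.call(simulate_svg, c(list(radius = radius, seed = seed),
                                 sim_args))
  out <- lapply(resolutions, function(res) {
    rasters <- permute_rasterize(sim$dataset, res, n_angles = n_angles)
    fits <- lapply(seq_along(rasters), function(i)
      svg_test(rasters[[i]], n_perm = n_perm, fdr = fdr,
               seed = seed * 1000L + i))
    cons <- vote_consensus(fits, required_votes)
    m <- classification_metrics(cons$consensus_is_svg, sim$truth$is_svg)
    ms <- lapply(fits, function(f)
      classification_metrics(f$is_svg, sim$truth$is_svg))
    avg <- function(f) mean(vapply(ms, `[[`, numeric(1), f), na.rm = TRUE)
    data.frame(resolution = res, TPR = m$TPR, PPV = m$PPV, TNR = m$TNR,
               TPR_rot = avg("TPR"), PPV_rot = avg("PPV"),
               TNR_rot = avg("TNR"),
               n_pixels = mean(vapply(rasters, function(r)
                 length(r$pixel_ids), numeric(1))))
  })
  do.call(rbind, out)
}

#' Cell-type co-enrichment across rasterization resolutions
#'
#' Runs the full co-enrichment pipeline on the simulated four-type
#' arrangement ([simulate_celltypes()]) at several resolutions: label
#' rasterization, relative enrichment, binarization at the given threshold
#' and pairwise affinity estimation.
#'
#' @param resolutions numeric vector of resolutions in um.
#' @param threshold relative-enrichment binarization cutoff (default 1).
#' @param fdr significance threshold (default 0.05).
#' @param seed integer seed for the simulation.
#' @param sim_args optional list of further arguments to
#'   [simulate_celltypes()].
#' @return Data frame stacking the [pairwise_affinity()] results with a
#'   `resolution` column.
#' @export
coenrichment_benchmark <- function(resolutions = c(50, 100, 200),
                                   threshold = 1, fdr = 0.05, seed = 1,
                                   sim_args = list()) {
  ds <- do.call(simulate_celltypes, c(list(seed = seed), sim_args))
  out <- lapply(resolutions, function(res) {
    aff <- pairwise_affinity(
      binarize(relative_enrichment(rasterize_labels(ds, res)), threshold),
      fdr = fdr)
    cbind(resolution = res, as.data.frame(aff))
  })
  do.call(rbind, out)
}
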