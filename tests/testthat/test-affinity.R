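# direct (non-log) arithmetic oracles, independent of the package's
# log-space implementations; safe for tables up to N ~ 30
oracle_weights <- function(N, mA, mB, alpha) {
  u <- max(0, mA + mB - N):min(mA, mB)
  list(u = u, w = choose(mA, u) * choose(N - mA, mB - u) *
         exp(alpha * (u - mean(u))))  # shift for numerical safety
}
oracle_mean <- function(N, mA, mB, alpha) {
  ow <- oracle_weights(N, mA, mB, alpha)
  sum(ow$u * ow$w) / sum(ow$w)
}

test_that("relative enrichment is observed over expected", {
  # single type everywhere -> RE = 1 in every pixel
  ds <- spatial_dataset(cbind(runif(50, 0, 100), runif(50, 0, 100)),
                        labels = rep("only", 50))
  re1 <- relative_enrichment(rasterize_labels(ds, 25))
  expect_true(all(abs(re1$RE - 1) < 1e-12))

  # worked example: 10-cell pixel, global proportion 0.2, observed 4 -> 2.0
  counts <- matrix(c(4, 14,
                     6, 66), 2, 2, byrow = TRUE,
                   dimnames = list(c("t", "other"), NULL))
  fake <- structure(list(values = counts, pixel_cell_count = c(10, 80),
                         pixel_centroids = cbind(c(0, 1), c(0, 0)),
                         pixel_ids = c("0_0", "1_0"), agg = "sum",
                         kind = "labels",
                         provenance = list(shape = "square", resolution = 1,
                                           rotation_angle = 0, n_cells = 90)),
                    class = "spatial_raster")
  re <- relative_enrichment(fake)
  expect_equal(unname(re$RE["t", 1]), 2.0)  # 4 / (10 * 0.2)

  # weighted identity: sum_q RE * expected = N_t for every type
  set.seed(17)
  ds2 <- spatial_dataset(cbind(runif(400, 0, 300), runif(400, 0, 300)),
                         labels = sample(LETTERS[1:4], 400, TRUE,
                                         prob = c(.4, .3, .2, .1)))
  re2 <- relative_enrichment(rasterize_labels(ds2, 60))
  expected <- outer(re2$type_totals / sum(re2$type_totals),
                    re2$pixel_cell_count)
  expect_equal(unname(rowSums(re2$RE * expected)),
               unname(as.numeric(re2$type_totals)), tolerance = 1e-9)
})

test_that("binarization thresholds behave as limits dictate", {
  m <- matrix(c(0, 0.5, 2.0, 1.0), 2, 2)
  expect_equal(binarize(m, 1e-12), m > 0)
  expect_equal(sum(binarize(m, 1e12)), 0)
  expect_true(binarize(matrix(2), 1.0)[1])
  expect_error(binarize(m, -1), "positive")
})

test_that("noncentral hypergeometric pmf matches its definition", {
  # alpha = 0 reduces to the central hypergeometric
  u <- 0:10
  expect_equal(fnchg_pmf(u, 20, 10, 10, 0), dhyper(u, 10, 10, 10),
               tolerance = 1e-12)
  # normalization over the support for assorted parameters
  for (par in list(c(20, 10, 10, 1), c(15, 3, 12, -2), c(30, 19, 7, 4))) {
    sup <- max(0, par[2] + par[3] - par[1]):min(par[2], par[3])
    expect_equal(sum(fnchg_pmf(sup, par[1], par[2], par[3], par[4])), 1,
                 tolerance = 1e-12)
  }
  # enumeration oracle at N=20, mA=mB=10, alpha=1
  ow <- oracle_weights(20, 10, 10, 1)
  expect_equal(fnchg_pmf(ow$u, 20, 10, 10, 1), ow$w / sum(ow$w),
               tolerance = 1e-12)
  expect_equal(fnchg_pmf(c(-1, 11), 20, 10, 10, 1), c(0, 0))
})

test_that("alpha MLE solves the moment equation and handles boundaries", {
  # X at the independence expectation -> alpha = 0
  expect_equal(alpha_mle(25, 100, 50, 50), 0, tolerance = 1e-6)
  # support maximum / minimum -> +-cap
  expect_equal(alpha_mle(50, 100, 50, 50), 10)
  expect_equal(alpha_mle(0, 100, 50, 50), -10)
  expect_true(is.na(alpha_mle(0, 100, 0, 50)))

  # staged grid search with enumeration-based expectations
  grid_oracle <- function(x, N, mA, mB) {
    a <- seq(-10, 10, by = 0.01)
    best <- a[which.min(abs(vapply(a, function(ai)
      oracle_mean(N, mA, mB, ai), numeric(1)) - x))]
    for (step in c(1e-4, 1e-6)) {
      a <- seq(best - step * 150, best + step * 150, by = step)
      best <- a[which.min(abs(vapply(a, function(ai)
        oracle_mean(N, mA, mB, ai), numeric(1)) - x))]
    }
    best
  }
  expect_equal(alpha_mle(8, 20, 10, 10), grid_oracle(8, 20, 10, 10),
               tolerance = 1e-6)
  expect_equal(alpha_mle(3, 25, 12, 7), grid_oracle(3, 25, 12, 7),
               tolerance = 1e-6)

  # strictly increasing in X over the interior support
  alphas <- vapply(1:9, function(x) alpha_mle(x, 20, 10, 10), numeric(1))
  expect_true(all(diff(alphas) > 0))
  # symmetric under margin swap
  expect_equal(alpha_mle(5, 30, 18, 9), alpha_mle(5, 30, 9, 18))
})

test_that("exact p-values match enumeration and stay in [0, 1]", {
  # extreme tail at N=20, mA=mB=10, X=10
  d <- dhyper(0:10, 10, 10, 10)
  expect_equal(affinity_pvalue(10, 20, 10, 10), d[1] + d[11],
               tolerance = 1e-12)
  # observed at the mode -> p close to 1 (whole distribution included)
  expect_equal(affinity_pvalue(5, 20, 10, 10), 1, tolerance = 1e-9)
  expect_equal(affinity_pvalue(3, 100, 0, 50), 1)  # degenerate margin
  set.seed(23)
  for (i in 1:200) {
    N <- sample(5:40, 1)
    mA <- sample(1:(N - 1), 1); mB <- sample(1:(N - 1), 1)
    sup <- max(0, mA + mB - N):min(mA, mB)
    x <- sample(sup, 1)
    p <- affinity_pvalue(x, N, mA, mB)
    expect_true(p >= 0 && p <= 1)
  }
})

test_that("pairwise affinity handles identical, complementary and null rows", {
  set.seed(9)
  base <- sample(c(TRUE, FALSE), 60, TRUE)
  bin <- rbind(a = base, b = base, c = !base)
  res <- pairwise_affinity(bin)
  get <- function(i, j) res[res$type_i == i & res$type_j == j, ]
  expect_equal(get("a", "b")$alpha_hat, 10)   # X = mA = mB
  expect_equal(get("a", "c")$alpha_hat, -10)  # complementary, X = 0
  # symmetric under relabeling of the pair
  bin2 <- bin[c(2, 1, 3), ]
  res2 <- pairwise_affinity(bin2)
  expect_equal(sort(res$alpha_hat), sort(res2$alpha_hat))
  expect_equal(nrow(res), 3)
  expect_error(pairwise_affinity(bin[1, , drop = FALSE]), "at least two")
})

test_that("alpha clustering recovers block structure", {
  types <- paste0("t", 1:6)
  am <- matrix(-10, 6, 6, dimnames = list(types, types))
  am[1:3, 1:3] <- 8; am[4:6, 4:6] <- 8; diag(am) <- 10
  cl <- cluster_alpha(am, k = 2)
  expect_equal(unname(cl$groups[1:3]), rep(cl$groups[["t1"]], 3))
  expect_equal(unname(cl$groups[4:6]), rep(cl$groups[["t4"]], 3))
  expect_true(cl$groups[["t1"]] != cl$groups[["t4"]])
  # merge heights non-decreasing on a random symmetric matrix
  set.seed(12)
  r <- matrix(rnorm(49), 7, 7); r <- (r + t(r)) / 2
  dimnames(r) <- list(paste0("x", 1:7), paste0("x", 1:7))
  hc <- cluster_alpha(r)$hclust
  expect_true(all(diff(hc$height) >= -1e-12))
  # two types: single merge, order = input order
  two <- matrix(c(10, 1, 1, 10), 2, 2, dimnames = list(c("p", "q"),
                                                       c("p", "q")))
  expect_equal(cluster_alpha(two)$order, c("p", "q"))
  bad <- r; bad[1, 2] <- bad[1, 2] + 1
  expect_error(cluster_alpha(bad), "symmetric")
})
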