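test_that("single-pixel aggregation does the stated arithmetic", {
  ds <- spatial_dataset(cbind(c(1, 2, 3, 4), c(1, 1, 2, 2)),
                        matrix(c(1, 3, 5, 7), 1, 4,
                               dimnames = list("g", NULL)))
  rm <- rasterize_expression(ds, resolution = 10, agg = "mean")
  expect_equal(as.numeric(rm$values), 4.0)
  rs <- rasterize_expression(ds, resolution = 10, agg = "sum")
  expect_equal(as.numeric(rs$values), 16.0)
  expect_error(rasterize_expression(ds, 10, agg = "median"),
               "invalid parameter")
})

test_that("a constant gene stays constant under mean regardless of density", {
  set.seed(3)
  n <- 300
  xy <- cbind(c(runif(250, 0, 50), runif(50, 50, 400)),  # very uneven density
              runif(n, 0, 400))
  ds <- spatial_dataset(xy, matrix(2.5, 1, n))
  r <- rasterize_expression(ds, 100, agg = "mean")
  expect_true(all(abs(as.numeric(r$values) - 2.5) < 1e-12))
})

test_that("aggregation matches a dense group-by oracle and conserves mass", {
  set.seed(11)
  ds <- random_dataset(n = 200, f = 50, side = 160, seed = 11, sparse = TRUE)
  for (agg in c("sum", "mean")) {
    r <- rasterize_expression(ds, 50, agg = agg)
    g <- build_grid(ds$coords, 50, "square")
    ref <- brute_aggregate(ds$features, assign_pixels(ds$coords, g), agg)
    expect_equal(as.matrix(r$values)[, colnames(ref)], ref,
                 ignore_attr = FALSE)
  }
  # exact mass conservation for integer counts under sum
  r <- rasterize_expression(ds, 50, agg = "sum")
  expect_identical(as.numeric(Matrix::rowSums(r$values)),
                   as.numeric(Matrix::rowSums(ds$features)))
  expect_equal(sum(r$pixel_cell_count), ds$n_cells)
})

test_that("mean-aggregated values stay within member-cell bounds", {
  set.seed(5)
  ds <- random_dataset(n = 150, f = 8, side = 300, seed = 5)
  g <- build_grid(ds$coords, 75, "square")
  pix <- assign_pixels(ds$coords, g)
  r <- rasterize_expression(ds, 75, agg = "mean")
  for (q in r$pixel_ids) {
    sub <- as.matrix(ds$features[, pix == q, drop = FALSE])
    v <- as.numeric(r$values[, q])
    expect_true(all(v >= apply(sub, 1, min) - 1e-12))
    expect_true(all(v <= apply(sub, 1, max) + 1e-12))
  }
})

test_that("rasterization is invariant to cell ordering and input sparsity", {
  ds <- random_dataset(n = 120, f = 6, side = 200, seed = 9)
  set.seed(1); perm <- sample(ds$n_cells)
  ds2 <- spatial_dataset(ds$coords[perm, ], ds$features[, perm],
                         cell_ids = ds$cell_ids[perm])
  dss <- spatial_dataset(ds$coords, Matrix::Matrix(ds$features, sparse = TRUE))
  r1 <- rasterize_expression(ds, 50)
  r2 <- rasterize_expression(ds2, 50)
  r3 <- rasterize_expression(dss, 50)
  expect_equal(r1$values, r2$values)
  expect_equal(r1$pixel_cell_count, r2$pixel_cell_count)
  expect_equal(unname(as.matrix(r3$values)), unname(r1$values))
  expect_s4_class(r3$values, "sparseMatrix")  # sparse stays sparse
})

test_that("label rasterization one-hot counts are exact", {
  ds <- spatial_dataset(cbind(c(1, 2, 3, 30), c(1, 2, 1, 30)),
                        labels = c("A", "A", "B", "C"))
  lr <- rasterize_labels(ds, 10)
  expect_equal(sort(rownames(lr$values)), c("A", "B", "C"))
  first <- as.numeric(lr$values[, "0_0"])
  names(first) <- rownames(lr$values)
  expect_equal(first, c(A = 2, B = 1, C = 0))
  # column sums equal pixel cell counts for any input
  set.seed(20)
  ds2 <- spatial_dataset(cbind(runif(300, 0, 200), runif(300, 0, 200)),
                         labels = sample(letters[1:5], 300, TRUE))
  lr2 <- rasterize_labels(ds2, 40)
  expect_equal(as.numeric(Matrix::colSums(lr2$values)),
               as.numeric(lr2$pixel_cell_count))
  # per-type totals conserved
  expect_equal(as.numeric(Matrix::rowSums(lr2$values)[letters[1:5]]),
               as.numeric(table(ds2$labels)[letters[1:5]]))
})

test_that("missing labels are excluded only when explicitly requested", {
  ds <- spatial_dataset(cbind(1:4, 1:4),
                        matrix(1:8, 2, 4),
                        labels = c("A", NA, "B", "A"))
  expect_error(rasterize_labels(ds, 10), "NA")
  expect_message(lr <- rasterize_labels(ds, 10, na_action = "exclude"),
                 "excluding 1")
  expect_equal(sum(lr$values), 3)  # 3 labelled cells
  # the NA-labelled cell still participates in expression rasterization
  r <- rasterize_expression(ds, 10, agg = "sum")
  expect_equal(sum(r$pixel_cell_count), 4)
})

test_that("subset rasterization equals rasterizing the filtered data", {
  ds <- random_dataset(n = 150, f = 5, side = 250, seed = 13,
                       labels = sample(c("x", "y"), 150, TRUE))
  rsub <- rasterize_subset(ds, "x", 60)
  keep <- ds$labels == "x"
  ref <- rasterize_expression(
    spatial_dataset(ds$coords[keep, ], ds$features[, keep]), 60)
  expect_equal(unname(as.matrix(rsub$values)), unname(as.matrix(ref$values)))
  expect_equal(sum(rsub$pixel_cell_count), sum(keep))
  expect_error(rasterize_subset(ds, "zzz", 60), "unknown label")

  # single-cell subset: one pixel holding that cell's expression
  ds1 <- random_dataset(n = 40, f = 3, side = 100, seed = 2,
                        labels = c("solo", rep("rest", 39)))
  r1 <- rasterize_subset(ds1, "solo", 50)
  expect_equal(length(r1$pixel_ids), 1L)
  expect_equal(as.numeric(r1$values), as.numeric(ds1$features[, 1]))
})

test_that("joint rasterization shares one grid across datasets", {
  a <- random_dataset(n = 60, f = 4, side = 100, seed = 1)
  b <- spatial_dataset(a$coords + 1000, a$features)  # distant section
  rr <- rasterize_joint(list(a, b), 50)
  expect_length(intersect(rr[[1]]$pixel_ids, rr[[2]]$pixel_ids), 0)
  expect_identical(rr[[1]]$grid$origin, rr[[2]]$grid$origin)

  # identical copies -> identical rasters
  cc <- rasterize_joint(list(a, a), 50)
  expect_equal(cc[[1]]$values, cc[[2]]$values)

  # translating by exactly one grid step shifts pixel ids by one
  shifted <- spatial_dataset(sweep(a$coords, 2, c(50, 0), "+"), a$features)
  rs <- rasterize_joint(list(a, shifted), 50)
  ij <- do.call(rbind, strsplit(rs[[1]]$pixel_ids, "_"))
  shifted_ids <- paste0(as.integer(ij[, 1]) + 1L, "_", ij[, 2])
  expect_setequal(rs[[2]]$pixel_ids, shifted_ids)
  expect_error(rasterize_joint(list(a), 50), "at least two")
})
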