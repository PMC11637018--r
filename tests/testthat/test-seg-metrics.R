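test_that("overlap metrics honour identity, disjointness and empty masks", {
  m <- nonempty_mask(c(6, 6, 4))
  expect_equal(dsc(m, m), 1)
  expect_equal(jaccard(m, m), 1)
  a <- array(0L, c(4, 4, 2)); a[1, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 2)); b[4, 4, 2] <- 1L
  expect_equal(dsc(a, b), 0)
  expect_equal(jaccard(a, b), 0)
  z <- array(0L, c(3, 3, 3))
  expect_equal(dsc(z, z), 1)        # both empty: perfect agreement
  expect_equal(jaccard(z, z), 1)
  expect_equal(hd95(z, z), 0)
  expect_equal(asd(z, z), 0)
  expect_error(dsc(a, array(0L, c(3, 3, 3))), "shape")
  z2 <- array(0L, c(4, 4, 2))
  expect_error(hd95(a, z2), "empty")
  expect_error(asd(z2, a), "empty")
})

test_that("a unit-shifted 10-cube reproduces the counted overlap values", {
  A <- array(0L, c(14, 14, 14)); A[2:11, 2:11, 2:11] <- 1L
  B <- array(0L, c(14, 14, 14)); B[3:12, 2:11, 2:11] <- 1L
  # brute-force voxel counts
  inter <- sum(A == 1 & B == 1); expect_equal(inter, 900)
  expect_equal(dsc(A, B), 2 * 900 / 2000)
  expect_equal(jaccard(A, B), 900 / 1100)
})

test_that("two single-voxel masks three voxels apart have distance 3", {
  a <- array(0L, c(8, 4, 4)); a[2, 2, 2] <- 1L
  b <- array(0L, c(8, 4, 4)); b[5, 2, 2] <- 1L
  expect_equal(hd95(a, b), 3)
  expect_equal(asd(a, b), 3)
  expect_equal(hausdorff(a, b), 3)
  # spacing scales physical distances
  expect_equal(asd(a, b, spacing = c(2, 1, 1)), 6)
})

test_that("surface extraction agrees with the erosion-based definition", {
  set.seed(1)
  for (trial in 1:20) {
    m <- random_mask(c(6, 5, 4), p = runif(1, 0.2, 0.7))
    expect_identical(surface_voxels(m), brute_surface(m))
  }
})

test_that("distance metrics match the exhaustive pairwise oracle", {
  set.seed(2)
  for (trial in 1:200) {
    d <- sample(3:8, 3, replace = TRUE)
    a <- nonempty_mask(d, runif(1, 0.15, 0.6))
    b <- nonempty_mask(d, runif(1, 0.15, 0.6))
    sp <- sample(c(1, 1, 1, 2, 3), 3, replace = TRUE)
    o <- brute_surface_dists(a, b, sp)
    pooled <- c(o$ab, o$ba)
    expect_equal(hd95(a, b, sp),
                 unname(quantile(pooled, 0.95, type = 7)), tolerance = 1e-9)
    expect_equal(asd(a, b, sp),
                 (sum(o$ab) + sum(o$ba)) / length(pooled), tolerance = 1e-9)
    expect_equal(hausdorff(a, b, sp), max(pooled), tolerance = 1e-9)
    # the 95th-percentile variant never exceeds the full Hausdorff distance
    expect_lte(hd95(a, b, sp), hausdorff(a, b, sp) + 1e-12)
  }
})

test_that("all metrics are symmetric and translation invariant", {
  set.seed(3)
  for (trial in 1:25) {
    d <- c(8, 8, 6)
    a <- nonempty_mask(d, 0.3); b <- nonempty_mask(d, 0.3)
    expect_equal(dsc(a, b), dsc(b, a), tolerance = 1e-12)
    expect_equal(jaccard(a, b), jaccard(b, a), tolerance = 1e-12)
    expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-12)
    expect_equal(asd(a, b), asd(b, a), tolerance = 1e-12)
  }
  # joint translation leaves every metric unchanged
  a <- array(0L, c(10, 10, 6)); a[3:5, 3:5, 2:3] <- 1L
  b <- array(0L, c(10, 10, 6)); b[4:6, 3:6, 2:4] <- 1L
  shift <- function(m) { s <- array(0L, dim(m)); s[4:10, 3:10, 3:6] <-
    m[1:7, 1:8, 1:4]; s }
  expect_equal(dsc(a, b), dsc(shift(a), shift(b)))
  expect_equal(hd95(a, b), hd95(shift(a), shift(b)), tolerance = 1e-12)
  expect_equal(asd(a, b), asd(shift(a), shift(b)), tolerance = 1e-12)
})

test_that("Dice and Jaccard obey their algebraic identity per case", {
  set.seed(4)
  for (trial in 1:50) {
    a <- nonempty_mask(c(7, 6, 5), 0.4); b <- nonempty_mask(c(7, 6, 5), 0.4)
    j <- jaccard(a, b)
    expect_equal(dsc(a, b), 2 * j / (1 + j), tolerance = 1e-9)
  }
})

test_that("relative change implements the signed percent convention", {
  expect_equal(relative_change(0.75, 0.82), (0.82 - 0.75) / 0.75 * 100)
  expect_equal(relative_change(3.7, 3.7), 0)
  expect_lt(relative_change(27.74, 8.93), 0)
  expect_error(relative_change(0, 1), "nonzero")
})

test_that("the relative-change table reproduces per-metric percentages", {
  vals <- tibble::tibble(
    method = c("base", "new"),
    dsc = c(0.8, 0.9), jaccard = c(0.7, 0.8),
    hd95 = c(10, 5), asd = c(2, 1))
  tab <- relative_change_table(vals, proposed = "new")
  expect_equal(nrow(tab), 4L)
  expect_equal(tab$change_pct[tab$metric == "dsc"], 12.5)
  expect_equal(tab$change_pct[tab$metric == "hd95"], -50)
})

test_that("evaluation aggregates equal hand-averaged per-case metrics", {
  dir <- withr::local_tempdir()
  spec <- tiny_phantom_spec(n_cases = 6L, test_fraction = 0.5)
  man <- generate_dataset(spec, dir)
  fit <- train(list(
    data = list(manifest = man, window = c(16L, 16L, 8L)),
    model = list(levels = 2L, base_channels = 2L, cam_reduction = 2L,
                 sam_kernel = 3L),
    loss = list(lambda_max = 0.1, rampup_length = 10L),
    trainer = list(epochs = 1L, seed = 2L, mc_passes = 2L,
                   checkpoint_every = 1000L)))
  rep <- evaluate(fit, man)
  expect_s3_class(rep, "metric_report")
  expect_equal(nrow(rep$per_case), 3L)
  for (met in c("dsc", "jaccard")) {
    expect_equal(rep$aggregate$mean[rep$aggregate$metric == met],
                 mean(rep$per_case[[met]]), tolerance = 1e-12)
    expect_true(all(rep$per_case[[met]] >= 0 & rep$per_case[[met]] <= 1))
  }
  expect_s3_class(tidy(rep), "tbl_df")
  expect_equal(nrow(tidy(rep)), 12L)
  expect_s3_class(glance(rep), "tbl_df")
})
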