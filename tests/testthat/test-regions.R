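test_that("dilation matches the brute-force distance oracle", {
  # single voxel examples
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_identical(sum(dilate_roi(m, c(1, 1, 1), 1)), 7L)
  expect_identical(sum(dilate_roi(m, c(1, 1, 1), 3)), 123L)
  # r -> 0+ is the identity
  expect_identical(dilate_roi(m, c(1, 1, 1), 1e-6), m)
  # random masks, isotropic and anisotropic
  for (s in 1:6) {
    set.seed(s)
    d <- c(10, 9, 8)
    mask <- array(runif(prod(d)) < 0.05, dim = d)
    if (!any(mask)) mask[5, 5, 4] <- TRUE
    sp <- if (s %% 2) c(1, 1, 1) else c(1, 1.5, 2)
    r <- sample(c(1, 2, 2.5), 1)
    got <- suppressWarnings(dilate_roi(mask, sp, r))
    expect_identical(got, oracle_dilate(mask, sp, r))
    expect_true(all(got[mask]))  # superset
  }
})

test_that("dilation reaching the grid boundary warns with clipped count", {
  m <- array(FALSE, c(5, 5, 5)); m[1, 3, 3] <- TRUE
  expect_warning(dilate_roi(m, c(1, 1, 1), 2), "clipped")
})

test_that("peritumoral shells are disjoint from and nested around the tumor", {
  m <- array(FALSE, c(9, 9, 9)); m[5, 5, 5] <- TRUE
  expect_identical(sum(peritumoral_shell(m, c(1, 1, 1), 1)), 6L)
  for (s in 1:8) {
    set.seed(s)
    mask <- array(runif(9 * 9 * 9) < 0.04, dim = c(9, 9, 9))
    if (!any(mask)) mask[5, 5, 5] <- TRUE
    sh1 <- suppressWarnings(peritumoral_shell(mask, c(1, 1, 1), 1))
    dil3 <- suppressWarnings(dilate_roi(mask, c(1, 1, 1), 3))
    expect_false(any(sh1 & mask))          # disjoint
    expect_true(all(dil3[sh1]))            # shell(1) within dilated(3)
  }
  full <- array(TRUE, c(4, 4, 4))
  expect_error(suppressWarnings(peritumoral_shell(full, c(1, 1, 1), 1)),
               "empty")
})

test_that("local feature map emits 13 named channels with the documented conventions", {
  # constant image, full mask
  vol <- annotated_volume(array(50, c(6, 6, 6)), c(1, 1, 1),
                          array(TRUE, c(6, 6, 6)))
  lf <- local_feature_map(vol)
  expect_identical(ncol(lf$channels), 13L)
  expect_identical(colnames(lf$channels),
                   c("mean", "median", "minimum", "maximum", "range",
                     "variance", "stddev", "skewness", "kurtosis", "energy",
                     "entropy", "uniformity", "cv"))
  expect_true(all(lf$channels[, "entropy"] == 0))
  expect_true(all(lf$channels[, "variance"] == 0))
  expect_true(all(lf$channels[, "uniformity"] == 1))
  # single hot voxel: interior local mean = v/27
  arr <- array(0, c(7, 7, 7)); arr[4, 4, 4] <- 54
  vol2 <- annotated_volume(arr, c(1, 1, 1), array(TRUE, c(7, 7, 7)))
  lf2 <- local_feature_map(vol2)
  center <- which(lf2$voxels == which(arr == 54))
  expect_equal(lf2$channels[center, "mean"], 54 / 27, ignore_attr = TRUE)
})

test_that("habitat clustering recovers the planted noiseless partition exactly", {
  v <- make_ball_volume(radius = 8, levels = c(-400, -150, 100))
  lf <- local_feature_map(v)
  hab <- kmeans_habitats(lf, k = 3, seed = 1)
  expect_equal(ari(hab[v$mask], v$truth[v$mask]), 1)
  # partition property: labels cover the tumor exactly
  expect_true(all(hab[v$mask] %in% 1:3))
  expect_true(all(hab[!v$mask] == 0L))
  # deterministic renumbering: labels ordered by mean intensity
  mu <- tapply(v$intensities[v$mask], hab[v$mask], mean)
  expect_true(all(diff(mu) > 0))
})

test_that("habitat labels are stable across clustering seeds on separated plateaus", {
  v <- make_ball_volume(radius = 6, levels = c(-400, -150, 100),
                        noise_sd = 10, seed = 4)
  lf <- local_feature_map(v)
  ref <- kmeans_habitats(lf, k = 3, seed = 1)
  for (s in c(2, 5, 17, 99)) {
    expect_identical(kmeans_habitats(lf, k = 3, seed = s), ref)
  }
})

test_that("habitat stage is invariant to a constant intensity shift", {
  v <- make_ball_volume(radius = 6, levels = c(-400, -150, 100),
                        noise_sd = 15, seed = 2)
  h1 <- kmeans_habitats(local_feature_map(v), k = 3, seed = 1)
  v2 <- v; v2$intensities <- v$intensities + 137.5
  h2 <- kmeans_habitats(local_feature_map(v2), k = 3, seed = 1)
  expect_identical(h1, h2)
})

test_that("degenerate habitat inputs behave per contract", {
  v <- make_ball_volume(radius = 3, levels = 0)
  lf <- local_feature_map(v)
  h1 <- kmeans_habitats(lf, k = 1, seed = 1)
  expect_identical(sort(unique(h1[v$mask])), 1L)
  small <- annotated_volume(array(0, c(3, 3, 3)), c(1, 1, 1),
                            array(c(TRUE, TRUE, rep(FALSE, 25)), c(3, 3, 3)))
  expect_error(kmeans_habitats(local_feature_map(small), k = 3),
               "fewer than k")
})

test_that("region_set bundles tumor, shells and habitats consistently", {
  v <- make_ball_volume(radius = 5, levels = c(-300, 0), noise_sd = 10)
  rs <- region_set(v, shell_radii_mm = c(1, 3), k = 2, seed = 1)
  expect_named(rs$shells, c("peri1", "peri3"))
  expect_false(any(rs$shells$peri1 & rs$tumor_mask))
  expect_true(all((rs$habitat_labels > 0) == rs$tumor_mask))
  dir <- withr::local_tempdir()
  paths <- write_region_set(rs, dir, prefix = "t")
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(grep("habitats", paths, value = TRUE))
  expect_identical(array(as.integer(back), dim(rs$habitat_labels)),
                   array(as.integer(rs$habitat_labels),
                         dim(rs$habitat_labels)))
})
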