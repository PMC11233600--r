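test_that("noiseless single-plateau phantom is constant inside the mask", {
  v <- make_ball_volume(radius = 3, levels = -120)
  expect_true(all(v$intensities[v$mask] == -120))
  expect_true(all(v$intensities[!v$mask] == -800))
})

test_that("sphere mask equals the lattice-ball enumeration", {
  expect_identical(oracle_ball_count(3), 123L)
  v <- make_ball_volume(radius = 3)
  expect_identical(sum(v$mask), 123L)
  # anisotropic spacing
  spec <- phantom_spec(grid_shape = c(15, 15, 11), spacing_mm = c(1, 1, 2),
                       nodule_radius_mm = 3, n_plateaus = 1,
                       plateau_levels = 0, noise_sd = 0)
  v2 <- generate_phantom(spec, seed = 1)
  expect_identical(sum(v2$mask), oracle_ball_count(3, c(1, 1, 2)))
})

test_that("three noiseless plateaus give exactly three in-mask values", {
  v <- make_ball_volume(radius = 6, levels = c(-400, -150, 100))
  expect_identical(length(unique(v$intensities[v$mask])), 3L)
  expect_setequal(sort(unique(v$truth[v$mask])), 1:3)
})

test_that("a nodule that does not fit in the grid is rejected", {
  expect_error(phantom_spec(grid_shape = c(10, 10, 10),
                            nodule_radius_mm = 8, n_plateaus = 1,
                            plateau_levels = 0),
               "exceeds")
  expect_error(phantom_spec(n_plateaus = 2, plateau_levels = c(5, 5)),
               "distinct")
})

test_that("same seed reproduces a bit-identical cohort", {
  cs <- cohort_spec(n_samples = 4, seed = 42,
                    phantom = phantom_spec(grid_shape = c(20, 20, 20),
                                           nodule_radius_mm = 5,
                                           noise_sd = 15))
  c1 <- generate_cohort(cs)
  c2 <- generate_cohort(cs)
  expect_identical(c1$labels, c2$labels)
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$latent, c2$latent)
  expect_identical(c1$samples[[2]]$volume$intensities,
                   c2$samples[[2]]$volume$intensities)
})

test_that("empirical mutant fraction matches the target (binomial CI)", {
  cs <- cohort_spec(n_samples = 1000, mutant_fraction = 0.638, seed = 7)
  co <- generate_cohort(cs, volumes = FALSE)
  f <- mean(co$labels == "mutant")
  ci <- stats::binom.test(round(0.638 * 1000), 1000)$conf.int
  margin <- 1.2 * (ci[2] - ci[1]) / 2
  expect_lt(abs(f - 0.638), margin + 0.02)
})

test_that("class-conditional smoking reproduces the planted odds ratio", {
  cs <- cohort_spec(n_samples = 3000, seed = 11,
                    smoking_prob_by_class = c(0.228, 0.474))
  co <- generate_cohort(cs, volumes = FALSE)
  tab <- table(co$clinical$smoking, co$clinical$egfr)
  or_hat <- (tab["yes", "mutant"] / tab["no", "mutant"]) /
    (tab["yes", "wild-type"] / tab["no", "wild-type"])
  or_true <- (0.228 / 0.772) / (0.474 / 0.526)
  expect_lt(abs(or_hat - or_true) / or_true, 0.20)
})

test_that("the designated latent feature is shifted by d within-class SDs", {
  cs <- cohort_spec(n_samples = 2000, effect_size_d = 1.5, seed = 3,
                    contrast_mean = 250, contrast_sd = 50)
  co <- generate_cohort(cs, volumes = FALSE)
  mu_m <- mean(co$latent$contrast[co$latent$egfr == "mutant"])
  mu_w <- mean(co$latent$contrast[co$latent$egfr == "wild-type"])
  expect_lt(abs((mu_m - mu_w) / 50 - 1.5), 0.15)
})

test_that("degenerate single-class draws error when resampling is off", {
  cs <- cohort_spec(n_samples = 3, mutant_fraction = 1e-6, seed = 1,
                    resample_degenerate = FALSE)
  expect_error(generate_cohort(cs, volumes = FALSE), "degenerate")
})

test_that("cohort writes NIfTI pairs, clinical table and manifest", {
  dir <- withr::local_tempdir()
  cs <- cohort_spec(n_samples = 2, seed = 5,
                    phantom = phantom_spec(grid_shape = c(18, 18, 18),
                                           nodule_radius_mm = 4))
  co <- generate_cohort(cs)
  mf <- write_cohort(co, dir)
  expect_true(all(file.exists(mf$image, mf$mask)))
  expect_true(file.exists(file.path(dir, "clinical.csv")))
  rt <- read_annotated_volume(mf$image[1], mf$mask[1])
  expect_equal(rt$intensities, co$samples[[1]]$volume$intensities,
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(rt$mask, co$samples[[1]]$volume$mask)
  expect_equal(rt$spacing, c(1, 1, 1))
})

test_that("tabular feature cohort has the planted Bayes separation", {
  sim <- simulate_feature_table(5000, d = 1, n_noise = 2, seed = 9)
  a <- roc_auc(sim$features$signal, sim$labels)$auc
  expect_lt(abs(a - pnorm(1 / sqrt(2))), 0.03)
})
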