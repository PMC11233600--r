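test_that("texture bank has the five families summing to 75 features", {
  r <- random_small_volume(1)
  tx <- texture_features(r$vol)
  fam <- attr(tx, "family")
  expect_identical(length(tx), 75L)
  expect_identical(as.vector(table(fam)[c("glcm", "glrlm", "glszm", "gldm",
                                          "ngtdm")]),
                   c(24L, 16L, 16L, 14L, 5L))
  expect_true(all(is.finite(tx)))
})

test_that("single-direction GLCM of a two-band image has zero contrast", {
  arr <- array(c(1, 1, 2, 2), c(2, 2, 1)) * 25
  mask <- array(TRUE, c(2, 2, 1))
  lev <- habitomics:::level_array(arr, mask, discretization())
  idx <- which(mask); ijk <- arrayInd(idx, dim(arr))
  P <- habitomics:::glcm_matrix(lev, dim(arr), idx, ijk, c(1, 0, 0),
                                max(lev, na.rm = TRUE))
  f <- habitomics:::glcm_features_from_matrix(P)
  expect_equal(unname(f["contrast"]), 0)
  expect_equal(unname(f["maximum_probability"]), 0.5)
})

test_that("constant regions take the documented degenerate conventions", {
  vol <- annotated_volume(array(100, c(4, 4, 4)), c(1, 1, 1),
                          array(TRUE, c(4, 4, 4)))
  tx <- texture_features(vol)
  expect_equal(unname(tx["glcm_contrast"]), 0)
  expect_equal(unname(tx["glcm_correlation"]), 1)
  expect_equal(unname(tx["ngtdm_coarseness"]),
               habitomics:::.ngtdm_coarseness_cap)
  expect_equal(unname(tx["glszm_zone_percentage"]), 1 / 64)  # one zone
  expect_true(all(is.finite(tx)))
})

test_that("every texture feature equals its brute-force oracle on random images", {
  for (s in 1:20) {
    r <- random_small_volume(s, d = c(5, 5, 5))
    disc <- discretization()
    got_glcm <- habitomics:::glcm_features(r$arr, r$mask, disc)
    expect_equal(got_glcm, oracle_glcm(r$arr, r$mask), tolerance = 1e-9)
    got_glrlm <- habitomics:::glrlm_features(r$arr, r$mask, disc)
    expect_equal(got_glrlm, oracle_glrlm(r$arr, r$mask), tolerance = 1e-9)
    got_glszm <- habitomics:::glszm_features(r$arr, r$mask, disc)
    expect_equal(got_glszm, oracle_glszm(r$arr, r$mask), tolerance = 1e-9)
    got_gldm <- habitomics:::gldm_features(r$arr, r$mask, disc)
    expect_equal(got_gldm, oracle_gldm(r$arr, r$mask), tolerance = 1e-9)
    got_ngtdm <- habitomics:::ngtdm_features(r$arr, r$mask, disc)
    expect_equal(got_ngtdm, oracle_ngtdm(r$arr, r$mask), tolerance = 1e-9)
  }
})

test_that("the texture bank is deterministic across runs", {
  r <- random_small_volume(5, d = c(6, 6, 6))
  expect_identical(texture_features(r$vol), texture_features(r$vol))
})
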