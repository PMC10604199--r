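test_that("SUVR of a constant PET volume is 1 for every region", {
  pet <- volume3d(array(3.7, c(6, 6, 6)))
  pr <- compute_suvr(pet, toy_atlas)
  expect_equal(unname(pr$values), rep(1, 3), tolerance = 1e-12)
})

test_that("toy-atlas SUVR matches the hand-computed mean ratio", {
  pr <- compute_suvr(toy_pet(region1 = 4, cereb = 2), toy_atlas)
  expect_equal(unname(pr$values[["1"]]), 2, tolerance = 1e-12)
  expect_equal(unname(pr$values[["3"]]), 1, tolerance = 1e-12)
  expect_equal(pr$reference_mean, 2, tolerance = 1e-12)
})

test_that("SUVR is invariant under global positive rescaling", {
  set.seed(42)
  arr <- array(abs(rnorm(6^3)) + 0.5, c(6, 6, 6))
  base <- compute_suvr(volume3d(arr), toy_atlas)$values
  for (sc in c(10, 0.03, exp(rnorm(3)))) {
    scaled <- compute_suvr(volume3d(arr * sc), toy_atlas)$values
    expect_equal(scaled, base, tolerance = 1e-12)
  }
})

test_that("cerebellar self-SUVR is exactly 1 and bad references error", {
  set.seed(7)
  for (i in 1:5) {
    arr <- array(abs(rnorm(6^3)) + 0.2, c(6, 6, 6))
    pr <- compute_suvr(volume3d(arr), toy_atlas)
    expect_equal(unname(pr$values[["3"]]), 1, tolerance = 1e-12)
  }
  expect_error(compute_suvr(volume3d(array(0, c(6, 6, 6))), toy_atlas),
               "positive")
})

test_that("suvr_normalize divides by the cerebellar mean voxel-wise", {
  pet <- toy_pet(cereb = 2)
  nv <- suvr_normalize(pet, toy_atlas)
  expect_equal(nv$data, pet$data / 2, tolerance = 1e-12)
})

test_that("ROI feature vector has length R(R-1)/2 and row-major order", {
  expect_length(compute_roi_matrix(c(a = 1, b = 2)), 1)
  expect_length(compute_roi_matrix(setNames(runif(90) + 0.5, 1:90)), 4005)
  expect_error(compute_roi_matrix(c(a = 1)), "at least 2")
  # hand case: values (1, 2, 4); log-ratio upper triangle row-major:
  # (1,2), (1,3), (2,3) -> log(1/2), log(1/4), log(2/4)
  v <- compute_roi_matrix(c(1, 2, 4))
  expect_equal(as.numeric(v), c(log(1 / 2), log(1 / 4), log(2 / 4)),
               tolerance = 1e-12)
  # identical regional values -> all zeros (log of unit ratios)
  expect_equal(as.numeric(compute_roi_matrix(rep(2.5, 8))), rep(0, 28))
})

test_that("cube extraction tiles, pads and orders deterministically", {
  v <- array(rnorm(48^3), c(48, 48, 48))
  cs <- extract_cubes(v)
  expect_length(cs$cubes, 1)
  expect_equal(unname(as.integer(cs$origins[1, ])), c(1L, 1L, 1L))
  expect_identical(cs$cubes[[1]], v)

  v2 <- array(rnorm(96 * 48 * 48), c(96, 48, 48))
  cs2 <- extract_cubes(v2)
  expect_length(cs2$cubes, 2)
  expect_equal(unname(as.matrix(cs2$origins)), rbind(c(1, 1, 1), c(49, 1, 1)),
               ignore_attr = TRUE)

  v3 <- array(rnorm(50 * 48 * 48), c(50, 48, 48))
  cs3 <- extract_cubes(v3, pad_value = 0)
  expect_length(cs3$cubes, 2)
  second <- cs3$cubes[[2]]
  expect_true(all(second[3:48, , ] == 0))   # 46 of 48 planes are padding
  expect_identical(second[1:2, , ], v3[49:50, , ])
})

test_that("cube tiling conserves voxel totals for awkward shapes", {
  set.seed(3)
  for (d in list(c(48, 48, 48), c(50, 48, 48), c(96, 48, 50), c(49, 51, 48))) {
    v <- array(rnorm(prod(d)), d)
    cs <- extract_cubes(v)
    expect_equal(sum(vapply(cs$cubes, sum, numeric(1))), sum(v), tolerance = 1e-8)
    expect_equal(length(cs$cubes), prod(ceiling(d / 48)))
  }
})

test_that("clinical standardisation z-scores with training stats only", {
  mk <- function(age, edu) clinical_vector(1, 1, age, 0, edu)
  stats <- cohort_stats(list(mk(30, 10), mk(40, 14), mk(50, 12)))
  v <- standardize_clinical(mk(40, 12), stats)
  expect_equal(v, c(1, 1, 0, 0, 0), tolerance = 1e-12)  # at the training means
  expect_length(standardize_clinical(clinical_vector(1, 1, 40, 0, 12, 1), stats), 6)
  expect_equal(standardize_clinical(clinical_vector(1, 1, 40, 0, 12, 1), stats)[6], 1)

  # zero-variance fallback: centre only
  same <- cohort_stats(list(mk(40, 12), mk(40, 12)))
  expect_equal(standardize_clinical(mk(40, 12), same)[3], 0)
  expect_equal(standardize_clinical(mk(43, 12), same)[3], 3)
})
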