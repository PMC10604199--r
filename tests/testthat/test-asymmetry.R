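test_that("mirror-symmetric volumes give all-zero difference cubes", {
  set.seed(1)
  half <- array(rnorm(48 * 48 * 48), c(48, 48, 48))
  arr2 <- array(0, c(96, 48, 48))
  arr2[1:48, , ] <- half
  arr2[96:49, , ] <- half
  pairs2 <- split_and_pair(volume3d(arr2))
  expect_length(pairs2, 1)
  expect_true(all(pairs2[[1]]$diff_cube == 0))
})

test_that("hand-built hemispheres subtract elementwise and zeros stay zero", {
  arr <- array(0, c(96, 48, 48))
  arr[1:48, , ] <- 2; arr[49:96, , ] <- 1
  pairs <- split_and_pair(volume3d(arr))
  expect_true(all(pairs[[1]]$diff_cube == 1))
  expect_true(all(pairs[[1]]$left_cube == 2))
  expect_true(all(pairs[[1]]$right_cube_mirrored == 1))

  zero <- split_and_pair(volume3d(array(0, c(96, 48, 48))))
  expect_true(all(vapply(zero, function(p) all(p$diff_cube == 0), logical(1))))
})

test_that("swapping hemispheres negates every difference cube exactly", {
  set.seed(11)
  vol <- volume3d(array(rnorm(96 * 48 * 48), c(96, 48, 48)))
  pairs <- split_and_pair(vol)
  swapped <- split_and_pair(mirror_lr(vol))
  for (i in seq_along(pairs))
    expect_identical(swapped[[i]]$diff_cube, -pairs[[i]]$diff_cube)
})

test_that("odd widths drop the midline plane", {
  set.seed(2)
  arr <- array(rnorm(97 * 48 * 48), c(97, 48, 48))
  pairs <- split_and_pair(volume3d(arr))
  expect_identical(pairs[[1]]$left_cube, arr[1:48, , ])
  expect_identical(pairs[[1]]$right_cube_mirrored, arr[97:50, , ])
  expect_error(split_and_pair(volume3d(array(0, c(1, 4, 4)))), "width")
})

test_that("subject flags follow the documented aggregation rules", {
  expect_identical(aggregate_subject_flag(c(0.9, 0.8, 0.1))$subject_flag, 1L)
  expect_identical(aggregate_subject_flag(c(0.9, 0.1, 0.1))$subject_flag, 0L)
  expect_identical(aggregate_subject_flag(c(0, 0, 0))$subject_flag, 0L)
  expect_identical(aggregate_subject_flag(c(0, 0, 0), rule = "any")$subject_flag, 0L)
  expect_identical(aggregate_subject_flag(0.6, rule = "any")$subject_flag, 1L)
  expect_identical(aggregate_subject_flag(c(0.6, 0.1, 0.1), rule = "any")$subject_flag, 1L)
  expect_error(aggregate_subject_flag(numeric(0)), "no pair scores")
  expect_error(aggregate_subject_flag(c(0.5, 1.2)), "probabilities")
})

test_that("pair classifier training is seeded-reproducible and validates labels", {
  set.seed(5)
  mk_pair <- function(label, amp) {
    d <- array(rnorm(12^3, 0, 0.1), c(12, 12, 12))
    if (label == 1) d[4:8, 4:8, 4:8] <- d[4:8, 4:8, 4:8] + amp
    structure(list(left_cube = d, right_cube_mirrored = array(0, c(12, 12, 12)),
                   diff_cube = d, origin = c(1, 1, 1), subject_label = label),
              class = "symmetric_cube_pair")
  }
  pairs <- c(lapply(1:8, function(i) mk_pair(1, 1)),
             lapply(1:8, function(i) mk_pair(0, 0)))
  cfg <- asym_config(epochs = 3, cube_size = 12L, seed = 99)
  clf1 <- train_asymmetry_classifier(pairs, cfg)
  clf2 <- train_asymmetry_classifier(pairs, cfg)
  expect_identical(clf1$loss_trace, clf2$loss_trace)
  s1 <- score_pairs(clf1, pairs)
  s2 <- score_pairs(clf2, pairs)
  expect_identical(s1, s2)
  expect_true(all(s1 >= 0 & s1 <= 1))
  # a strong planted difference is separable on the training pairs
  labs <- vapply(pairs, function(p) p$subject_label, numeric(1))
  expect_gte(roc_auc(s1, labs), 0.9)

  only_ep <- pairs[1:8]
  expect_error(train_asymmetry_classifier(only_ep, cfg), "both classes")
  nolab <- pairs
  nolab[[1]]$subject_label <- NA_integer_
  expect_error(train_asymmetry_classifier(nolab, cfg), "label")
})
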