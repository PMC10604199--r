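test_that("model building respects channel subsets and fails on none", {
  cfg <- tiny_model_config()
  m <- build_model(cfg, "clinical", clin_len = 5L)
  expect_null(m$branches); expect_null(m$trunk)
  p <- epifuse:::forward_subject(m, list(label = 1, clin = rnorm(5)))$prob
  expect_true(p >= 0 && p <= 1)

  m2 <- build_model(cfg, c("mri", "pet"))
  expect_null(m2$clin_branch)
  expect_named(m2$branches, c("mri", "pet"))
  expect_error(build_model(cfg, character(0)), "at least one")
})

test_that("builds with the same seed have identical parameters", {
  cfg <- tiny_model_config()
  set.seed(31); m1 <- build_model(cfg, c("mri", "pet", "clinical"))
  set.seed(31); m2 <- build_model(cfg, c("mri", "pet", "clinical"))
  expect_identical(epifuse:::model_fingerprint(m1), epifuse:::model_fingerprint(m2))
  set.seed(32); m3 <- build_model(cfg, c("mri", "pet", "clinical"))
  expect_false(identical(epifuse:::model_fingerprint(m1),
                         epifuse:::model_fingerprint(m3)))
})

test_that("training is reproducible, separates a strong cohort, and validates", {
  prep <- tiny_prepared(n = 8, signal = 3)
  cfg <- tiny_model_config()
  tcfg <- train_config(epochs = 6, head_warmup = 800, seed = 21)
  set.seed(21); m <- build_model(cfg, c("mri", "pet", "clinical"))
  r1 <- train_model(m, prep, tcfg)
  set.seed(21); m <- build_model(cfg, c("mri", "pet", "clinical"))
  r2 <- train_model(m, prep, tcfg)
  expect_identical(r1$loss_trace, r2$loss_trace)

  pr1 <- predict_model(r1$model, prep)
  pr2 <- predict_model(r2$model, prep)
  expect_identical(pr1$probability, pr2$probability)

  labs <- vapply(prep, function(s) s$label, integer(1))
  expect_equal(roc_auc(pr1$probability, labs), 1)
  expect_equal(pr1$predicted_label, labs)   # training accuracy 1 when separable
  # the trained model fits the training set better than a fresh one
  set.seed(21); fresh <- build_model(cfg, c("mri", "pet", "clinical"))
  pr0 <- predict_model(fresh, prep)
  bce <- function(p, y) mean(-(y * log(pmin(pmax(p, 1e-7), 1 - 1e-7)) +
                                 (1 - y) * log(1 - pmin(pmax(p, 1e-7), 1 - 1e-7))))
  expect_lt(bce(pr1$probability, labs), bce(pr0$probability, labs))

  ep_only <- prep[labs == 1]
  expect_error(train_model(m, ep_only, tcfg), "both classes")
})

test_that("probabilities stay in [0,1] for arbitrary finite inputs", {
  cfg <- tiny_model_config()
  set.seed(4); m <- build_model(cfg, c("mri", "pet", "clinical"))
  set.seed(5)
  for (i in 1:20) {
    sub <- list(label = 1L,
                mri = list(array(rnorm(8^3, sd = 10^runif(1, -3, 3)), c(8, 8, 8))),
                pet = list(array(rnorm(8^3, sd = 10^runif(1, -3, 3)), c(8, 8, 8))),
                clin = rnorm(5, sd = 10^runif(1, -2, 2)))
    p <- epifuse:::forward_subject(m, sub)$prob
    expect_true(is.finite(p) && p >= 0 && p <= 1)
  }
})

test_that("prediction uses the >= 0.5 tie convention and contract checks fire", {
  cfg <- tiny_model_config()
  set.seed(6); m <- build_model(cfg, "clinical", clin_len = 5L)
  # zero the final layer so the logit is exactly 0 -> probability exactly 0.5
  m$head[[5]]$W[] <- 0; m$head[[5]]$b[] <- 0
  pr <- predict_model(m, list(list(subject_id = "s", label = 1, clin = rnorm(5))))
  expect_equal(pr$probability, 0.5)
  expect_identical(pr$predicted_label, 1L)

  expect_error(epifuse:::forward_subject(m, list(label = 1, clin = rnorm(7))),
               "length")
  m2 <- build_model(cfg, "pet")
  expect_error(
    epifuse:::forward_subject(m2, list(label = 1,
                                       pet = list(array(0, c(4, 4, 4))))),
    "cube size")
})

test_that("multiple cubes per subject average their logits", {
  cfg <- tiny_model_config()
  set.seed(8); m <- build_model(cfg, "pet")
  cube <- array(rnorm(8^3), c(8, 8, 8))
  p1 <- epifuse:::forward_subject(m, list(label = 1, pet = list(cube)))
  p2 <- epifuse:::forward_subject(m, list(label = 1, pet = list(cube, cube)))
  expect_equal(p1$prob, p2$prob, tolerance = 1e-12)   # duplicated cube, same mean
  expect_length(p2$logits, 2)
})
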