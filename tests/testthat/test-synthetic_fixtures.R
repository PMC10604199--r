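test_that("phantom atlas construction is deterministic with mirrored targets", {
  a1 <- make_phantom_atlas(c(48, 48, 48), R = 4)
  a2 <- make_phantom_atlas(c(48, 48, 48), R = 4)
  expect_identical(a1$labels, a2$labels)
  expect_identical(sort(unique(as.integer(a1$labels[a1$labels > 0]))), 1:4)
  for (r in 1:4) expect_gt(sum(a1$labels == r), 0)

  # reflecting about the midplane maps left target onto right target exactly
  flipped <- a1$labels[rev(seq_len(48)), , ]
  expect_identical(flipped == 1L, a1$labels == 2L)
  expect_identical(flipped == 2L, a1$labels == 1L)
  # cerebellum and filler bands are midline-symmetric
  expect_identical(flipped == 3L, a1$labels == 3L)

  expect_error(make_phantom_atlas(c(48, 48, 48), R = 2), "R must be >= 3")
})

test_that("cohort generation is a deterministic function of spec and seed", {
  atlas <- make_phantom_atlas(c(48, 48, 48), R = 6)
  spec <- phantom_spec(dims = c(48, 48, 48), n_ep = 2, n_hc = 2, seed = 77)
  c1 <- generate_cohort(spec, atlas, keep_in_memory = TRUE)
  c2 <- generate_cohort(spec, atlas, keep_in_memory = TRUE)
  expect_identical(as.data.frame(c1$manifest)[, -(3:4)],
                   as.data.frame(c2$manifest)[, -(3:4)])
  expect_identical(c1$truth, c2$truth)
  for (id in names(c1$subjects)) {
    expect_identical(c1$subjects[[id]]$mri$data, c2$subjects[[id]]$mri$data)
    expect_identical(c1$subjects[[id]]$pet$data, c2$subjects[[id]]$pet$data)
  }
  spec2 <- phantom_spec(dims = c(48, 48, 48), n_ep = 2, n_hc = 2, seed = 78)
  c3 <- generate_cohort(spec2, atlas, keep_in_memory = TRUE)
  expect_false(identical(c1$subjects[[1]]$mri$data, c3$subjects[[1]]$mri$data))
})

test_that("ground truth matches the manifest and HC rows carry zero effects", {
  ph <- small_phantom()
  truth <- ground_truth(ph$cohort)
  man <- ph$cohort$manifest
  expect_equal(nrow(truth), ph$spec$n_ep + ph$spec$n_hc)
  expect_identical(truth$subject_id, man$subject_id)
  expect_identical(truth$label, man$label)
  hc <- truth[truth$label == 0, ]
  expect_true(all(hc$atrophy_frac == 0))
  expect_true(all(hc$hypometab_frac == 0))
  expect_true(all(hc$lateralization == "none"))
  ep <- truth[truth$label == 1, ]
  expect_true(all(ep$lateralization %in% c("left", "right")))
  expect_error(ground_truth(list(a = 1)), "provenance")
})

test_that("planted hypometabolism shows up in SUVR at about the planted size", {
  ph <- small_phantom()
  truth <- ground_truth(ph$cohort)
  frac <- ph$spec$hypometab_frac
  for (i in which(truth$label == 1)) {
    pr <- compute_suvr(ph$cohort$subjects[[truth$subject_id[i]]]$pet, ph$atlas)
    affected <- if (truth$lateralization[i] == "left") "1" else "2"
    other <- setdiff(c("1", "2"), affected)
    ratio <- pr$values[[affected]] / pr$values[[other]]
    # anatomical jitter + noise blur the planted contrast a little
    expect_equal(unname(ratio), 1 - frac, tolerance = 0.12)
    expect_lt(pr$values[[affected]], pr$values[[other]])
  }
  for (i in which(truth$label == 0)) {
    pr <- compute_suvr(ph$cohort$subjects[[truth$subject_id[i]]]$pet, ph$atlas)
    expect_equal(unname(pr$values[["1"]] / pr$values[["2"]]), 1, tolerance = 0.1)
  }
})

test_that("phantom volumes are finite, brain-shaped and written to disk", {
  ph <- small_phantom()
  s <- ph$cohort$subjects[[1]]
  expect_true(all(is.finite(s$mri$data)))
  expect_true(all(is.finite(s$pet$data)))
  # brain centre is bright, far corner is background + noise
  expect_gt(s$mri$data[24, 24, 24], 0.5)
  expect_lt(abs(s$mri$data[1, 1, 1]), 0.5)
  files <- list.files(ph$cohort$out_dir)
  expect_true(all(c("manifest.csv", "ground_truth.csv", "atlas.nii") %in% files))
  expect_equal(sum(grepl("_mri\\.nii$", files)), 10)
})

test_that("spec validation rejects out-of-range effect sizes", {
  expect_error(phantom_spec(atrophy_frac = 1.2), "atrophy_frac")
  expect_error(phantom_spec(symptom_prob_ep = -0.1), "symptom_prob_ep")
  expect_warning(phantom_spec(dims = c(32, 32, 32)), "48")
})
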