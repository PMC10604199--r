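# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the unit suite stays fast.

# a toy 6x6x6 atlas: region 1 (two voxels), region 2 (two voxels),
# cerebellar region 3 (two voxels); the rest background
toy_atlas <- local({
  lab <- array(0L, c(6, 6, 6))
  lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L
  lab[4, 4, 4] <- 2L; lab[5, 4, 4] <- 2L
  lab[1, 6, 6] <- 3L; lab[2, 6, 6] <- 3L
  parcellation_atlas(lab, cerebellar_ids = 3L)
})

toy_pet <- function(region1 = 4, region2 = 3, cereb = 2, bg = 1) {
  arr <- array(bg, c(6, 6, 6))
  arr[toy_atlas$labels == 1L] <- region1
  arr[toy_atlas$labels == 2L] <- region2
  arr[toy_atlas$labels == 3L] <- cereb
  volume3d(arr)
}

# small phantom cohort at 48^3, cached across tests
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- phantom_spec(dims = c(48, 48, 48), n_ep = 5, n_hc = 5, seed = 404)
      atlas <- make_phantom_atlas(c(48, 48, 48), R = 6)
      cache <<- list(
        spec = spec, atlas = atlas,
        cohort = generate_cohort(spec, atlas, keep_in_memory = TRUE))
    }
    cache
  }
})

# a minimal prepared-subject list for fusion-model unit tests: tiny cubes so
# a forward/backward pass costs microseconds
tiny_prepared <- function(n = 6, cube = 8L, seed = 1, signal = 2) {
  set.seed(seed)
  labs <- rep(c(1L, 0L), length.out = n)
  lapply(seq_len(n), function(i) {
    base <- array(rnorm(cube^3), rep(cube, 3))
    if (labs[i] == 1L) base[1:3, 1:3, 1:3] <- base[1:3, 1:3, 1:3] + signal
    list(subject_id = paste0("S", i), label = labs[i],
         mri = list(base), pet = list(base * 0.5),
         clin = c(labs[i], labs[i], rnorm(1), rbinom(1, 1, 0.5), rnorm(1)))
  })
}

tiny_model_config <- function(cube = 8L)
  model_config(widths = c(2, 3, 4), trunk_widths = c(4, 4), clin_widths = c(2, 2),
               head_hidden = 4, dropout = 0.2, cube_size = cube)
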