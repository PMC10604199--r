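# Procedural brain phantoms: ellipsoidal head, mirrored "hippocampal" target
# structures, a midline cerebellar reference, planted MRI atrophy and
# lateralised PET hypometabolism. These emulate the statistical structure of
# an MTLE cohort (not MRI/PET physics) so every pipeline stage has ground
# truth to recover.

#' Phantom cohort specification
#'
#' Defaults describe the emulated study conditions: 15 patients and 15
#' age-matched controls, 96^3 template-space volumes, hippocampal atrophy
#' with compensatory intensity increase in patient MRI, a 30% unilateral SUV
#' reduction in patient PET, symptom flags at 0.8 (EP) vs 0.2 (HC), and mild
#' additive Gaussian noise.
#'
#' @param dims volume dimensions in voxels.
#' @param n_ep,n_hc numbers of patients and controls.
#' @param atrophy_frac fractional volume reduction of the target structure in
#'   EP MRI (in `[0, 1)`).
#' @param hypometab_frac fractional SUV reduction on the lateralised side in
#'   EP PET (in `[0, 1)`).
#' @param lateralization `"left"`, `"right"` or `"random"` per patient.
#' @param mri_negative_frac fraction of patients whose MRI shows no
#'   structural effect (MRI-negative MTLE); their atrophy is set to zero.
#' @param pet_negative_frac fraction of patients whose PET shows no
#'   hypometabolism; drawn independently of MRI negativity. Nonzero values
#'   make the imaging channels carry complementary rather than redundant
#'   evidence.
#' @param symptom_prob_ep,symptom_prob_hc Bernoulli rates for each symptom
#'   flag by class.
#' @param noise_sd additive Gaussian intensity noise.
#' @param anat_jitter per-subject anatomical variability: standard deviation
#'   of structure-centre displacement, as a fraction of the volume dimension
#'   (mirror-symmetric, so controls stay bilaterally symmetric up to noise).
#' @param size_jitter per-subject log-scale standard deviation of structure
#'   size.
#' @param seed RNG seed; the whole cohort is a deterministic function of the
#'   spec.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(dims = c(96, 96, 96), n_ep = 15L, n_hc = 15L,
                         atrophy_frac = 0.3, hypometab_frac = 0.3,
                         lateralization = c("random", "left", "right"),
                         mri_negative_frac = 0, pet_negative_frac = 0,
                         symptom_prob_ep = 0.8, symptom_prob_hc = 0.2,
                         noise_sd = 0.05, anat_jitter = 0.01,
                         size_jitter = 0.03, seed = 1L) {
  lateralization <- match.arg(lateralization)
  stopifnot(atrophy_frac >= 0, atrophy_frac < 1,
            hypometab_frac >= 0, hypometab_frac < 1,
            mri_negative_frac >= 0, mri_negative_frac <= 1,
            pet_negative_frac >= 0, pet_negative_frac <= 1,
            symptom_prob_ep >= 0, symptom_prob_ep <= 1,
            symptom_prob_hc >= 0, symptom_prob_hc <= 1,
            noise_sd >= 0, n_ep >= 1, n_hc >= 1)
  dims <- as.integer(dims)
  if (any(dims < 48L))
    warning("dims below 48 voxels: cubes will be mostly padding")
  structure(list(dims = dims, n_ep = as.integer(n_ep), n_hc = as.integer(n_hc),
                 atrophy_frac = atrophy_frac, hypometab_frac = hypometab_frac,
                 lateralization = lateralization,
                 mri_negative_frac = mri_negative_frac,
                 pet_negative_frac = pet_negative_frac,
                 symptom_prob_ep = symptom_prob_ep,
                 symptom_prob_hc = symptom_prob_hc,
                 noise_sd = noise_sd, anat_jitter = anat_jitter,
                 size_jitter = size_jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

coord_grids <- function(dims) {
  list(x = array(rep(seq_len(dims[1]), times = dims[2] * dims[3]), dims),
       y = array(rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]), dims),
       z = array(rep(seq_len(dims[3]), each = dims[1] * dims[2]), dims))
}

in_ellipsoid <- function(g, center, semi) {
  ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2 <= 1
}

phantom_geometry <- function(dims) {
  mid <- (dims[1] + 1) / 2
  hipp_l_center <- c(0.30 * dims[1], 0.50 * dims[2], 0.45 * dims[3])
  list(brain = list(center = c(mid, 0.50 * dims[2], 0.50 * dims[3]),
                    semi = 0.45 * dims),
       hipp_l = list(center = hipp_l_center,
                     semi = c(0.10, 0.14, 0.10) * dims),
       hipp_r = list(center = c(dims[1] + 1 - hipp_l_center[1],
                                hipp_l_center[2], hipp_l_center[3]),
                     semi = c(0.10, 0.14, 0.10) * dims),
       cereb = list(center = c(mid, 0.30 * dims[2], 0.18 * dims[3]),
                    semi = c(0.22, 0.14, 0.10) * dims))
}

#' Build a phantom parcellation atlas
#'
#' Regions: 1 = left target ("hippocampal") structure, 2 = its exact mirror
#' image on the right, 3 = a midline-symmetric cerebellar reference, and
#' regions 4..R filler bands splitting the remaining brain-mask voxels along
#' the inferior-superior axis. The construction is deterministic and mirror
#' symmetry of the paired structures is exact by design (the mirror map only
#' touches the left-right axis, and every other structure is centred on the
#' midplane).
#'
#' @param dims volume dimensions.
#' @param R total region count, at least 3 (left target, right target,
#'   cerebellum).
#' @param seed accepted for interface uniformity; the construction draws no
#'   random numbers.
#' @return A [parcellation_atlas()] carrying the phantom geometry needed by
#'   [generate_cohort()].
#' @export
make_phantom_atlas <- function(dims = c(96, 96, 96), R = 6L, seed = 1L) {
  dims <- as.integer(dims)
  R <- as.integer(R)
  if (R < 3L) stop("R must be >= 3 (left/right target + cerebellum)", call. = FALSE)
  geom <- phantom_geometry(dims)
  g <- coord_grids(dims)
  lab <- array(0L, dims)
  brain <- in_ellipsoid(g, geom$brain$center, geom$brain$semi)
  hl <- in_ellipsoid(g, geom$hipp_l$center, geom$hipp_l$semi)
  hr <- in_ellipsoid(g, geom$hipp_r$center, geom$hipp_r$semi)
  cb <- in_ellipsoid(g, geom$cereb$center, geom$cereb$semi)
  if (!any(hl) || !any(hr) || !any(cb))
    stop("phantom structures do not fit the requested dims", call. = FALSE)
  lab[hl] <- 1L
  lab[hr] <- 2L
  lab[cb & lab == 0L] <- 3L
  rest <- brain & lab == 0L
  if (R == 4L) {
    lab[rest] <- 4L
  } else if (R > 4L) {
    zb <- cut(g$z[rest], breaks = R - 3L, labels = FALSE)
    lab[rest] <- 3L + zb
  }
  atlas <- parcellation_atlas(lab, region_ids = seq_len(max(lab)),
                              cerebellar_ids = 3L)
  atlas$geom <- geom
  atlas$dims <- dims
  atlas
}

draw_clinical <- function(p_sympt) {
  list(symptom_abdominal = stats::rbinom(1, 1, p_sympt),
       symptom_fear = stats::rbinom(1, 1, p_sympt),
       age = round(min(max(stats::rnorm(1, 30, 8), 18), 65)),
       sex = stats::rbinom(1, 1, 0.5),
       education = round(min(max(stats::rnorm(1, 12, 3), 6), 20)))
}

# Per-subject anatomy: template geometry plus mirror-symmetric jitter of
# structure centres and sizes, emulating inter-subject anatomical
# variability and residual registration error. The target pair is displaced
# with mirrored x-offsets and midline structures move only in y/z, so
# control anatomy remains exactly bilaterally symmetric.
jitter_geometry <- function(geom, dims, anat_jitter, size_jitter) {
  cj <- anat_jitter * dims
  dh <- stats::rnorm(3, 0, cj)
  sh <- exp(stats::rnorm(1, 0, size_jitter))
  dcb <- c(0, stats::rnorm(2, 0, cj[2:3]))
  scb <- exp(stats::rnorm(1, 0, size_jitter))
  # the outer brain envelope is fixed: template registration normalises
  # overall brain size/position, leaving only internal structures variable
  list(brain = geom$brain,
       hipp_l = list(center = geom$hipp_l$center + dh, semi = geom$hipp_l$semi * sh),
       hipp_r = list(center = geom$hipp_r$center + c(-dh[1], dh[2], dh[3]),
                     semi = geom$hipp_r$semi * sh),
       cereb = list(center = geom$cereb$center + dcb, semi = geom$cereb$semi * scb))
}

subject_masks <- function(g, geom_s) {
  brain <- in_ellipsoid(g, geom_s$brain$center, geom_s$brain$semi)
  hl <- in_ellipsoid(g, geom_s$hipp_l$center, geom_s$hipp_l$semi)
  hr <- in_ellipsoid(g, geom_s$hipp_r$center, geom_s$hipp_r$semi)
  cb <- in_ellipsoid(g, geom_s$cereb$center, geom_s$cereb$semi)
  brain <- brain | hl | hr | cb
  tl <- in_ellipsoid(g, geom_s$hipp_l$center, 2 * geom_s$hipp_l$semi) & brain & !cb
  tr <- in_ellipsoid(g, geom_s$hipp_r$center, 2 * geom_s$hipp_r$semi) & brain & !cb
  list(brain = brain, hl = hl, hr = hr, cb = cb, tl = tl, tr = tr)
}

phantom_mri <- function(g, geom, brain, hl, hr, side, atrophy, noise_sd) {
  base <- ifelse(brain, 1.0, 0.0)
  base[hl | hr] <- 1.15
  if (!is.na(side) && atrophy > 0) {
    hip <- if (side == "left") geom$hipp_l else geom$hipp_r
    region <- if (side == "left") hl else hr
    shrunk <- in_ellipsoid(g, hip$center, hip$semi * (1 - atrophy)^(1 / 3))
    base[region & !shrunk] <- 0.55             # CSF-like signal where tissue was lost
    base[region & shrunk] <- 1.15 * (1 + 0.5 * atrophy)  # "increased density"
  }
  scale <- exp(stats::rnorm(1, 0, 0.05))
  base * scale + stats::rnorm(length(base), 0, noise_sd)
}

phantom_pet <- function(g, geom, brain, hl, hr, cb, tl, tr, side, hypometab,
                        noise_sd) {
  base <- ifelse(brain, 1.2, 0.0)
  base[hl | hr] <- 1.2
  base[cb] <- 1.0
  if (!is.na(side) && hypometab > 0) {
    # Interictal hypometabolism in MTLE extends beyond the hippocampus over
    # the surrounding temporal lobe: full planted fraction in the target
    # structure, half of it in the mesial-temporal penumbra.
    region <- if (side == "left") hl else hr
    pen <- if (side == "left") tl else tr
    base[pen] <- base[pen] * (1 - hypometab / 2)
    base[region] <- 1.2 * (1 - hypometab)
  }
  scale <- exp(stats::rnorm(1, 0, 0.25))       # dose/weight variation; SUVR removes it
  base * scale + stats::rnorm(length(base), 0, noise_sd)
}

#' Generate a synthetic multi-modal cohort
#'
#' Draws the cohort described by a [phantom_spec()] against a
#' [make_phantom_atlas()]: controls are midline-symmetric up to noise;
#' patients carry lateralised hippocampal atrophy in MRI and hypometabolism
#' in PET on the same side, plus symptom flags at the patient rate. Ages are
#' sampled from a single distribution for both classes (age matching).
#' Volumes are written as NIfTI, the manifest as CSV and the ground truth as
#' CSV; the same spec and seed always reproduce identical files.
#'
#' @param spec a [phantom_spec()].
#' @param atlas a [make_phantom_atlas()] for `spec$dims`.
#' @param out_dir output directory (created if needed).
#' @param keep_in_memory additionally return the `subject_record`s, saving a
#'   disk round-trip.
#' @return A `phantom_cohort`: `manifest` (a `cohort_manifest`), `truth`
#'   (data.frame), `spec`, and `subjects` when `keep_in_memory = TRUE`.
#' @export
generate_cohort <- function(spec, atlas = make_phantom_atlas(spec$dims),
                            out_dir = tempfile("phantom"),
                            keep_in_memory = FALSE) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(atlas, "parcellation_atlas"))
  if (is.null(atlas$geom) || !identical(as.integer(atlas$dims), spec$dims))
    stop("atlas is not a phantom atlas for these dims", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  g <- coord_grids(spec$dims)
  geom <- atlas$geom
  n <- spec$n_ep + spec$n_hc
  ids <- c(sprintf("EP%02d", seq_len(spec$n_ep)),
           sprintf("HC%02d", seq_len(spec$n_hc)))
  labels <- c(rep(1L, spec$n_ep), rep(0L, spec$n_hc))
  rows <- vector("list", n)
  truth <- vector("list", n)
  subjects <- if (keep_in_memory) vector("list", n)
  for (i in seq_len(n)) {
    ep <- labels[i] == 1L
    side <- if (!ep) NA_character_
            else if (spec$lateralization == "random") sample(c("left", "right"), 1)
            else spec$lateralization
    clin <- draw_clinical(if (ep) spec$symptom_prob_ep else spec$symptom_prob_hc)
    atrophy_i <- if (ep && stats::runif(1) >= spec$mri_negative_frac)
      spec$atrophy_frac else 0
    hypometab_i <- if (ep && stats::runif(1) >= spec$pet_negative_frac)
      spec$hypometab_frac else 0
    geom_s <- jitter_geometry(geom, spec$dims, spec$anat_jitter, spec$size_jitter)
    mk <- subject_masks(g, geom_s)
    mri_arr <- array(phantom_mri(g, geom_s, mk$brain, mk$hl, mk$hr, side,
                                 atrophy_i, spec$noise_sd),
                     spec$dims)
    pet_arr <- array(phantom_pet(g, geom_s, mk$brain, mk$hl, mk$hr, mk$cb,
                                 mk$tl, mk$tr, side,
                                 hypometab_i, spec$noise_sd),
                     spec$dims)
    mri <- volume3d(mri_arr)
    pet <- volume3d(pet_arr)
    mri_path <- file.path(out_dir, paste0(ids[i], "_mri.nii"))
    pet_path <- file.path(out_dir, paste0(ids[i], "_pet.nii"))
    write_volume(mri, mri_path)
    write_volume(pet, pet_path)
    rows[[i]] <- data.frame(subject_id = ids[i], label = labels[i],
                            mri_path = mri_path, pet_path = pet_path,
                            symptom_abdominal = clin$symptom_abdominal,
                            symptom_fear = clin$symptom_fear, age = clin$age,
                            sex = clin$sex, education = clin$education)
    truth[[i]] <- data.frame(subject_id = ids[i], label = labels[i],
                             lateralization = ifelse(is.na(side), "none", side),
                             atrophy_frac = atrophy_i,
                             hypometab_frac = hypometab_i)
    if (keep_in_memory)
      subjects[[i]] <- subject_record(ids[i], labels[i], mri, pet,
                                      do.call(clinical_vector, clin))
  }
  manifest <- do.call(rbind, rows)
  truth <- do.call(rbind, truth)
  save_manifest(manifest, file.path(out_dir, "manifest.csv"))
  utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_atlas(atlas, file.path(out_dir, "atlas.nii"))
  class(manifest) <- c("cohort_manifest", "data.frame")
  out <- structure(list(manifest = manifest, truth = truth, spec = spec,
                        out_dir = out_dir),
                   class = "phantom_cohort")
  if (keep_in_memory) {
    names(subjects) <- ids
    out$subjects <- subjects
  }
  out
}

#' Ground truth of a generated cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return Data.frame with per-subject label, lateralization and planted
#'   effect sizes; errors on objects not produced by [generate_cohort()].
#' @export
ground_truth <- function(cohort) {
  if (!inherits(cohort, "phantom_cohort") || is.null(cohort$truth))
    stop("not a cohort generated by this package (no ground-truth provenance)",
         call. = FALSE)
  cohort$truth
}
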