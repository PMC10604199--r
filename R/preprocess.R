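#' Regional SUVR profile
#'
#' Computes the standardized uptake value ratio of every atlas region: the
#' mean PET intensity over the region's voxels divided by the mean intensity
#' over the cerebellar reference voxels. The ratio removes global
#' between-subject scale differences (injected dose, body weight), so SUVR is
#' invariant under multiplying the whole PET image by a positive constant,
#' and the cerebellar reference itself always maps to SUVR 1.
#'
#' @param pet a [volume3d()] PET image (SUV or proportional units).
#' @param atlas a [parcellation_atlas()] with the same dimensions.
#' @return An object of class `suvr_profile`: `values` (named numeric,
#'   region id -> SUVR) and `reference_mean`.
#' @export
compute_suvr <- function(pet, atlas) {
  stopifnot(inherits(pet, "volume3d"), inherits(atlas, "parcellation_atlas"))
  if (!identical(dim(pet$data), dim(atlas$labels)))
    stop("PET and atlas dimensions differ", call. = FALSE)
  lab <- as.integer(atlas$labels)
  vals <- as.numeric(pet$data)
  ref <- mean(vals[lab %in% atlas$cerebellar_ids])
  if (!is.finite(ref) || ref <= 0)
    stop("cerebellar reference mean must be positive, got ", ref, call. = FALSE)
  region_means <- vapply(atlas$region_ids, function(r) {
    sel <- lab == r
    if (!any(sel)) stop("region ", r, " has no voxels in atlas", call. = FALSE)
    mean(vals[sel])
  }, numeric(1))
  suvr <- region_means / ref
  names(suvr) <- as.character(atlas$region_ids)
  structure(list(values = suvr, reference_mean = ref), class = "suvr_profile")
}

#' Voxel-wise SUVR normalisation of a PET volume
#'
#' Divides every voxel by the cerebellar reference mean, so downstream cube
#' inputs are on the dimensionless SUVR scale.
#'
#' @inheritParams compute_suvr
#' @return A [volume3d()] on the SUVR scale.
#' @export
suvr_normalize <- function(pet, atlas) {
  stopifnot(inherits(pet, "volume3d"), inherits(atlas, "parcellation_atlas"))
  if (!identical(dim(pet$data), dim(atlas$labels)))
    stop("PET and atlas dimensions differ", call. = FALSE)
  ref <- mean(pet$data[atlas$labels %in% atlas$cerebellar_ids])
  if (!is.finite(ref) || ref <= 0)
    stop("cerebellar reference mean must be positive, got ", ref, call. = FALSE)
  volume3d(pet$data / ref, spacing = pet$spacing, axis_order = pet$axis_order)
}

#' Write an SUVR profile as CSV
#'
#' @param profile a [compute_suvr()] result.
#' @param path output CSV path (`region_id,suvr`).
#' @return `path`, invisibly.
#' @export
save_suvr <- function(profile, path) {
  stopifnot(inherits(profile, "suvr_profile"))
  utils::write.csv(data.frame(region_id = as.integer(names(profile$values)),
                              suvr = unname(profile$values)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Region-pair feature vector (upper triangle of the ROI matrix)
#'
#' Builds an R x R region-pair matrix from the regional SUVR profile and
#' returns its strict upper triangle flattened in row-major order. The pair
#' matrix used is the log-ratio `M[i,j] = log(SUVR_i / SUVR_j)`, which is
#' antisymmetric, so the strict upper triangle carries all the pairwise
#' information; its length is R(R-1)/2.
#'
#' @param profile a [compute_suvr()] result (or named numeric of regional
#'   values).
#' @return Numeric vector of length `R*(R-1)/2` with attribute `R`.
#' @export
compute_roi_matrix <- function(profile) {
  vals <- if (inherits(profile, "suvr_profile")) profile$values else profile
  vals <- as.numeric(vals)
  R <- length(vals)
  if (R < 2L) stop("need at least 2 regions for a pair matrix", call. = FALSE)
  if (any(vals <= 0)) stop("regional values must be positive for log-ratios",
                           call. = FALSE)
  lv <- log(vals)
  M <- outer(lv, lv, `-`)          # M[i, j] = log(v_i / v_j)
  tM <- t(M)                        # row-major upper tri == col-major lower tri of t(M)
  out <- tM[lower.tri(tM)]
  attr(out, "R") <- R
  out
}

#' Partition a volume into fixed-size cubes
#'
#' Tiles the volume with non-overlapping (at the default stride) cubes of
#' `size^3` voxels, zero-padding the high side of each axis up to the next
#' multiple of the stride, as the network consumes 48-voxel cubes regardless
#' of the original field of view. Cubes are enumerated in lexicographic order
#' of their origins (axis 1 fastest), so the tiling is deterministic.
#'
#' @param vol a [volume3d()] or 3D array.
#' @param size cube edge length in voxels (default 48).
#' @param stride step between cube origins (default `size`, i.e. exact
#'   tiling).
#' @param pad_value fill value for voxels beyond the original volume.
#' @return An object of class `cube_set`: `cubes` (list of `size^3` arrays),
#'   `origins` (matrix of 1-based minimum-corner voxel coordinates),
#'   `dim_padded`, `size`, `stride`, `pad_value`.
#' @export
extract_cubes <- function(vol, size = 48L, stride = size, pad_value = 0) {
  arr <- if (inherits(vol, "volume3d")) vol$data else vol
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  size <- as.integer(size); stride <- as.integer(stride)
  if (size < 1L || stride < 1L) stop("size and stride must be >= 1", call. = FALSE)
  d <- dim(arr)
  dpad <- pmax(stride * ceiling(d / stride), size)
  padded <- array(pad_value, dim = dpad)
  padded[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- arr
  starts <- lapply(seq_len(3), function(a) seq(1L, dpad[a] - size + 1L, by = stride))
  grid <- expand.grid(x = starts[[1]], y = starts[[2]], z = starts[[3]])
  cubes <- lapply(seq_len(nrow(grid)), function(i) {
    o <- as.integer(grid[i, ])
    padded[o[1]:(o[1] + size - 1L), o[2]:(o[2] + size - 1L),
           o[3]:(o[3] + size - 1L)]
  })
  structure(list(cubes = cubes, origins = as.matrix(grid), dim_padded = dpad,
                 size = size, stride = stride, pad_value = pad_value),
            class = "cube_set")
}

#' @export
print.cube_set <- function(x, ...) {
  cat(sprintf("<cube_set> %d cubes of %d^3 (stride %d) tiling %s\n",
              length(x$cubes), x$size, x$stride,
              paste(x$dim_padded, collapse = "x")))
  invisible(x)
}

#' Cohort standardisation statistics
#'
#' Means and standard deviations of the continuous clinical fields (age,
#' education), computed on training subjects only so cross-validation folds
#' never leak test-set statistics.
#'
#' @param clinicals list of [clinical_vector()]s from the training subjects.
#' @return An object of class `cohort_stats`.
#' @export
cohort_stats <- function(clinicals) {
  stopifnot(length(clinicals) >= 1L)
  ages <- vapply(clinicals, function(c) c$age, numeric(1))
  edus <- vapply(clinicals, function(c) c$education, numeric(1))
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  structure(list(age_mean = mean(ages), age_sd = sd0(ages),
                 edu_mean = mean(edus), edu_sd = sd0(edus),
                 n = length(clinicals)),
            class = "cohort_stats")
}

#' Standardise a clinical vector
#'
#' Maps a [clinical_vector()] to the fixed-length numeric input of the
#' clinical network branch: `(symptom_abdominal, symptom_fear, age_z, sex,
#' education_z)`, with the optional PET-positivity flag appended last when
#' present (length 5 without it, 6 with). Age and education are z-scored with
#' training-cohort statistics; when a training standard deviation is zero the
#' field is centred only.
#'
#' @param clin a [clinical_vector()].
#' @param stats a [cohort_stats()] from the training fold.
#' @return Numeric vector of length 5 or 6.
#' @export
standardize_clinical <- function(clin, stats) {
  stopifnot(inherits(clin, "clinical_vector"), inherits(stats, "cohort_stats"))
  zs <- function(x, m, s) if (s > 0) (x - m) / s else x - m
  v <- c(clin$symptom_abdominal, clin$symptom_fear,
         zs(clin$age, stats$age_mean, stats$age_sd), clin$sex,
         zs(clin$education, stats$edu_mean, stats$edu_sd))
  if (!is.null(clin$pet_positive)) v <- c(v, clin$pet_positive)
  v
}
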