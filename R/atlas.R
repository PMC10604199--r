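#' Construct a parcellation atlas
#'
#' An integer label volume mapping each voxel to a brain region (AAL-style:
#' region ids 1..R, 0 = background) plus the subset of region ids forming the
#' cerebellar reference used for SUVR normalisation.
#'
#' @param labels 3D integer array of region labels; 0 is background.
#' @param region_ids integer vector of valid region ids (default: all nonzero
#'   labels present).
#' @param cerebellar_ids nonempty subset of `region_ids` serving as the SUVR
#'   reference region.
#' @param spacing voxel spacing in mm.
#' @return An object of class `parcellation_atlas`.
#' @export
parcellation_atlas <- function(labels, region_ids = NULL, cerebellar_ids,
                               spacing = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3D array", call. = FALSE)
  lab <- as.integer(labels)
  if (anyNA(lab) || any(lab < 0L))
    stop("labels must be nonnegative integers", call. = FALSE)
  present <- sort(unique(lab[lab > 0L]))
  if (is.null(region_ids)) region_ids <- present
  region_ids <- sort(as.integer(region_ids))
  if (!all(present %in% region_ids))
    stop("labels contain ids outside region_ids: ",
         paste(setdiff(present, region_ids), collapse = ","), call. = FALSE)
  cerebellar_ids <- as.integer(cerebellar_ids)
  if (length(cerebellar_ids) == 0L || !all(cerebellar_ids %in% region_ids))
    stop("cerebellar_ids must be a nonempty subset of region_ids", call. = FALSE)
  for (cid in cerebellar_ids)
    if (!any(lab == cid))
      stop("cerebellar region ", cid, " has no voxels", call. = FALSE)
  arr <- array(lab, dim = dim(labels))
  structure(list(labels = arr, region_ids = region_ids,
                 cerebellar_ids = cerebellar_ids,
                 spacing = as.numeric(spacing)),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(sprintf("<parcellation_atlas> %s voxels, %d regions, cerebellar ref {%s}\n",
              paste(dim(x$labels), collapse = "x"), length(x$region_ids),
              paste(x$cerebellar_ids, collapse = ",")))
  invisible(x)
}

#' Read a parcellation atlas from NIfTI
#'
#' @param path NIfTI file of integer region labels.
#' @param cerebellar_ids region ids of the cerebellar reference.
#' @return A [parcellation_atlas()].
#' @export
load_atlas <- function(path, cerebellar_ids) {
  vol <- load_volume(path)
  if (max(abs(vol$data - round(vol$data))) > 1e-6)
    stop("atlas volume is not integer-labelled: ", path, call. = FALSE)
  parcellation_atlas(array(as.integer(round(vol$data)), dim = dim(vol$data)),
                     cerebellar_ids = cerebellar_ids, spacing = vol$spacing)
}

#' Write a parcellation atlas as NIfTI
#'
#' @param atlas a [parcellation_atlas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  stopifnot(inherits(atlas, "parcellation_atlas"))
  write_volume(volume3d(array(as.numeric(atlas$labels), dim(atlas$labels)),
                        spacing = atlas$spacing), path)
}
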