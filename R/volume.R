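#' Construct a 3D volume
#'
#' A `volume3d` is a plain 3D numeric array carrying voxel spacing (mm per
#' axis) and an anatomical axis-order tag. Throughout the package the
#' left-right axis is axis 1, so the midsagittal plane is always the plane
#' perpendicular to the first array dimension — the bilateral asymmetry block
#' depends on this convention.
#'
#' @param data 3D numeric array, all values finite.
#' @param spacing numeric length-3, voxel size in mm per axis; strictly
#'   positive.
#' @param axis_order three-letter orientation tag (e.g. `"LAS"`); the first
#'   letter must be `L` or `R`, marking axis 1 as left-right.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing = c(1, 1, 1), axis_order = "LAS") {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("data must be a 3D array, got dims: ",
         paste(dim(data), collapse = "x"), call. = FALSE)
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1", call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume contains non-finite values (NaN/Inf/NA)", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive numbers", call. = FALSE)
  axis_order <- toupper(as.character(axis_order))
  if (!grepl("^[LR]", axis_order))
    stop("axis 1 must be the left-right axis (axis_order starting L or R), got: ",
         axis_order, call. = FALSE)
  structure(list(data = data, spacing = spacing, axis_order = axis_order),
            class = "volume3d")
}

#' @export
dim.volume3d <- function(x) dim(x$data)

#' @export
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels, spacing %s mm, orientation %s\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"), x$axis_order))
  invisible(x)
}

#' Read a NIfTI volume
#'
#' Loads a `.nii`/`.nii.gz` file, verifies it is a finite-valued 3D image, and
#' reorients it so the left-right axis is axis 1 (canonical `LAS`-style
#' ordering). Orientation is taken from the NIfTI xform; images whose header
#' does not put left-right first are reoriented losslessly by permuting and
#' flipping axes.
#'
#' @param path path to a NIfTI file.
#' @return A [volume3d()].
#' @export
load_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), " dimensions in ", path,
         call. = FALSE)
  orient <- tryCatch(RNifti::orientation(img), error = function(e) NA_character_)
  if (!is.na(orient) && nchar(orient) == 3L && !grepl("^[LR]", orient)) {
    RNifti::orientation(img) <- "LAS"
    orient <- "LAS"
  }
  if (is.na(orient) || nchar(orient) != 3L) orient <- "LAS"
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) spacing <- c(1, 1, 1)
  arr <- array(as.numeric(img), dim = dim(img))
  if (!all(is.finite(arr)))
    stop("volume contains non-finite voxels (NaN/Inf): ", path, call. = FALSE)
  volume3d(arr, spacing = spacing, axis_order = orient)
}

#' Write a volume as NIfTI
#'
#' Inverse of [load_volume()]: writes the array with its spacing into a
#' `.nii.gz` (or `.nii`) file. Round-tripping a finite volume through
#' `write_volume()` then [load_volume()] preserves the voxel data exactly
#' (data are written as float64).
#'
#' @param vol a [volume3d()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  arr <- vol$data
  attr(arr, "pixdim") <- vol$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Flip a volume across the midsagittal plane
#'
#' Reverses axis 1 (left-right). Used to mirror the right hemisphere onto the
#' left for symmetric cube pairing.
#'
#' @param vol a [volume3d()] or 3D array.
#' @return Same type as the input, mirrored along axis 1.
#' @export
mirror_lr <- function(vol) {
  if (inherits(vol, "volume3d")) {
    vol$data <- vol$data[rev(seq_len(dim(vol$data)[1])), , , drop = FALSE]
    return(vol)
  }
  vol[rev(seq_len(dim(vol)[1])), , , drop = FALSE]
}
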