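MANIFEST_COLUMNS <- c("subject_id", "label", "mri_path", "pet_path",
                      "symptom_abdominal", "symptom_fear", "age", "sex",
                      "education")

#' Construct a clinical/demographic vector
#'
#' The per-subject clinical record: the two typical MTLE symptom flags
#' (upper-abdominal aura, feeling of fear), age, binary-coded sex and years
#' of education. `pet_positive` is absent until the PET asymmetry block has
#' run, after which it is appended as a sixth element.
#'
#' @param symptom_abdominal,symptom_fear binary symptom flags (0/1).
#' @param age age in years, nonnegative.
#' @param sex binary-coded sex (0/1).
#' @param education years of education, nonnegative.
#' @param pet_positive optional binary PET-asymmetry flag; `NULL` until set.
#' @return An object of class `clinical_vector`.
#' @export
clinical_vector <- function(symptom_abdominal, symptom_fear, age, sex,
                            education, pet_positive = NULL) {
  chk01 <- function(x, nm) {
    if (length(x) != 1L || is.na(x) || !x %in% c(0, 1))
      stop(nm, " must be 0 or 1", call. = FALSE)
    as.integer(x)
  }
  if (length(age) != 1L || is.na(age) || age < 0) stop("age must be >= 0", call. = FALSE)
  if (length(education) != 1L || is.na(education) || education < 0)
    stop("education must be >= 0", call. = FALSE)
  if (!is.null(pet_positive)) pet_positive <- chk01(pet_positive, "pet_positive")
  structure(list(symptom_abdominal = chk01(symptom_abdominal, "symptom_abdominal"),
                 symptom_fear = chk01(symptom_fear, "symptom_fear"),
                 age = as.numeric(age), sex = chk01(sex, "sex"),
                 education = as.numeric(education),
                 pet_positive = pet_positive),
            class = "clinical_vector")
}

#' Read a cohort manifest
#'
#' Reads the tabular index of a cohort: one row per subject with its label
#' (EP = 1, HC = 0), paths to the co-registered MRI and PET NIfTI volumes and
#' the clinical fields. Comma-separated with a header by default; tabs are
#' accepted by sniffing the first line.
#'
#' @param path CSV/TSV file with columns
#'   `subject_id,label,mri_path,pet_path,symptom_abdominal,symptom_fear,age,sex,education`.
#' @param check_paths verify that every referenced volume exists (relative
#'   paths are resolved against the manifest's directory).
#' @return A `data.frame` of class `cohort_manifest`.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("manifest missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicate subject_id in manifest: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]), collapse = ", "),
         call. = FALSE)
  if (!all(df$label %in% c(0L, 1L)))
    stop("label must be 0 (HC) or 1 (EP)", call. = FALSE)
  root <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  df$mri_path <- resolve(df$mri_path)
  df$pet_path <- resolve(df$pet_path)
  if (check_paths) {
    gone <- c(df$mri_path[!file.exists(df$mri_path)],
              df$pet_path[!file.exists(df$pet_path)])
    if (length(gone) > 0L)
      stop("manifest references missing volumes: ",
           paste(utils::head(gone, 5), collapse = ", "), call. = FALSE)
  }
  class(df) <- c("cohort_manifest", "data.frame")
  df
}

#' Write a cohort manifest
#'
#' @param manifest a `cohort_manifest` or data.frame with the manifest columns.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
save_manifest <- function(manifest, path) {
  df <- as.data.frame(manifest)
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("manifest missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  utils::write.csv(df[, MANIFEST_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Load one subject from a manifest row
#'
#' Reads both volumes, enforces the co-registration contract (identical
#' dimensions and spacing) and assembles the subject record.
#'
#' @param row one row of a [load_manifest()] result (data.frame of 1 row).
#' @return An object of class `subject_record` with fields `subject_id`,
#'   `label`, `mri`, `pet`, `clinical`.
#' @export
load_subject <- function(row) {
  stopifnot(is.data.frame(row), nrow(row) == 1L)
  mri <- load_volume(row$mri_path)
  pet <- load_volume(row$pet_path)
  if (!identical(dim(mri$data), dim(pet$data)))
    stop(sprintf("MRI/PET not co-registered for %s: MRI %s vs PET %s",
                 row$subject_id, paste(dim(mri$data), collapse = "x"),
                 paste(dim(pet$data), collapse = "x")), call. = FALSE)
  if (max(abs(mri$spacing - pet$spacing)) > 1e-6)
    stop("MRI/PET voxel spacing differs for ", row$subject_id, call. = FALSE)
  subject_record(row$subject_id, row$label, mri, pet,
                 clinical_vector(row$symptom_abdominal, row$symptom_fear,
                                 row$age, row$sex, row$education))
}

#' @rdname load_subject
#' @param subject_id opaque subject identifier.
#' @param label binary diagnosis label, EP = 1, HC = 0.
#' @param mri,pet co-registered [volume3d()] volumes.
#' @param clinical a [clinical_vector()].
#' @export
subject_record <- function(subject_id, label, mri, pet, clinical) {
  stopifnot(inherits(mri, "volume3d"), inherits(pet, "volume3d"),
            inherits(clinical, "clinical_vector"))
  if (!label %in% c(0, 1)) stop("label must be 0 or 1", call. = FALSE)
  if (!identical(dim(mri$data), dim(pet$data)))
    stop("MRI and PET dimensions differ", call. = FALSE)
  structure(list(subject_id = as.character(subject_id),
                 label = as.integer(label), mri = mri, pet = pet,
                 clinical = clinical),
            class = "subject_record")
}

#' Load a whole cohort into memory
#'
#' @param manifest a [load_manifest()] result.
#' @return List of `subject_record`s, named by subject id.
#' @export
load_cohort <- function(manifest) {
  subs <- lapply(seq_len(nrow(manifest)),
                 function(i) load_subject(manifest[i, , drop = FALSE]))
  names(subs) <- manifest$subject_id
  subs
}
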