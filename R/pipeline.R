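normalize_mri <- function(arr) {
  m <- mean(arr)
  if (!is.finite(m) || m <= 0)
    stop("MRI volume has non-positive mean intensity", call. = FALSE)
  arr / m
}

#' Training-cohort image intensity statistics
#'
#' Global mean and standard deviation of MRI voxel intensities and of
#' SUVR-normalised PET voxel intensities over the given (training) subjects.
#' T1 MRI intensities are in arbitrary scanner units, so each MRI volume is
#' first divided by its own mean intensity (the usual proxy for intensity
#' normalisation), mirroring what SUVR does for PET. Image cubes fed to the
#' network are z-scored with these statistics; computing them on the
#' training fold only keeps cross-validation leak-free.
#'
#' @param subjects list of `subject_record`s (the training fold).
#' @param atlas a [parcellation_atlas()] used for SUVR normalisation.
#' @return An `image_stats` list.
#' @export
compute_image_stats <- function(subjects, atlas) {
  acc <- function(get) {
    s <- 0; s2 <- 0; n <- 0
    for (sub in subjects) {
      v <- get(sub)
      s <- s + sum(v); s2 <- s2 + sum(v^2); n <- n + length(v)
    }
    m <- s / n
    list(mean = m, sd = sqrt(max(s2 / n - m^2, 0)))
  }
  mri <- acc(function(s) normalize_mri(s$mri$data))
  pet <- acc(function(s) suvr_normalize(s$pet, atlas)$data)
  structure(list(mri_mean = mri$mean, mri_sd = max(mri$sd, 1e-8),
                 pet_mean = pet$mean, pet_sd = max(pet$sd, 1e-8)),
            class = "image_stats")
}

#' Prepare subjects for the fusion network
#'
#' Applies the full preprocessing contract: SUVR-normalise PET, z-score both
#' image volumes with training-fold statistics, tile them into cubes,
#' standardise the clinical vector (appending the PET-positivity flag and,
#' optionally, the upper-triangle ROI log-ratio features), and bundle
#' everything per subject for [train_model()] / [predict_model()].
#'
#' @param subjects list of `subject_record`s to prepare (any fold).
#' @param atlas a [parcellation_atlas()].
#' @param channels character subset of `c("mri", "pet", "clinical")`.
#' @param image_stats a [compute_image_stats()] result from the training fold.
#' @param clin_stats a [cohort_stats()] result from the training fold.
#' @param flags optional named vector of PET-positivity flags to append.
#' @param cube_size cube edge length.
#' @param roi_stats optional list(mean, sd) of training-fold ROI features;
#'   when supplied the standardised ROI vector is appended to the clinical
#'   input.
#' @return List of prepared subjects (fields `subject_id`, `label`, `mri`,
#'   `pet`, `clin`).
#' @export
prepare_model_inputs <- function(subjects, atlas, channels, image_stats = NULL,
                                 clin_stats = NULL, flags = NULL,
                                 cube_size = 48L, roi_stats = NULL) {
  lapply(subjects, function(s) {
    out <- list(subject_id = s$subject_id, label = s$label)
    if ("mri" %in% channels)
      out$mri <- extract_cubes((normalize_mri(s$mri$data) - image_stats$mri_mean) /
                                 image_stats$mri_sd,
                               size = cube_size)$cubes
    if ("pet" %in% channels) {
      petn <- suvr_normalize(s$pet, atlas)$data
      out$pet <- extract_cubes((petn - image_stats$pet_mean) / image_stats$pet_sd,
                               size = cube_size)$cubes
    }
    if ("clinical" %in% channels) {
      clin <- s$clinical
      if (!is.null(flags)) clin$pet_positive <- unname(flags[s$subject_id])
      v <- standardize_clinical(clin, clin_stats)
      if (!is.null(roi_stats)) {
        roi <- compute_roi_matrix(compute_suvr(s$pet, atlas))
        v <- c(v, (roi - roi_stats$mean) / pmax(roi_stats$sd, 1e-8))
      }
      out$clin <- v
    }
    out
  })
}

#' Pipeline configuration
#'
#' Bundles every stage's settings for [cross_validate()] and the fixed-split
#' evaluation.
#'
#' @param channels input channels to enable.
#' @param use_asymmetry run the PET-asymmetry pre-training block per fold and
#'   append its flag to the clinical vector.
#' @param use_roi_features append the upper-triangle ROI log-ratio features
#'   to the clinical input (off by default).
#' @param model_cfg a [model_config()].
#' @param epochs,lr,head_warmup,branch_lr_scale,weight_decay,early_stop_patience
#'   training controls (see [train_config()]); `lr = NULL` takes the
#'   optimizer default.
#' @param asym_cfg an [asym_config()] for the asymmetry block.
#' @param asym_threshold,asym_rule flag aggregation (see
#'   [aggregate_subject_flag()]).
#' @param cube_size image cube edge length.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(channels = c("mri", "pet", "clinical"),
                            use_asymmetry = FALSE, use_roi_features = FALSE,
                            model_cfg = model_config(), epochs = 20L,
                            lr = NULL, head_warmup = 400L,
                            branch_lr_scale = 0.05, weight_decay = 1,
                            early_stop_patience = 1000L,
                            asym_cfg = asym_config(),
                            asym_threshold = 0.5,
                            asym_rule = "majority", cube_size = 48L) {
  structure(list(channels = channels, use_asymmetry = use_asymmetry,
                 use_roi_features = use_roi_features, model_cfg = model_cfg,
                 epochs = as.integer(epochs), lr = lr,
                 head_warmup = as.integer(head_warmup),
                 branch_lr_scale = branch_lr_scale,
                 weight_decay = weight_decay,
                 early_stop_patience = as.integer(early_stop_patience),
                 asym_cfg = asym_cfg, asym_threshold = asym_threshold,
                 asym_rule = asym_rule, cube_size = as.integer(cube_size)),
            class = "pipeline_config")
}

# Fit every fold-local stage on the training subjects only, then train and
# evaluate. Returns predictions on the held-out subjects plus fingerprints of
# all fold-local state, used by the leakage checks.
run_fold <- function(subjects, atlas, train_ids, test_ids, config, seed) {
  train_subs <- subjects[train_ids]
  img_stats <- NULL; roi_stats <- NULL; flags <- NULL
  if (any(c("mri", "pet") %in% config$channels) || config$use_roi_features)
    img_stats <- compute_image_stats(train_subs, atlas)
  if (config$use_asymmetry) {
    acfg <- config$asym_cfg
    acfg$seed <- seed
    flags <- asymmetry_flags(subjects, atlas, train_ids = train_ids, cfg = acfg,
                             threshold = config$asym_threshold,
                             rule = config$asym_rule)$flags
  }
  clin_stats <- NULL
  if ("clinical" %in% config$channels)
    clin_stats <- cohort_stats(lapply(train_subs, function(s) s$clinical))
  if (config$use_roi_features) {
    rois <- vapply(train_subs,
                   function(s) compute_roi_matrix(compute_suvr(s$pet, atlas)),
                   numeric(length(compute_roi_matrix(compute_suvr(train_subs[[1]]$pet, atlas)))))
    rois <- matrix(rois, ncol = length(train_subs))
    roi_stats <- list(mean = rowMeans(rois), sd = apply(rois, 1, stats::sd))
  }
  prep_all <- prepare_model_inputs(subjects, atlas, config$channels, img_stats,
                                   clin_stats, flags, config$cube_size, roi_stats)
  clin_len <- if ("clinical" %in% config$channels)
    length(prep_all[[train_ids[1]]]$clin) else 0L
  set.seed(seed)
  model <- build_model(config$model_cfg, config$channels, clin_len = clin_len)
  tr <- train_model(model, prep_all[train_ids],
                    train_config(epochs = config$epochs, lr = config$lr,
                                 head_warmup = config$head_warmup,
                                 branch_lr_scale = config$branch_lr_scale,
                                 weight_decay = config$weight_decay,
                                 early_stop_patience = config$early_stop_patience,
                                 seed = seed))
  preds <- predict_model(tr$model, prep_all[test_ids])
  preds$label <- vapply(subjects[test_ids], function(s) s$label, integer(1))
  list(predictions = preds,
       fingerprint = list(train_ids = train_ids,
                          clin_stats = clin_stats,
                          image_stats = img_stats,
                          model = model_fingerprint(tr$model),
                          iterations = tr$iterations))
}

fold_metrics <- function(preds) {
  cts <- confusion(preds$predicted_label, preds$label)
  m <- metrics_from_counts(cts)
  m$auc <- tryCatch(roc_auc(preds$probability, preds$label),
                    error = function(e) NA_real_)
  m
}

#' Stratified k-fold cross-validated evaluation
#'
#' The primary evaluation protocol: seeded stratified folds; within each
#' fold every training-derived quantity — image and clinical standardisation
#' statistics, the asymmetry classifier and its flags, the fusion-model
#' weights — is recomputed from the training subjects only, and the held-out
#' subjects are scored once. Reports per-fold metrics (accuracy, sensitivity,
#' both specificity and F1 variants, AUC) and their mean and standard
#' deviation.
#'
#' @param subjects named list of `subject_record`s.
#' @param atlas a [parcellation_atlas()].
#' @param k number of folds.
#' @param seed seed controlling fold assignment and all per-fold training.
#' @param config a [pipeline_config()].
#' @return A `metrics_report`: `per_fold` (data.frame), `summary`
#'   (mean/sd per metric), `predictions`, `fold_assignment`, `fingerprints`.
#' @export
cross_validate <- function(subjects, atlas, k = 5L, seed = 1L,
                           config = pipeline_config()) {
  if (is.null(names(subjects)))
    names(subjects) <- vapply(subjects, function(s) s$subject_id, character(1))
  labels <- vapply(subjects, function(s) s$label, integer(1))
  folds <- make_folds(labels, k = k, seed = seed)
  ids <- names(subjects)
  fold_results <- lapply(seq_len(k), function(f) {
    run_fold(subjects, atlas, train_ids = ids[folds != f],
             test_ids = ids[folds == f], config = config, seed = seed + f)
  })
  build_report(fold_results, ids, folds, seed, config)
}

#' Fixed-split evaluation
#'
#' The alternative to k-fold CV: a single seeded stratified split into
#' training and test subjects (e.g. 10 EP + 10 HC training, 5 + 5 test on a
#' 30-subject cohort), evaluated once.
#'
#' @inheritParams cross_validate
#' @param train_frac fraction of each class assigned to training.
#' @return A `metrics_report` with one fold.
#' @export
fixed_split_evaluate <- function(subjects, atlas, train_frac = 2 / 3, seed = 1L,
                                 config = pipeline_config()) {
  if (is.null(names(subjects)))
    names(subjects) <- vapply(subjects, function(s) s$subject_id, character(1))
  labels <- vapply(subjects, function(s) s$label, integer(1))
  ids <- names(subjects)
  set.seed(seed)
  train_ids <- unlist(lapply(c(0L, 1L), function(cl) {
    cls <- ids[labels == cl]
    sample(cls, round(length(cls) * train_frac))
  }))
  test_ids <- setdiff(ids, train_ids)
  fr <- run_fold(subjects, atlas, train_ids, test_ids, config, seed = seed + 1L)
  folds <- ifelse(ids %in% test_ids, 1L, 0L)
  build_report(list(fr), ids, folds, seed, config)
}

build_report <- function(fold_results, ids, folds, seed, config) {
  metric_names <- c("accuracy", "sensitivity", "specificity_as_printed",
                    "f1_as_printed", "specificity_standard", "precision",
                    "f1_standard", "auc")
  per_fold <- do.call(rbind, lapply(seq_along(fold_results), function(f) {
    m <- fold_metrics(fold_results[[f]]$predictions)
    data.frame(fold = f, t(unlist(m[metric_names])))
  }))
  summ <- lapply(metric_names, function(nm) {
    v <- per_fold[[nm]]
    list(mean = mean(v, na.rm = TRUE),
         sd = if (sum(!is.na(v)) > 1L) stats::sd(v, na.rm = TRUE) else NA_real_)
  })
  names(summ) <- metric_names
  preds <- do.call(rbind, lapply(seq_along(fold_results), function(f)
    cbind(fold = f, fold_results[[f]]$predictions)))
  structure(list(per_fold = per_fold, summary = summ, predictions = preds,
                 fold_assignment = stats::setNames(folds, ids), seed = seed,
                 channels = config$channels,
                 use_asymmetry = config$use_asymmetry,
                 fingerprints = lapply(fold_results, `[[`, "fingerprint")),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> %d folds, channels %s%s\n",
              nrow(x$per_fold), paste(x$channels, collapse = "+"),
              if (isTRUE(x$use_asymmetry)) " + PET-asymmetry flag" else ""))
  for (nm in names(x$summary))
    cat(sprintf("  %-24s %.4f +/- %s\n", nm, x$summary[[nm]]$mean,
                ifelse(is.na(x$summary[[nm]]$sd), "NA",
                       sprintf("%.4f", x$summary[[nm]]$sd))))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' Serialises per-fold metrics, the summary and per-subject predictions;
#' numbers are written unrounded so two runs at the same seed produce
#' byte-identical reports.
#'
#' @param report a [cross_validate()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
save_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- list(seed = report$seed, channels = report$channels,
              use_asymmetry = report$use_asymmetry,
              per_fold = report$per_fold, summary = report$summary,
              predictions = report$predictions,
              fold_assignment = as.list(report$fold_assignment))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
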