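#' Split a PET volume bilaterally and pair mirrored cubes
#'
#' Divides the volume at the midsagittal plane (the geometric midplane of
#' axis 1, which by the package's loading convention is the left-right axis),
#' reflects the right hemisphere onto the left, tiles both hemifields with
#' [extract_cubes()] and pairs blocks with identical origins. Each pair
#' carries the difference cube `left - mirrored right`, the raw material of
#' the asymmetry classifier: a perfectly midline-symmetric brain gives
#' all-zero difference cubes, while unilateral hypometabolism leaves a
#' signed residue.
#'
#' For odd widths the single midline plane belongs to neither hemisphere and
#' is dropped.
#'
#' @param pet a [volume3d()] (typically SUVR-normalised).
#' @param size cube edge length (default 48).
#' @param subject_label optional binary label attached to every pair.
#' @return List of `symmetric_cube_pair` objects with fields `left_cube`,
#'   `right_cube_mirrored`, `diff_cube`, `origin`, `subject_label`.
#' @export
split_and_pair <- function(pet, size = 48L, subject_label = NA_integer_) {
  arr <- if (inherits(pet, "volume3d")) pet$data else pet
  stopifnot(is.array(arr), length(dim(arr)) == 3L)
  X <- dim(arr)[1]
  if (X < 2L) stop("volume width < 2 along the left-right axis", call. = FALSE)
  h <- X %/% 2L
  left <- arr[seq_len(h), , , drop = FALSE]
  right <- arr[(X - h + 1L):X, , , drop = FALSE]
  right_m <- right[rev(seq_len(h)), , , drop = FALSE]
  lc <- extract_cubes(left, size = size)
  rc <- extract_cubes(right_m, size = size)
  lapply(seq_along(lc$cubes), function(i) {
    structure(list(left_cube = lc$cubes[[i]],
                   right_cube_mirrored = rc$cubes[[i]],
                   diff_cube = lc$cubes[[i]] - rc$cubes[[i]],
                   origin = lc$origins[i, ],
                   subject_label = subject_label),
              class = "symmetric_cube_pair")
  })
}

#' Asymmetry-classifier configuration
#'
#' A small 3D convolutional network over difference cubes: two convolutional
#' layers with ReLU and max pooling, a third pooling stage, dropout, and a
#' dense logit. Kept deliberately lighter than the fusion branches — its job
#' is only to flag lateralised signal, and it runs once per mirrored cube
#' pair.
#'
#' @param widths two convolution channel widths.
#' @param dropout dropout probability.
#' @param epochs,optimizer,lr,momentum,early_stop_patience,seed training
#'   controls (batch size 1, binary cross-entropy; Adam by default).
#' @param cube_size cube edge length.
#' @return An `asym_config` list.
#' @export
asym_config <- function(widths = c(4, 8), dropout = 0.3, epochs = 4L,
                        optimizer = c("adam", "sgd"), lr = NULL,
                        momentum = 0, early_stop_patience = 1000L, seed = 1L,
                        cube_size = 48L) {
  optimizer <- match.arg(optimizer)
  if (is.null(lr)) lr <- if (optimizer == "adam") 1e-3 else 0.01
  stopifnot(length(widths) == 2L, momentum >= 0, momentum < 1)
  structure(list(widths = as.integer(widths), dropout = dropout,
                 epochs = as.integer(epochs), optimizer = optimizer, lr = lr,
                 momentum = momentum,
                 early_stop_patience = as.integer(early_stop_patience),
                 seed = as.integer(seed), cube_size = as.integer(cube_size)),
            class = "asym_config")
}

asym_net_layers <- function(cfg) {
  w <- cfg$widths
  d <- cfg$cube_size
  for (i in 1:3) d <- as.integer(ceiling(d / 2))  # three ceil-mode 2x poolings
  flat_len <- d^3 * w[2]
  list(nn_conv3d(1L, w[1]), nn_relu(), nn_pool(),
       nn_conv3d(w[1], w[2]), nn_relu(), nn_pool(), nn_pool(),
       nn_dropout(cfg$dropout), nn_flatten(),
       nn_dense(flat_len, 1L))
}

#' Train the PET-asymmetry pair classifier
#'
#' Trains the difference-cube network on labelled [split_and_pair()] output.
#' Every pair inherits its subject's EP/HC label — accepted label noise,
#' since patient hemifields also contain healthy tissue; the classifier
#' learns to score pairs whose difference cube carries lateralised signal.
#'
#' @param pairs list of `symmetric_cube_pair`s with non-missing
#'   `subject_label`s from both classes.
#' @param cfg an [asym_config()].
#' @return An object of class `asym_classifier` with the trained network and
#'   its loss trace.
#' @export
train_asymmetry_classifier <- function(pairs, cfg = asym_config()) {
  labs <- vapply(pairs, function(p) as.numeric(p$subject_label), numeric(1))
  if (anyNA(labs)) stop("all training pairs must carry a subject label", call. = FALSE)
  if (length(unique(labs)) < 2L)
    stop("training pairs must contain both classes (EP and HC)", call. = FALSE)
  set.seed(cfg$seed)
  net <- asym_net_layers(cfg)
  trace <- numeric(0)
  best <- Inf; since <- 0L; it <- 0L
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample(length(pairs))
    for (i in ord) {
      it <- it + 1L
      x <- array(pairs[[i]]$diff_cube, c(dim(pairs[[i]]$diff_cube), 1L))
      fw <- seq_forward(net, x, training = TRUE)
      net <- fw$net
      p <- sigmoid_(fw$out)
      loss <- bce_loss(p, labs[i])
      if (!is.finite(loss))
        stop("asymmetry training diverged at iteration ", it, call. = FALSE)
      trace[it] <- loss
      bw <- seq_backward(net, fw$caches, p - labs[i])
      net <- seq_update(net, bw$grads, cfg$lr, cfg$optimizer, it, cfg$momentum)
      if (loss < best - 1e-9) { best <- loss; since <- 0L } else since <- since + 1L
      if (since >= cfg$early_stop_patience) break
    }
    if (since >= cfg$early_stop_patience) break
  }
  structure(list(net = net, cfg = cfg, loss_trace = trace, iterations = it),
            class = "asym_classifier")
}

#' Score mirrored cube pairs
#'
#' @param clf an [train_asymmetry_classifier()] result.
#' @param pairs list of `symmetric_cube_pair`s.
#' @return Numeric vector of probabilities in `[0, 1]`, one per pair.
#' @export
score_pairs <- function(clf, pairs) {
  stopifnot(inherits(clf, "asym_classifier"))
  vapply(pairs, function(p) {
    x <- array(p$diff_cube, c(dim(p$diff_cube), 1L))
    sigmoid_(seq_forward(clf$net, x)$out)
  }, numeric(1))
}

#' Aggregate pair scores into a subject-level PET-positivity flag
#'
#' Under the `"majority"` rule the subject is flagged PET-positive when more
#' than half of its pair scores exceed the threshold; under `"any"` a single
#' supra-threshold pair suffices. `"any"` is the appropriate rule for focal
#' lesions, which occupy only a subset of the mirrored cube pairs.
#'
#' @param pair_scores numeric vector of pair probabilities.
#' @param threshold score threshold.
#' @param rule `"majority"` or `"any"`.
#' @return An `asymmetry_decision`: `pair_scores` and binary `subject_flag`.
#' @export
aggregate_subject_flag <- function(pair_scores, threshold = 0.5,
                                   rule = c("majority", "any")) {
  rule <- match.arg(rule)
  if (length(pair_scores) == 0L) stop("no pair scores supplied", call. = FALSE)
  if (any(!is.finite(pair_scores)) || any(pair_scores < 0 | pair_scores > 1))
    stop("pair scores must be probabilities in [0, 1]", call. = FALSE)
  above <- sum(pair_scores > threshold)
  flag <- switch(rule,
                 majority = as.integer(above > length(pair_scores) / 2),
                 any = as.integer(above > 0L))
  structure(list(pair_scores = pair_scores, subject_flag = flag, rule = rule,
                 threshold = threshold),
            class = "asymmetry_decision")
}

#' Run the asymmetry block over a cohort
#'
#' Fits the pair classifier on the training subjects' SUVR-normalised PET
#' volumes and returns a PET-positivity flag for every subject, ready to be
#' appended to the clinical vector as its sixth element.
#'
#' @param subjects list of `subject_record`s.
#' @param atlas the [parcellation_atlas()] (for SUVR normalisation).
#' @param train_ids subject ids used to fit the classifier; flags are
#'   produced for all subjects.
#' @param cfg an [asym_config()].
#' @param threshold,rule passed to [aggregate_subject_flag()].
#' @param suvr_normalized normalise PET by the cerebellar mean first
#'   (default TRUE).
#' @return List with `flags` (named integer vector over all subjects),
#'   `classifier`, and per-subject `scores`.
#' @export
asymmetry_flags <- function(subjects, atlas, train_ids = names(subjects),
                            cfg = asym_config(), threshold = 0.5,
                            rule = c("majority", "any"),
                            suvr_normalized = TRUE) {
  rule <- match.arg(rule)
  pet_of <- function(s) if (suvr_normalized) suvr_normalize(s$pet, atlas) else s$pet
  pairs_by_sub <- lapply(subjects, function(s)
    split_and_pair(pet_of(s), size = cfg$cube_size, subject_label = s$label))
  train_pairs <- unlist(pairs_by_sub[train_ids], recursive = FALSE)
  clf <- train_asymmetry_classifier(train_pairs, cfg)
  scores <- lapply(pairs_by_sub, function(p) score_pairs(clf, p))
  flags <- vapply(scores, function(s)
    aggregate_subject_flag(s, threshold, rule)$subject_flag, integer(1))
  list(flags = flags, classifier = clf, scores = scores)
}
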