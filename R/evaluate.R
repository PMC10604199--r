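#' Confusion counts
#'
#' Counts true/false positives/negatives under the EP = 1 positive
#' convention.
#'
#' @param predicted binary predicted labels.
#' @param labels binary true labels.
#' @return A `confusion_counts` list with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(predicted, labels) {
  if (length(predicted) != length(labels))
    stop("predicted and labels differ in length", call. = FALSE)
  if (!all(predicted %in% c(0, 1)) || !all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1", call. = FALSE)
  structure(list(TP = sum(predicted == 1 & labels == 1),
                 TN = sum(predicted == 0 & labels == 0),
                 FP = sum(predicted == 1 & labels == 0),
                 FN = sum(predicted == 0 & labels == 1)),
            class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy and sensitivity in their standard forms, plus two
#' variants of specificity and F1. The "as-printed" specificity is
#' `TP / (TP + FP)` — algebraically this is precision, not specificity, but
#' it is reported alongside the standard `TN / (TN + FP)` rather than being
#' silently corrected, and the as-printed F1 `2*Sen*Spe_ap/(Sen+Spe_ap)` is
#' therefore identical to the standard F1 (harmonic mean of precision and
#' recall). Metrics whose denominator is zero are reported as `NA`
#' (undefined), never clamped to 0 or 1.
#'
#' @param counts a [confusion()] result.
#' @return Named list of metrics, all in `[0, 1]` or `NA`.
#' @export
metrics_from_counts <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- rat(TP + TN, TP + TN + FP + FN)
  sen <- rat(TP, TP + FN)                  # recall
  spe_ap <- rat(TP, TP + FP)               # as printed; algebraically precision
  spe_std <- rat(TN, TN + FP)
  f1_of <- function(a, b) if (is.na(a) || is.na(b) || a + b == 0) NA_real_
                          else 2 * a * b / (a + b)
  list(accuracy = acc,
       sensitivity = sen,
       specificity_as_printed = spe_ap,
       f1_as_printed = f1_of(sen, spe_ap),
       specificity_standard = spe_std,
       precision = spe_ap,
       f1_standard = f1_of(spe_ap, sen))
}

#' Rank-based ROC AUC
#'
#' The area under the ROC curve computed as the normalised Mann-Whitney U
#' statistic from midranks, so tied scores count half.
#'
#' @param scores numeric classifier scores.
#' @param labels binary true labels (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1))) stop("labels must be binary 0/1", call. = FALSE)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified fold assignment
#'
#' Seeded, stratified assignment of subjects to `k` cross-validation folds:
#' within each class, subjects are shuffled and dealt to folds round-robin,
#' so folds are disjoint, exhaustive and as class-balanced as the counts
#' allow.
#'
#' @param labels binary labels.
#' @param k number of folds.
#' @param seed RNG seed for the shuffle.
#' @return Integer vector of fold indices in `1..k`, one per subject.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1", call. = FALSE)
  if (min(table(factor(labels, levels = c(0, 1)))) < k)
    stop("need at least k = ", k, " subjects per class for stratified ",
         k, "-fold CV", call. = FALSE)
  set.seed(seed)
  folds <- integer(length(labels))
  for (cl in c(0L, 1L)) {
    idx <- sample(which(labels == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}
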