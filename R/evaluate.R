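#' Leave-one-group-out study schemes
#'
#' Builds the three leave-one-group-out train/test schemes of the two
#' LOOCV study designs: each scheme tests on one HI group (G4, G2, G1 in
#' turn) and trains on the remaining HI groups, with the sham-normothermia
#' group G3 included in training when `include_sham = TRUE` (study #1) and
#' excluded when `FALSE` (study #2). G3 is never a test group (it contains
#' no seizures).
#'
#' @param manifest Data frame with one row per segment, columns `group`
#'   (`G1..G4`) and `label` (`"HAS"`/`"non-HAS"`).
#' @param include_sham Include G3 segments in the training side.
#' @return List of three objects of class `study_scheme`, each with
#'   `study_id`, `scheme`, `train_groups`, `test_group`, `train_idx`,
#'   `test_idx`, train/test `counts` (total/seizure/non-seizure) and
#'   `ratio` (train total / test total).
#' @export
build_loocv_schemes <- function(manifest, include_sham = TRUE) {
  check_manifest(manifest)
  need <- if (include_sham) c("G1", "G2", "G3", "G4") else c("G1", "G2", "G4")
  missing <- setdiff(need, unique(manifest$group))
  if (length(missing))
    stop("manifest lacks group(s): ", paste(missing, collapse = ", "))
  study_id <- if (include_sham) 1L else 2L
  tests <- c("G4", "G2", "G1")
  lapply(seq_along(tests), function(s) {
    test_group <- tests[s]
    train_groups <- setdiff(need, test_group)
    train_idx <- which(manifest$group %in% train_groups)
    test_idx <- which(manifest$group == test_group)
    new_scheme(study_id, s, train_groups, test_group, train_idx, test_idx,
               manifest)
  })
}

#' Stratified k-fold study schemes
#'
#' Pools all groups and partitions segments into `k` class-stratified folds
#' (study #3; the default k = 5 gives an 80/20 train/test split). Per
#' class, shuffled indices are dealt into folds of equal size, remainders
#' going to the earliest folds. The partition is a pure function of the
#' seed, so every detector sees identical folds.
#'
#' @param manifest As in [build_loocv_schemes()].
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return List of `k` `study_scheme` objects (`study_id = 3`).
#' @export
build_kfold <- function(manifest, k = 5L, seed = 1L) {
  check_manifest(manifest)
  if (k < 2L) stop("`k` must be at least 2")
  n <- nrow(manifest)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fold <- integer(n)
  for (cls in unique(manifest$label)) {
    idx <- sample(which(manifest$label == cls))
    sizes <- rep(length(idx) %/% k, k)
    extra <- length(idx) %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    fold[idx] <- rep(seq_len(k), times = sizes)
  }
  lapply(seq_len(k), function(f) {
    new_scheme(3L, f, "G1+G2+G3+G4", sprintf("fold %d", f),
               which(fold != f), which(fold == f), manifest)
  })
}

check_manifest <- function(manifest) {
  stopifnot(is.data.frame(manifest),
            all(c("group", "label") %in% names(manifest)))
  if (!all(manifest$label %in% c("HAS", "non-HAS")))
    stop("manifest labels must be 'HAS' or 'non-HAS'")
  invisible(manifest)
}

new_scheme <- function(study_id, scheme, train_groups, test_group,
                       train_idx, test_idx, manifest) {
  cnt <- function(idx) c(total = length(idx),
                         seizures = sum(manifest$label[idx] == "HAS"),
                         non_seizures = sum(manifest$label[idx] == "non-HAS"))
  structure(list(study_id = study_id, scheme = scheme,
                 train_groups = train_groups, test_group = test_group,
                 train_idx = train_idx, test_idx = test_idx,
                 train_counts = cnt(train_idx), test_counts = cnt(test_idx),
                 ratio = length(train_idx) / length(test_idx)),
            class = "study_scheme")
}

#' @export
print.study_scheme <- function(x, ...) {
  cat(sprintf(
    "<study_scheme> study #%d scheme %s: train %s (%d/%d/%d) test %s (%d/%d/%d) ratio %.2f\n",
    x$study_id, as.character(x$scheme),
    paste(x$train_groups, collapse = "+"),
    x$train_counts[1], x$train_counts[2], x$train_counts[3],
    x$test_group, x$test_counts[1], x$test_counts[2], x$test_counts[3],
    x$ratio))
  invisible(x)
}

#' Confusion-matrix metrics for binary seizure detection
#'
#' `confusion()` counts TP/FP/FN/TN from labels and predictions (positive
#' class `"HAS"`) and derives sensitivity `100*TP/(TP+FN)`, selectivity
#' (true-negative rate) `100*TN/(TN+FP)`, precision `100*TP/(TP+FP)` and
#' accuracy `100*(TP+TN)/total`. Ratios with a zero denominator are
#' reported as `NaN`, never coerced to 0 or 100.
#' `confusion_from_counts()` computes the same metrics from raw counts.
#'
#' @param labels True labels (`"HAS"`/`"non-HAS"`).
#' @param predictions Predicted labels, same length.
#' @param auc Optional AUC to attach.
#' @return An object of class `confusion_metrics` with fields `tp, fp, fn,
#'   tn, sensitivity, selectivity, precision, accuracy` (percentages) and
#'   optionally `auc`.
#' @export
confusion <- function(labels, predictions, auc = NA_real_) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(predictions))
    stop("labels and predictions differ in length")
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  ok <- c("HAS", "non-HAS")
  if (!all(labels %in% ok) || !all(predictions %in% ok))
    stop("labels must be 'HAS' or 'non-HAS'")
  confusion_from_counts(
    tp = sum(labels == "HAS" & predictions == "HAS"),
    fp = sum(labels == "non-HAS" & predictions == "HAS"),
    fn = sum(labels == "HAS" & predictions == "non-HAS"),
    tn = sum(labels == "non-HAS" & predictions == "non-HAS"),
    auc = auc)
}

#' @rdname confusion
#' @param tp,fp,fn,tn Confusion counts.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn, auc = NA_real_) {
  pct <- function(num, den) if (den == 0) NaN else 100 * num / den
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = pct(tp, tp + fn),
                 selectivity = pct(tn, tn + fp),
                 precision = pct(tp, tp + fp),
                 accuracy = pct(tp + tn, tp + fp + fn + tn),
                 auc = auc),
            class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat(sprintf(
    "<confusion_metrics> TP %d FP %d FN %d TN %d | sens %.2f sel %.2f prec %.2f acc %.2f%s\n",
    x$tp, x$fp, x$fn, x$tn, x$sensitivity, x$selectivity, x$precision,
    x$accuracy,
    if (is.finite(x$auc)) sprintf(" auc %.4f", x$auc) else ""))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' Sweeps the decision threshold over the unique scores (prediction =
#' `"HAS"` when score >= threshold) and integrates the resulting
#' (FPR, TPR) staircase by the trapezoidal rule. The AUC equals the
#' Mann-Whitney pairwise-comparison statistic (ties counted half).
#'
#' @param scores Numeric HAS-class scores.
#' @param labels True labels (`"HAS"`/`"non-HAS"`); both classes required.
#' @return An object of class `roc_curve`: `points` (data frame `fpr`,
#'   `tpr`, ordered), and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  pos <- labels == "HAS"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L)
    stop("ROC requires both classes; got ", n1, " HAS and ", n0, " non-HAS")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  tp <- cumsum(p)
  fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)   # threshold boundaries
  tpr <- c(0, tp[last] / n1)
  fpr <- c(0, fp[last] / n0)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Vertically averaged ROC over schemes or folds
#'
#' Interpolates each curve's TPR on a fixed FPR grid and reports the mean
#' and standard deviation per grid point (mean +/- SD bands).
#'
#' @param rocs List of [roc_auc()] results.
#' @param fpr_grid FPR grid in the unit interval.
#' @return Data frame `fpr, tpr_mean, tpr_sd`.
#' @export
average_roc <- function(rocs, fpr_grid = seq(0, 1, by = 0.01)) {
  stopifnot(length(rocs) >= 1L)
  tprs <- vapply(rocs, function(r) {
    stats::approx(r$points$fpr, r$points$tpr, xout = fpr_grid,
                  method = "constant", ties = max, rule = 2)$y
  }, numeric(length(fpr_grid)))
  tprs <- matrix(tprs, nrow = length(fpr_grid))
  data.frame(fpr = fpr_grid,
             tpr_mean = rowMeans(tprs),
             tpr_sd = apply(tprs, 1, function(z)
               sqrt(mean((z - mean(z))^2))))
}

#' Summarise metrics over the schemes of a study
#'
#' Mean and standard deviation of accuracy and AUC across schemes/folds.
#' Dispersion uses the population (n-divisor) convention. Order of the
#' input rows does not affect the summary.
#'
#' @param metrics List of `confusion_metrics` objects (with `auc` attached where
#'   available).
#' @return One-row data frame: `n`, `accuracy_mean`, `accuracy_sd`,
#'   `auc_mean`, `auc_sd`.
#' @export
summarize_study <- function(metrics) {
  stopifnot(length(metrics) >= 1L)
  acc <- vapply(metrics, `[[`, 0, "accuracy")
  auc <- vapply(metrics, `[[`, 0, "auc")
  pop_sd <- function(z) sqrt(mean((z - mean(z))^2))
  data.frame(n = length(metrics),
             accuracy_mean = mean(acc), accuracy_sd = pop_sd(acc),
             auc_mean = if (all(is.finite(auc))) mean(auc) else NA_real_,
             auc_sd = if (all(is.finite(auc))) pop_sd(auc) else NA_real_)
}

#' Assemble a per-scheme metrics table
#'
#' One row per scheme with the confusion counts and derived percentages,
#' mirroring the package's standard reporting layout.
#'
#' @param metrics List of `confusion_metrics` objects.
#' @param ids Optional scheme identifiers.
#' @return Data frame.
#' @export
metrics_table <- function(metrics, ids = seq_along(metrics)) {
  do.call(rbind, lapply(seq_along(metrics), function(i) {
    m <- metrics[[i]]
    data.frame(scheme = ids[i], tp = m$tp, fp = m$fp, fn = m$fn, tn = m$tn,
               sensitivity = round(m$sensitivity, 2),
               selectivity = round(m$selectivity, 2),
               precision = round(m$precision, 2),
               accuracy = round(m$accuracy, 2),
               auc = round(m$auc, 4))
  }))
}
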