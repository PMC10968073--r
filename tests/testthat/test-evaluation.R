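test_that("LOOCV schemes rebuild the reference partition arithmetic", {
  manifest <- manifest_from_counts(reference_cohort_counts())
  expect_equal(nrow(manifest), 31015L)
  expect_equal(sum(manifest$label == "HAS"), 3955L)
  expect_equal(sum(manifest$label == "non-HAS"), 27060L)

  s1 <- build_loocv_schemes(manifest, include_sham = TRUE)
  expect_length(s1, 3L)
  expect_equal(unname(s1[[1]]$train_counts),
               c(20491L, 2311L, 18180L))
  expect_equal(unname(s1[[1]]$test_counts), c(10524L, 1644L, 8880L))
  expect_equal(round(s1[[1]]$ratio, 2), 1.95)
  expect_equal(unname(s1[[2]]$train_counts),
               c(20852L, 2652L, 18200L))
  expect_equal(unname(s1[[2]]$test_counts), c(10163L, 1303L, 8860L))
  expect_equal(unname(s1[[3]]$train_counts),
               c(25582L, 2947L, 22635L))
  expect_equal(unname(s1[[3]]$test_counts), c(5433L, 1008L, 4425L))

  s2 <- build_loocv_schemes(manifest, include_sham = FALSE)
  expect_equal(unname(s2[[1]]$train_counts),
               c(15596L, 2311L, 13285L))
  for (sch in s2)
    expect_false("G3" %in% manifest$group[sch$train_idx])
  for (sch in c(s1, s2))
    expect_length(intersect(sch$train_idx, sch$test_idx), 0L)
})

test_that("missing cohorts are reported by name", {
  manifest <- data.frame(group = c("G1", "G2"), label = c("HAS", "non-HAS"))
  expect_error(build_loocv_schemes(manifest), "G3")
  expect_error(build_loocv_schemes(manifest, include_sham = FALSE), "G4")
})

test_that("stratified 5-fold partition reproduces the reference fold sizes", {
  manifest <- manifest_from_counts(reference_cohort_counts())
  folds <- build_kfold(manifest, k = 5, seed = 1)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_equal(unname(f$test_counts), c(6203L, 791L, 5412L))
    expect_equal(unname(f$train_counts), c(24812L, 3164L, 21648L))
    expect_equal(f$ratio, 4.0)
  }
  # disjoint cover of the dataset
  all_test <- sort(unlist(lapply(folds, `[[`, "test_idx")))
  expect_equal(all_test, seq_len(nrow(manifest)))
  # same seed, same membership
  again <- build_kfold(manifest, k = 5, seed = 1)
  expect_identical(lapply(folds, `[[`, "test_idx"),
                   lapply(again, `[[`, "test_idx"))
  expect_error(build_kfold(manifest, k = 1), "at least 2")
})

test_that("uneven class counts spill into the earliest folds", {
  manifest <- data.frame(group = "G1",
                         label = c(rep("HAS", 7), rep("non-HAS", 11)))
  folds <- build_kfold(manifest, k = 3, seed = 2)
  test_has <- vapply(folds, function(f) unname(f$test_counts["seizures"]),
                     0L)
  test_non <- vapply(folds, function(f)
    unname(f$test_counts["non_seizures"]), 0L)
  expect_equal(test_has, c(3L, 2L, 2L))
  expect_equal(test_non, c(4L, 4L, 3L))
})

test_that("every reference confusion row reproduces at two decimals", {
  rows <- reference_confusion_rows()
  expect_equal(nrow(rows), 33L)
  for (i in seq_len(nrow(rows))) {
    m <- confusion_from_counts(rows$tp[i], rows$fp[i], rows$fn[i],
                               rows$tn[i])
    expect_equal(round(m$sensitivity, 2), rows$sensitivity[i])
    expect_equal(round(m$selectivity, 2), rows$selectivity[i])
    expect_equal(round(m$precision, 2), rows$precision[i])
    expect_equal(round(m$accuracy, 2), rows$accuracy[i])
  }
})

test_that("confusion counts come out of labelled predictions", {
  labels <- c(rep("HAS", 4), rep("non-HAS", 6))
  preds <- c("HAS", "HAS", "non-HAS", "HAS", rep("non-HAS", 5), "HAS")
  m <- confusion(labels, preds)
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 1, 5))
  expect_equal(m$tp + m$fp + m$fn + m$tn, 10)
  perfect <- confusion(labels, labels)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$fp + perfect$fn, 0)
  expect_error(confusion(character(0), character(0)), "empty")
  expect_error(confusion(labels, preds[-1]), "length")
})

test_that("zero denominators give NaN, never 0 or 100", {
  m <- confusion_from_counts(tp = 0, fp = 0, fn = 3, tn = 7)
  expect_true(is.nan(m$precision))
  expect_false(is.nan(m$accuracy))
  m2 <- confusion_from_counts(tp = 0, fp = 0, fn = 0, tn = 5)
  expect_true(is.nan(m2$sensitivity))
})

test_that("ROC/AUC behaves at the extremes and matches Mann-Whitney", {
  scores <- c(0.9, 0.8, 0.7, 0.3, 0.2, 0.1)
  labels <- c(rep("HAS", 3), rep("non-HAS", 3))
  expect_equal(roc_auc(scores, labels)$auc, 1.0)
  expect_error(roc_auc(scores, rep("HAS", 6)), "both classes")

  # label-independent scores give AUC near one half
  set.seed(20)
  s <- runif(2000)
  l <- sample(c("HAS", "non-HAS"), 2000, replace = TRUE)
  expect_lt(abs(roc_auc(s, l)$auc - 0.5), 0.05)

  # exhaustive pairwise-comparison oracle on small instances, with ties
  for (seed in 1:5) {
    set.seed(seed)
    n <- 150
    l <- sample(c("HAS", "non-HAS"), n, replace = TRUE,
                prob = c(0.3, 0.7))
    s <- round(runif(n), 1) + ifelse(l == "HAS", 0.2, 0)
    pos <- s[l == "HAS"]
    neg <- s[l == "non-HAS"]
    u <- 0
    for (a in pos) u <- u + sum(a > neg) + 0.5 * sum(a == neg)
    expect_equal(roc_auc(s, l)$auc, u / (length(pos) * length(neg)),
                 tolerance = 1e-12)
  }
})

test_that("AUC agrees with an established reference implementation", {
  set.seed(31)
  s <- rnorm(300) + ifelse(rep(c(TRUE, FALSE), 150), 1.2, 0)
  l <- rep(c("HAS", "non-HAS"), 150)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(l, levels = c("non-HAS", "HAS")),
    predictor = s, quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(s, l)$auc, ref, tolerance = 1e-10)
})

test_that("vertical ROC averaging returns mean and SD bands", {
  set.seed(8)
  rocs <- lapply(1:4, function(i) {
    l <- rep(c("HAS", "non-HAS"), 50)
    s <- rnorm(100) + ifelse(l == "HAS", 1.5, 0)
    roc_auc(s, l)
  })
  avg <- average_roc(rocs)
  expect_equal(names(avg), c("fpr", "tpr_mean", "tpr_sd"))
  expect_true(all(avg$tpr_mean >= 0 & avg$tpr_mean <= 1))
  expect_true(all(diff(avg$tpr_mean) >= -1e-12))
  expect_equal(avg$tpr_mean[nrow(avg)], 1)
})

test_that("study summaries use the population SD and ignore row order", {
  ms <- lapply(c(99.65, 97.19, 98.62), function(a) {
    m <- confusion_from_counts(1, 0, 0, 1)
    m$accuracy <- a
    m$auc <- a / 100
    m
  })
  sm <- summarize_study(ms)
  expect_equal(round(sm$accuracy_mean, 1), 98.5)
  expect_equal(round(sm$accuracy_sd, 2), 1.01)
  expect_identical(summarize_study(rev(ms))[, -1], sm[, -1])
  single <- summarize_study(ms[1])
  expect_equal(single$accuracy_sd, 0)
})

test_that("metrics tables mirror the reporting layout", {
  m <- confusion_from_counts(10, 2, 1, 87, auc = 0.98)
  tab <- metrics_table(list(m, m), ids = c("a", "b"))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$scheme, c("a", "b"))
  expect_equal(tab$accuracy, rep(97, 2))
})
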