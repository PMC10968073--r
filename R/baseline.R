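#' Energy-threshold baseline classifier
#'
#' A deliberately trivial reference detector: each segment is reduced to
#' its log root-mean-square amplitude and a single threshold is chosen on
#' the training set (the midpoint between consecutive sorted feature
#' values that maximises training accuracy; HAS is always the high-energy
#' side). The CNN detectors are expected to beat this baseline; on
#' maximally separable synthetic data the baseline itself is nearly
#' perfect, which anchors scaled-down training tests.
#'
#' @param train_segments,test_segments Lists of [eeg_segment()].
#' @param train_labels Labels for the training segments.
#' @return List with `threshold`, `labels` (test predictions), `scores`
#'   (test log-RMS features) and `train_accuracy`.
#' @export
energy_threshold_baseline <- function(train_segments, train_labels,
                                      test_segments) {
  feat <- function(segs) vapply(segs, function(s)
    log10(sqrt(mean(s$samples^2)) + 1e-12), 0)
  f_tr <- feat(train_segments)
  y <- as.character(train_labels)
  stopifnot(length(y) == length(f_tr), all(y %in% c("HAS", "non-HAS")))
  sv <- sort(unique(f_tr))
  cand <- if (length(sv) > 1)
    (utils::head(sv, -1) + utils::tail(sv, -1)) / 2 else sv
  acc <- vapply(cand, function(th)
    mean(ifelse(f_tr >= th, "HAS", "non-HAS") == y), 0)
  th <- cand[which.max(acc)]
  f_te <- feat(test_segments)
  list(threshold = th,
       labels = ifelse(f_te >= th, "HAS", "non-HAS"),
       scores = f_te,
       train_accuracy = max(acc))
}
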