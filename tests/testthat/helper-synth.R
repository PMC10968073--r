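# Shared helpers: small synthetic constructions and reference tables.

ref_path <- function(file) system.file("extdata", file, package = "hasdetect")

reference_confusion_rows <- function() {
  read.csv(ref_path("reference_confusion_rows.csv"), stringsAsFactors = FALSE)
}

reference_cohort_counts <- function() {
  read.csv(ref_path("reference_cohort_counts.csv"), stringsAsFactors = FALSE)
}

# Expand per-group segment counts into a per-segment manifest (group, label).
manifest_from_counts <- function(counts) {
  has <- counts$has_left + counts$has_right
  non <- counts$non_left + counts$non_right
  data.frame(
    group = c(rep(counts$group, has), rep(counts$group, non)),
    label = c(rep("HAS", sum(has)), rep("non-HAS", sum(non))),
    stringsAsFactors = FALSE)
}

# A 300 s term-background record with one HAS burst of known centre.
# Burst durations are drawn in the window-matched band (32-44 s at 256 Hz,
# comparable to the 8000-sample movmad window) where the centre of weight
# is sharply identifiable; amplitude 200 uV against a 10 uV RMS background
# (contrast 20x).
make_burst_excerpt <- function(seed, dur_range = c(32, 44),
                               amplitude = 200) {
  set.seed(seed)
  dur <- runif(1, dur_range[1], dur_range[2])
  bg <- generate_background(300, "term", seed = 1000 + seed)
  x <- bg$samples
  burst <- generate_has_event(dur, amplitude, c(0.5, 4), 256,
                              seed = 2000 + seed)
  ctr_true <- (150 + round(runif(1, -15, 15))) * 256
  idx <- (ctr_true - length(burst) %/% 2) + seq_along(burst)
  x[idx] <- x[idx] + burst
  list(record = eeg_record(x), true_center = ctr_true,
       marked_minute = 3L, duration = dur)
}

# Brute-force movmad oracle: explicit centred shrinking windows and
# stats::median(), independent of the package's implementation.
movmad_oracle <- function(x, w, at = seq_along(x)) {
  vapply(at, function(i) {
    lo <- max(1, i - w %/% 2)
    hi <- min(length(x), i + (w + 1) %/% 2 - 1)
    win <- x[lo:hi]
    median(abs(win - median(win)))
  }, 0)
}

# Small labelled segment lists for classifier tests: high-contrast cohort
# cut into L-sample segments.
make_desk_dataset <- function(seed = 42L, duration = 2700,
                              contrast = 10, L = 1024L,
                              has_rate_base = 12, artifact_rate = 2) {
  cfg <- synthetic_cohort_config(
    animals_per_group = 2L, record_duration = duration,
    has_rate_base = has_rate_base, contrast = contrast,
    artifact_rate = artifact_rate,
    segment_length = L, seed = seed)
  co <- generate_cohort(cfg)
  ds <- build_segment_dataset(co, seed = seed + 1L)
  ds$cohort <- co
  ds
}

# Tiny architecture for fast engine tests (not one of the three detectors).
tiny_spec <- function(input_shape = c(8L, 6L, 1L)) {
  ns <- asNamespace("hasdetect")
  cnn_spec(input_shape, list(
    conv_layer(4), pool_layer(2, stride = 2), ns$flatten_layer(),
    fc_layer(6), fc_layer(2, relu = FALSE), ns$softmax_layer(),
    ns$classification_layer()), name = "tiny")
}
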