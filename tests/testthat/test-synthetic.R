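test_that("background generation is deterministic and rejects empty records", {
  a <- generate_background(600, "preterm", seed = 1)
  b <- generate_background(600, "preterm", seed = 1)
  expect_identical(a$samples, b$samples)
  expect_error(generate_background(0, "term", seed = 1), "positive")
  expect_error(generate_background(-5, "term", seed = 1), "positive")
})

test_that("term background carries more power above 8 Hz than preterm", {
  band_frac <- function(rec, lo, hi) {
    x <- rec$samples
    P <- abs(stats::fft(x))^2
    f <- (seq_along(x) - 1) * rec$fs / length(x)
    sum(P[f >= lo & f <= hi]) / sum(P[f >= 0.3 & f <= 128])
  }
  for (s in 1:3) {
    te <- generate_background(600, "term", seed = s)
    pe <- generate_background(600, "preterm", seed = s)
    # matched total power by construction (both scaled to their RMS target);
    # compare fractional band power above 8 Hz
    expect_gt(band_frac(te, 8, 30), 3 * band_frac(pe, 8, 30))
  }
})

test_that("background RMS stays well below the 20 uV seizure threshold", {
  te <- generate_background(300, "term", seed = 2)
  expect_lt(sqrt(mean(te$samples^2)), 20)
  expect_lt(abs(mean(te$samples)), 1e-8)
})

test_that("HAS events respect their definitional minima", {
  expect_error(generate_has_event(9, 50), "at least 10 s")
  expect_error(generate_has_event(30, 20), "20 uV")
  expect_error(generate_has_event(30, 15), "20 uV")
})

test_that("HAS waveform is delta-dominant, amplitude-exact and deterministic", {
  w <- generate_has_event(30, 100, rhythm_band = c(0.5, 4), fs = 256,
                          seed = 7)
  expect_identical(w, generate_has_event(30, 100, c(0.5, 4), 256, seed = 7))
  expect_equal(max(abs(w)), 100, tolerance = 1e-12)
  # dominant periodogram peak inside the configured band
  P <- abs(stats::fft(w))^2
  f <- (seq_along(w) - 1) * 256 / length(w)
  half <- which(f > 0 & f <= 128)
  f_peak <- f[half][which.max(P[half])]
  expect_gte(f_peak, 0.5)
  expect_lte(f_peak, 4)
})

test_that("preterm rhythm band keeps the dominant frequency under its edge", {
  for (s in 1:5) {
    w <- generate_has_event(20, 80, rhythm_band = c(0.5, 2.5), seed = s)
    P <- abs(stats::fft(w))^2
    f <- (seq_along(w) - 1) * 256 / length(w)
    half <- which(f > 0 & f <= 128)
    expect_lte(f[half][which.max(P[half])], 2.5)
  }
})

test_that("cohort config enforces definitional bounds", {
  expect_error(synthetic_cohort_config(has_amplitude_range = c(10, 50)),
               "20 uV")
  expect_error(synthetic_cohort_config(has_duration_range = c(5, 50)),
               "10 s")
})

test_that("sham group G3 never contains HAS events", {
  cfg <- synthetic_cohort_config(animals_per_group = 2L,
                                 record_duration = 1800,
                                 segment_length = 1024L, seed = 3L)
  co <- generate_cohort(cfg)
  g3 <- co$truth[co$truth$group == "G3", ]
  expect_equal(sum(g3$event_type == "HAS"), 0)
  # a config forcing seizures into the sham group is rejected
  cfg$has_rate[["G3"]] <- 1
  expect_error(generate_cohort(cfg), "sham")
})

test_that("cohort generation is a pure function of (config, seed)", {
  cfg <- synthetic_cohort_config(animals_per_group = 1L,
                                 record_duration = 900,
                                 segment_length = 1024L, seed = 11L)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(lapply(a$records, `[[`, "samples"),
                   lapply(b$records, `[[`, "samples"))
  expect_identical(a$truth, b$truth)
})

test_that("every truth HAS re-measures above definitional thresholds", {
  ds <- make_desk_dataset(seed = 42L)
  truth <- ds$cohort$truth
  has <- truth[truth$event_type == "HAS", ]
  expect_gt(nrow(has), 10)
  for (i in seq_len(nrow(has))) {
    rec <- ds$cohort$records[[paste(has$animal_id[i], has$channel[i],
                                    sep = "/")]]
    expect_gte((has$offset_sample[i] - has$onset_sample[i]) / rec$fs, 10)
    seg <- rec$samples[(has$onset_sample[i] + 1):has$offset_sample[i]]
    expect_gt(diff(range(seg)), 20)  # peak-to-peak amplitude
    expect_true(has$onset_sample[i] < has$center_sample[i] &&
                  has$center_sample[i] < has$offset_sample[i])
  }
  # events are non-overlapping within a channel
  for (key in unique(paste(truth$animal_id, truth$channel))) {
    tr <- truth[paste(truth$animal_id, truth$channel) == key, ]
    tr <- tr[order(tr$onset_sample), ]
    if (nrow(tr) > 1)
      expect_true(all(tr$onset_sample[-1] >=
                        tr$offset_sample[-nrow(tr)]))
  }
})

test_that("dataset HAS:non-HAS ratio tracks the configured 1:6.84", {
  ds <- make_desk_dataset(seed = 42L)
  n_has <- sum(ds$manifest$label == "HAS")
  n_non <- sum(ds$manifest$label == "non-HAS")
  expect_gt(n_has, 0)
  ratio <- n_non / n_has
  expect_gt(ratio, 6.84 * 0.9)
  expect_lt(ratio, 6.84 * 1.1)
})

test_that("a zero HAS rate yields a dataset of only non-HAS segments", {
  cfg <- synthetic_cohort_config(animals_per_group = 1L,
                                 record_duration = 900,
                                 has_rate_base = 0,
                                 segment_length = 1024L, seed = 5L)
  co <- generate_cohort(cfg)
  ds <- build_segment_dataset(co, seed = 6L)
  expect_gt(length(ds$segments), 0)
  expect_true(all(ds$manifest$label == "non-HAS"))
})

test_that("at high contrast an energy threshold separates the classes", {
  ds <- make_desk_dataset(seed = 43L, contrast = 10)
  n <- length(ds$segments)
  set.seed(1)
  idx <- sample(n)
  tr <- idx[seq_len(n %/% 2)]
  te <- idx[(n %/% 2 + 1):n]
  y <- ds$manifest$label
  bl <- energy_threshold_baseline(ds$segments[tr], y[tr], ds$segments[te])
  expect_gte(mean(bl$labels == y[te]), 0.99)
})
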