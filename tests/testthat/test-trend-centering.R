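test_that("power trend follows periodogram scaling exactly", {
  t <- seq_len(256 * 120) / 256
  base <- sin(2 * pi * 10 * t)
  p1 <- compute_power_trend(eeg_record(5 * base))
  p2 <- compute_power_trend(eeg_record(10 * base))
  # doubling the amplitude quadruples band power: +20*log10(4) dB per bin
  expect_equal(p2$values - p1$values, rep(20 * log10(4), 2),
               tolerance = 1e-8)
})

test_that("out-of-band tones sit at the numerical noise floor", {
  t <- seq_len(256 * 60) / 256
  in_band <- compute_power_trend(eeg_record(sin(2 * pi * 10 * t)))
  out_band <- compute_power_trend(eeg_record(sin(2 * pi * 30 * t)))
  expect_gt(in_band$values[1] - out_band$values[1], 60)
})

test_that("partial minutes are dropped and short records rejected", {
  expect_length(compute_power_trend(eeg_record(rnorm(256 * 61)))$values, 1L)
  expect_length(compute_power_trend(eeg_record(rnorm(256 * 120)))$values, 2L)
  expect_error(compute_power_trend(eeg_record(rnorm(256 * 59))),
               "one minute")
})

test_that("movmad agrees with a dense brute-force oracle", {
  set.seed(10)
  x <- rnorm(1500)
  for (w in c(2L, 7L, 64L, 301L))
    expect_equal(movmad(x, w), movmad_oracle(x, w), tolerance = 1e-12)
})

test_that("movmad at the production window agrees with the oracle", {
  set.seed(11)
  x <- rnorm(30721)
  at <- seq(1, length(x), by = 997)
  expect_equal(movmad(x, 8000L)[at], movmad_oracle(x, 8000L, at = at),
               tolerance = 1e-12)
})

test_that("centering recovers injected burst centres within one second", {
  errs <- vapply(1:20, function(s) {
    ex <- make_burst_excerpt(s)
    tr <- center_seizure(ex$record, ex$marked_minute)
    (tr$center_sample - ex$true_center) / 256
  }, 0)
  expect_gte(mean(abs(errs) <= 1), 0.9)
})

test_that("centering trace matches its definition and the movmad oracle", {
  ex <- make_burst_excerpt(3)
  tr <- center_seizure(ex$record, ex$marked_minute)
  expect_length(tr$sig_2, length(tr$sig_1))
  expect_length(tr$sig_3, length(tr$sig_1))
  # sig_2 is the normalised zero-meaned excerpt to the 10th power
  centred <- tr$sig_1 - mean(tr$sig_1)
  expect_equal(tr$sig_2, (abs(centred) / max(abs(centred)))^10,
               tolerance = 1e-12)
  # sig_3 is the movmad of sig_2; centre is its earliest argmax
  at <- sort(unique(c(which.max(tr$sig_3),
                      seq(1, length(tr$sig_3), by = 4999))))
  expect_equal(tr$sig_3[at], movmad_oracle(tr$sig_2, 8000L, at = at),
               tolerance = 1e-12)
  expect_equal(tr$center_sample - tr$excerpt_start,
               which.max(tr$sig_3) - 1L)
})

test_that("a flat excerpt centres at the midpoint", {
  rec <- eeg_record(rep(0, 256 * 180))
  tr <- center_seizure(rec, 2)
  expect_equal(tr$center_sample - tr$excerpt_start,
               floor(length(tr$sig_1) / 2))
})

test_that("identical twin bursts resolve to the first by tie-break", {
  # each burst must fill over half the movmad window (> 15.6 s), otherwise
  # every window's median deviation is identically zero on a silent record
  burst <- generate_has_event(20, 100, seed = 21)
  x <- numeric(256 * 180)
  c1 <- 70 * 256
  c2 <- 110 * 256
  for (ctr in c(c1, c2)) {
    idx <- (ctr - length(burst) %/% 2) + seq_along(burst)
    x[idx] <- x[idx] + burst
  }
  tr <- center_seizure(eeg_record(x), 2)   # excerpt 30-150 s covers both
  # identical translated copies make the movmad trace around each burst an
  # exact translate of the other; the earliest argmax wins the tie, so the
  # chosen centre belongs to the first burst's neighbourhood...
  expect_lt(tr$center_sample, 90 * 256)
  # ...and the trace value repeats exactly one burst-spacing later
  loc <- tr$center_sample - tr$excerpt_start + 1L
  expect_identical(tr$sig_3[loc], tr$sig_3[loc + (c2 - c1)])
})

test_that("centering is invariant under positive rescaling", {
  ex <- make_burst_excerpt(12)
  tr1 <- center_seizure(ex$record, ex$marked_minute)
  scaled <- ex$record
  scaled$samples <- scaled$samples * 37.5
  tr2 <- center_seizure(scaled, ex$marked_minute)
  expect_identical(tr1$center_sample, tr2$center_sample)
})

test_that("re-centering on the found centre moves at most half a window", {
  for (s in c(5, 9)) {
    ex <- make_burst_excerpt(s)
    tr1 <- center_seizure(ex$record, ex$marked_minute)
    minute2 <- floor((tr1$center_sample / 256) / 60) + 1L
    tr2 <- center_seizure(ex$record, minute2)
    expect_lte(abs(tr2$center_sample - tr1$center_sample), 4000)
  }
})

test_that("marked minutes outside the record are rejected", {
  rec <- eeg_record(rnorm(256 * 120))
  expect_error(center_seizure(rec, 0), "outside")
  expect_error(center_seizure(rec, 5), "outside")
})

test_that("extracted segments have exact length and documented window", {
  # 51,302 samples at 256 Hz span 3.34 minutes
  expect_equal(round(51302 / 256 / 60, 2), 3.34)
  rec <- eeg_record(seq_len(256 * 300))    # ramp encodes sample index + 1
  seg <- extract_segment(rec, center_sample = 38400, L = 51302L)
  expect_length(seg$samples, 51302L)
  expect_false(seg$padded)
  # window is [center - floor(L/2), center + ceiling(L/2))
  seg4 <- extract_segment(rec, center_sample = 100, L = 4L)
  expect_equal(seg4$samples, c(99, 100, 101, 102))  # samples 98..101, 0-based
  # edge windows are zero-padded and flagged
  seg0 <- extract_segment(rec, center_sample = 0, L = 64L)
  expect_length(seg0$samples, 64L)
  expect_true(seg0$padded)
  expect_equal(seg0$samples[seq_len(32)], rep(0, 32))
})

test_that("non-HAS sampling avoids every HAS interval", {
  ex <- make_burst_excerpt(7)
  dur_n <- round(ex$duration * 256)
  truth <- data.frame(event_type = "HAS",
                      onset_sample = ex$true_center - dur_n %/% 2,
                      offset_sample = ex$true_center + dur_n %/% 2)
  segs <- sample_non_has(ex$record, truth, n = 100, L = 1024L, seed = 5)
  expect_length(segs, 100L)
  for (s in segs) {
    lo <- s$center_sample - 512
    hi <- lo + 1024
    # exhaustive interval-intersection check against the truth table
    expect_true(hi <= truth$onset_sample || lo >= truth$offset_sample)
    expect_identical(s$label, "non-HAS")
  }
  # deterministic under a fixed seed
  again <- sample_non_has(ex$record, truth, n = 100, L = 1024L, seed = 5)
  expect_identical(vapply(segs, `[[`, 0, "center_sample"),
                   vapply(again, `[[`, 0, "center_sample"))
})

test_that("sampling fails with a clear message when no span is free", {
  rec <- eeg_record(rnorm(256 * 30))
  truth <- data.frame(event_type = "HAS", onset_sample = 0,
                      offset_sample = 256 * 30)
  expect_error(sample_non_has(rec, truth, n = 1, L = 1024L),
               "no HAS-free span")
})

test_that("QC plot writes a PNG with both panels", {
  ex <- make_burst_excerpt(2)
  tr <- center_seizure(ex$record, ex$marked_minute)
  path <- withr::local_tempfile(fileext = ".png")
  plot_centering_trace(tr, ex$record, path, L = 2048L)
  expect_true(file.exists(path))
  expect_gt(file.size(path), 1000)
})
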