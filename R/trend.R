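#' Per-minute EEG power trend
#'
#' For each complete minute of the record, a rectangular-window periodogram
#' is computed and the power in the 1-20 Hz band (bins inclusive) is summed
#' to give the minute's intensity; the trend value is `20 * log10(intensity)`
#' in dB. A trailing partial minute is dropped.
#'
#' @param record An [eeg_record()] of at least 60 s.
#' @param band Two-element band in Hz (default `c(1, 20)`).
#' @return An object of class `power_trend` with fields `values` (dB, one
#'   per complete minute), `band`, `bin_duration` (60 s) and `fs`.
#' @export
compute_power_trend <- function(record, band = c(1, 20)) {
  stopifnot(inherits(record, "eeg_record"), length(band) == 2L,
            band[1] < band[2])
  fs <- record$fs
  nb <- fs * 60
  n_min <- floor(length(record$samples) / nb)
  if (n_min < 1L)
    stop("record shorter than one minute (", record_duration(record),
         " s); the power trend needs at least one complete 60 s bin")
  f <- seq(0, nb - 1) * fs / nb
  keep <- which(f >= band[1] & f <= band[2])
  vals <- vapply(seq_len(n_min), function(i) {
    x <- record$samples[((i - 1) * nb + 1):(i * nb)]
    X <- stats::fft(x)
    # one-sided periodogram power in the band (rectangular window)
    p <- 2 * abs(X[keep])^2 / nb^2
    20 * log10(sum(p))
  }, 0)
  structure(list(values = vals, band = band, bin_duration = 60, fs = fs),
            class = "power_trend")
}

#' @export
print.power_trend <- function(x, ...) {
  cat(sprintf("<power_trend> %d one-minute bins, %g-%g Hz, %.1f to %.1f dB\n",
              length(x$values), x$band[1], x$band[2],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Moving median absolute deviation
#'
#' Sliding-window robust dispersion: for each sample, the median absolute
#' deviation of the values in a centred window of `window` samples (for
#' even windows the extra sample lies to the left of the centre), with the
#' window truncated (shrunk) at the record edges.
#'
#' @param x Numeric vector.
#' @param window Window length in samples.
#' @return Numeric vector of the same length as `x`.
#' @export
movmad <- function(x, window = 8000L) {
  stopifnot(is.numeric(x), length(x) >= 1L)
  movmad_cpp(as.numeric(x), as.integer(window))
}

#' Centre a marked seizure within its excerpt
#'
#' Implements the seizure-centering procedure used to turn a per-minute
#' power-trend mark into an exact seizure centre: take the raw EEG one
#' minute either side of the marked minute's midpoint (`sig_1`); zero-mean
#' it, normalise to unit peak and raise it elementwise to the 10th power to
#' intensify high-energy sections (`sig_2`; the normalisation only prevents
#' floating overflow - the argmax below is scale-invariant); pass it
#' through a moving median absolute deviation of window 8000 (`sig_3`); the
#' argmax of `sig_3` is the centre of weight of the seizure. Ties take the
#' earliest index; a fully flat trace falls back to the excerpt midpoint.
#'
#' @param record An [eeg_record()].
#' @param marked_minute 1-based index of the marked minute in the record's
#'   power trend.
#' @param window movmad window length (default 8000 samples).
#' @return An object of class `centering_trace`: `sig_1`, `sig_2`, `sig_3`,
#'   `sig_3_scaled` (rescaled to `sig_1`'s range, for QC plots only),
#'   `center_sample` (0-based, record coordinates), `excerpt_start`
#'   (0-based) and `fs`.
#' @export
center_seizure <- function(record, marked_minute, window = 8000L) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  n <- length(record$samples)
  n_min <- n / (60 * fs)
  if (marked_minute < 1 || marked_minute > ceiling(n_min))
    stop("marked minute ", marked_minute, " lies outside the record (",
         floor(n_min), " complete minutes)")
  mid <- round(((marked_minute - 1) + 0.5) * 60 * fs)   # 0-based midpoint
  lo <- max(0L, mid - 60L * fs)                          # 1 min either side
  hi <- min(n, mid + 60L * fs)                           # half-open
  sig_1 <- record$samples[(lo + 1):hi]
  centred <- sig_1 - mean(sig_1)
  peak <- max(abs(centred))
  sig_2 <- if (peak == 0) centred else (abs(centred) / peak)^10
  sig_3 <- movmad(sig_2, window)
  if (diff(range(sig_3)) == 0) {
    local <- floor(length(sig_3) / 2)                    # flat: midpoint
  } else {
    local <- which.max(sig_3) - 1L                       # earliest argmax
  }
  rng1 <- range(sig_1)
  rng3 <- range(sig_3)
  sig_3_scaled <- if (diff(rng3) == 0) rep(mean(rng1), length(sig_3)) else
    (sig_3 - rng3[1]) / diff(rng3) * diff(rng1) + rng1[1]
  structure(list(sig_1 = sig_1, sig_2 = sig_2, sig_3 = sig_3,
                 sig_3_scaled = sig_3_scaled,
                 center_sample = lo + local, excerpt_start = lo, fs = fs),
            class = "centering_trace")
}

#' @export
print.centering_trace <- function(x, ...) {
  cat(sprintf("<centering_trace> excerpt [%d, %d), centre at sample %d\n",
              x$excerpt_start, x$excerpt_start + length(x$sig_1),
              x$center_sample))
  invisible(x)
}

#' QC plot of a centering trace
#'
#' Writes a two-panel PNG: the raw excerpt with the (range-rescaled) movmad
#' trace and chosen centre overlaid, and the final centred segment.
#'
#' @param trace A `centering_trace`.
#' @param record The source [eeg_record()].
#' @param path Output PNG path.
#' @param L Segment length for the lower panel.
#' @return `path`, invisibly.
#' @export
plot_centering_trace <- function(trace, record, path, L = 51302L) {
  grDevices::png(path, width = 900, height = 600)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  t1 <- (trace$excerpt_start + seq_along(trace$sig_1) - 1) / trace$fs
  plot(t1, trace$sig_1, type = "l", col = "grey40", xlab = "time (s)",
       ylab = "uV", main = "excerpt with movmad weight")
  graphics::lines(t1, trace$sig_3_scaled, col = "red")
  graphics::abline(v = trace$center_sample / trace$fs, col = "blue", lty = 2)
  seg <- extract_segment(record, trace$center_sample, L = L)
  t2 <- seq_along(seg$samples) / trace$fs
  plot(t2, seg$samples, type = "l", col = "grey20", xlab = "time (s)",
       ylab = "uV", main = "centred segment")
  invisible(path)
}

#' Extract a fixed-length segment around a centre sample
#'
#' The window is `[center - floor(L/2), center + ceiling(L/2))` in 0-based
#' sample coordinates, giving exactly `L` samples; at 256 Hz the default
#' L = 51,302 spans 200.4 s (3.34 min). Windows overrunning the record
#' edges are zero-padded and flagged.
#'
#' @param record An [eeg_record()].
#' @param center_sample 0-based centre index.
#' @param L Segment length in samples.
#' @param label Segment label to attach (default `"HAS"`, since segments
#'   are usually cut around detected seizure centres).
#' @return An [eeg_segment()] with `padded = TRUE` when an edge was hit.
#' @export
extract_segment <- function(record, center_sample, L = 51302L,
                            label = "HAS") {
  stopifnot(inherits(record, "eeg_record"), L >= 1)
  n <- length(record$samples)
  lo <- center_sample - floor(L / 2)       # 0-based inclusive
  hi <- lo + L                             # 0-based exclusive
  out <- numeric(L)
  src_lo <- max(lo, 0L)
  src_hi <- min(hi, n)
  padded <- src_lo > lo || src_hi < hi
  if (src_hi > src_lo)
    out[(src_lo - lo + 1):(src_hi - lo)] <-
      record$samples[(src_lo + 1):src_hi]
  eeg_segment(out, label = label, animal_id = record$animal_id,
              channel = record$channel, group = record$group,
              center_sample = center_sample, fs = record$fs,
              padded = padded)
}

#' Randomly sample non-HAS segments from a record
#'
#' Draws `n` windows of length `L` whose half-open intervals do not
#' intersect any ground-truth HAS interval of the record. Windows may
#' contain artifacts or noise by design (a non-HAS epoch is any
#' electrophysiological activity that is not a seizure) and may overlap one
#' another. Sampling is uniform over the admissible window starts and
#' deterministic given the seed.
#'
#' @param record An [eeg_record()].
#' @param truth Ground-truth data frame for this record (columns
#'   `event_type, onset_sample, offset_sample`); only HAS rows constrain
#'   the sampling.
#' @param n Number of segments to draw.
#' @param L Segment length in samples.
#' @param seed Integer seed.
#' @return List of [eeg_segment()] objects labelled `"non-HAS"`.
#' @export
sample_non_has <- function(record, truth, n, L = 51302L, seed = 1L) {
  stopifnot(inherits(record, "eeg_record"), n >= 1, L >= 1)
  N <- length(record$samples)
  if (N < L)
    stop("record (", N, " samples) shorter than the segment length ", L)
  has <- truth[truth$event_type == "HAS", , drop = FALSE]
  # admissible 0-based starts: s in [0, N-L], window [s, s+L) disjoint from
  # every HAS interval [onset, offset)
  lim <- N - L
  free <- data.frame(lo = 0, hi = lim)                 # inclusive bounds
  if (nrow(has)) {
    for (i in seq_len(nrow(has))) {
      block_lo <- has$onset_sample[i] - L + 1          # first blocked start
      block_hi <- has$offset_sample[i] - 1             # last blocked start
      keep <- list()
      for (j in seq_len(nrow(free))) {
        a <- free$lo[j]; b <- free$hi[j]
        if (block_hi < a || block_lo > b) {
          keep[[length(keep) + 1L]] <- c(a, b)
        } else {
          if (a < block_lo) keep[[length(keep) + 1L]] <- c(a, block_lo - 1)
          if (b > block_hi) keep[[length(keep) + 1L]] <- c(block_hi + 1, b)
        }
      }
      free <- if (length(keep))
        as.data.frame(do.call(rbind, keep)) else
          data.frame(lo = numeric(0), hi = numeric(0))
      names(free) <- c("lo", "hi")
    }
  }
  total <- if (nrow(free)) sum(free$hi - free$lo + 1) else 0
  if (total < 1)
    stop("no HAS-free span of length ", L, " exists in ",
         record$animal_id, "/", record$channel,
         " (needed at least 1 admissible start, found 0)")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  u <- floor(stats::runif(n, 0, total))                # 0..total-1
  cum <- cumsum(free$hi - free$lo + 1)
  starts <- vapply(u, function(ui) {
    j <- which(ui < cum)[1]
    free$lo[j] + ui - (if (j > 1) cum[j - 1] else 0)
  }, 0)
  lapply(starts, function(s) {
    seg <- extract_segment(record, s + floor(L / 2), L = L,
                           label = "non-HAS")
    seg$label <- "non-HAS"
    seg
  })
}
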