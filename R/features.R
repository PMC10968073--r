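#' Morlet pseudo-frequency of a CWT scale
#'
#' The characteristic frequency associated with a Morlet wavelet scale:
#' `Fc * fs / scale`, with the conventional Morlet centre frequency
#' Fc = 0.8125 cycles per sample unit. At 256 Hz the scale grid 1..500
#' spans 208 Hz down to 0.42 Hz.
#'
#' @param scale Positive scale (vectorised).
#' @param fs Sampling rate in Hz.
#' @param fc Morlet centre frequency (default 0.8125).
#' @return Pseudo-frequency in Hz.
#' @export
morlet_pseudo_frequency <- function(scale, fs, fc = 0.8125) {
  if (any(scale <= 0)) stop("`scale` must be positive")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  fc * fs / scale
}

# Real Morlet mother wavelet ("morl"): psi(x) = exp(-x^2/2) cos(5 x),
# effective support [-4, 4].
morl_psi <- function(x) exp(-x^2 / 2) * cos(5 * x)

#' Continuous wavelet transform with the real Morlet wavelet
#'
#' Signed CWT coefficients `C[a, b] = sum_n x[n] psi((n - b)/a) / sqrt(a)`
#' computed by FFT convolution, one row per scale, same number of columns
#' as the input. Edges are treated as zero-padded.
#'
#' @param x Numeric signal.
#' @param scales Vector of positive scales.
#' @return `length(scales) x length(x)` matrix of signed coefficients.
#' @export
morlet_cwt <- function(x, scales) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(scales > 0))
  L <- length(x)
  out <- matrix(0, nrow = length(scales), ncol = L)
  for (i in seq_along(scales)) {
    a <- scales[i]
    h <- ceiling(4 * a)
    k <- (-h):h
    ker <- morl_psi(k / a) / sqrt(a)
    m <- stats::nextn(L + length(ker) - 1L, 2)
    Y <- stats::fft(stats::fft(c(x, numeric(m - L))) *
                      stats::fft(c(ker, numeric(m - length(ker)))),
                    inverse = TRUE) / m
    out[i, ] <- Re(Y[(h + 1):(h + L)])
  }
  out
}

#' Wavelet scalogram of an EEG segment
#'
#' Zero-means the segment and computes the magnitude of its Morlet CWT over
#' the scale grid 1, 6, ..., 496 (1 to 500 in steps of 5; 100 scales),
#' covering pseudo-frequencies 208 Hz down to 0.42 Hz at 256 Hz sampling.
#'
#' @param segment An [eeg_segment()] or numeric vector.
#' @param scales Scale grid (default `seq(1, 500, by = 5)`).
#' @param fs Sampling rate (taken from the segment when available).
#' @return An object of class `scalogram`: `coefficients` (|scales| x L
#'   magnitude matrix), `scales`, `fs`, `wavelet = "morlet"`.
#' @export
compute_scalogram <- function(segment, scales = seq(1, 500, by = 5),
                              fs = 256) {
  x <- if (inherits(segment, "eeg_segment")) segment$samples else
    as.numeric(segment)
  if (inherits(segment, "eeg_segment")) fs <- segment$fs
  x <- x - mean(x)
  coef <- abs(morlet_cwt(x, scales))
  structure(list(coefficients = coef, scales = scales, fs = fs,
                 wavelet = "morlet"),
            class = "scalogram")
}

#' @export
print.scalogram <- function(x, ...) {
  cat(sprintf("<scalogram> %d scales x %d samples (morlet, %g Hz)\n",
              nrow(x$coefficients), ncol(x$coefficients), x$fs))
  invisible(x)
}

# 64-entry jet colour map (dark blue -> blue -> cyan -> yellow -> red ->
# dark red), the fixed documented palette used for rendered scalograms.
jet_map <- function(n = 64L) {
  anchors <- rbind(c(0, 0, 0.5), c(0, 0, 1), c(0, 1, 1),
                   c(1, 1, 0), c(1, 0, 0), c(0.5, 0, 0))
  pos <- seq(0, 1, length.out = nrow(anchors))
  u <- seq(0, 1, length.out = n)
  sapply(1:3, function(ch) stats::approx(pos, anchors[, ch], u)$y)
}

#' Render a scalogram as a fixed-size RGB image
#'
#' Resamples the coefficient matrix to `width x height` by nearest-index
#' lookup (time on x, scale increasing downwards on y), normalises
#' intensities per image to the unit range (min-max), applies the fixed
#' 64-level jet palette and optionally writes a PNG with 300 dpi metadata.
#' Rendering is deterministic: the same segment yields a byte-identical
#' file.
#'
#' @param scalogram A [compute_scalogram()] result.
#' @param path Optional PNG output path.
#' @param width,height Image size in pixels (defaults 500 x 333).
#' @return The `height x width x 3` RGB array, invisibly when `path` is
#'   given.
#' @export
render_scalogram_image <- function(scalogram, path = NULL, width = 500L,
                                   height = 333L) {
  stopifnot(inherits(scalogram, "scalogram"))
  co <- scalogram$coefficients
  ri <- round(seq(1, nrow(co), length.out = height))
  ci <- round(seq(1, ncol(co), length.out = width))
  m <- co[ri, ci, drop = FALSE]
  rng <- range(m)
  v <- if (diff(rng) == 0) matrix(0, height, width) else
    (m - rng[1]) / diff(rng)
  pal <- jet_map(64L)
  idx <- pmin(63L, floor(v * 64)) + 1L
  img <- array(0, dim = c(height, width, 3L))
  for (ch in 1:3) img[, , ch] <- matrix(pal[idx, ch], height, width)
  if (!is.null(path)) {
    png::writePNG(img, target = path, dpi = 300)
    return(invisible(img))
  }
  img
}

#' Band-limited Fourier reconstruction
#'
#' Forward DFT, zeroing of all bins whose two-sided frequency magnitude
#' lies outside `[f_lo, f_hi]` (conjugate-symmetrically, so the inverse is
#' real up to numerical noise), inverse DFT. The default band 0.2-4.5 Hz
#' isolates the delta-dominant content neonatal seizures live in.
#'
#' @param x Numeric signal or [eeg_segment()].
#' @param fs Sampling rate.
#' @param f_lo,f_hi Band edges in Hz, `f_lo < f_hi`.
#' @return Real numeric vector of the same length.
#' @export
band_limited_reconstruction <- function(x, fs = 256, f_lo = 0.2,
                                        f_hi = 4.5) {
  if (f_lo >= f_hi) stop("`f_lo` must be below `f_hi`")
  if (inherits(x, "eeg_segment")) {
    fs <- x$fs
    x <- x$samples
  }
  n <- length(x)
  X <- stats::fft(x)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)
  X[f < f_lo | f > f_hi] <- 0
  y <- stats::fft(X, inverse = TRUE) / n
  resid <- max(abs(Im(y)))
  if (resid > 1e-9 * max(1e-300, sqrt(mean(Re(y)^2))) && resid > 1e-12)
    warning("imaginary residue ", signif(resid, 3),
            " after band-limited reconstruction")
  Re(y)
}

#' Three-column dominant-feature matrix (wavelet/Fourier front-end)
#'
#' Stacks, for one segment of length L, the signed Morlet CWT coefficients
#' at scale 80 (pseudo-frequency 2.6 Hz, near the delta-band mean), the
#' 0.2-4.5 Hz band-limited Fourier reconstruction, and the raw segment
#' itself, into an L x 3 matrix (presented to the 2D network as
#' L x 3 x 1).
#'
#' @param segment An [eeg_segment()] or numeric vector.
#' @param scale CWT scale for column 1 (default 80).
#' @param f_lo,f_hi Band for column 2.
#' @param fs Sampling rate.
#' @return An L x 3 matrix of class `wf_matrix` with columns
#'   `cwt80, bandlimited, raw`.
#' @export
compute_wf_matrix <- function(segment, scale = 80, f_lo = 0.2, f_hi = 4.5,
                              fs = 256) {
  x <- if (inherits(segment, "eeg_segment")) segment$samples else
    as.numeric(segment)
  if (inherits(segment, "eeg_segment")) fs <- segment$fs
  cwt <- drop(morlet_cwt(x, scale))
  bl <- band_limited_reconstruction(x, fs = fs, f_lo = f_lo, f_hi = f_hi)
  m <- cbind(cwt80 = cwt, bandlimited = bl, raw = x)
  class(m) <- c("wf_matrix", class(m))
  attr(m, "fs") <- fs
  m
}
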