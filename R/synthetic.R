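#' Configuration for a synthetic post-hypoxia-ischemia EEG cohort
#'
#' Describes the four study groups (G1 HI-normothermia term, G2
#' HI-hypothermia term, G3 sham-normothermia term, G4 HI-normothermia
#' preterm) and the statistical structure of the signals the generator
#' produces: 1/f-coloured background (with burst-suppression discontinuity
#' for the preterm group), high-amplitude stereotypic evolving seizures
#' (HAS: repetitive stereotyped delta-dominant discharge trains,
#' duration of 10 s or more, amplitude over 20 uV), and non-HAS artifacts (movement, mains
#' noise, electrode spikes).
#'
#' HAS rates are expressed per channel-hour; their relative sizes across
#' groups mirror the study composition (hypothermia suppresses the G2 rate
#' and amplitude by `hypothermia_suppression`; the preterm rate is 0.815 of
#' the term rate; the sham group has rate 0 by definition). `record_duration`
#' and `animals_per_group` are the scale dials: shrinking them scales the
#' whole cohort down proportionally.
#'
#' @param animals_per_group Integer vector (G1..G4) of animals per group.
#' @param record_duration Record length per channel, seconds.
#' @param fs Sampling rate, samples/s.
#' @param has_rate_base Base HAS rate for G1, events per channel-hour.
#' @param has_amplitude_range Range (uV) HAS peak amplitudes are drawn from;
#'   lower bound must exceed 20.
#' @param has_duration_range Range (s) HAS durations are drawn from; lower
#'   bound must be >= 10.
#' @param rhythm_band_term,rhythm_band_preterm Delta-dominant discharge
#'   bands (Hz); the preterm band has a lower upper edge.
#' @param background_rms_term,background_rms_preterm Background RMS (uV).
#' @param background_exponent_term,background_exponent_preterm Spectral
#'   exponents of the 1/f^a background.
#' @param hypothermia_suppression Multiplicative amplitude/rate factor
#'   applied to G2 (therapeutic hypothermia partially suppresses seizures).
#' @param artifact_rate Non-HAS artifact events per channel-hour.
#' @param non_has_per_has Non-HAS segments cut per HAS segment when building
#'   a classifier dataset (default 27,060/3,955 ~ 6.84, i.e. roughly 1:7).
#' @param non_has_weights Per-group shares of the non-HAS segment budget.
#' @param contrast Separability dial: divides the background RMS, raising
#'   the HAS-to-background amplitude ratio while keeping seizure and
#'   artifact amplitudes physiological. 1 is the realistic default; large
#'   values make segments separable by a trivial energy threshold.
#' @param segment_length Classifier segment length, samples.
#' @param seed Integer seed; generation is a pure function of
#'   (config, seed).
#' @return An object of class `synthetic_cohort_config`.
#' @export
synthetic_cohort_config <- function(
    animals_per_group = c(G1 = 7L, G2 = 14L, G3 = 5L, G4 = 14L),
    record_duration = 1800,
    fs = 256,
    has_rate_base = 6,
    has_amplitude_range = c(40, 250),
    has_duration_range = c(15, 90),
    rhythm_band_term = c(0.5, 4),
    rhythm_band_preterm = c(0.5, 2.5),
    background_rms_term = 10,
    background_rms_preterm = 8,
    background_exponent_term = 1,
    background_exponent_preterm = 1.6,
    hypothermia_suppression = 0.65,
    artifact_rate = 2,
    non_has_per_has = 27060 / 3955,
    non_has_weights = c(G1 = 4425, G2 = 8860, G3 = 4895, G4 = 8880) / 27060,
    contrast = 1,
    segment_length = 51302L,
    seed = 1L) {
  if (length(animals_per_group) == 1L)
    animals_per_group <- rep(animals_per_group, 4L)
  stopifnot(length(animals_per_group) == 4L, all(animals_per_group >= 0),
            record_duration > 0, fs > 0, has_rate_base >= 0,
            length(has_amplitude_range) == 2L,
            length(has_duration_range) == 2L,
            contrast > 0, segment_length > 0)
  if (has_amplitude_range[1] <= 20)
    stop("HAS amplitudes must exceed 20 uV (definitional minimum)")
  if (has_duration_range[1] < 10)
    stop("HAS durations must be at least 10 s (definitional minimum)")
  names(animals_per_group) <- c("G1", "G2", "G3", "G4")
  cfg <- list(
    animals_per_group = as.integer(animals_per_group),
    record_duration = record_duration, fs = fs,
    has_rate = c(G1 = has_rate_base,
                 G2 = has_rate_base * hypothermia_suppression,
                 G3 = 0,
                 G4 = has_rate_base * 0.815),
    has_amplitude_range = has_amplitude_range,
    has_duration_range = has_duration_range,
    rhythm_band = list(G1 = rhythm_band_term, G2 = rhythm_band_term,
                       G3 = rhythm_band_term, G4 = rhythm_band_preterm),
    background_rms = c(term = background_rms_term,
                       preterm = background_rms_preterm),
    background_exponent = c(term = background_exponent_term,
                            preterm = background_exponent_preterm),
    hypothermia_suppression = hypothermia_suppression,
    artifact_rate = artifact_rate,
    non_has_per_has = non_has_per_has,
    non_has_weights = non_has_weights,
    contrast = contrast,
    segment_length = as.integer(segment_length),
    maturity = c(G1 = "term", G2 = "term", G3 = "term", G4 = "preterm"),
    seed = as.integer(seed))
  names(cfg$animals_per_group) <- c("G1", "G2", "G3", "G4")
  structure(cfg, class = "synthetic_cohort_config")
}

#' Generate coloured-noise EEG background
#'
#' Zero-mean 1/f^a coloured noise shaped in the frequency domain. The term
#' variant is continuous with a broad band (low-pass edge 30 Hz); the
#' preterm variant has a steeper spectral slope, a lower edge (10 Hz) and
#' trace discontinuity, modelled as alternating burst/interburst amplitude
#' modulation (interburst epochs suppressed to 25% amplitude).
#'
#' @param duration_s Duration in seconds (> 0).
#' @param maturity `"term"` or `"preterm"`.
#' @param fs Sampling rate.
#' @param rms Target overall RMS amplitude in uV (default 10 term,
#'   8 preterm; well below the 20 uV seizure threshold).
#' @param exponent Spectral exponent a of the 1/f^a shape (default 1 term,
#'   1.6 preterm).
#' @param seed Integer seed; output is a deterministic function of the
#'   arguments.
#' @return An [eeg_record()] (channel/identity fields left at defaults).
#' @export
generate_background <- function(duration_s, maturity = c("term", "preterm"),
                                fs = 256, rms = NULL, exponent = NULL,
                                seed = 1L) {
  maturity <- match.arg(maturity)
  if (!is.numeric(duration_s) || duration_s <= 0)
    stop("`duration_s` must be positive; an empty record cannot be generated")
  if (is.null(rms)) rms <- if (maturity == "term") 10 else 8
  if (is.null(exponent)) exponent <- if (maturity == "term") 1 else 1.6
  n <- round(duration_s * fs)
  if (n < 2L) stop("duration too short at this sampling rate")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  x <- colored_noise(n, fs, exponent,
                     edge = if (maturity == "term") 30 else 10)
  if (maturity == "preterm") x <- x * discontinuity_envelope(n, fs)
  x <- x - mean(x)
  x <- x * (rms / stats::sd(x))
  eeg_record(x, fs = fs)
}

colored_noise <- function(n, fs, exponent, edge) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- seq(0, n - 1) * fs / n
  f <- pmin(f, fs - f)                      # two-sided frequency axis
  shape <- pmax(f, 0.3)^(-exponent / 2) / sqrt(1 + (f / edge)^8)
  shape[1] <- 0                             # kill DC
  Re(stats::fft(X * shape, inverse = TRUE)) / n
}

# Alternating burst/interburst amplitude modulation with smooth (0.25 s
# half-cosine) transitions; burst 4-10 s, interburst 2-8 s.
discontinuity_envelope <- function(n, fs, interburst_level = 0.25) {
  env <- numeric(0)
  state <- TRUE
  while (length(env) < n) {
    len <- round(fs * if (state) stats::runif(1, 4, 10)
                 else stats::runif(1, 2, 8))
    env <- c(env, rep(if (state) 1 else interburst_level, len))
    state <- !state
  }
  env <- env[seq_len(n)]
  k <- max(3L, round(0.25 * fs))
  stats::filter(c(rep(env[1], k), env, rep(env[n], k)),
                rep(1 / k, k), sides = 2)[(k + 1):(k + n)]
}

#' Generate a single high-amplitude stereotypic evolving seizure waveform
#'
#' A train of stereotyped sharp-wave discharges repeated at an
#' inter-discharge rate that evolves (slows) within the configured delta
#' band, under a waxing/waning envelope. Each discharge is the same
#' morphology throughout the event (the stereotypy that defines a HAS): a
#' Hann-windowed oscillation at a dominant frequency inside the band with a
#' sharpening third-harmonic component. The waveform's peak absolute
#' amplitude is scaled exactly to `amplitude_uV`.
#'
#' @param duration_s Event duration, seconds; must be >= 10 (definitional
#'   minimum for a HAS).
#' @param amplitude_uV Peak amplitude, uV; must exceed 20 (definitional
#'   minimum).
#' @param rhythm_band Two-element band (Hz) the discharge rhythm evolves in.
#' @param fs Sampling rate.
#' @param seed Integer seed.
#' @return Numeric waveform of `round(duration_s * fs)` samples.
#' @export
generate_has_event <- function(duration_s, amplitude_uV,
                               rhythm_band = c(0.5, 4), fs = 256,
                               seed = 1L) {
  if (duration_s < 10)
    stop("a HAS lasts at least 10 s; got ", duration_s, " s")
  if (amplitude_uV <= 20)
    stop("a HAS exceeds 20 uV in amplitude; got ", amplitude_uV, " uV")
  stopifnot(length(rhythm_band) == 2L, rhythm_band[1] > 0,
            rhythm_band[2] > rhythm_band[1])
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  lo <- rhythm_band[1]; hi <- rhythm_band[2]
  # discharge repetition rate sweeps from the upper to the lower half of the
  # band (post-ictal slowing of the rhythm)
  r0 <- stats::runif(1, lo + 0.6 * (hi - lo), hi)
  r1 <- stats::runif(1, lo, lo + 0.3 * (hi - lo))
  rate <- r0 + (r1 - r0) * (t / duration_s)        # instantaneous rate, Hz
  phase <- cumsum(rate) / fs                       # cycles elapsed
  # stereotyped discharge morphology, fixed for the whole event
  f_d <- stats::runif(1, lo + 0.3 * (hi - lo), hi) # dominant frequency
  sharp <- stats::runif(1, 0.15, 0.3)              # 3rd-harmonic content
  cyc <- phase %% 1                                # position within cycle
  duty <- 0.85                                     # discharge fills 85% cycle
  w <- ifelse(cyc < duty, 0.5 - 0.5 * cos(2 * pi * cyc / duty), 0)
  carrier <- sin(2 * pi * f_d * t) + sharp * sin(2 * pi * 3 * f_d * t)
  x <- w * carrier
  # waxing/waning envelope: a single smooth crescendo-decrescendo (root-Hann)
  # symmetric about the event midpoint, so the event's centre of weight (the
  # quantity seizure centering recovers) coincides with the stated centre
  env <- (0.5 - 0.5 * cos(2 * pi * t / duration_s))^0.5
  x <- x * env
  x / max(abs(x)) * amplitude_uV
}

#' Generate a non-seizure artifact waveform
#'
#' @param duration_s Duration, seconds.
#' @param fs Sampling rate.
#' @param kind `"movement"` (large slow lurch), `"mains"` (50 Hz electronic
#'   noise burst) or `"spike"` (brief electrode transient).
#' @param amplitude_uV Peak amplitude, uV.
#' @param seed Integer seed.
#' @return Numeric waveform.
#' @export
generate_artifact <- function(duration_s, fs = 256,
                              kind = c("movement", "mains", "spike"),
                              amplitude_uV = 80, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(duration_s > 0, amplitude_uV > 0)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  n <- round(duration_s * fs)
  t <- seq_len(n) / fs
  x <- switch(kind,
    movement = {
      k <- round(fs / 2)
      y <- stats::filter(c(numeric(k), cumsum(stats::rnorm(n)), numeric(k)),
                         rep(1 / k, k), sides = 2)[(k + 1):(k + n)]
      y * (0.5 - 0.5 * cos(2 * pi * t / duration_s))
    },
    mains = sin(2 * pi * 50 * t) * (0.5 - 0.5 * cos(2 * pi * t / duration_s)) +
      0.2 * stats::rnorm(n),
    spike = {
      tau <- 0.02
      tc <- duration_s / 2
      s <- (t - tc) / tau
      y <- ifelse(s > 0, s * exp(1 - s), 0)
      y - 0.4 * c(numeric(round(0.05 * fs)),
                  y[seq_len(n - round(0.05 * fs))])
    })
  x <- x - mean(x)
  x / max(abs(x)) * amplitude_uV
}

#' Generate a labelled synthetic cohort
#'
#' Produces two EEG channels per animal for each group in the configuration,
#' with HAS events (none in the sham group G3), artifacts and coloured-noise
#' background, plus a ground-truth event table. HAS amplitudes and the HAS
#' rate in G2 are scaled by the hypothermia suppression factor; the preterm
#' group uses the slower delta rhythm band and discontinuous background.
#'
#' @param config A [synthetic_cohort_config()].
#' @return An object of class `eeg_cohort`: `records` (list of
#'   [eeg_record()]) and `truth` (data frame: `animal_id, channel, group,
#'   event_type, onset_sample, offset_sample, center_sample`; 0-based,
#'   half-open intervals).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "synthetic_cohort_config"))
  if (config$has_rate[["G3"]] > 0)
    stop("the sham-normothermia group (G3) cannot contain HAS events")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)
  records <- list()
  truth <- list()
  fs <- config$fs
  dur_h <- config$record_duration / 3600
  n <- round(config$record_duration * fs)
  for (g in c("G1", "G2", "G3", "G4")) {
    mat <- config$maturity[[g]]
    amp_scale <- if (g == "G2") config$hypothermia_suppression else 1
    # the separability dial suppresses the background, keeping seizure
    # amplitudes physiological while raising the HAS-to-background ratio
    bg_rms <- config$background_rms[[mat]] / config$contrast
    for (a in seq_len(config$animals_per_group[[g]])) {
      animal <- sprintf("%s_A%02d", g, a)
      for (ch in c("left", "right")) {
        ch_seed <- config$seed + 7919L * match(g, c("G1", "G2", "G3", "G4")) +
          101L * a + 13L * (ch == "right")
        bg <- generate_background(config$record_duration, mat, fs = fs,
                                  rms = bg_rms, seed = ch_seed)
        x <- bg$samples
        n_has <- stats::rpois(1, config$has_rate[[g]] * dur_h)
        n_art <- stats::rpois(1, config$artifact_rate * dur_h)
        ev <- place_events(n, fs, n_has, n_art, config)
        if (nrow(ev)) {
          for (i in seq_len(nrow(ev))) {
            len_s <- (ev$offset[i] - ev$onset[i]) / fs
            if (ev$type[i] == "HAS") {
              amp <- stats::runif(1, config$has_amplitude_range[1],
                                  config$has_amplitude_range[2]) * amp_scale
              wav <- generate_has_event(len_s, amp,
                                        rhythm_band = config$rhythm_band[[g]],
                                        fs = fs,
                                        seed = ch_seed + 31L * i)
            } else {
              kind <- sample(c("movement", "mains", "spike"), 1L)
              wav <- generate_artifact(len_s, fs, kind,
                                       amplitude_uV = stats::runif(1, 30, 120),
                                       seed = ch_seed + 31L * i + 17L)
            }
            idx <- (ev$onset[i] + 1L):(ev$offset[i])
            x[idx] <- x[idx] + wav[seq_along(idx)]
          }
          ev$animal_id <- animal
          ev$channel <- ch
          ev$group <- g
          truth[[length(truth) + 1L]] <- ev
        }
        rec <- eeg_record(x, fs = fs, channel = ch, animal_id = animal,
                          group = g)
        records[[paste(animal, ch, sep = "/")]] <- rec
      }
    }
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(type = character(), onset = integer(), offset = integer(),
               center = integer(), animal_id = character(),
               channel = character(), group = character())
  truth <- data.frame(animal_id = truth$animal_id, channel = truth$channel,
                      group = truth$group, event_type = truth$type,
                      onset_sample = truth$onset,
                      offset_sample = truth$offset,
                      center_sample = truth$center,
                      stringsAsFactors = FALSE)
  structure(list(records = records, truth = truth, config = config),
            class = "eeg_cohort")
}

# Draw non-overlapping event intervals (0-based, half-open), HAS first, then
# artifacts, with a 30 s guard gap between events. Returns what fits.
place_events <- function(n, fs, n_has, n_art, config) {
  gap <- 30 * fs
  taken <- matrix(numeric(0), ncol = 2)
  out <- list()
  draw <- function(len) {
    for (try in seq_len(200L)) {
      onset <- floor(stats::runif(1, 0, max(1, n - len)))
      lo <- onset - gap; hi <- onset + len + gap
      if (!nrow(taken) || all(hi <= taken[, 1] | lo >= taken[, 2]))
        return(c(onset, onset + len))
    }
    NULL
  }
  for (i in seq_len(n_has)) {
    len <- round(stats::runif(1, config$has_duration_range[1],
                              config$has_duration_range[2]) * fs)
    if (len >= n) next
    iv <- draw(len)
    if (is.null(iv)) next
    taken <- rbind(taken, iv)
    out[[length(out) + 1L]] <- data.frame(
      type = "HAS", onset = iv[1], offset = iv[2],
      center = floor((iv[1] + iv[2]) / 2))
  }
  for (i in seq_len(n_art)) {
    len <- round(stats::runif(1, 1, 8) * fs)
    if (len >= n) next
    iv <- draw(len)
    if (is.null(iv)) next
    taken <- rbind(taken, iv)
    out[[length(out) + 1L]] <- data.frame(
      type = "artifact", onset = iv[1], offset = iv[2],
      center = floor((iv[1] + iv[2]) / 2))
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(type = character(), onset = integer(), offset = integer(),
               center = integer())
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d records, %d truth events (%d HAS)\n",
              length(x$records), nrow(x$truth),
              sum(x$truth$event_type == "HAS")))
  invisible(x)
}

#' Cut a labelled classifier dataset from a cohort
#'
#' Extracts one segment per ground-truth HAS (centred on the true centre, or
#' on the centre found by [center_seizure()] when `center = "detect"`) and
#' randomly samples non-HAS segments outside the HAS intervals, at
#' `non_has_per_has` non-HAS per HAS overall, distributed across groups by
#' the configured weights. If the cohort has no HAS at all, a fixed number
#' of non-HAS segments per channel is cut instead.
#'
#' @param cohort An `eeg_cohort`.
#' @param L Segment length in samples (default from the config).
#' @param center `"truth"` or `"detect"`.
#' @param non_has_per_record Fallback non-HAS count per channel when the
#'   cohort contains no HAS events.
#' @param seed Integer seed for the non-HAS sampling.
#' @return List with `segments` (list of [eeg_segment()]) and `manifest`
#'   (data frame with label/provenance per segment).
#' @export
build_segment_dataset <- function(cohort, L = NULL,
                                  center = c("truth", "detect"),
                                  non_has_per_record = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "eeg_cohort"))
  center <- match.arg(center)
  cfg <- cohort$config
  if (is.null(L)) L <- cfg$segment_length
  segments <- list()
  truth <- cohort$truth
  has <- truth[truth$event_type == "HAS", , drop = FALSE]
  for (i in seq_len(nrow(has))) {
    rec <- cohort$records[[paste(has$animal_id[i], has$channel[i],
                                 sep = "/")]]
    ctr <- if (center == "truth") has$center_sample[i] else {
      minute <- floor((has$center_sample[i] / rec$fs) / 60) + 1L
      center_seizure(rec, minute)$center_sample
    }
    segments[[length(segments) + 1L]] <-
      extract_segment(rec, ctr, L = L, label = "HAS")
  }
  # non-HAS budget split across groups by the configured weights, then
  # spread over that group's channels
  n_has_total <- nrow(has)
  per_group <- if (n_has_total > 0) {
    n_non <- round(cfg$non_has_per_has * n_has_total)
    round(n_non * cfg$non_has_weights /
            sum(cfg$non_has_weights))
  } else {
    g_count <- table(factor(vapply(cohort$records, `[[`, "", "group"),
                            levels = c("G1", "G2", "G3", "G4")))
    stats::setNames(as.numeric(g_count) * non_has_per_record,
                    c("G1", "G2", "G3", "G4"))
  }
  rec_groups <- vapply(cohort$records, `[[`, "", "group")
  k <- 0L
  for (g in c("G1", "G2", "G3", "G4")) {
    recs_g <- names(rec_groups)[rec_groups == g]
    if (!length(recs_g) || per_group[[g]] <= 0) next
    counts <- spread_counts(per_group[[g]], length(recs_g))
    for (j in seq_along(recs_g)) {
      if (counts[j] == 0L) next
      rec <- cohort$records[[recs_g[j]]]
      tr <- truth[truth$animal_id == rec$animal_id &
                    truth$channel == rec$channel, , drop = FALSE]
      k <- k + 1L
      segs <- sample_non_has(rec, tr, n = counts[j], L = L,
                             seed = seed + k)
      segments <- c(segments, segs)
    }
  }
  manifest <- data.frame(
    label = vapply(segments, `[[`, "", "label"),
    animal_id = vapply(segments, `[[`, "", "animal_id"),
    channel = vapply(segments, `[[`, "", "channel"),
    group = vapply(segments, `[[`, "", "group"),
    center_sample = vapply(segments, function(s) s$center_sample, 0),
    stringsAsFactors = FALSE)
  list(segments = segments, manifest = manifest)
}

spread_counts <- function(total, k) {
  base <- total %/% k
  extra <- total %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Write a cohort to disk
#'
#' One two-channel EDF file per animal plus a tab-separated ground-truth
#' annotation table (`truth.tsv`).
#'
#' @param cohort An `eeg_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  animals <- unique(vapply(cohort$records, `[[`, "", "animal_id"))
  for (a in animals) {
    chans <- cohort$records[vapply(cohort$records, `[[`, "", "animal_id") == a]
    write_edf(unname(chans), file.path(dir, paste0(a, ".edf")))
  }
  write_annotations(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

# RNG bookkeeping so seeded generators do not disturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible()
}
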