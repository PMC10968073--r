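#' Continuous EEG record
#'
#' Container for a single channel of continuous EEG sampled at a fixed rate
#' (canonically 256 Hz), in microvolts, with cohort identity attached.
#' Sample indices used throughout the package are 0-based and intervals are
#' half-open `[onset, offset)`.
#'
#' @param samples Numeric vector of EEG samples in microvolts. Must be finite.
#' @param fs Sampling rate in samples/s. Default 256.
#' @param channel Channel name, `"left"` or `"right"`.
#' @param animal_id Identifier of the animal the channel was recorded from.
#' @param group Cohort code: `"G1"` (HI-normothermia term), `"G2"`
#'   (HI-hypothermia term), `"G3"` (sham-normothermia term) or `"G4"`
#'   (HI-normothermia preterm).
#' @param t0 Acquisition origin of the first sample, in samples (0-based).
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs = 256, channel = c("left", "right"),
                       animal_id = "A1", group = c("G1", "G2", "G3", "G4"),
                       t0 = 0) {
  channel <- match.arg(channel)
  group <- match.arg(group)
  samples <- as.numeric(samples)
  if (length(samples) == 0L)
    stop("an EEG record must contain at least one sample")
  if (!all(is.finite(samples)))
    stop("EEG samples must all be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number")
  structure(
    list(samples = samples, fs = fs, channel = channel,
         animal_id = animal_id, group = group, t0 = as.numeric(t0)),
    class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s/%s [%s] %d samples @ %g Hz (%.1f s)\n",
              x$animal_id, x$channel, x$group, length(x$samples), x$fs,
              length(x$samples) / x$fs))
  invisible(x)
}

#' Number of samples and duration of a record
#' @param record An `eeg_record`.
#' @return `n_samples()` the sample count; `record_duration()` seconds.
#' @export
n_samples <- function(record) length(record$samples)

#' @rdname n_samples
#' @export
record_duration <- function(record) length(record$samples) / record$fs

#' Labelled fixed-length EEG epoch
#'
#' A fixed-length epoch cut from a continuous record, labelled `"HAS"`
#' (high-amplitude stereotypic evolving seizure) or `"non-HAS"`, with its
#' provenance. The canonical length is 51,302 samples (200.4 s at 256 Hz).
#'
#' @param samples Numeric vector in microvolts.
#' @param label `"HAS"` or `"non-HAS"`.
#' @param animal_id,channel,group Provenance of the source record.
#' @param center_sample 0-based index in the source record the epoch was
#'   centred on.
#' @param fs Sampling rate of the source record.
#' @param padded Logical; `TRUE` when the window overran a record edge and
#'   was zero-padded.
#' @return An object of class `eeg_segment`.
#' @export
eeg_segment <- function(samples, label = c("non-HAS", "HAS"),
                        animal_id = "A1", channel = "left", group = "G1",
                        center_sample = NA_real_, fs = 256, padded = FALSE) {
  label <- match.arg(label)
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("a segment must contain samples")
  if (!all(is.finite(samples))) stop("segment samples must all be finite")
  structure(
    list(samples = samples, label = label, animal_id = animal_id,
         channel = channel, group = group,
         center_sample = as.numeric(center_sample), fs = fs,
         padded = isTRUE(padded)),
    class = "eeg_segment")
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> %s  %d samples  %s/%s [%s]%s\n", x$label,
              length(x$samples), x$animal_id, x$channel, x$group,
              if (x$padded) " (edge-padded)" else ""))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Continuous-record file formats

#' Write a continuous EEG record to disk
#'
#' Three formats are supported: `"tsv"` (self-describing delimited text with
#' a commented metadata header), `"f32"` (a raw little-endian float32 array
#' with a JSON sidecar, the package's portable array container) and `"edf"`
#' (European Data Format; see [write_edf()]).
#'
#' @param record An `eeg_record` (for `"edf"` a list of records is also
#'   accepted and written as one multi-channel file).
#' @param path Output file path.
#' @param format One of `"tsv"`, `"f32"`, `"edf"`; `"auto"` picks by file
#'   extension.
#' @return `path`, invisibly.
#' @export
write_eeg_record <- function(record, path,
                             format = c("auto", "tsv", "f32", "edf")) {
  format <- match.arg(format)
  if (format == "auto") format <- format_from_ext(path)
  if (format == "edf") {
    recs <- if (inherits(record, "eeg_record")) list(record) else record
    return(write_edf(recs, path))
  }
  stopifnot(inherits(record, "eeg_record"))
  meta <- record[c("fs", "channel", "animal_id", "group", "t0")]
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    for (k in names(meta))
      writeLines(sprintf("# %s=%s", k, meta[[k]]), con)
    writeLines("uV", con)
    writeLines(format(record$samples, digits = 17, trim = TRUE,
                      scientific = FALSE), con)
  } else { # f32
    con <- file(path, "wb")
    writeBin(as.numeric(record$samples), con, size = 4L, endian = "little")
    close(con)
    jsonlite::write_json(c(meta, list(n = length(record$samples))),
                         paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

format_from_ext <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         tsv = "tsv", txt = "tsv",
         f32 = "f32", bin = "f32",
         edf = "edf",
         stop("cannot infer record format from extension '.", ext, "'"))
}

#' Read a continuous EEG record
#'
#' Reads a record written by [write_eeg_record()] (or any conforming file).
#' Samples are returned in microvolts; EDF physical-dimension fields are
#' honoured (mV is converted). A sampling rate other than 256 Hz triggers a
#' warning: the package's downstream defaults assume 256 Hz and no resampling
#' is performed.
#'
#' @param path Input file path.
#' @param format See [write_eeg_record()].
#' @param channels For EDF: channel labels to keep (default
#'   `c("left", "right")`); other channels are ignored with a notice.
#' @return An `eeg_record`, or for multi-channel EDF a list of them.
#' @export
read_eeg_record <- function(path, format = c("auto", "tsv", "f32", "edf"),
                            channels = c("left", "right")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") format <- format_from_ext(path)
  if (format == "edf") {
    recs <- read_edf(path, channels = channels)
    check_fs(recs[[1]]$fs)
    return(if (length(recs) == 1L) recs[[1]] else recs)
  }
  if (format == "tsv") {
    lines <- readLines(path)
    hdr <- grep("^# ", lines)
    meta <- list()
    for (h in lines[hdr]) {
      kv <- strsplit(sub("^# ", "", h), "=", fixed = TRUE)[[1]]
      meta[[kv[1]]] <- kv[2]
    }
    if (is.null(meta$fs)) stop("malformed header: no fs declared in ", path)
    body <- lines[-seq_len(max(hdr) + 1L)]
    rec <- eeg_record(as.numeric(body), fs = as.numeric(meta$fs),
                      channel = meta$channel %||% "left",
                      animal_id = meta$animal_id %||% "A1",
                      group = meta$group %||% "G1",
                      t0 = as.numeric(meta$t0 %||% 0))
  } else { # f32
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    if (is.null(meta$fs)) stop("malformed sidecar: no fs declared for ", path)
    con <- file(path, "rb")
    x <- readBin(con, what = "numeric", n = meta$n, size = 4L,
                 endian = "little")
    close(con)
    rec <- eeg_record(x, fs = as.numeric(meta$fs), channel = meta$channel,
                      animal_id = meta$animal_id, group = meta$group,
                      t0 = as.numeric(meta$t0))
  }
  check_fs(rec$fs)
  rec
}

check_fs <- function(fs) {
  if (!isTRUE(all.equal(fs, 256)))
    warning("record sampled at ", fs, " Hz, not 256 Hz; no resampling is ",
            "performed and downstream defaults assume 256 Hz", call. = FALSE)
  invisible(fs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Segment stores: a directory holding a delimited manifest plus one float32
# array file with all segment samples back to back.

#' Write a set of labelled segments to a segment store
#'
#' A store is a directory containing `manifest.csv` (one row per segment:
#' label, provenance, centre sample, pad flag), `samples.f32` (all samples
#' concatenated as little-endian float32) and `meta.json`. All segments in
#' one store must have identical length.
#'
#' @param segments List of [eeg_segment()] objects (may be empty).
#' @param path Directory to create/overwrite.
#' @return The manifest data frame, invisibly.
#' @export
write_segment_store <- function(segments, path) {
  stopifnot(is.list(segments))
  lens <- vapply(segments, function(s) length(s$samples), integer(1))
  if (length(unique(lens)) > 1L)
    stop("mixed segment lengths in one store are not allowed (found ",
         paste(unique(lens), collapse = ", "), ")")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(
    label = vapply(segments, `[[`, "", "label"),
    animal_id = vapply(segments, `[[`, "", "animal_id"),
    channel = vapply(segments, `[[`, "", "channel"),
    group = vapply(segments, `[[`, "", "group"),
    center_sample = vapply(segments, function(s) s$center_sample, 0),
    fs = vapply(segments, function(s) s$fs, 0),
    padded = vapply(segments, function(s) s$padded, FALSE),
    stringsAsFactors = FALSE)
  write.csv(manifest, file.path(path, "manifest.csv"), row.names = FALSE)
  con <- file(file.path(path, "samples.f32"), "wb")
  for (s in segments)
    writeBin(as.numeric(s$samples), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(
    list(n_segments = length(segments),
         segment_length = if (length(segments)) lens[1] else 0L),
    file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(manifest)
}

#' Read a segment store written by [write_segment_store()]
#'
#' @param path Store directory.
#' @return List of `eeg_segment` objects (empty list for an empty store).
#' @export
read_segment_store <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  manifest <- read.csv(file.path(path, "manifest.csv"),
                       stringsAsFactors = FALSE)
  if (meta$n_segments == 0L) return(list())
  con <- file(file.path(path, "samples.f32"), "rb")
  x <- readBin(con, what = "numeric",
               n = meta$n_segments * meta$segment_length, size = 4L,
               endian = "little")
  close(con)
  lapply(seq_len(meta$n_segments), function(i) {
    idx <- ((i - 1L) * meta$segment_length + 1L):(i * meta$segment_length)
    eeg_segment(x[idx], label = manifest$label[i],
                animal_id = manifest$animal_id[i],
                channel = manifest$channel[i], group = manifest$group[i],
                center_sample = manifest$center_sample[i],
                fs = manifest$fs[i], padded = manifest$padded[i])
  })
}

# ---------------------------------------------------------------------------
# Annotation tables (ground truth / event lists)

#' Write or read an event annotation table
#'
#' Delimited table with columns `animal_id, channel, group, event_type,
#' onset_sample, offset_sample, center_sample`; sample indices 0-based,
#' intervals half-open `[onset, offset)`.
#'
#' @param truth Data frame of events.
#' @param path File path (tab-separated).
#' @return `read_annotations()` returns the data frame.
#' @export
write_annotations <- function(truth, path) {
  write.table(truth, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
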