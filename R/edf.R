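# Minimal European Data Format (EDF) support, sufficient for two-channel
# 256 Hz EEG: 16-bit integer encoding, one-second data records, physical
# dimension honoured (uV canonical, mV converted on read). The per-signal
# reserved field carries the original sample count so that records whose
# length is not a whole number of seconds round-trip exactly (the trailing
# zero padding required by the format is dropped again on read).

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = "-")
}

num8 <- function(x) {
  for (d in c(6, 5, 4, 3, 2, 1)) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8) return(pad_ascii(s, 8))
  }
  stop("cannot encode ", x, " in an 8-character EDF field")
}

#' Write EEG records as a multi-channel EDF file
#'
#' All records must come from the same animal and share the same duration.
#' Signals are encoded as 16-bit integers with symmetric physical scaling,
#' so round-trip precision is `max(abs(x))/32767` per channel.
#'
#' @param records List of [eeg_record()] objects (one per channel).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(records, path) {
  stopifnot(length(records) >= 1L,
            all(vapply(records, inherits, TRUE, "eeg_record")))
  ns <- length(records)
  fs <- vapply(records, `[[`, 0, "fs")
  n <- vapply(records, function(r) length(r$samples), integer(1))
  ndr <- max(ceiling(n / fs))
  con <- file(path, "wb")
  on.exit(close(con))
  w <- function(s, width) writeChar(pad_ascii(s, width), con, nchars = width,
                                    eos = NULL)
  w("0", 8)
  w(records[[1]]$animal_id, 80)
  w(sprintf("animal=%s group=%s", records[[1]]$animal_id,
            records[[1]]$group), 80)
  w("01.01.00", 8)
  w("00.00.00", 8)
  w(as.character(256L * (ns + 1L)), 8)
  w("", 44)
  w(as.character(ndr), 8)
  w("1", 8)
  w(as.character(ns), 4)
  physmax <- vapply(records, function(r) max(1, max(abs(r$samples))), 0)
  for (r in records) w(r$channel, 16)
  for (r in records) w("AgAgCl electrode", 80)
  for (r in records) w("uV", 8)
  for (i in seq_len(ns)) w(num8(-physmax[i]), 8)
  for (i in seq_len(ns)) w(num8(physmax[i]), 8)
  for (i in seq_len(ns)) w("-32768", 8)
  for (i in seq_len(ns)) w("32767", 8)
  for (r in records) w("HP:1.6Hz LP:128Hz", 80)
  for (i in seq_len(ns)) w(as.character(fs[i]), 8)
  for (i in seq_len(ns)) w(sprintf("n=%d", n[i]), 32)
  # physmax as actually encoded (8-char ascii) so scaling is reversible;
  # encoding inverts the standard EDF decode map
  # x = physmin + (dig - digmin) * (physmax - physmin) / (digmax - digmin)
  physmax_enc <- vapply(physmax, function(p) as.numeric(num8(p)), 0)
  dig <- lapply(seq_len(ns), function(i) {
    x <- records[[i]]$samples
    x <- c(x, numeric(ndr * fs[i] - length(x)))
    p <- physmax_enc[i]
    d <- round((x + p) / (2 * p) * 65535) - 32768
    as.integer(pmin(32767, pmax(-32768, d)))
  })
  for (rec in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      idx <- ((rec - 1L) * fs[i] + 1L):(rec * fs[i])
      writeBin(dig[[i]][idx], con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' @param path EDF file path.
#' @param channels Channel labels to keep; `NULL` keeps all. Channels present
#'   in the file but not requested are ignored with a notice.
#' @return List of [eeg_record()] objects, one per kept channel.
#' @export
read_edf <- function(path, channels = c("left", "right")) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  version <- rd(8)
  if (!identical(version, "0")) stop("malformed EDF header in ", path)
  animal <- rd(80)
  recording <- rd(80)
  rd(8); rd(8)
  header_bytes <- as.integer(rd(8))
  rd(44)
  ndr <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L || is.na(ndr) ||
      header_bytes != 256L * (ns + 1L))
    stop("malformed EDF header in ", path)
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)            # transducer
  physdim <- vapply(seq_len(ns), function(i) rd(8), "")
  physmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  physmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digmin <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  digmax <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)            # prefiltering
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  reserved <- vapply(seq_len(ns), function(i) rd(32), "")
  keep <- if (is.null(channels)) seq_len(ns) else which(labels %in% channels)
  if (length(keep) == 0L)
    stop("no channel in ", path, " matches ", paste(channels, collapse = "/"))
  if (length(keep) < ns)
    message("ignoring ", ns - length(keep), " channel(s) in ", basename(path),
            ": ", paste(labels[-keep], collapse = ", "))
  group <- sub(".*group=(\\S+).*", "\\1", recording)
  if (!group %in% c("G1", "G2", "G3", "G4")) group <- "G1"
  sigs <- lapply(seq_len(ns), function(i) numeric(ndr * spr[i]))
  for (rec in seq_len(ndr)) {
    for (i in seq_len(ns)) {
      x <- readBin(con, what = "integer", n = spr[i], size = 2L,
                   endian = "little")
      if (i %in% keep)
        sigs[[i]][((rec - 1L) * spr[i] + 1L):(rec * spr[i])] <- x
    }
  }
  out <- lapply(keep, function(i) {
    x <- physmin[i] + (sigs[[i]] - digmin[i]) *
      (physmax[i] - physmin[i]) / (digmax[i] - digmin[i])
    if (identical(physdim[i], "mV")) x <- x * 1000
    n_orig <- suppressWarnings(as.integer(sub("^n=", "", reserved[i])))
    if (!is.na(n_orig) && n_orig <= length(x)) x <- x[seq_len(n_orig)]
    eeg_record(x, fs = spr[i] / dur,
               channel = if (labels[i] %in% c("left", "right"))
                 labels[i] else "left",
               animal_id = animal, group = group)
  })
  names(out) <- labels[keep]
  out
}
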