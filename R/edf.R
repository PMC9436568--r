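# Minimal European Data Format (EDF) writer/reader for continuous
# recordings, plus the tab-separated event sidecar. EDF stores 16-bit
# samples against per-channel physical ranges, so a write/read round trip
# quantizes amplitudes to ~1/65535 of each channel's range. Recordings are
# padded with zeros to a whole number of 1 s data records.

.edf_field <- function(x, width) {
  s <- as.character(x)
  if (nchar(s) > width) s <- substr(s, 1, width)
  formatC(s, width = -width)
}

.edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  if (nchar(s) > width) stop("cannot format ", x, " in ", width, " chars")
  .edf_field(s, width)
}

#' Write a recording to an EDF file
#'
#' Writes the continuous signal as 16-bit EDF with physical units in
#' microvolts and one-second data records, and (optionally) the event table
#' as a tab-separated sidecar via [write_events_tsv()].
#'
#' @param rec an [eeg_recording()]; `fs` must be a whole number.
#' @param path output EDF path.
#' @param events_path optional path for the event TSV.
#' @return `path`, invisibly.
#' @export
write_recording_edf <- function(rec, path, events_path = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate")
  x <- rec$data
  nch <- nrow(x)
  n <- ncol(x)
  n_rec <- ceiling(n / fs)
  if (n_rec * fs > n)
    x <- cbind(x, matrix(0, nch, n_rec * fs - n))

  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  flat <- hi - lo <= 0
  lo[flat] <- lo[flat] - 1
  hi[flat] <- hi[flat] + 1
  # The stored physical range is limited to 8 ASCII characters; round it
  # outward so no sample falls outside it, and digitize against the stored
  # (re-parsed) values so the reader reconstructs with identical scaling.
  fmt_outward <- function(v, rng, dir) {
    repeat {
      s <- .edf_num(v)
      if (dir * (as.numeric(trimws(s)) - v) >= 0) return(s)
      v <- v + dir * (1e-3 * rng + 1e-3 * abs(v) + 1e-9)
    }
  }
  rng <- hi - lo
  pmin_s <- mapply(fmt_outward, lo, rng, MoreArgs = list(dir = -1))
  pmax_s <- mapply(fmt_outward, hi, rng, MoreArgs = list(dir = 1))
  pmn <- as.numeric(trimws(pmin_s))
  pmx <- as.numeric(trimws(pmax_s))
  dmin <- -32768; dmax <- 32767
  dig <- round((x - pmn) / (pmx - pmn) * (dmax - dmin) + dmin)
  dig <- pmin(pmax(dig, dmin), dmax)
  storage.mode(dig) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    .edf_field("0", 8),
    .edf_field("X", 80),
    .edf_field("X", 80),
    .edf_field("01.01.00", 8),
    .edf_field("00.00.00", 8),
    .edf_field(256 * (nch + 1), 8),
    .edf_field("", 44),
    .edf_field(n_rec, 8),
    .edf_field(1, 8),
    .edf_field(nch, 4)), con, eos = NULL)
  fields <- c(
    vapply(rec$channels, .edf_field, "", width = 16),
    rep(.edf_field("", 80), nch),
    rep(.edf_field("uV", 8), nch),
    vapply(pmin_s, .edf_field, "", width = 8),
    vapply(pmax_s, .edf_field, "", width = 8),
    rep(.edf_field(dmin, 8), nch),
    rep(.edf_field(dmax, 8), nch),
    rep(.edf_field("", 80), nch),
    rep(.edf_field(fs, 8), nch),
    rep(.edf_field("", 32), nch))
  writeChar(paste(fields, collapse = ""), con, eos = NULL)
  # data records: per record, channels in sequence
  idx <- matrix(seq_len(n_rec * fs), nrow = fs)
  for (r in seq_len(n_rec))
    writeBin(as.vector(t(dig[, idx[, r]])), con, size = 2, endian = "little")
  if (!is.null(events_path)) write_events_tsv(rec$events, events_path)
  invisible(path)
}

#' Read an EDF file written by [write_recording_edf()]
#'
#' @param path EDF path.
#' @param events_path optional event TSV to attach.
#' @return an [eeg_recording()]. The signal length is the stored whole
#'   number of one-second records.
#' @export
read_recording_edf <- function(path, events_path = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(wd) trimws(readChar(con, wd, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  for (i in seq_len(nch)) rd(80)          # transducer
  for (i in seq_len(nch)) rd(8)           # unit
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(80)          # prefilter
  spr <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  for (i in seq_len(nch)) rd(32)
  if (length(unique(spr)) != 1L)
    stop("mixed per-channel sampling rates are not supported")
  fs <- spr[1] / rec_dur
  data <- matrix(0, nch, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    blk <- readBin(con, "integer", n = nch * spr[1], size = 2,
                   endian = "little")
    m <- matrix(blk, nrow = spr[1], ncol = nch)
    data[, (r - 1L) * spr[1] + seq_len(spr[1])] <- t(m)
  }
  data <- (data - dmin) / (dmax - dmin) * (pmax - pmin) + pmin
  events <- if (!is.null(events_path)) read_events_tsv(events_path, fs)
            else event_list(integer(0), character(0), fs)
  eeg_recording(data, fs, labels, events)
}

#' Write an event table as TSV
#'
#' Columns: `onset_sample` (0-based), `onset_s`, `code`.
#' @param events event data.frame from [event_list()].
#' @param path output path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an event TSV
#' @param path TSV path.
#' @param fs sampling rate used to recompute onset seconds.
#' @return event data.frame.
#' @export
read_events_tsv <- function(path, fs) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  event_list(ev$onset_sample, ev$code, fs)
}
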