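# Filtering, filter-bank construction, epoching, and bipolar derivation.
#
# All filters are Butterworth designs applied with exactly zero phase: the
# squared-magnitude response |H(f)|^2 (the response of one forward and one
# backward pass) is applied in the frequency domain to odd-reflection
# padded segments. The pad absorbs the filter's settling transient and the
# circular wrap-around; stopband attenuation is double that of a single
# pass.

# |H(e^jw)|^2 of the rational filter (b, a) on the length-nfft DFT grid
.h_mag2 <- function(b, a, nfft) {
  w <- 2 * pi * (seq_len(nfft) - 1) / nfft
  ejw <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- drop(ejw %*% b)
  ejw <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- drop(ejw %*% a)
  Mod(num / den)^2
}

# columns of x are independent series; odd-reflection pad, apply |H|^2 in
# the frequency domain, trim
.zp_filter_cols <- function(x, b, a, pad) {
  n <- nrow(x)
  p <- min(n - 1L, as.integer(pad))
  # grow the pad so the FFT length is 2-3-5-smooth (reflection can supply at
  # most n - 1 samples per side)
  nfft <- stats::nextn(n + 2L * p, c(2, 3, 5))
  if (nfft - n > 2L * (n - 1L)) nfft <- n + 2L * p
  extra <- nfft - n
  pr <- min(n - 1L, as.integer(ceiling(extra / 2)))
  pl <- extra - pr
  if (pl > n - 1L) { pl <- n - 1L; pr <- extra - pl }
  xe <- rbind(2 * rep(1, pl) %o% x[1L, ] - x[(pl + 1L):2L, , drop = FALSE],
              x,
              2 * rep(1, pr) %o% x[n, ] - x[(n - 1L):(n - pr), , drop = FALSE])
  h2 <- .h_mag2(b, a, nfft)
  y <- Re(stats::mvfft(stats::mvfft(xe) * h2, inverse = TRUE)) / nfft
  y[(pl + 1L):(pl + n), , drop = FALSE]
}

.zp_filter_vec <- function(x, b, a, pad) {
  drop(.zp_filter_cols(cbind(as.numeric(x)), b, a, pad))
}

# channels x samples orientation
.zp_filter_mat <- function(x, b, a, pad) {
  t(.zp_filter_cols(t(x), b, a, pad))
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth band-pass applied forward and backward
#' (zero-phase) with odd-reflection padding. Works on continuous
#' recordings, epoch sets (each trial filtered independently), plain
#' channel x sample matrices, or numeric vectors.
#'
#' @param x an [eeg_recording()], [epoch_set()], matrix or numeric vector.
#' @param low,high band edges in Hz; `0 <= low < high < fs/2`.
#' @param fs sampling rate, required only for matrix/vector input.
#' @param ... passed to methods.
#' @return object of the same class as `x`, filtered.
#' @export
bandpass <- function(x, low, high, ...) UseMethod("bandpass")

.band_design <- function(low, high, fs) {
  if (low < 0 || high <= low)
    stop("need 0 <= low < high")
  if (high >= fs / 2)
    stop("upper edge ", high, " Hz reaches the Nyquist frequency (fs/2 = ",
         fs / 2, " Hz)")
  flt <- if (low == 0) signal::butter(4, high / (fs / 2), type = "low")
         else signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  # pad long enough for both the low-edge corner and the bandwidth transient
  flt$pad <- ceiling(3 * fs * max(1 / max(low, 1), 1 / (high - low)))
  flt
}

#' @rdname bandpass
#' @export
bandpass.default <- function(x, low, high, fs, ...) {
  flt <- .band_design(low, high, fs)
  .zp_filter_vec(as.numeric(x), flt$b, flt$a, pad = flt$pad)
}

#' @rdname bandpass
#' @export
bandpass.matrix <- function(x, low, high, fs, ...) {
  flt <- .band_design(low, high, fs)
  .zp_filter_mat(x, flt$b, flt$a, pad = flt$pad)
}

#' @rdname bandpass
#' @export
bandpass.eeg_recording <- function(x, low, high, ...) {
  x$data <- bandpass.matrix(x$data, low, high, fs = x$fs)
  rownames(x$data) <- x$channels
  x
}

#' @rdname bandpass
#' @export
bandpass.epoch_set <- function(x, low, high, ...) {
  flt <- .band_design(low, high, x$fs)
  d <- dim(x$data)
  if (d[1] == 0) return(x)
  # batch all trial/channel series as columns of one matrix
  series <- matrix(aperm(x$data, c(3, 2, 1)), nrow = d[3])
  series <- .zp_filter_cols(series, flt$b, flt$a, flt$pad)
  x$data <- aperm(array(series, d[c(3, 2, 1)]), c(3, 2, 1))
  x
}

#' Zero-phase notch filter
#'
#' 2nd-order Butterworth band-stop centred on `f0` (default width 4 Hz)
#' applied forward-backward: attenuation exceeds 30 dB at `f0` while
#' frequencies 10 Hz away pass within 1 dB. The 60 Hz default removes
#' power-line interference.
#'
#' @param x recording, epoch set, matrix or numeric vector.
#' @param f0 notch centre in Hz, `0 < f0 < fs/2`.
#' @param width stop-band width in Hz.
#' @param fs sampling rate for matrix/vector input.
#' @param ... passed to methods.
#' @export
notch <- function(x, f0 = 60, width = 4, ...) UseMethod("notch")

.notch_design <- function(f0, width, fs) {
  if (f0 <= 0 || f0 >= fs / 2)
    stop("notch frequency ", f0, " Hz must lie in (0, fs/2)")
  flt <- signal::butter(2, c(f0 - width / 2, f0 + width / 2) / (fs / 2),
                        type = "stop")
  flt$pad <- ceiling(3 * fs / width)
  flt
}

#' @rdname notch
#' @export
notch.default <- function(x, f0 = 60, width = 4, fs, ...) {
  flt <- .notch_design(f0, width, fs)
  .zp_filter_vec(as.numeric(x), flt$b, flt$a, pad = flt$pad)
}

#' @rdname notch
#' @export
notch.matrix <- function(x, f0 = 60, width = 4, fs, ...) {
  flt <- .notch_design(f0, width, fs)
  .zp_filter_mat(x, flt$b, flt$a, pad = flt$pad)
}

#' @rdname notch
#' @export
notch.eeg_recording <- function(x, f0 = 60, width = 4, ...) {
  x$data <- notch.matrix(x$data, f0, width, fs = x$fs)
  rownames(x$data) <- x$channels
  x
}

#' Build an overlapping filter bank
#'
#' Constructs the list of sub-bands used by filter-bank CSP. Two edge
#' conventions are offered. The default, `"inclusive"`, counts band size and
#' overlap in inclusive integer frequencies, so
#' `build_filter_bank(76, 115, 10, 5)` yields the standard seven SSSEP
#' sub-bands 76-85, 81-90, ..., 106-115 Hz ("size 10 Hz, 5 Hz overlap").
#' The `"continuous"` convention uses `high = low + width` exactly.
#'
#' @param low0 lower edge of the first band, Hz.
#' @param high_max largest admissible upper edge, Hz.
#' @param width band size, Hz.
#' @param overlap overlap between consecutive bands, Hz; `width > overlap >= 0`.
#' @param edges `"inclusive"` or `"continuous"` (see Details).
#' @return data.frame of class `filter_bank` with columns `low`, `high`.
#' @export
#' @examples
#' build_filter_bank(76, 115, 10, 5)   # the 7 SSSEP sub-bands
build_filter_bank <- function(low0 = 76, high_max = 115, width = 10,
                              overlap = 5,
                              edges = c("inclusive", "continuous")) {
  edges <- match.arg(edges)
  if (!(width > overlap && overlap >= 0))
    stop("need width > overlap >= 0")
  span <- if (edges == "inclusive") width - 1 else width
  if (low0 + span > high_max)
    stop("first band [", low0, ", ", low0 + span, "] exceeds high_max = ",
         high_max)
  step <- width - overlap
  lows <- seq(low0, high_max - span, by = step)
  bank <- data.frame(low = lows, high = lows + span)
  class(bank) <- c("filter_bank", "data.frame")
  bank
}

#' Cut a recording into cue-locked epochs
#'
#' Extracts one trial per event whose code is in `codes`, over the half-open
#' window `[window[1], window[2])` seconds relative to the event onset.
#' Trial labels default to the event codes; `label_map` can rename them
#' (e.g. `c(CUE_LEFT = "LEFT", CUE_RIGHT = "RIGHT")`).
#'
#' @param rec an [eeg_recording()].
#' @param codes event codes that define trials.
#' @param window numeric `(start, end)` seconds relative to each event.
#' @param label_map optional named character vector mapping codes to labels.
#' @return an [epoch_set()]; zero trials if no event matches.
#' @export
epoch_recording <- function(rec, codes, window, label_map = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  ev <- rec$events[rec$events$code %in% codes, , drop = FALSE]
  fs <- rec$fs
  nsamp <- round((window[2] - window[1]) * fs)
  nch <- length(rec$channels)
  data <- array(0, dim = c(nrow(ev), nch, nsamp))
  for (i in seq_len(nrow(ev))) {
    start <- ev$onset_sample[i] + round(window[1] * fs)   # 0-based
    if (start < 0 || start + nsamp > ncol(rec$data))
      stop("epoch window [", window[1], ", ", window[2], ") for event ", i,
           " (", ev$code[i], " at sample ", ev$onset_sample[i],
           ") exceeds the recording bounds")
    data[i, , ] <- rec$data[, (start + 1L):(start + nsamp)]
  }
  labels <- if (nrow(ev)) {
    if (is.null(label_map)) ev$code else unname(label_map[ev$code])
  } else character(0)
  epoch_set(data, labels, fs, rec$channels, window)
}

#' Derive bipolar channels
#'
#' Appends anode-minus-cathode difference channels (labelled `"A-C"`) to a
#' recording; the original channels are untouched. The `CP1-Cz` / `Cz-CP2`
#' pair is the standard derivation for inspecting the SSSEP over the
#' somatosensory hand area.
#'
#' @param rec an [eeg_recording()].
#' @param pairs list of `c(anode, cathode)` character pairs.
#' @return an [eeg_recording()] with the derived channels appended.
#' @export
#' @examples
#' \dontrun{bipolar(rec, list(c("CP1", "Cz"), c("Cz", "CP2")))}
bipolar <- function(rec, pairs = list(c("CP1", "Cz"), c("Cz", "CP2"))) {
  stopifnot(inherits(rec, "eeg_recording"))
  derived <- lapply(pairs, function(p) {
    i <- match(p, rec$channels)
    if (anyNA(i))
      stop("unknown channel(s): ", paste(p[is.na(i)], collapse = ", "))
    rec$data[i[1], ] - rec$data[i[2], ]
  })
  labels <- vapply(pairs, function(p) paste(p, collapse = "-"), "")
  eeg_recording(rbind(rec$data, do.call(rbind, derived)), rec$fs,
                c(rec$channels, labels), rec$events)
}
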