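# Resonance-like frequency screening: trial-averaged FFT amplitude spectra
# at a contralateral central electrode, and the attention-minus-inattention
# difference scan over the candidate stimulation grid.

#' Trial-averaged single-sided amplitude spectrum
#'
#' Computes the discrete-Fourier amplitude spectrum of one channel for every
#' trial (rectangular window, FFT length the next power of two at or above
#' the trial length) and averages over trials. Amplitudes are scaled so a
#' unit-amplitude sinusoid completing an integer number of cycles in the
#' window peaks at 1.0.
#'
#' @param epochs an [epoch_set()] with at least one trial.
#' @param channel channel label to analyse (C4 for left-hand stimulation,
#'   C3 for right-hand, by the contralateral convention).
#' @param normalize if `TRUE`, scale amplitudes to a maximum of 1.
#' @return list of class `eeg_spectrum` with `freqs` (Hz), `amps`
#'   (dimensionless when normalized, otherwise input units) and `channel`.
#' @export
amplitude_spectrum <- function(epochs, channel, normalize = FALSE) {
  stopifnot(inherits(epochs, "epoch_set"))
  ci <- match(channel, epochs$channels)
  if (is.na(ci)) stop("unknown channel: ", channel)
  if (n_trials(epochs) < 1) stop("need at least one trial")
  n <- dim(epochs$data)[3]
  nfft <- 2^ceiling(log2(n))
  half <- nfft / 2 + 1
  acc <- numeric(half)
  for (tr in seq_len(n_trials(epochs))) {
    x <- epochs$data[tr, ci, ]
    sp <- stats::fft(c(x, numeric(nfft - n)))
    a <- 2 * Mod(sp[seq_len(half)]) / n
    a[1] <- a[1] / 2                       # DC is not duplicated
    if (nfft %% 2 == 0) a[half] <- a[half] / 2
    acc <- acc + a
  }
  amps <- acc / n_trials(epochs)
  if (normalize && max(amps) > 0) amps <- amps / max(amps)
  structure(list(freqs = (seq_len(half) - 1) * epochs$fs / nfft,
                 amps = amps, channel = channel),
            class = "eeg_spectrum")
}

#' Determine the resonance-like frequency from paired spectra
#'
#' Scans the candidate stimulation grid and returns the frequency with the
#' biggest attention-minus-inattention amplitude difference, each candidate
#' being evaluated at the nearest spectral bin. By default the absolute
#' difference is scanned; `signed = TRUE` restricts the scan to
#' attention-greater-than-inattention differences. Exact ties are broken
#' toward the lowest frequency with a warning.
#'
#' @param att,inatt `eeg_spectrum` objects on the same frequency grid.
#' @param candidates candidate frequencies in Hz (default the 85-127 Hz
#'   screening grid in 2 Hz steps).
#' @param signed scan signed rather than absolute differences.
#' @param side optional `"left"`/`"right"` tag carried into the result.
#' @return list of class `screening_result` with `f_star`, `channel_used`,
#'   `side` and `diff_by_freq` (candidate grid with differences).
#' @export
resonance_frequency <- function(att, inatt, candidates = seq(85, 127, by = 2),
                                signed = FALSE, side = NULL) {
  if (length(att$freqs) != length(inatt$freqs) ||
      max(abs(att$freqs - inatt$freqs)) > 1e-9)
    stop("attention and inattention spectra must share one frequency grid")
  if (!length(candidates)) stop("`candidates` must be nonempty")
  if (min(candidates) < min(att$freqs) || max(candidates) > max(att$freqs))
    stop("candidates fall outside the spectrum's frequency range")
  bins <- vapply(candidates,
                 function(f) which.min(abs(att$freqs - f)), integer(1))
  d <- att$amps[bins] - inatt$amps[bins]
  score <- if (signed) ifelse(d > 0, d, 0) else abs(d)
  if (all(d == 0) || (signed && all(score == 0)))
    stop(structure(class = c("noDiscriminablePeak", "error", "condition"),
                   list(message = paste("no discriminable attention peak:",
                                        "all candidate differences are zero"),
                        call = sys.call(-1))))
  best <- max(score)
  hits <- which(score == best)
  if (length(hits) > 1)
    warning("tie among candidates ",
            paste(candidates[hits], collapse = ", "),
            " Hz; taking the lowest")
  f_star <- candidates[min(hits)]
  structure(list(side = side, channel_used = att$channel, f_star = f_star,
                 diff_by_freq = data.frame(freq = candidates, diff = d)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat(sprintf("<screening_result> f* = %g Hz (%s%s)\n", x$f_star,
              x$channel_used,
              if (is.null(x$side)) "" else paste0(", ", x$side, " hand")))
  invisible(x)
}

#' Screen a recording for the resonance-like frequency of one hand
#'
#' Convenience wrapper: epochs the attention and inattention blocks of a
#' screening recording, computes trial-averaged spectra at the
#' contralateral central electrode (C4 for the left hand, C3 for the
#' right), and scans the candidate grid with [resonance_frequency()].
#'
#' @param rec screening [eeg_recording()] with `ATT_BLOCK`/`INATT_BLOCK`
#'   events.
#' @param side `"left"` or `"right"`.
#' @param candidates candidate grid in Hz.
#' @param window epoch window in seconds relative to block onset.
#' @param channel override the contralateral channel convention.
#' @param signed passed to [resonance_frequency()].
#' @return a `screening_result`.
#' @export
screen_recording <- function(rec, side = c("left", "right"),
                             candidates = seq(85, 127, by = 2),
                             window = c(0, 2), channel = NULL,
                             signed = FALSE) {
  side <- match.arg(side)
  channel <- channel %||% if (side == "left") "C4" else "C3"
  att <- epoch_recording(rec, "ATT_BLOCK", window)
  inatt <- epoch_recording(rec, "INATT_BLOCK", window)
  resonance_frequency(amplitude_spectrum(att, channel),
                      amplitude_spectrum(inatt, channel),
                      candidates, signed = signed, side = side)
}
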