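# Core containers: continuous recordings, event lists, and epoch sets.
# Conventions: channel x sample matrices, microvolts, 0-based sample onsets,
# half-open time windows [start, end).

#' Event marker codes
#'
#' The symbolic event codes used by the simulators and the epoching
#' machinery: trial cues (`CUE_LEFT`, `CUE_RIGHT`), stimulation on/offsets,
#' screening attention/inattention block starts, and rest markers.
#'
#' @export
EVENT_CODES <- c("CUE_LEFT", "CUE_RIGHT", "STIM_ON", "STIM_OFF",
                 "ATT_BLOCK", "INATT_BLOCK", "REST")

#' Build an event list
#'
#' @param onset 0-based sample indices, nondecreasing.
#' @param code character vector of codes from [EVENT_CODES].
#' @param fs sampling rate in Hz, used to derive onset times in seconds.
#' @return a data.frame with columns `onset_sample`, `onset_s`, `code`.
#' @export
event_list <- function(onset, code, fs) {
  onset <- as.integer(onset)
  code <- as.character(code)
  if (length(onset) != length(code))
    stop("`onset` and `code` must have the same length")
  if (is.unsorted(onset))
    stop("event onsets must be nondecreasing")
  bad <- setdiff(unique(code), EVENT_CODES)
  if (length(bad))
    stop("unknown event code(s): ", paste(bad, collapse = ", "))
  data.frame(onset_sample = onset, onset_s = onset / fs, code = code,
             stringsAsFactors = FALSE)
}

#' Construct a continuous EEG recording
#'
#' @param data channels x samples numeric matrix, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels channel labels (defaults to `rownames(data)`).
#' @param events event data.frame as returned by [event_list()].
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels = rownames(data),
                          events = event_list(integer(0), character(0), fs)) {
  data <- as.matrix(data)
  if (is.null(channels))
    stop("channel labels are required")
  channels <- as.character(channels)
  if (nrow(data) != length(channels))
    stop("rows of `data` (", nrow(data), ") must match the number of channel ",
         "labels (", length(channels), ")")
  if (anyDuplicated(channels))
    stop("channel labels must be unique")
  if (!is.numeric(fs) || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz")
  if (nrow(events) && (min(events$onset_sample) < 0 ||
                       max(events$onset_sample) >= ncol(data)))
    stop("event onsets must lie within [0, n_samples)")
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = channels, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d events\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$events)))
  invisible(x)
}

#' Construct an epoch set
#'
#' The trial unit consumed by every feature-extraction stage: a
#' trials x channels x samples array with one class label per trial.
#'
#' @param data trials x channels x samples numeric array, microvolts.
#' @param labels per-trial class labels (character or factor).
#' @param fs sampling rate in Hz.
#' @param channels channel labels.
#' @param window `(t_start, t_end)` in seconds relative to the locking event.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(data, labels, fs, channels, window) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a trials x channels x samples array")
  labels <- as.factor(labels)
  if (dim(data)[1] != length(labels))
    stop("label length (", length(labels), ") must equal the trial count (",
         dim(data)[1], ")")
  if (dim(data)[2] != length(channels))
    stop("channel label count must match dim(data)[2]")
  nsamp <- round((window[2] - window[1]) * fs)
  if (dim(data)[3] != nsamp)
    stop("window length x fs (", nsamp, ") must equal the sample count (",
         dim(data)[3], ")")
  structure(list(data = data, labels = labels, fs = fs,
                 channels = as.character(channels),
                 window = as.numeric(window[1:2])),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d trials x %d channels x %d samples @ %g Hz, window [%g, %g) s\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$fs,
              x$window[1], x$window[2]))
  if (dim(x$data)[1]) print(table(x$labels))
  invisible(x)
}

#' Number of trials in an epoch set
#' @param epochs an `epoch_set`.
#' @export
n_trials <- function(epochs) dim(epochs$data)[1]
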