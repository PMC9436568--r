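# Synthetic SSSEP session generator.
#
# The simulator plants the statistical structure the downstream analysis
# assumes: two hand-specific steady-state oscillations in the 85-127 Hz
# range with contralateral scalp topographies, an attention-dependent
# amplitude gain on the attended hand's oscillation, and 1/f background
# noise with a small spatially shared component.

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic selective-attention
#' (SA) and screening sessions.
#'
#' @param f_left left-hand stimulation frequency in Hz (evokes a
#'   right-hemisphere SSSEP).
#' @param f_right right-hand stimulation frequency in Hz.
#' @param amp base oscillation amplitude at the topography peak, microvolts.
#' @param gamma attention gain (dimensionless, >= 0): the attended side's
#'   oscillation has amplitude `amp * (1 + gamma)`.
#' @param noise_scale standard deviation of the background noise per
#'   channel, microvolts.
#' @param noise_exponent spectral slope beta of the 1/f^beta background.
#' @param fs sampling rate, Hz.
#' @param n_trials_per_class cued trials per side in an SA session.
#' @param seed RNG seed; identical configurations give bit-identical
#'   recordings.
#' @param cue_s duration of the attention cue (arrow) in seconds. The
#'   stimulation window of each trial runs from 2 s to `4 + cue_s` s.
#' @param allow_equal_freqs set `TRUE` to permit `f_left == f_right`.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(f_left = 90, f_right = 92, amp = 1, gamma = 0.6,
                       noise_scale = 2, noise_exponent = 1, fs = 500,
                       n_trials_per_class = 45, seed = 1, cue_s = 4,
                       allow_equal_freqs = FALSE) {
  if (fs <= 0) stop("`fs` must be positive")
  for (f in c(f_left, f_right))
    if (f <= 0 || f >= fs / 2)
      stop("stimulation frequency ", f,
           " Hz violates the Nyquist limit (0, fs/2) = (0, ", fs / 2, ")")
  if (f_left == f_right && !allow_equal_freqs)
    stop("f_left == f_right; set allow_equal_freqs = TRUE if intended")
  if (gamma < 0) stop("`gamma` must be >= 0")
  if (noise_scale < 0) stop("`noise_scale` must be >= 0")
  if (n_trials_per_class < 1) stop("`n_trials_per_class` must be >= 1")
  if (cue_s <= 0) stop("`cue_s` must be positive")
  structure(list(f_left = f_left, f_right = f_right, amp = amp,
                 gamma = gamma, noise_scale = noise_scale,
                 noise_exponent = noise_exponent, fs = fs,
                 n_trials_per_class = as.integer(n_trials_per_class),
                 seed = seed, cue_s = cue_s),
            class = "sim_config")
}

#' 1/f^beta noise
#'
#' Generates a zero-mean, unit-variance series whose expected power spectrum
#' is proportional to `1/f^beta`, by shaping the spectrum of Gaussian white
#' noise. `beta = 0` gives white noise; `beta = 1` the pink background used
#' as the default EEG noise floor.
#'
#' @param n_samples series length.
#' @param beta spectral slope (>= 0).
#' @param seed optional seed; the same seed yields an identical series.
#' @return numeric vector of length `n_samples`.
#' @export
pink_noise <- function(n_samples, beta = 1, seed = NULL) {
  if (n_samples < 1) stop("`n_samples` must be positive")
  if (beta < 0) stop("`beta` must be >= 0")
  with_seed(seed, drop(.pink_noise_matrix(1L, n_samples, beta)))
}

# channels x samples matrix of independent 1/f^beta series (column-major fft
# over channels at once); each row centred and scaled to unit sd.
.pink_noise_matrix <- function(n_ch, n, beta) {
  w <- matrix(stats::rnorm(n_ch * n), nrow = n, ncol = n_ch)
  if (beta == 0) {
    x <- w
  } else {
    spec <- stats::mvfft(w)
    k <- c(1, seq_len(n - 1))                    # guard DC
    shape <- k^(-beta / 2)
    shape[1] <- 0                                # remove DC
    # mirror the shaping so the filter is real (conjugate-symmetric)
    half <- floor(n / 2)
    shape[(half + 2):n] <- shape[n - seq((half + 2), n) + 2]
    x <- Re(stats::mvfft(spec * shape, inverse = TRUE)) / n
  }
  x <- sweep(x, 2, colMeans(x))
  sds <- apply(x, 2, stats::sd)
  sds[sds == 0] <- 1
  t(sweep(x, 2, sds, "/"))
}

#' Scalp projection weights of the two hand sources
#'
#' Each hand's SSSEP source projects onto the scalp with a smooth Gaussian
#' profile in flattened montage coordinates, centred over the contralateral
#' somatosensory hand area: between C4 and CP2 for the left hand, between C3
#' and CP1 for the right hand, with spatial width 0.35 disc units. The
#' weight at the profile centre is 1, so channel amplitudes are the source
#' amplitude times the returned weight.
#'
#' @param montage a [make_montage()] montage.
#' @param width Gaussian spatial width in disc units.
#' @return list with numeric weight vectors `left` and `right` (one entry
#'   per channel, named).
#' @export
sa_topography <- function(montage = make_montage(), width = 0.35) {
  pos <- cbind(montage$x, montage$y)
  centre_left <- colMeans(montage_position(montage, c("C4", "CP2")))
  centre_right <- colMeans(montage_position(montage, c("C3", "CP1")))
  wfun <- function(centre) {
    d2 <- (pos[, 1] - centre[1])^2 + (pos[, 2] - centre[2])^2
    w <- exp(-d2 / (2 * width^2))
    names(w) <- montage$label
    w
  }
  list(left = wfun(centre_left), right = wfun(centre_right))
}

# shared noise model: per-channel independent pink noise plus a 20%-variance
# spatially common component, scaled to `noise_scale` sd per channel
.session_noise <- function(n_ch, n, cfg) {
  if (cfg$noise_scale == 0) return(matrix(0, n_ch, n))
  indep <- .pink_noise_matrix(n_ch, n, cfg$noise_exponent)
  shared <- .pink_noise_matrix(1L, n, cfg$noise_exponent)
  cfg$noise_scale * (sqrt(0.8) * indep +
                     sqrt(0.2) * matrix(shared, n_ch, n, byrow = TRUE))
}

#' Simulate a selective-attention session
#'
#' Generates a continuous recording of `2 * n_trials_per_class` concatenated
#' 10 s trials (white fixation 2 s, preparation 2 s, attention cue `cue_s`
#' s, rest). Vibrotactile stimulation runs from 2 s to `4 + cue_s` s of each
#' trial; during stimulation both hand oscillations are present, projected
#' with their contralateral topographies, and the attended side's
#' oscillation is scaled by `1 + gamma`. Oscillation phase is drawn
#' uniformly per trial; cue order is pseudorandom and balanced under the
#' configuration seed.
#'
#' @param cfg a [sim_config()].
#' @param montage montage to simulate; defaults to [make_montage()].
#' @return an [eeg_recording()] with `STIM_ON`, `CUE_LEFT`/`CUE_RIGHT`,
#'   `STIM_OFF` and `REST` events.
#' @export
simulate_sa_session <- function(cfg = sim_config(), montage = make_montage()) {
  stopifnot(inherits(cfg, "sim_config"))
  fs <- cfg$fs
  trial_s <- 2 + 2 + cfg$cue_s + 2
  trial_len <- round(trial_s * fs)
  n_tr <- 2L * cfg$n_trials_per_class
  total <- n_tr * trial_len
  topo <- sa_topography(montage)
  stim_start <- round(2 * fs)
  stim_end <- round((4 + cfg$cue_s) * fs)          # half-open [start, end)
  cue_start <- round(4 * fs)

  with_seed(cfg$seed, {
    cues <- sample(rep(c("CUE_LEFT", "CUE_RIGHT"),
                       each = cfg$n_trials_per_class))
    phases <- matrix(stats::runif(2 * n_tr, 0, 2 * pi), nrow = n_tr)
    data <- .session_noise(nrow(montage), total, cfg)

    idx_rel <- stim_start:(stim_end - 1L)
    t_rel <- idx_rel / fs
    for (tr in seq_len(n_tr)) {
      off <- (tr - 1L) * trial_len
      a_left <- cfg$amp * (1 + cfg$gamma * (cues[tr] == "CUE_LEFT"))
      a_right <- cfg$amp * (1 + cfg$gamma * (cues[tr] == "CUE_RIGHT"))
      s_left <- a_left * sin(2 * pi * cfg$f_left * t_rel + phases[tr, 1])
      s_right <- a_right * sin(2 * pi * cfg$f_right * t_rel + phases[tr, 2])
      cols <- off + idx_rel + 1L
      data[, cols] <- data[, cols] + outer(topo$left, s_left) +
        outer(topo$right, s_right)
    }
  })

  starts <- (seq_len(n_tr) - 1L) * trial_len
  ev <- event_list(
    onset = as.vector(rbind(starts + stim_start, starts + cue_start,
                            starts + stim_end, starts + stim_end)),
    code = as.vector(rbind(rep("STIM_ON", n_tr), cues,
                           rep("STIM_OFF", n_tr), rep("REST", n_tr))),
    fs = fs)
  eeg_recording(data, fs, montage$label, ev)
}

#' Simulate a screening session for one hand
#'
#' For each candidate stimulation frequency, generates a paired attention
#' block and inattention block (2 s each, contiguous) in which the
#' candidate-frequency oscillation is present with the hand's contralateral
#' topography. Attention multiplies the oscillation amplitude by
#' `1 + gamma * exp(-(f - f_side)^2 / (2 * sigma_f^2))` with `sigma_f = 3`
#' Hz, so the attention-minus-inattention spectral difference is maximal at
#' the planted resonance-like frequency of that side (`f_left` or
#' `f_right` of the configuration).
#'
#' @param cfg a [sim_config()]; `f_left`/`f_right` act as the planted
#'   resonance-like frequencies.
#' @param side `"left"` or `"right"` (which hand is stimulated).
#' @param candidate_freqs candidate grid in Hz, default 85 to 127 in 2 Hz
#'   steps.
#' @param block_s block duration in seconds.
#' @param sigma_f width (Hz) of the attention-gain profile around the
#'   resonance-like frequency.
#' @param montage montage to simulate.
#' @return an [eeg_recording()] with `ATT_BLOCK`/`INATT_BLOCK` events, one
#'   pair per candidate frequency.
#' @export
simulate_screening_session <- function(cfg = sim_config(),
                                       side = c("left", "right"),
                                       candidate_freqs = seq(85, 127, by = 2),
                                       block_s = 2, sigma_f = 3,
                                       montage = make_montage()) {
  stopifnot(inherits(cfg, "sim_config"))
  side <- match.arg(side)
  if (!length(candidate_freqs)) stop("`candidate_freqs` must be nonempty")
  if (any(candidate_freqs <= 0 | candidate_freqs >= cfg$fs / 2))
    stop("candidate frequencies violate the Nyquist limit (0, fs/2)")
  fs <- cfg$fs
  f_side <- if (side == "left") cfg$f_left else cfg$f_right
  topo <- sa_topography(montage)[[side]]
  blk <- round(block_s * fs)
  n_cand <- length(candidate_freqs)
  n_blocks <- 2L * n_cand
  total <- n_blocks * blk
  t_rel <- (0:(blk - 1L)) / fs

  with_seed(cfg$seed, {
    data <- .session_noise(nrow(montage), total, cfg)
    phases <- matrix(stats::runif(n_blocks, 0, 2 * pi), nrow = n_cand)
    for (i in seq_len(n_cand)) {
      f <- candidate_freqs[i]
      gain <- 1 + cfg$gamma * exp(-(f - f_side)^2 / (2 * sigma_f^2))
      for (b in 1:2) {            # b = 1 attention, b = 2 inattention
        a <- cfg$amp * if (b == 1) gain else 1
        s <- a * sin(2 * pi * f * t_rel + phases[i, b])
        cols <- ((i - 1L) * 2L + (b - 1L)) * blk + seq_len(blk)
        data[, cols] <- data[, cols] + outer(topo, s)
      }
    }
  })

  starts <- (seq_len(n_blocks) - 1L) * blk
  codes <- rep(c("ATT_BLOCK", "INATT_BLOCK"), n_cand)
  eeg_recording(data, fs, montage$label, event_list(starts, codes, fs))
}

#' Per-subject resonance-like stimulation frequencies of the study cohort
#'
#' The subject-specific left- and right-hand resonance-like frequencies (Hz)
#' determined by coin-motor screening over 85-127 Hz for a seven-subject
#' cohort. These serve as the default stimulation frequencies for the
#' simulated virtual cohort.
#'
#' @return data.frame with columns `subject`, `f_left`, `f_right`.
#' @export
cohort_frequencies <- function() {
  data.frame(subject = paste0("S", 1:7),
             f_left = c(90, 94, 91, 86, 88, 96, 107),
             f_right = c(92, 91, 87, 87, 108, 91, 98))
}
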