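---
title: "High-frequency SSSEP selective-attention decoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{High-frequency SSSEP selective-attention decoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sssepbci)
```

## The problem

A steady-state somatosensory evoked potential (SSSEP) is an EEG oscillation
entrained at the frequency of a sustained vibrotactile stimulus. When both
index fingers are stimulated at two different high frequencies (85–127 Hz,
the range of inexpensive coin-type eccentric rotating mass motors) and the
subject covertly attends to one hand, the attended hand's SSSEP amplitude
increases over the contralateral somatosensory cortex. A binary
brain–computer interface can therefore decode *which hand* the user attends
to from a few seconds of EEG. `sssepbci` implements the full analysis
stack: a synthetic-session generator with the statistical structure this
paradigm assumes, screening for subject-specific resonance-like
frequencies, three spatial-spectral feature-extraction methods (CSP, FBCSP,
FBCSP–MIBIF) with an SVM decoder under a bootstrap protocol, and the
supporting statistics (finite-sample chance level, repeated-measures method
comparison, a-priori power analysis).

Because no public recordings exist for this paradigm, the generator is a
first-class, tested module: every end-to-end claim in the test suite is a
claim about planted structure that the pipeline must recover.

## The generative model

A session consists of `2 * n_trials_per_class` ten-second trials sampled at
`fs = 500` Hz over the standard 31-channel 10/20 montage (`make_montage()`).
Each trial shows a fixation (2 s), a preparation cue (2 s), an attention
arrow (4 s) and rest (2 s); vibrotactile stimulation runs over `[2, 8)` s.
During stimulation, channel $c$ carries

$$x_c(t) = a_L w^L_c \sin(2\pi f_L t + \phi_L) +
           a_R w^R_c \sin(2\pi f_R t + \phi_R) + \varepsilon_c(t),$$

with hand-specific frequencies $f_L, f_R$ and source amplitudes
$a_\mathrm{attended} = \mathrm{amp}\,(1+\gamma)$,
$a_\mathrm{unattended} = \mathrm{amp}$. Design choices the recording
hardware and physiology do not pin down:

* **Topography** $w^L, w^R$: a Gaussian bump (width 0.35 disc units) in
  flattened montage coordinates, centred between C4/CP2 for the left hand
  and C3/CP1 for the right — SSSEPs localize contralaterally over the
  somatosensory hand area, but no forward model is specified, so a smooth
  unimodal projection is the minimal assumption. The weight at the bump
  centre is 1, making planted amplitudes exactly recoverable in tests.
* **Noise** $\varepsilon$: $1/f$ (pink) noise, unit-sd scaled to
  `noise_scale`, independent per channel plus a 20%-variance spatially
  shared component for realistic inter-channel correlation.
* **Phase**: uniform per trial; every downstream statistic uses amplitude
  only.
* **Units and conventions**: microvolts, 0-based sample onsets, half-open
  windows `[start, end)`.

The screening generator plants one oscillation per 2 s block over the
85–127 Hz candidate grid; attention multiplies its amplitude by
$1 + \gamma \exp(-(f - f^\ast)^2 / 2\sigma_f^2)$ with $\sigma_f = 3$ Hz, so
exactly one grid frequency maximizes the attention–inattention contrast.
The "resonance-like frequency" notion implies a peaked gain profile without
defining one; a 3 Hz Gaussian makes neighbouring grid points (2 Hz apart)
clearly distinguishable while keeping the peak non-trivial.

Default parameters are the study conditions: 45 trials per side,
`gamma = 0.6`, `noise_scale = 2 * amp`, and the per-subject stimulation
frequencies of `cohort_frequencies()`. An arrow duration of 4 s follows the
protocol text; it is exposed as `cue_s` because the figure caption of the
source protocol mentions 3 s.

## Preprocessing

Filters are 4th-order Butterworth band-passes (2nd-order band-stop for the
60 Hz notch) applied with exactly zero phase: the squared-magnitude
response $|H(f)|^2$ — the response of one forward and one backward pass —
is applied in the frequency domain after odd-reflection padding. The pad
is sized to the slowest filter transient (three time constants of the
low-frequency corner or of the bandwidth, whichever is longer) and grown to
a 2-3-5-smooth FFT length; this absorbs both the settling transient and
the circular wrap-around, and batches the 90-trial × 31-channel × 8-band
workload into a handful of FFT calls. Passband gain is within ±1 dB and
stopband attenuation is twice the single-pass Butterworth roll-off.
Attenuation is a steady-state property: a finite snippet of a pure
stopband tone keeps an irreducible edge transient, so tests measure the
settled interior.

`build_filter_bank()` constructs the seven standard SSSEP sub-bands
76–85, 81–90, …, 106–115 Hz from "size 10 Hz, overlap 5 Hz". Note these
counts are *inclusive* integer conventions (76..85 spans ten 1 Hz bins);
the default `edges = "inclusive"` reproduces them, while
`edges = "continuous"` gives literal `high = low + width` bands.

Epoching is cue-locked over `[0, 4)` s — the arrow period, which lies
entirely inside the stimulation window. The analysed window is a
configuration choice, not a property of the data.

## Screening

Per-trial single-sided FFT amplitude spectra (rectangular window, FFT
length the next power of two ≥ the trial length, calibrated so a unit
sinusoid with integer cycles peaks at 1.0) are averaged across blocks at
the contralateral central electrode — C4 for the left hand, C3 for the
right. The resonance-like frequency is the candidate with the largest
absolute attention-minus-inattention amplitude at the nearest spectral bin.
The absolute difference is scanned because the selection rule is stated
without sign; `signed = TRUE` restricts to attention-positive differences.
Exact ties (a measure-zero event for real spectra) resolve to the lowest
frequency with a warning, and identical spectra raise a
`noDiscriminablePeak` error rather than returning an arbitrary candidate.

## CSP, FBCSP and MIBIF

For two classes with mean trace-normalized covariances $\Sigma_1,
\Sigma_2$, CSP solves $\Sigma_1 w = \lambda (\Sigma_1 + \Sigma_2) w$ with
filters scaled so $w^\top(\Sigma_1+\Sigma_2)w = 1$; $\lambda_i \in [0,1]$
is class 1's variance share along component $i$ and class 2's share is
$1-\lambda_i$. The implementation whitens the composite covariance and
eigendecomposes the whitened $\Sigma_1$; a shrinkage term
$10^{-6}\,\mathrm{tr}(\Sigma)/p \cdot I$ guarantees invertibility. Spatial
patterns are columns of $A = W^{-1}$, max-normalized for topography
rendering. With two classes the one-versus-one strategy reduces to this
single binary decomposition.

Features are *normalized* log-variances, $\log(v_p / \sum_q v_q)$ over the
kept components — the scale-invariant standard form of the "logarithmic
variance" feature. Broadband CSP keeps all 31 components; FBCSP keeps the
first and last two per band (28 features over 7 bands). Degenerate
quadratic forms (possible only for noise-free synthetic input, where trial
covariances are rank-deficient) are floored at machine scale so features
stay finite.

MIBIF ranks features by a Parzen-window estimate of $I(\omega; f) =
H(\omega) - H(\omega|f)$ in bits: class-conditional Gaussian kernel
densities with the normal-reference bandwidth $h = \hat\sigma (4/3n)^{1/5}$
per class, leave-one-out evaluation (each point excluded from its own
kernel sum, preventing the degenerate zero-entropy solution), posteriors by
Bayes' rule, and clipping at zero. Selection is pair-completed: a chosen
feature brings in its eigenvalue-complement partner from the same band
(kept components 1↔4, 2↔3), and "5 pairs" means five complete pairs — ten
features.

## Evaluation protocol

`bootstrap_accuracy()` runs 100 repetitions of: a stratified 80/20
train–test split; with-replacement resampling of the training portion
within class to its own size (the held-out fifth stays untouched and
i.i.d.); the full pipeline — CSP/FBCSP fitting, MI ranking, feature
standardization, SVM training — fit on training trials only; accuracy on
the held-out trials. Band-pass filtering is linear and parameter-free, so
it is applied once outside the loop without information leakage. The
stated "radial-basis SVM" is taken at face value (the accompanying word
"linear" is contradictory): C = 1, kernel width $1/d$ on standardized
features; a linear kernel is available via `eval_spec(kernel = "linear")`.
All randomness flows from the single `seed` in the spec, giving
bit-identical results on replay.

The finite-sample chance level is the upper adjusted-Wald bound
$\tilde p + z_{1-\alpha/2}\sqrt{\tilde p(1-\tilde p)/(n+4)}$,
$\tilde p = (n/2+2)/(n+4)$: 60.1% at $n = 90$ trials, 70.9% at the
per-repetition test size $n = 18$. Methods are compared by a one-way
repeated-measures ANOVA on per-subject mean accuracies with Bonferroni-
corrected paired t tests and paired Cohen's $d$. The a-priori sample size
inverts the noncentral-$t$ power curve of a matched-pairs test; at
$d = 1.132$, $\alpha = 0.05$, power 0.8, one-sided, it returns $n = 7$.

## Numerical choices and degenerate inputs

* Tie-breaks: screening ties go to the lowest candidate (warned); MI
  ranking ties go to the lower feature index.
* Zero-variance features return 0 bits with a warning; far-tail points
  whose class densities both underflow fall back to the prior.
* Rank-deficient composite covariances raise an error suggesting a larger
  `reg`; the default $10^{-6}$ shrinkage handles full-rank noise.
* EDF export stores 16-bit codes against per-channel physical ranges
  rounded *outward* to their 8-character header representation, so no code
  wraps; recordings are zero-padded to whole one-second records.

## Problem sizes used by the tests

Unit tests run on reduced sessions (8–15 trials per class) where the
property under test does not depend on the full trial count; the
end-to-end acceptance checks use the full study geometry — 45 trials per
side, 100 bootstrap repetitions, the 7-band bank, 50 screening seeds, and
a seven-subject cohort at `gamma = 0.6`, `noise_scale = 2 * amp` with the
`cohort_frequencies()` stimulation table.

## What passing tests do and do not show

The generator plants stationary, perfectly narrowband sinusoids with a
smooth static topography and artifact-free $1/f$ noise. Real SSSEP
sessions add eye/muscle artifacts, nonstationary attention, motor
frequency jitter (the coin motors drift by up to ~1 Hz with skin
compliance), inter-subject topography variability and electrode noise.
Consequently the synthetic cohort separates far better (90–100% accuracy)
than real cohorts (~65–72%), and passing the ordering check
(FBCSP ≥ CSP, both above chance) demonstrates that the *pipeline* extracts
and ranks the planted spectral-spatial structure correctly — not that the
paradigm achieves any particular real-world accuracy. Known limitations:
no artifact model, no online/incremental decoding, no channel selection,
and the MRI-informed cortical localization discussion is reduced to the
CP1–Cz / Cz–CP2 bipolar derivation.
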