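`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards.  All stochastic entry points funnel
# their draws through this so that identical seeds give identical output
# without clobbering the user's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# least-squares amplitude of a sinusoid at frequency f in a sampled series;
# used by tests and examples to read planted oscillation amplitudes back out
#' Estimate the amplitude of a sinusoidal component
#'
#' Projects a series onto sine and cosine at frequency `f` and returns the
#' amplitude `sqrt(a^2 + b^2)` of the best-fitting sinusoid. Convenient for
#' reading the amplitude of a steady-state oscillation out of a single
#' channel without spectral leakage concerns.
#'
#' @param x numeric series.
#' @param f frequency in Hz.
#' @param fs sampling rate in Hz.
#' @return amplitude (same units as `x`).
#' @export
sine_amplitude <- function(x, f, fs) {
  t <- seq_along(x) / fs
  s <- sin(2 * pi * f * t)
  co <- cos(2 * pi * f * t)
  fit <- stats::lm.fit(cbind(s, co), x)
  sqrt(sum(fit$coefficients^2))
}
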