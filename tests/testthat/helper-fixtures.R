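# Shared fixtures, built once per test run and cached. Small sessions (few
# trials per class) keep simulation cost down; the acceptance tests use the
# full 45-trial sessions.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

small_sa_epochs <- function(gamma = 0.6, noise_scale = 2, seed = 5,
                            n_per_class = 10, f_left = 90, f_right = 92) {
  key <- paste("sa", gamma, noise_scale, seed, n_per_class, f_left, f_right,
               sep = "_")
  cached(key, {
    cfg <- sim_config(f_left = f_left, f_right = f_right, gamma = gamma,
                      noise_scale = noise_scale, seed = seed,
                      n_trials_per_class = n_per_class)
    rec <- simulate_sa_session(cfg)
    epoch_recording(rec, c("CUE_LEFT", "CUE_RIGHT"), c(0, 4),
                    c(CUE_LEFT = "LEFT", CUE_RIGHT = "RIGHT"))
  })
}

# two-class Gaussian trials with known diagonal channel variances, for the
# closed-form CSP checks
gaussian_epochs <- function(n_per_class, sd1, sd2, n_samp = 100, seed = 7) {
  set.seed(seed)
  p <- length(sd1)
  n <- 2 * n_per_class
  d <- array(0, c(n, p, n_samp))
  for (i in seq_len(n_per_class))
    d[i, , ] <- matrix(stats::rnorm(p * n_samp), p) * sd1
  for (i in (n_per_class + 1):n)
    d[i, , ] <- matrix(stats::rnorm(p * n_samp), p) * sd2
  epoch_set(d, rep(c("A", "B"), each = n_per_class), fs = n_samp,
            channels = paste0("ch", seq_len(p)), window = c(0, 1))
}
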