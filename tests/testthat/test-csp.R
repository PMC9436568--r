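test_that("identically distributed classes give eigenvalues near one half", {
  ep <- gaussian_epochs(100, sd1 = c(1, 1, 1, 1), sd2 = c(1, 1, 1, 1),
                        seed = 2)
  m <- fit_csp(ep)
  expect_true(all(abs(m$lambda - 0.5) < 0.05))
})

test_that("the diagonal toy matches the closed-form generalized eigendecomposition", {
  # population Sigma1 = diag(4, 1), Sigma2 = diag(1, 4): after trace
  # normalization the top eigenvalue of S1 w = lambda (S1 + S2) w is
  # 0.8 with eigenvector along axis 1
  ep <- gaussian_epochs(500, sd1 = c(2, 1), sd2 = c(1, 2), seed = 7)
  m <- fit_csp(ep)
  expect_lt(abs(m$lambda[1] - 0.8), 0.03)
  w1 <- m$W[1, ]
  expect_gte(abs(w1[1]) / sqrt(sum(w1^2)), 0.98)
  # pattern of the first component concentrates on channel 1
  p <- csp_patterns(m, 1)
  expect_equal(which.max(abs(p)), c(ch1 = 1L))
  expect_equal(max(abs(p)), 1)
})

test_that("filters and patterns are exact inverses and diagonalize both classes", {
  ep <- small_sa_epochs(n_per_class = 10)
  eb <- bandpass(ep, 86, 95)
  m <- fit_csp(eb, band = c(86, 95))
  expect_lt(max(abs(m$W %*% m$A - diag(31))), 1e-8)
  # simultaneous diagonalization with complementary unit diagonals
  covs <- sssepbci:::.trial_covmat(eb)
  s1 <- sssepbci:::.mean_cov(covs, which(eb$labels == levels(eb$labels)[1]))
  s2 <- sssepbci:::.mean_cov(covs, which(eb$labels == levels(eb$labels)[2]))
  d1 <- m$W %*% s1 %*% t(m$W)
  d2 <- m$W %*% s2 %*% t(m$W)
  expect_lt(max(abs(d1 - diag(diag(d1)))), 1e-6)
  expect_lt(max(abs(d2 - diag(diag(d2)))), 1e-6)
  expect_equal(diag(d1) + diag(d2), rep(1, 31), tolerance = 1e-4)
  # class-2 variance share is the eigenvalue complement
  expect_equal(diag(d2), 1 - m$lambda, tolerance = 1e-4)
  expect_true(all(diff(m$lambda) <= 1e-12))
  expect_true(all(m$lambda >= 0 & m$lambda <= 1))
})

test_that("filters agree with a dense generalized eigensolver on small problems", {
  ep <- gaussian_epochs(50, sd1 = c(2, 1, 0.5, 1.5, 1), sd2 = c(1, 2, 1, 1, 0.5),
                        seed = 11)
  m <- fit_csp(ep)
  covs <- sssepbci:::.trial_covmat(ep)
  s1 <- sssepbci:::.mean_cov(covs, 1:50)
  s2 <- sssepbci:::.mean_cov(covs, 51:100)
  # independent route: non-symmetric dense solve of (S1+S2)^-1 S1
  ref <- eigen(solve(s1 + s2) %*% s1)
  expect_equal(sort(Re(ref$values), decreasing = TRUE), m$lambda,
               tolerance = 1e-6)
  for (k in 1:5) {
    v <- Re(ref$vectors[, k])
    w <- m$W[k, ]
    expect_gt(abs(sum(v * w)) / sqrt(sum(v^2) * sum(w^2)), 1 - 1e-6)
  }
})

test_that("log variance-share features follow the stated arithmetic", {
  # identity filters, one trial whose two channel energies are 3 and 1
  model <- structure(list(W = diag(2), lambda = c(0.75, 0.25), A = diag(2),
                          class_order = c("A", "B"),
                          channels = c("ch1", "ch2"), band = "broadband"),
                     class = "csp_model")
  x <- array(0, c(1, 2, 4))
  x[1, 1, ] <- c(sqrt(3), 0, 0, 0)
  x[1, 2, ] <- c(1, 0, 0, 0)
  ep <- epoch_set(x, "A", fs = 4, channels = c("ch1", "ch2"),
                  window = c(0, 1))
  f <- csp_features(model, ep, keep = "all")
  expect_equal(unname(f$values[1, ]), c(log(3 / 4), log(1 / 4)),
               tolerance = 1e-12)
})

test_that("feature dimensionality and duplication behave as specified", {
  ep <- small_sa_epochs(n_per_class = 10)
  m <- fit_csp(bandpass(ep, 2, 120))
  f_all <- csp_features(m, bandpass(ep, 2, 120), keep = "all")
  expect_equal(ncol(f_all$values), 31L)
  # duplicating a trial duplicates its feature row
  ep2 <- ep
  ep2$data[2, , ] <- ep2$data[1, , ]
  ep2$labels[2] <- ep2$labels[1]
  f2 <- csp_features(m, bandpass(ep2, 2, 120), keep = "all")
  expect_equal(f2$values[1, ], f2$values[2, ])
  expect_error(csp_features(m, bandpass(ep, 2, 120), keep = "first_last",
                            m = 16), "exceeds half")
})

test_that("filter-bank features concatenate 2m components per band", {
  ep <- small_sa_epochs(n_per_class = 10)
  bank7 <- build_filter_bank(76, 115, 10, 5)
  f <- fbcsp_features(ep, bank7, m = 2)
  expect_equal(ncol(f$values), 28L)
  expect_equal(nrow(f$values), 20L)
  expect_equal(f$meta$band, rep(1:7, each = 4))
  f1 <- fbcsp_features(ep, bank7[1, , drop = FALSE], m = 2)
  expect_equal(ncol(f1$values), 4L)
  f3 <- fbcsp_features(ep, bank7[1:3, ], m = 1)
  expect_equal(ncol(f3$values), 6L)
})

test_that("the stimulation bands carry the strongest class contrast", {
  bank7 <- build_filter_bank(76, 115, 10, 5)
  # bands containing the planted 90/92 Hz oscillations
  signal_bands <- which((bank7$low <= 90 & bank7$high >= 90) |
                        (bank7$low <= 92 & bank7$high >= 92))
  hits <- 0
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    ep <- small_sa_epochs(gamma = 1, seed = 100 + seed, n_per_class = 10)
    dev <- vapply(seq_len(nrow(bank7)), function(b) {
      m <- fit_csp(bandpass(ep, bank7$low[b], bank7$high[b]))
      max(abs(m$lambda - 0.5))
    }, numeric(1))
    hits <- hits + (which.max(dev) %in% signal_bands)
  }
  expect_gte(hits, 0.8 * n_seeds)
})

test_that("pattern extraction validates its component index", {
  ep <- gaussian_epochs(20, sd1 = c(2, 1), sd2 = c(1, 2), seed = 3)
  m <- fit_csp(ep)
  expect_length(csp_patterns(m, 2), 2L)
  expect_error(csp_patterns(m, 3), "out of range")
})
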