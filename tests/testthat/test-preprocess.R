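fs <- 500

test_that("broadband band-pass keeps the passband and kills DC", {
  t <- (0:1999) / fs
  # DC lies outside the 2-120 Hz passband
  dc <- bandpass(rep(1, 2000), 2, 120, fs = fs)
  expect_lt(20 * log10(max(sqrt(mean(dc^2)), 1e-300)), -40)
  # 90 Hz passband sinusoid within +/- 1 dB
  g <- sine_amplitude(bandpass(sin(2 * pi * 90 * t), 2, 120, fs = fs), 90, fs)
  expect_lt(abs(20 * log10(g)), 1)
  # designed transfer function gain at 90 Hz, via a second route (filter a
  # complex of known amplitude and compare against the narrowband gain)
  g_band <- sine_amplitude(bandpass(0.5 * sin(2 * pi * 80 * t), 76, 85,
                                    fs = fs), 80, fs)
  expect_lt(abs(20 * log10(g_band / 0.5)), 1)
  expect_error(bandpass(t, 2, 300, fs = fs), "Nyquist")
})

test_that("notch removes its centre frequency and spares neighbours", {
  tl <- (0:4999) / fs
  x60 <- sin(2 * pi * 60 * tl)
  y <- notch(x60, 60, fs = fs)
  settle <- 500:4500                       # settled region
  expect_lt(sqrt(mean(y[settle]^2)) / sqrt(mean(x60[settle]^2)), 0.032)
  for (f in c(50, 70, 90)) {
    g <- sine_amplitude(notch(sin(2 * pi * f * tl), 60, fs = fs), f, fs)
    expect_lt(abs(20 * log10(g)), 1)
  }
})

test_that("broadband noise through the notch dips at 60 Hz", {
  set.seed(31)
  x <- rnorm(20000)
  y <- notch(x, 60, fs = fs)
  spx <- stats::spec.pgram(stats::ts(x, frequency = fs), spans = 101,
                           plot = FALSE, taper = 0)
  spy <- stats::spec.pgram(stats::ts(y, frequency = fs), spans = 101,
                           plot = FALSE, taper = 0)
  ratio <- spy$spec / spx$spec
  expect_lt(abs(spx$freq[which.min(ratio)] - 60), 2)
})

test_that("zero-phase filters are linear and do not shift passband peaks", {
  set.seed(8)
  x <- rnorm(2000)
  expect_equal(bandpass(3 * x, 2, 120, fs = fs),
               3 * bandpass(x, 2, 120, fs = fs), tolerance = 1e-10)
  t <- (0:1999) / fs
  s <- sin(2 * pi * 90 * t)
  y <- bandpass(s, 2, 120, fs = fs)
  cc <- stats::ccf(s, y, lag.max = 5, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("filter bank reproduces both edge conventions", {
  b <- build_filter_bank(76, 115, 10, 5)
  expect_equal(b$low, c(76, 81, 86, 91, 96, 101, 106))
  expect_equal(b$high, c(85, 90, 95, 100, 105, 110, 115))
  expect_equal(nrow(b), 7L)
  b2 <- build_filter_bank(10, 20, 4, 2, edges = "continuous")
  expect_equal(unname(as.matrix(b2)),
               cbind(c(10, 12, 14, 16), c(14, 16, 18, 20)))
  expect_equal(nrow(build_filter_bank(0, 10, 10, 0, edges = "continuous")),
               1L)
  # constant width, exact overlap
  expect_true(all(diff(b$high - b$low) == 0))
  expect_equal(unique(b$high[-7] - b$low[-1]), 5 - 1)
  expect_error(build_filter_bank(76, 80, 10, 12))
})

test_that("epoching follows half-open index arithmetic", {
  x <- matrix(seq_len(400), nrow = 1)
  ev <- event_list(c(100L, 300L), c("CUE_LEFT", "CUE_RIGHT"), fs = 500)
  rec <- eeg_recording(x, 500, "C3", ev)
  ep <- epoch_recording(rec, c("CUE_LEFT", "CUE_RIGHT"), c(0, 0.01))
  expect_equal(dim(ep$data), c(2L, 1L, 5L))
  expect_equal(ep$data[1, 1, ], 101:105)    # 0-based onset 100 -> samples 100..104
  # no matching events -> empty epoch set
  empty <- epoch_recording(rec, "STIM_ON", c(0, 0.01))
  expect_equal(n_trials(empty), 0L)
  # window past the end names the offending event
  ev2 <- event_list(398L, "CUE_LEFT", fs = 500)
  rec2 <- eeg_recording(x, 500, "C3", ev2)
  expect_error(epoch_recording(rec2, "CUE_LEFT", c(0, 0.01)),
               "CUE_LEFT at sample 398")
})

test_that("epoching a simulated session recovers one labelled trial per cue", {
  ep <- small_sa_epochs(n_per_class = 10)
  expect_equal(dim(ep$data), c(20L, 31L, 2000L))
  expect_equal(as.vector(table(ep$labels)), c(10L, 10L))
})

test_that("bipolar derivation appends anode-minus-cathode channels", {
  x <- rbind(c(1, 2, 3), c(10, 20, 30), c(100, 200, 300))
  rec <- eeg_recording(x, 100, c("CP1", "Cz", "CP2"))
  out <- bipolar(rec, list(c("CP1", "Cz"), c("Cz", "CP2")))
  expect_equal(out$channels, c("CP1", "Cz", "CP2", "CP1-Cz", "Cz-CP2"))
  expect_equal(out$data["CP1-Cz", ], c(-9, -18, -27))
  expect_equal(out$data["Cz-CP2", ], c(-90, -180, -270))
  expect_equal(out$data[1:3, ], rec$data)   # originals untouched
  zero <- bipolar(rec, list(c("Cz", "Cz")))
  expect_true(all(zero$data["Cz-Cz", ] == 0))
  expect_error(bipolar(rec, list(c("CP1", "F3"))), "F3")
})
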