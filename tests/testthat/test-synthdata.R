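test_that("montage has the full 31-channel 10/20 layout", {
  m <- make_montage()
  expect_equal(nrow(m), 31L)
  expect_false(anyDuplicated(m$label) > 0)
  expect_true(all(c("C3", "C4", "CP1", "CP2", "Cz") %in% m$label))
  expect_identical(m$label[1], "Fp1")
  expect_identical(m$label[31], "PO10")
  expect_true(all(m$x^2 + m$y^2 < 1))       # inside the unit disc
})

test_that("SA sessions have balanced cues and a 10 s trial grid", {
  for (seed in 1:3) {
    cfg <- sim_config(n_trials_per_class = 3, noise_scale = 0.5, seed = seed)
    rec <- simulate_sa_session(cfg)
    cues <- rec$events[rec$events$code %in% c("CUE_LEFT", "CUE_RIGHT"), ]
    expect_equal(sum(cues$code == "CUE_LEFT"), 3)
    expect_equal(sum(cues$code == "CUE_RIGHT"), 3)
    starts <- rec$events$onset_sample[rec$events$code == "STIM_ON"]
    expect_equal(unique(diff(starts)), 5000L)  # 10 s x 500 Hz
    expect_equal(ncol(rec$data), 6L * 5000L)
  }
})

test_that("attended oscillation amplitude follows amp * (1 + gamma) * topography", {
  cfg <- sim_config(noise_scale = 0, gamma = 0.5, n_trials_per_class = 2,
                    seed = 3)
  rec <- simulate_sa_session(cfg)
  topo <- sa_topography()
  cues <- rec$events[rec$events$code %in% c("CUE_LEFT", "CUE_RIGHT"), ]
  lt <- cues$onset_sample[cues$code == "CUE_LEFT"][1]
  idx <- (lt + 1):(lt + 2000)               # cue window, inside stimulation
  # attended left-hand oscillation at C4: amp * 1.5 * w_left(C4)
  expect_equal(sine_amplitude(rec$data["C4", idx], cfg$f_left, cfg$fs),
               cfg$amp * 1.5 * unname(topo$left["C4"]), tolerance = 1e-6)
  # unattended right-hand oscillation at C3: amp * 1.0 * w_right(C3)
  expect_equal(sine_amplitude(rec$data["C3", idx], cfg$f_right, cfg$fs),
               cfg$amp * 1.0 * unname(topo$right["C3"]), tolerance = 1e-6)
})

test_that("each hand's oscillation is lateralized to the contralateral side", {
  for (seed in 1:3) {
    cfg <- sim_config(noise_scale = 0, seed = seed, n_trials_per_class = 1)
    rec <- simulate_sa_session(cfg)
    stim <- rec$events$onset_sample[rec$events$code == "STIM_ON"][1]
    idx <- (stim + 1):(stim + 3000)
    expect_gt(sine_amplitude(rec$data["C4", idx], cfg$f_left, cfg$fs),
              sine_amplitude(rec$data["C3", idx], cfg$f_left, cfg$fs))
    expect_gt(sine_amplitude(rec$data["C3", idx], cfg$f_right, cfg$fs),
              sine_amplitude(rec$data["C4", idx], cfg$f_right, cfg$fs))
  }
})

test_that("identical configurations give bit-identical recordings", {
  cfg <- sim_config(n_trials_per_class = 2, seed = 9)
  r1 <- simulate_sa_session(cfg)
  r2 <- simulate_sa_session(cfg)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$events, r2$events)
  r3 <- simulate_sa_session(sim_config(n_trials_per_class = 2, seed = 10))
  expect_false(identical(r1$data, r3$data))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(f_left = 300), "Nyquist")
  expect_error(sim_config(f_left = 90, f_right = 90), "allow_equal_freqs")
  expect_no_error(sim_config(f_left = 90, f_right = 90,
                             allow_equal_freqs = TRUE))
  expect_error(sim_config(gamma = -1))
})

test_that("pink noise has the requested spectral slope", {
  slope_of <- function(x, spans = 51) {
    sp <- stats::spec.pgram(x, spans = spans, plot = FALSE, taper = 0)
    keep <- sp$freq > 0.002 & sp$freq < 0.4
    unname(stats::coef(stats::lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2])
  }
  white <- mean(vapply(1:5, function(s)
    slope_of(pink_noise(2^14, beta = 0, seed = s)), numeric(1)))
  expect_lt(abs(white), 0.1)
  pink <- mean(vapply(1:20, function(s)
    slope_of(pink_noise(2^16, beta = 1, seed = s)), numeric(1)))
  expect_lt(abs(pink - (-1)), 0.2)
})

test_that("pink noise is zero mean, unit sd, and seed-deterministic", {
  x <- pink_noise(4096, beta = 1, seed = 42)
  expect_identical(x, pink_noise(4096, beta = 1, seed = 42))
  expect_equal(mean(x), 0, tolerance = 1e-12)
  expect_equal(stats::sd(x), 1, tolerance = 1e-12)
})

test_that("screening sessions pair one attention and one inattention block per candidate", {
  cfg <- sim_config(f_left = 91, gamma = 1, noise_scale = 0.2, seed = 2)
  rec <- simulate_screening_session(cfg, side = "left")
  expect_equal(sum(rec$events$code == "ATT_BLOCK"), 22)
  expect_equal(sum(rec$events$code == "INATT_BLOCK"), 22)
  expect_equal(nrow(rec$events), 44)
  expect_equal(ncol(rec$data), 44L * 1000L)   # 2 s blocks at 500 Hz
})

test_that("with gamma = 0 attention and inattention blocks carry equal amplitude", {
  cfg <- sim_config(f_left = 91, gamma = 0, noise_scale = 0, seed = 4)
  rec <- simulate_screening_session(cfg, side = "left",
                                    candidate_freqs = c(89, 91, 93))
  ev <- rec$events
  for (i in 1:3) {
    f <- c(89, 91, 93)[i]
    att <- ev$onset_sample[ev$code == "ATT_BLOCK"][i]
    ina <- ev$onset_sample[ev$code == "INATT_BLOCK"][i]
    a_att <- sine_amplitude(rec$data["C4", (att + 1):(att + 1000)], f, cfg$fs)
    a_ina <- sine_amplitude(rec$data["C4", (ina + 1):(ina + 1000)], f, cfg$fs)
    expect_equal(a_att, a_ina, tolerance = 1e-6)
  }
})
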