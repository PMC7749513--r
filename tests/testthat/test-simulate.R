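# Synthetic EEG generator: determinism, design counts, planted-effect
# fidelity, and the null configuration.

test_that("the same config and seed reproduce byte-identical epochs", {
  sc <- scaled_scenario(n_subjects = 2, seed = 42)
  a <- simulate_subject(sc$cfg, sc$truth, 1)
  b <- simulate_subject(sc$cfg, sc$truth, 1)
  expect_identical(a$Go$data, b$Go$data)
  expect_identical(a$NoGo$data, b$NoGo$data)
  expect_identical(a$Go$rts, b$Go$rts)
})

test_that("epoch sets carry the configured design", {
  sc <- scaled_scenario(n_subjects = 2, seed = 7)
  es <- simulate_subject(sc$cfg, sc$truth, 2)
  expect_equal(dim(es$Go$data), c(40, 24, 384))
  expect_equal(dim(es$NoGo$data)[1], 10)
  expect_equal(range(es$Go$times), c(-1, 2 - 1 / 128))
  expect_true(all(es$Go$rts >= 0.15 & es$Go$rts <= 1))
  expect_null(es$NoGo$rts)
})

test_that("the full-scale default scenario matches the emulated study design", {
  sc <- default_scenario(n_subjects = 3, seed = 1)
  expect_length(sc$truth$sources, 6)
  expect_equal(sc$cfg$trials_go, 160)
  expect_equal(sc$cfg$trials_nogo, 40)
  expect_equal(sc$cfg$trials_go / (sc$cfg$trials_go + sc$cfg$trials_nogo), 0.8)
  scheme <- band_scheme()$bands
  for (e in sc$truth$effects) {
    expect_true(any(vapply(scheme, function(b) all(b == e$band), TRUE)))
    expect_lte(e$onset_s + e$duration_s, 0.8 + 1e-9)
  }
  expect_equal(ncol(sc$truth$mixing), 6)
})

test_that("an effect band outside 1-30 Hz is rejected with a named error", {
  expect_error(effect_spec("x", "Go", c(30, 45), 0, 0.2, "increase", 3),
               class = "ersplearn_band_range")
})

test_that("channel data scale linearly with source amplitude before noise", {
  cfg <- sim_config(n_subjects = 1, trials_go = 2, trials_nogo = 2,
                    n_channels = 16, sample_rate_hz = 128,
                    sensor_noise_amp = 0, subject_amp_sd = 0, seed = 5)
  s1 <- list(source_spec(c(10, 0, 40), "a", background_amp = 1))
  s2 <- list(source_spec(c(10, 0, 40), "a", background_amp = 3))
  t1 <- ground_truth(cfg, s1, list())
  t2 <- ground_truth(cfg, s2, list())
  a <- simulate_subject(cfg, t1, 1)$Go$data
  b <- simulate_subject(cfg, t2, 1)$Go$data
  expect_equal(b, 3 * a, tolerance = 1e-12)
})

test_that("planted spectral change matches the nominal magnitude within 1 dB", {
  # long effect (window mostly inside) and noise off: the ERSP at the
  # effect's centre should read back the planted dB
  cfg <- sim_config(n_subjects = 1, trials_go = 40, trials_nogo = 5,
                    n_channels = 16, sample_rate_hz = 128,
                    sensor_noise_amp = 0, subject_amp_sd = 0, seed = 11)
  srcs <- list(source_spec(c(9, -14, 19), "thal", osc_amp = 4))
  effs <- list(effect_spec("thal", "Go", c(4, 8), onset_s = 0.1,
                           duration_s = 0.6, direction = "increase",
                           magnitude_db = 6))
  tr <- ground_truth(cfg, srcs, effs)
  es <- simulate_subject(cfg, tr, 1)
  bc <- which.max(abs(tr$mixing[, 1]))
  e <- compute_ersp(es$Go$data[, bc, , drop = FALSE], fs = 128)
  sup <- ersplearn:::osc_support(c(4, 8))
  rows <- e$freqs >= floor(sup[1]) & e$freqs <= ceiling(sup[2])
  ctr <- which.min(abs(e$frame_times - 0.4))
  expect_lt(abs(mean(e$values[1, rows, ctr]) - 6), 1)
})

test_that("without planted effects the two conditions are exchangeable", {
  sc <- null_scenario(n_subjects = 1, seed = 9)
  es <- simulate_subject(sc$cfg, sc$truth, 1)
  band_power <- function(d) {
    # post-stimulus theta power per trial at the strongest channel
    bc <- which.max(apply(d, 2, stats::sd))
    apply(d[, bc, 129:384, drop = FALSE], 1, function(v) {
      p <- Mod(stats::fft(as.numeric(v)))^2
      f <- (seq_along(v) - 1) * 128 / length(v)
      mean(p[f >= 4 & f <= 8])
    })
  }
  p <- stats::t.test(log(band_power(es$Go$data)),
                     log(band_power(es$NoGo$data)))$p.value
  expect_gt(p, 0.01)
})
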