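# FIR filtering, resampling, artifact rejection, interpolation,
# average reference.

test_that("the band-pass filter preserves the passband and kills drift and DC", {
  fs <- 512
  t <- (0:(8 * fs - 1)) / fs
  mid <- (2 * fs):(6 * fs)
  y10 <- bandpass_filter(sin(2 * pi * 10 * t), fs)
  expect_lt(abs(stats::sd(y10[mid]) / stats::sd(sin(2 * pi * 10 * t)[mid]) - 1),
            0.01)
  ydrift <- bandpass_filter(sin(2 * pi * 0.2 * t), fs)
  expect_lt(20 * log10(stats::sd(ydrift[mid]) /
                       stats::sd(sin(2 * pi * 0.2 * t)[mid])), -40)
  ydc <- bandpass_filter(rep(1, 4096), fs)
  expect_lt(max(abs(ydc[1000:3000])), 0.01)
  expect_error(bandpass_filter(t, fs, 1, 300), class = "ersplearn_nyquist")
})

test_that("downsampling preserves in-band tones for integer and rational ratios", {
  fs <- 512
  t <- (0:(8 * fs - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  z <- downsample(x, fs, 128)
  expect_equal(length(z), length(x) / 4)
  expect_lt(abs(stats::sd(z[300:700]) / stats::sd(x) - 1), 0.01)
  # 3 s x 128 Hz bookkeeping
  expect_equal(length(downsample(numeric(1536), 512, 128)), 384)
  # non-integer ratio: compare against the analytic tone on the new grid
  z2 <- downsample(x, 512, 500)
  ref <- sin(2 * pi * 10 * (seq_along(z2) - 1) / 500)
  expect_lt(max(abs(z2[500:3500] - ref[500:3500])), 0.01)
  expect_error(downsample(x, 512, 1024), class = "ersplearn_upsample")
})

test_that("artifact rejection flags constructed outliers and only those", {
  sc <- scaled_scenario(n_subjects = 1, seed = 2)
  es <- simulate_subject(sc$cfg, sc$truth, 1)$Go
  expect_equal(sum(reject_epochs(es)$rejected_mask), 0)
  es$data[3, 5, 100] <- es$data[3, 5, 100] + 500
  expect_equal(which(reject_epochs(es)$rejected_mask), 3L)
  # monotone in thresholds: loosening never rejects more
  strict <- sum(reject_epochs(es, 100, 3)$rejected_mask)
  loose <- sum(reject_epochs(es, 400, 8)$rejected_mask)
  expect_lte(loose, strict)
  bad <- es
  bad$data <- bad$data * 0 + 1e6
  bad$data[, , 1] <- 0   # give peak-to-peak beyond any threshold
  expect_error(reject_epochs(bad, 10, 1e9), class = "ersplearn_all_rejected")
})

test_that("15% broadband contamination yields retention in the 80-90% regime", {
  sc <- scaled_scenario(n_subjects = 1, seed = 8)
  es <- simulate_subject(sc$cfg, sc$truth, 1)$Go    # 40 trials
  set.seed(81)
  contam <- sample(40, 6)                           # 15%
  for (tr in contam) {
    es$data[tr, , ] <- es$data[tr, , ] +
      matrix(rnorm(prod(dim(es$data)[2:3]), 0, 5 * stats::sd(es$data)),
             dim(es$data)[2])
  }
  kept <- mean(!reject_epochs(es)$rejected_mask)
  expect_gte(kept, 0.80)
  expect_lte(kept, 0.90)
})

test_that("spherical-spline interpolation reconstructs a held-out channel", {
  mont <- build_montage(64)
  src <- list(source_spec(c(-10, 20, 40), "s"))
  map <- build_forward_model(mont, src,
                             orientations = list(c(0, 0.6, 0.8)))[, 1]
  # treat one mid-cap channel as bad, reconstruct from the rest
  hold <- 20L
  sc <- scaled_scenario(n_subjects = 1, seed = 3)
  es <- simulate_subject(sc$cfg, sc$truth, 1)$NoGo
  # graft a pure dipolar topography as one "trial" on the 64-channel montage
  es2 <- epoch_set(1, "NoGo", array(rep(map, each = 1), c(1, 64, 5)),
                   128, (0:4) / 128, mont)
  for (k in 1:5) es2$data[1, , k] <- map
  out <- interpolate_and_rereference(es2, mont$channel_names[hold])
  err <- abs(out$data[1, hold, 1] - (map[hold] - mean(map)))
  expect_lt(err, 0.1 * diff(range(map)))
})

test_that("average referencing zeroes channel means and is idempotent", {
  sc <- scaled_scenario(n_subjects = 1, seed = 4)
  es <- simulate_subject(sc$cfg, sc$truth, 1)$NoGo
  r1 <- interpolate_and_rereference(es)
  expect_lt(max(abs(colMeans(r1$data[1, , ]))), 1e-9 * stats::sd(r1$data))
  r2 <- interpolate_and_rereference(r1)
  expect_equal(r2$data, r1$data, tolerance = 1e-12)
  expect_error(interpolate_and_rereference(es, es$montage$channel_names[1:10]),
               class = "ersplearn_too_many_bad")
})
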