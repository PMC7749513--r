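# ERSP estimation, band x time reduction, RT adjustment, feature scaling.

test_that("an amplitude-doubling step reads +6.02 dB at the tone frequency", {
  fs <- 128
  times <- -1 + (0:383) / fs
  set.seed(1)
  tone <- sin(2 * pi * 10 * times) * ifelse(times >= 0, 2, 1)
  # 40 trials with a small noise floor so off-tone rows are well defined
  x <- array(0, c(40, 1, 384))
  for (tr in 1:40) x[tr, 1, ] <- tone + rnorm(384, 0, 0.2)
  e <- compute_ersp(x, fs = fs)
  post <- e$frame_times >= 0.3 & e$frame_times <= 1.5
  expect_lt(abs(mean(e$values[1, e$freqs == 10, post]) - 6.02), 1)
  # rows where the noise floor dominates the tapered tone's spectral skirt
  # (the skirt itself doubles with the tone, so nearer rows legitimately move)
  far <- e$freqs >= 24
  expect_lt(max(abs(apply(e$values[1, far, post], 1, mean))), 1)
  # baseline window mean is zero by construction
  expect_lt(max(abs(apply(e$values[, , e$frame_times <= 0, drop = FALSE],
                          c(1, 2), mean))), 1e-9)
  expect_equal(dim(e$values), c(1L, 30L, 51L))
  expect_error(compute_ersp(array(0, c(1, 1, 32)), fs = fs),
               class = "ersplearn_short_trial")
})

test_that("stationary noise shows no systematic spectral perturbation", {
  set.seed(2)
  x <- array(rnorm(30 * 1 * 384), c(30, 1, 384))
  e <- compute_ersp(x, fs = 128)
  # trial-averaged dB values: mean over many cells should sit near 0 and
  # single cells within ~4.5 SE of it (SE ~ 1 dB at 30 trials)
  expect_lt(abs(mean(e$values)), 0.2)
  expect_lt(max(abs(e$values)), 4.5)
})

test_that("band x time reduction indexes bands, bins and ordering correctly", {
  ft <- ersplearn:::ersp_frame_times()
  vals <- array(1, c(6, 30, 51))
  e <- structure(list(values = vals, freqs = 1:30, frame_times = ft),
                 class = "ersp_array")
  blk <- bandtime_reduce(e)
  expect_true(all(abs(blk - 1) < 1e-12))
  expect_equal(dim(blk), c(6L, 40L))
  fv <- ersplearn:::feature_vector(blk, "1", "Go")
  expect_equal(fv$p, 240L)                 # 6 components x 5 bands x 8 bins
  # a single nonzero frame at 0.35 s / 6 Hz lands in theta bin 4 only
  vals0 <- array(0, c(1, 30, 51))
  vals0[1, 6, which(abs(ft - 0.35) < 1e-9)] <- 2
  e0 <- structure(list(values = vals0, freqs = 1:30, frame_times = ft),
                  class = "ersp_array")
  b0 <- bandtime_reduce(e0)
  nz <- which(b0[1, ] != 0)
  expect_equal(colnames(b0)[nz], "theta.bin4")
})

test_that("the RT window adjustment recovers a planted latency-RT slope", {
  ft <- ersplearn:::ersp_frame_times()
  set.seed(3)
  rts <- stats::runif(57, 0.25, 0.55)
  ersps <- lapply(rts, function(r) {
    vals <- array(0, c(2, 30, 51))
    lat <- 0.2 + 0.5 * r
    vals[1, 6, which.min(abs(ft - lat))] <- 5     # theta |peak| at the latency
    structure(list(values = vals, freqs = 1:30, frame_times = ft),
              class = "ersp_array")
  })
  names(ersps) <- paste0(seq_along(rts), ".Go")
  names(rts) <- names(ersps)
  adj <- estimate_rt_adjustment(ersps, rts, components = 1)
  expect_lt(abs(adj$slope - 0.5), 0.05)
  # shifts live on the 0.05 s frame grid
  expect_true(all(abs(adj$shifts / 0.05 - round(adj$shifts / 0.05)) < 1e-9))
  # degenerate RT variance: zero shifts with a warning
  expect_warning(adj0 <- estimate_rt_adjustment(ersps[1:5],
                                                setNames(rep(0.4, 5),
                                                         names(ersps)[1:5])),
                 "degenerate")
  expect_true(all(adj0$shifts == 0))
})

test_that("window shifts are clamped to keep 0.8 s inside the frame range", {
  expect_equal(ersplearn:::clamp_shift(5), 0.9)
  expect_equal(ersplearn:::clamp_shift(-5), -0.7)
  expect_equal(ersplearn:::clamp_shift(0.1249), 0.10)
  ft <- ersplearn:::ersp_frame_times()
  vals <- array(stats::rnorm(30 * 51), c(1, 30, 51))
  e <- structure(list(values = vals, freqs = 1:30, frame_times = ft),
                 class = "ersp_array")
  expect_true(all(is.finite(bandtime_reduce(e, shift_s = 5))))
  expect_true(all(is.finite(bandtime_reduce(e, shift_s = -5))))
})

test_that("feature scaling is per subject x component with joint-condition blocks", {
  set.seed(4)
  blocks <- list("1.Go" = matrix(rnorm(3 * 40, 5, 2), 3,
                                 dimnames = list(paste0("IC", 1:3), NULL)),
                 "1.NoGo" = matrix(rnorm(3 * 40, 5, 2), 3,
                                   dimnames = list(paste0("IC", 1:3), NULL)))
  fvs <- scale_features(blocks)
  stacked <- rbind(matrix(fvs[["1.Go"]]$x, 3, byrow = TRUE),
                   matrix(fvs[["1.NoGo"]]$x, 3, byrow = TRUE))
  for (comp in 1:3) {
    vals <- c(stacked[comp, ], stacked[comp + 3, ])
    expect_lt(abs(mean(vals)), 1e-12)
    expect_lt(abs(stats::var(vals) - 1), 1e-12)
  }
  # idempotence
  blocks2 <- list("1.Go" = matrix(fvs[["1.Go"]]$x, 3, byrow = TRUE,
                                  dimnames = list(paste0("IC", 1:3), NULL)),
                  "1.NoGo" = matrix(fvs[["1.NoGo"]]$x, 3, byrow = TRUE,
                                    dimnames = list(paste0("IC", 1:3), NULL)))
  fvs2 <- scale_features(blocks2)
  expect_equal(fvs2[["1.Go"]]$x, fvs[["1.Go"]]$x, tolerance = 1e-10)
  # invariance to per-subject affine amplitude changes
  blocks3 <- lapply(blocks, function(b) b * 3 + 2)
  fvs3 <- scale_features(blocks3)
  expect_equal(fvs3[["1.Go"]]$x, fvs[["1.Go"]]$x, tolerance = 1e-10)
  # zero-variance guard
  zb <- list("1.Go" = matrix(1, 1, 40, dimnames = list("IC1", NULL)),
             "1.NoGo" = matrix(1, 1, 40, dimnames = list("IC1", NULL)))
  expect_warning(scale_features(zb), "zero-variance")
})
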