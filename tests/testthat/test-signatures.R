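# Canonical inputs, unit attribution, bootstrap significance, summary rows.

# a one-unit model whose NoGo probability increases with feature 1
slope_model <- function(p = 2, gain = 10) {
  alpha <- matrix(c(0, gain, rep(0, p - 1)), 1)   # (bias, w1, 0, ...)
  nn_model(c(as.numeric(alpha), c(-2, 4)), M = 1, p = p, lambda = 0)
}

mk_fvs <- function(X_go, X_nogo) {
  p <- ncol(X_go)
  comps <- p / 40
  fvs <- list()
  for (s in seq_len(nrow(X_go))) {
    zg <- matrix(X_go[s, ], comps, byrow = TRUE,
                 dimnames = list(paste0("IC", seq_len(comps)), NULL))
    zn <- matrix(X_nogo[s, ], comps, byrow = TRUE,
                 dimnames = list(paste0("IC", seq_len(comps)), NULL))
    fvs[[paste0(s, ".Go")]] <- ersplearn:::feature_vector(zg, as.character(s), "Go")
    fvs[[paste0(s, ".NoGo")]] <- ersplearn:::feature_vector(zn, as.character(s), "NoGo")
  }
  fvs
}

test_that("canonical qualification applies the probability-ratio criterion", {
  set.seed(20)
  p <- 40
  # feature 1 drives the prediction; subject 5's margins are weak
  X_go <- matrix(rnorm(8 * p, 0, 0.05), 8); X_go[, 1] <- -1
  X_nogo <- matrix(rnorm(8 * p, 0, 0.05), 8); X_nogo[, 1] <- 1
  X_go[5, 1] <- -0.085; X_nogo[5, 1] <- 0.085   # f ~ 0.70 -> ratio ~ 2.33 < 3
  m <- slope_model(p)
  fvs <- mk_fvs(X_go, X_nogo)
  cn <- build_canonical(m, fvs, threshold = 3)
  expect_false("5" %in% cn$qualifying)
  expect_equal(sort(cn$qualifying), sort(setdiff(as.character(1:8), "5")))
  expect_equal(cn$fraction, 7 / 8)
  # impossible threshold: named error
  expect_error(build_canonical(m, fvs, threshold = 1e9),
               class = "ersplearn_no_qualifying")
})

test_that("units are attributed to the condition that moves them from rest", {
  # unit 1 fires only on the NoGo canonical, unit 2 only on the Go canonical
  p <- 2
  alpha <- rbind(c(-4, 8, 0),    # z ~ 0 at rest, ~1 when x1 = 1
                 c(-4, 0, 8))
  beta <- c(0, 2, -2)
  m <- nn_model(c(as.numeric(alpha), beta), M = 2, p = p, lambda = 0)
  cn <- structure(list(x_go = c(0, 1), x_nogo = c(1, 0),
                       qualifying = as.character(1:6), fraction = 1,
                       threshold = 3), class = "canonical_input")
  at <- unit_attribution(m, cn)
  expect_equal(at$attribution, c("NoGo", "Go"))
  # all-zero output weights: every unit is mixed
  m0 <- nn_model(c(as.numeric(alpha), c(0, 0, 0)), M = 2, p = p, lambda = 0)
  expect_true(all(unit_attribution(m0, cn)$attribution == "mixed"))
})

test_that("bootstrap significance flags planted means and respects monotonicity", {
  set.seed(21)
  n <- 40; p <- 40
  X_nogo <- matrix(rnorm(n * p), n)
  X_nogo[, 7] <- rnorm(n, 5, 1)          # subject-level mean 5 sigma from 0
  X_nogo[, 9] <- 0                       # identically zero feature
  X_go <- matrix(rnorm(n * p), n)
  fvs <- mk_fvs(X_go, X_nogo)
  alpha <- matrix(c(-2, rep(1, p)), 1)   # unit reads every feature
  m <- nn_model(c(as.numeric(alpha), c(0, 3)), M = 1, p = p, lambda = 0)
  cn <- structure(list(x_go = colMeans(X_go), x_nogo = colMeans(X_nogo),
                       qualifying = as.character(1:n), fraction = 1,
                       threshold = 3), class = "canonical_input")
  pr <- bootstrap_significance(m, fvs, cn, B = 5000, seed = 3)
  nogo_units <- Filter(function(u) u$condition == "NoGo", pr$units)
  expect_gte(length(nogo_units), 1)
  u <- nogo_units[[1]]
  expect_true(u$sig[7])
  expect_false(u$sig[9])
  # monotone in the familywise level
  pr2 <- bootstrap_significance(m, fvs, cn, B = 5000, alpha = 0.5, seed = 3)
  u2 <- Filter(function(x) x$condition == "NoGo", pr2$units)[[1]]
  expect_true(all(u$sig <= u2$sig))
  # signatures are linear in the canonical features
  fvs3 <- lapply(fvs, function(f) { f$x <- 3 * f$x; f })
  pr3 <- bootstrap_significance(m, fvs3, cn, B = 1000, seed = 3)
  u3 <- Filter(function(x) x$condition == "NoGo", pr3$units)[[1]]
  expect_equal(u3$s, 3 * u$s, tolerance = 1e-12)
})

test_that("summaries map significant peaks to region, band, epoch and direction", {
  p <- 40
  im <- ersplearn:::feature_vector(matrix(0, 1, 40,
                                          dimnames = list("IC1", NULL)),
                                   "1", "Go")$index_map
  s <- rep(0, p); s[1] <- 2               # theta bin 1 peak
  sig <- rep(FALSE, p); sig[1] <- TRUE
  profiles <- structure(list(units = list(list(unit = 1, condition = "NoGo",
                                               attribution = "NoGo", s = s,
                                               sig = sig)),
                             index_map = im), class = "signature_profiles")
  blocks <- list(Go = matrix(0, 1, 40), NoGo = matrix(0, 1, 40))
  blocks$NoGo[1, 1] <- 3.5                # visible positive panel value
  out <- summarize_signatures(profiles, blocks, "right_thalamus")
  expect_equal(nrow(out), 1)
  expect_equal(out$region, "right_thalamus")
  expect_equal(out$condition, "NoGo")
  expect_equal(out$band, "theta")
  expect_equal(out$epoch, "early")
  expect_equal(out$direction, "increase")
  # sub-panel-floor peaks are not reported; no significance, no rows
  blocks$NoGo[1, 1] <- 0.4
  expect_equal(nrow(summarize_signatures(profiles, blocks, "right_thalamus")), 0)
  profiles$units[[1]]$sig[] <- FALSE
  blocks$NoGo[1, 1] <- 3.5
  expect_equal(nrow(summarize_signatures(profiles, blocks, "right_thalamus")), 0)
})
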