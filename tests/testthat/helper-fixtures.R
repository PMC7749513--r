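# Shared fixtures and small oracles, built in code at test time.

fixture_env <- new.env(parent = emptyenv())

# permutation- and scale-invariant distance between true and estimated
# unmixing; 0 means perfect recovery (standard ICA benchmark)
amari_index <- function(P) {
  P <- abs(P)
  n <- nrow(P)
  s1 <- sum(rowSums(P / apply(P, 1, max)) - 1)
  s2 <- sum(colSums(sweep(P, 2, apply(P, 2, max), `/`)) - 1)
  (s1 + s2) / (2 * n * (n - 1))
}

# the pipeline configuration used for desk-scale end-to-end runs; problem
# sizes documented in the methods vignette
e2e_config <- function(...) {
  pipeline_config(pca_rank = 8, ica_max_cols = 16000, ica_max_iter = 100,
                  grid_M = 4, grid_lambda = 0.005, restarts = 1L,
                  batch_sizes = c(2, 3), inner_folds = 3L, M_select = 2,
                  maxit = 300L, ...)
}

# a very small preprocessed cohort + cv run, cached across test files
tiny_cv_run <- function() {
  if (is.null(fixture_env$tiny_cv)) {
    sc <- scaled_scenario(n_subjects = 6, seed = 301)
    esets <- lapply(simulate_cohort(sc$cfg, sc$truth), preprocess_epochs)
    cfg <- e2e_config(select_components = FALSE)
    fixture_env$tiny_cv <- list(
      scenario = sc, esets = esets, config = cfg,
      cv = run_cv(esets, config = cfg, seed = 301))
  }
  fixture_env$tiny_cv
}

# write a minimal EDF file (16-bit LE) for importer tests
edf_fixture <- function(path, chans, fs, dur_s) {
  # chans: named list of numeric vectors (physical units), equal length
  n <- length(chans[[1]])
  n_rec <- n / (fs * dur_s)
  stopifnot(n_rec == round(n_rec))
  ns <- length(chans)
  pmin_ <- -200; pmax_ <- 200; dmin <- -32768; dmax <- 32767
  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s, w) writeBin(charToRaw(pad(s, w)), con)
  wr("0", 8); wr("test patient", 80); wr("test recording", 80)
  wr("01.01.20", 8); wr("00.00.00", 8)
  wr(256 + ns * 256, 8); wr("", 44); wr(n_rec, 8); wr(dur_s, 8); wr(ns, 4)
  for (nm in names(chans)) wr(nm, 16)
  for (i in seq_len(ns)) wr("transducer", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(pmin_, 8)
  for (i in seq_len(ns)) wr(pmax_, 8)
  for (i in seq_len(ns)) wr(dmin, 8)
  for (i in seq_len(ns)) wr(dmax, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs * dur_s, 8)
  for (i in seq_len(ns)) wr("", 32)
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      seg <- chans[[i]][((r - 1) * fs * dur_s + 1):(r * fs * dur_s)]
      dig <- as.integer(round((seg - pmin_) / gain + dmin))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
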