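# Filtering, epoch rejection, interpolation, re-referencing.
#
# The pipeline order is fixed: filter -> downsample -> epoch -> reject ->
# interpolate -> average reference. Filters are zero-phase windowed-sinc
# FIR (Hamming window, transition width 25% of the cutoff).

#' Construct an epoch set
#'
#' One subject x condition block of trials x channels x samples plus the
#' montage and (for Go) per-trial reaction times.
#'
#' @param subject_id Integer id.
#' @param condition `"Go"` or `"NoGo"`.
#' @param data Numeric array, trials x channels x samples.
#' @param sample_rate_hz Sampling rate.
#' @param times Time axis in seconds (stimulus at 0).
#' @param montage A `montage`.
#' @param rts Per-trial reaction times (s), or `NULL`.
#' @param rejected_mask Logical per-trial rejection flags.
#' @return An `epoch_set`.
#' @export
epoch_set <- function(subject_id, condition, data, sample_rate_hz, times,
                      montage, rts = NULL, rejected_mask = NULL) {
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(montage$channel_names),
            dim(data)[3] == length(times))
  if (is.null(rejected_mask)) rejected_mask <- rep(FALSE, dim(data)[1])
  structure(list(subject_id = subject_id, condition = condition, data = data,
                 sample_rate_hz = sample_rate_hz, times = times,
                 montage = montage, rts = rts, rejected_mask = rejected_mask),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> subject %s, %s: %d trials (%d rejected) x %d ch x %d samples @ %g Hz\n",
    x$subject_id, x$condition, d[1], sum(x$rejected_mask), d[2], d[3],
    x$sample_rate_hz))
  invisible(x)
}

#' Retained trials of an epoch set
#' @param eset An `epoch_set`.
#' @return The epoch set with rejected trials dropped from `data` and `rts`.
#' @export
retained <- function(eset) {
  keep <- !eset$rejected_mask
  eset$data <- eset$data[keep, , , drop = FALSE]
  if (!is.null(eset$rts)) eset$rts <- eset$rts[keep]
  eset$rejected_mask <- rep(FALSE, sum(keep))
  eset
}

# windowed-sinc FIR with Hamming window; transition width 25% of cutoff
fir_design <- function(low_hz, high_hz, fs) {
  trans <- 0.25 * if (low_hz > 0) low_hz else high_hz
  ntaps <- ceiling(3.3 * fs / trans)            # Hamming: ~3.3/normalized width
  ntaps <- ntaps + (ntaps %% 2 == 0)            # odd length, type-I linear phase
  w <- c(low_hz, high_hz) / (fs / 2)
  if (low_hz <= 0) {
    signal::fir1(ntaps - 1, w[2], type = "low")
  } else if (high_hz >= fs / 2) {
    signal::fir1(ntaps - 1, w[1], type = "high")
  } else {
    signal::fir1(ntaps - 1, w, type = "pass")
  }
}

# zero-phase FIR by forward filtering and compensating the group delay
fir_apply <- function(x, h) {
  n <- length(x)
  d <- (length(h) - 1) / 2
  xp <- c(rev(x[seq_len(min(d, n))]), x, rev(x[seq(n - min(d, n) + 1, n)]))
  y <- stats::filter(xp, h, method = "convolution", sides = 1)
  as.numeric(y[(d + min(d, n) + 1):(d + min(d, n) + n)])
}

#' Band-pass filter continuous or epoched data
#'
#' Zero-phase FIR (windowed sinc, Hamming). The filter order follows from a
#' transition width of 25% of the lower cutoff, giving > 40 dB attenuation
#' at half the low cutoff and 1.2x the high cutoff.
#'
#' @param x Numeric vector, or matrix (channels x samples), or 3-d array
#'   (trials x channels x samples).
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Pass-band edges (default 1 and 50 Hz).
#' @return Filtered data, same shape.
#' @export
bandpass_filter <- function(x, fs, low_hz = 1, high_hz = 50) {
  if (high_hz >= fs / 2) {
    stop(errorCondition("high cutoff must be below the Nyquist frequency",
                        class = c("ersplearn_nyquist", "error")))
  }
  h <- fir_design(low_hz, high_hz, fs)
  apply_over_samples(x, function(v) fir_apply(v, h))
}

apply_over_samples <- function(x, f) {
  if (is.null(dim(x))) return(f(x))
  if (length(dim(x)) == 2) return(t(apply(x, 1, f)))
  out <- x
  for (tr in seq_len(dim(x)[1])) {
    out[tr, , ] <- t(apply(x[tr, , , drop = TRUE], 1, f))
  }
  out
}

#' Downsample data with anti-alias filtering
#'
#' Integer decimation uses a zero-phase FIR anti-alias filter; non-integer
#' ratios use windowed-sinc interpolation onto the new sample grid.
#'
#' @inheritParams bandpass_filter
#' @param target_hz New sampling rate; must not exceed `fs`.
#' @return Resampled data, same shape family as the input.
#' @export
downsample <- function(x, fs, target_hz) {
  if (target_hz > fs) {
    stop(errorCondition("upsampling requested; target rate must be <= source rate",
                        class = c("ersplearn_upsample", "error")))
  }
  if (target_hz == fs) return(x)
  k <- fs / target_hz
  if (abs(k - round(k)) < 1e-9) {
    k <- round(k)
    h <- fir_design(0, 0.45 * target_hz, fs)
    dec <- function(v) fir_apply(v, h)[seq(1, length(v), by = k)]
    apply_over_samples(x, dec)
  } else {
    # windowed-sinc interpolation onto the new grid (mild anti-alias first)
    h <- if (0.45 * target_hz < fs / 2) fir_design(0, 0.45 * target_hz, fs) else NULL
    interp <- function(v) {
      if (!is.null(h)) v <- fir_apply(v, h)
      n <- length(v)
      t_new <- seq(0, (n - 1) / fs, by = 1 / target_hz)
      idx <- t_new * fs + 1
      half <- 16L
      vapply(idx, function(i) {
        j <- seq(max(1, floor(i) - half), min(n, floor(i) + half))
        u <- i - j
        w <- sinc(u) * hann_win(u / (half + 1))
        sum(v[j] * w) / sum(w)
      }, 0)
    }
    apply_over_samples(x, interp)
  }
}

sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(pi * x) / (pi * x))
hann_win <- function(u) ifelse(abs(u) < 1, 0.5 * (1 + cos(pi * u)), 0)

#' Flag artifact epochs
#'
#' A trial is flagged if its peak-to-peak amplitude exceeds `amp_thresh_uv`
#' on any channel, or if its high-frequency (> 20 Hz) power z-score across
#' trials exceeds `zscore_thresh` on any channel. Original data are kept;
#' only the `rejected_mask` is updated.
#'
#' @param eset An `epoch_set`.
#' @param amp_thresh_uv Peak-to-peak threshold (uV).
#' @param zscore_thresh High-frequency power z-score threshold.
#' @return The epoch set with an updated `rejected_mask`.
#' @export
reject_epochs <- function(eset, amp_thresh_uv = 150, zscore_thresh = 5) {
  stopifnot(amp_thresh_uv > 0, zscore_thresh > 0)
  d <- eset$data
  ntr <- dim(d)[1]
  ptp <- apply(d, c(1, 2), function(v) diff(range(v)))
  flag_amp <- apply(ptp > amp_thresh_uv, 1, any)
  # high-frequency power is roughly lognormal across trials, so the z-score
  # is taken on the log scale with robust (median/MAD) centering, keeping
  # contaminated trials from masking themselves by inflating the spread
  hf <- log10(hf_power(d, eset$sample_rate_hz) + 1e-20)  # trials x channels
  ctr <- apply(hf, 2, stats::median)
  sc <- apply(hf, 2, stats::mad)
  sc[sc == 0] <- apply(hf, 2, stats::sd)[sc == 0]
  sc[sc == 0] <- Inf
  z <- sweep(sweep(hf, 2, ctr), 2, sc, `/`)
  flag_hf <- apply(z > zscore_thresh, 1, any)
  mask <- flag_amp | flag_hf
  if (all(mask)) {
    stop(errorCondition("all trials rejected",
                        class = c("ersplearn_all_rejected", "error")))
  }
  eset$rejected_mask <- mask
  eset
}

# mean power above 20 Hz per trial and channel
hf_power <- function(d, fs) {
  ns <- dim(d)[3]
  freqs <- (seq_len(ns) - 1) * fs / ns
  hi <- freqs > 20 & freqs < fs / 2
  t(apply(d, 1, function(ch_by_samp) {
    sp <- Mod(stats::mvfft(t(ch_by_samp)))^2
    colMeans(sp[hi, , drop = FALSE])
  }))
}

#' Interpolate bad channels and apply the average reference
#'
#' Bad channels are replaced by spherical-spline interpolation (order m = 4,
#' 30 Legendre terms) from the good channels, then every sample is
#' re-referenced to the channel mean.
#'
#' @param eset An `epoch_set`.
#' @param bad_channels Character vector of channel names (may be empty).
#' @return The epoch set, interpolated and average-referenced.
#' @export
interpolate_and_rereference <- function(eset, bad_channels = character()) {
  ch <- eset$montage$channel_names
  bad <- match(bad_channels, ch)
  if (anyNA(bad)) stop("unknown channel in bad_channels", call. = FALSE)
  if (length(bad) > 0.25 * length(ch)) {
    stop(errorCondition("more than 25% of channels are bad",
                        class = c("ersplearn_too_many_bad", "error")))
  }
  if (length(bad) > 0) {
    good <- setdiff(seq_along(ch), bad)
    W <- spline_interp_matrix(eset$montage$positions[good, , drop = FALSE],
                              eset$montage$positions[bad, , drop = FALSE])
    for (tr in seq_len(dim(eset$data)[1])) {
      eset$data[tr, bad, ] <- W %*% eset$data[tr, good, , drop = TRUE]
    }
  }
  for (tr in seq_len(dim(eset$data)[1])) {
    x <- eset$data[tr, , , drop = TRUE]
    eset$data[tr, , ] <- sweep(x, 2, colMeans(x))
  }
  eset
}

# Perrin-style spherical spline interpolation operator: rows = bad electrode
# positions, columns = good electrode positions.
spline_interp_matrix <- function(pos_good, pos_bad, m = 4, n_terms = 30) {
  gfun <- function(cosang) {
    leg <- legendre_terms(cosang, n_terms)$p      # n x npts
    n <- seq_len(n_terms)
    w <- (2 * n + 1) / (n^m * (n + 1)^m)
    as.numeric(t(leg) %*% w) / (4 * pi)
  }
  unit <- function(p) p / sqrt(rowSums(p^2))
  ug <- unit(pos_good); ub <- unit(pos_bad)
  G <- matrix(gfun(pmin(1, pmax(-1, tcrossprod(ug)))), nrow(ug))
  Gb <- matrix(gfun(pmin(1, pmax(-1, tcrossprod(ub, ug)))), nrow(ub))
  ng <- nrow(ug)
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  # weights solve [G 1; 1' 0] [c; c0] = [v; 0]; interpolant = Gb c + c0
  Ainv <- solve(A)
  cbind(Gb, 1) %*% Ainv[, seq_len(ng), drop = FALSE]
}

#' Run the fixed preprocessing chain on an epoch set
#'
#' Order is enforced: (optional) band-pass filter, (optional) downsample,
#' artifact rejection, interpolation of bad channels, average reference.
#'
#' @param eset An `epoch_set`.
#' @param filter_band `NULL` to skip filtering (synthetic data are already
#'   band-limited), else `c(low, high)` in Hz.
#' @param target_hz `NULL` to keep the sampling rate, else the new rate.
#' @param amp_thresh_uv,zscore_thresh Rejection thresholds.
#' @param bad_channels Channels to interpolate.
#' @return The preprocessed epoch set (rejected trials dropped).
#' @export
preprocess_epochs <- function(eset, filter_band = NULL, target_hz = NULL,
                              amp_thresh_uv = 150, zscore_thresh = 5,
                              bad_channels = character()) {
  if (!is.null(filter_band)) {
    eset$data <- bandpass_filter(eset$data, eset$sample_rate_hz,
                                 filter_band[1], filter_band[2])
  }
  if (!is.null(target_hz) && target_hz != eset$sample_rate_hz) {
    eset$data <- downsample(eset$data, eset$sample_rate_hz, target_hz)
    n_new <- dim(eset$data)[3]
    eset$times <- eset$times[1] + (seq_len(n_new) - 1) / target_hz
    eset$sample_rate_hz <- target_hz
  }
  eset <- reject_epochs(eset, amp_thresh_uv, zscore_thresh)
  eset <- retained(eset)
  interpolate_and_rereference(eset, bad_channels)
}
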