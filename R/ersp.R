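# Event-related spectral perturbation (ERSP) estimation and construction of
# the scaled band x time feature vector.
#
# ERSP grid: frequencies 1..30 Hz (1 Hz steps, from a 0.5-s Hann-tapered
# window zero-padded to the sample rate), frames every 0.05 s from -0.75 to
# 1.75 s; per-trial dB (10 log10 power), trial-averaged, baseline-corrected
# by the mean over the -0.75..0 s frames.

ersp_frame_times <- function() seq(-0.75, 1.75, by = 0.05)

#' Compute ERSP for one subject x condition block of component activations
#'
#' @param component_trials Array trials x components x samples (activations
#'   from [project_subject()]), spanning -1..2 s.
#' @param fs Sampling rate (must make 0.5 s an integer number of samples).
#' @param times Time axis of the samples; defaults to -1..2 s.
#' @return An `ersp_array`: values (components x 30 frequencies x 51
#'   frames, dB change from baseline), plus `freqs`, `frame_times`.
#' @export
compute_ersp <- function(component_trials, fs = 128,
                         times = NULL) {
  d <- dim(component_trials)
  stopifnot(length(d) == 3)
  ns <- d[3]
  if (is.null(times)) times <- -1 + (seq_len(ns) - 1) / fs
  win <- as.integer(round(0.5 * fs))
  if (ns < win) {
    stop(errorCondition("trials too short for the 0.5 s analysis window",
                        class = c("ersplearn_short_trial", "error")))
  }
  nfft <- as.integer(2 * win)            # x2 zero-padding -> 1 Hz grid
  freqs <- seq_len(nfft) - 1             # Hz, since nfft = fs
  fsel <- which(freqs >= 1 & freqs <= 30)
  ft <- ersp_frame_times()
  starts <- vapply(ft, function(t0) {
    s <- as.integer(round((t0 - 0.25 - times[1]) * fs)) + 1L
    max(1L, min(ns - win + 1L, s))
  }, 1L)
  taper <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1) / (win - 1))
  ntr <- d[1]; k <- d[2]; nf <- length(ft)
  eps <- 1e-20
  # one batched FFT over every (frame, trial, component) window
  A <- matrix(aperm(component_trials, c(3, 1, 2)), nrow = ns)  # ns x (ntr*k)
  big <- matrix(0, nfft, nf * ntr * k)
  for (fi in seq_len(nf)) {
    idx <- starts[fi]:(starts[fi] + win - 1)
    big[seq_len(win), (fi - 1) * ntr * k + seq_len(ntr * k)] <- A[idx, ] * taper
  }
  p <- Mod(stats::mvfft(big))^2
  db <- 10 * log10(p[fsel, , drop = FALSE] + eps)        # per-trial dB
  m <- array(db, c(length(fsel), ntr, k, nf))
  tm <- colMeans(aperm(m, c(2, 1, 3, 4)))                # freq x k x frames
  vals <- aperm(tm, c(2, 1, 3))                          # k x freq x frames
  base <- ft <= 0
  vals <- sweep(vals, c(1, 2), apply(vals[, , base, drop = FALSE], c(1, 2), mean))
  structure(list(values = vals, freqs = freqs[fsel], frame_times = ft),
            class = "ersp_array")
}

#' Reduce an ERSP array to band x time features
#'
#' Means over the five canonical frequency bands and eight 0.1-s bins
#' covering 0-0.8 s post-stimulus (optionally shifted by a per-subject RT
#' adjustment, in whole 0.05-s frames). Output is ordered (component, band,
#' bin) with bin fastest.
#'
#' @param ersp An `ersp_array`.
#' @param bands A band scheme, see [band_scheme()].
#' @param shift_s Window shift in seconds (multiple of 0.05; clamped so the
#'   0.8-s window stays inside the computed frames).
#' @return Matrix components x 40 with `dimnames` giving band.bin labels.
#' @export
bandtime_reduce <- function(ersp, bands = band_scheme(), shift_s = 0) {
  ft <- ersp$frame_times
  shift_s <- clamp_shift(shift_s)
  k <- dim(ersp$values)[1]
  out <- matrix(0, k, length(bands$bands) * 8)
  cn <- character(ncol(out))
  col <- 0
  for (b in seq_along(bands$bands)) {
    fr <- ersp$freqs >= bands$bands[[b]][1] & ersp$freqs <= bands$bands[[b]][2]
    for (bin in 1:8) {
      col <- col + 1
      lo <- (bin - 1) * 0.1 + shift_s
      hi <- bin * 0.1 + shift_s
      tsel <- ft > lo + 1e-9 & ft <= hi + 1e-9
      out[, col] <- apply(ersp$values[, fr, tsel, drop = FALSE], 1, mean)
      cn[col] <- sprintf("%s.bin%d", bands$labels[b], bin)
    }
  }
  dimnames(out) <- list(paste0("IC", seq_len(k)), cn)
  out
}

# keep the shifted 0..0.8 s window inside the -0.75..1.75 s frame range
clamp_shift <- function(shift_s) {
  shift_s <- round(shift_s / 0.05) * 0.05
  max(-0.7, min(0.9, shift_s))
}

#' Estimate the reaction-time window adjustment
#'
#' Regresses each subject's peak latency of |ERSP| (theta band of the seed
#' components, 0-0.8 s, Go condition) on the subject's mean Go reaction
#' time; the per-subject window shift is `slope * (rt - mean rt)`, rounded
#' to the 0.05-s frame grid and applied identically to both conditions.
#'
#' @param ersps Named list (by subject) of Go-condition `ersp_array`s.
#' @param rts Named numeric vector of mean Go RTs (s), same subjects.
#' @param components Component indices to search for the peak (seed
#'   components by convention).
#' @return An `rt_adjustment`: `slope`, `intercept`, `shifts` (named, s).
#' @export
estimate_rt_adjustment <- function(ersps, rts, components = NULL) {
  stopifnot(length(ersps) >= 3, all(names(ersps) %in% names(rts)))
  rts <- rts[names(ersps)]
  lat <- vapply(ersps, function(e) {
    k <- dim(e$values)[1]
    comps <- if (is.null(components)) seq_len(k) else intersect(components, seq_len(k))
    fr <- e$freqs >= 4 & e$freqs <= 8
    tsel <- e$frame_times > 0 & e$frame_times <= 0.8
    sub <- abs(e$values[comps, fr, tsel, drop = FALSE])
    prof <- apply(sub, 3, max)
    e$frame_times[tsel][which.max(prof)]
  }, 0)
  if (stats::sd(rts) < 1e-12) {
    warning("degenerate RT variance; all shifts set to zero", call. = FALSE)
    return(structure(list(slope = 0, intercept = mean(lat),
                          shifts = setNames(rep(0, length(rts)), names(rts))),
                     class = "rt_adjustment"))
  }
  fit <- stats::lm(lat ~ rts)
  slope <- unname(stats::coef(fit)[2])
  shifts <- vapply(rts, function(r) clamp_shift(slope * (r - mean(rts))), 0)
  structure(list(slope = slope, intercept = unname(stats::coef(fit)[1]),
                 shifts = shifts), class = "rt_adjustment")
}

#' Scale raw band x time blocks into feature vectors
#'
#' Within each subject and component, values are centered and variance-
#' scaled across all available entries (5 bands x 8 bins x conditions
#' present), so each (subject, component) block has mean 0 and variance 1.
#' Held-out subjects are self-normalizing by construction: no cohort
#' statistics enter.
#'
#' @param blocks Named list `"<subject>.<condition>"` of component x 40
#'   matrices from [bandtime_reduce()].
#' @return List of `feature_vector`s (same names): `x` (length p), `p`,
#'   `subject_id`, `condition`, and `index_map` (data frame j -> component,
#'   band, bin).
#' @export
scale_features <- function(blocks) {
  info <- strsplit(names(blocks), ".", fixed = TRUE)
  subjects <- vapply(info, `[`, "", 1)
  out <- list()
  for (sid in unique(subjects)) {
    idx <- which(subjects == sid)
    stacked <- do.call(cbind, blocks[idx])          # comps x (40*nconds)
    mu <- rowMeans(stacked)
    sdv <- apply(stacked, 1, stats::sd)
    if (any(sdv == 0)) {
      warning("zero-variance (subject, component) block; unit scale used",
              call. = FALSE)
      sdv[sdv == 0] <- 1
    }
    for (i in idx) {
      z <- (blocks[[i]] - mu) / sdv
      out[[names(blocks)[i]]] <- feature_vector(z, subjects[i],
                                                vapply(info[i], `[`, "", 2))
    }
  }
  out[names(blocks)]
}

feature_vector <- function(z, subject_id, condition) {
  k <- nrow(z)
  im <- expand.grid(bin = 1:8, band = band_scheme()$labels,
                    component = seq_len(k), stringsAsFactors = FALSE)
  im <- im[, c("component", "band", "bin")]
  x <- as.numeric(t(z))                  # (component, band, bin), bin fastest
  names(x) <- paste(rownames(z)[im$component], im$band, im$bin, sep = ".")
  structure(list(x = x, p = length(x), subject_id = subject_id,
                 condition = condition, index_map = im),
            class = "feature_vector")
}

#' Feature-matrix view of a list of feature vectors
#' @param fvs List of `feature_vector`s.
#' @return List with `X` (n x p matrix), `y` (factor Go/NoGo), `subjects`.
#' @export
feature_matrix <- function(fvs) {
  X <- do.call(rbind, lapply(fvs, `[[`, "x"))
  rownames(X) <- names(fvs)
  y <- factor(vapply(fvs, `[[`, "", "condition"), levels = c("Go", "NoGo"))
  subjects <- vapply(fvs, `[[`, "", "subject_id")
  list(X = X, y = y, subjects = subjects, index_map = fvs[[1]]$index_map)
}
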