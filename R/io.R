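# Portable epoch container and a minimal EDF importer.
#
# Container layout: a directory holding `epochs.bin` (float32 little-endian,
# trials x channels x samples, C order: sample index fastest) and
# `meta.json` (subject, condition, sample rate, time window, channel names
# and positions, reaction times). `truth.json` optionally serializes the
# ground truth of a simulation.

#' Write an epoch set to a container directory
#'
#' @param eset An `epoch_set`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_epochs <- function(eset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dim(eset$data)
  # C order trials x channels x samples: samples fastest
  flat <- as.numeric(aperm(eset$data, c(3, 2, 1)))
  con <- file(file.path(dir, "epochs.bin"), "wb")
  writeBin(flat, con, size = 4, endian = "little")
  close(con)
  meta <- list(subject_id = eset$subject_id, condition = eset$condition,
               n_trials = d[1], n_channels = d[2], n_samples = d[3],
               sample_rate_hz = eset$sample_rate_hz,
               window_s = c(eset$times[1], eset$times[length(eset$times)]),
               channel_names = eset$montage$channel_names,
               positions = unname(apply(eset$montage$positions, 1, as.numeric,
                                        simplify = FALSE)),
               scalp_radius_mm = eset$montage$scalp_radius_mm,
               reference = eset$montage$reference,
               rts = eset$rts, rejected_mask = eset$rejected_mask)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Read an epoch set from a container directory
#'
#' @param dir Directory written by [write_epochs()].
#' @return An `epoch_set`.
#' @export
read_epochs <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- meta$n_trials * meta$n_channels * meta$n_samples
  con <- file(file.path(dir, "epochs.bin"), "rb")
  flat <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  close(con)
  data <- aperm(array(flat, c(meta$n_samples, meta$n_channels, meta$n_trials)),
                c(3, 2, 1))
  pos <- if (is.matrix(meta$positions)) meta$positions else
    do.call(rbind, lapply(meta$positions, as.numeric))
  rownames(pos) <- meta$channel_names
  montage <- structure(list(channel_names = meta$channel_names,
                            positions = pos,
                            reference = meta$reference,
                            scalp_radius_mm = meta$scalp_radius_mm),
                       class = "montage")
  times <- seq(meta$window_s[1], by = 1 / meta$sample_rate_hz,
               length.out = meta$n_samples)
  epoch_set(meta$subject_id, meta$condition, data, meta$sample_rate_hz, times,
            montage, rts = meta$rts,
            rejected_mask = as.logical(meta$rejected_mask))
}

#' Import continuous signals from an EDF file
#'
#' Minimal reader for the (uncompressed, 16-bit) European Data Format:
#' parses the fixed-width ASCII header, applies each signal's physical
#' calibration, and returns the continuous data. Annotations channels
#' ("EDF Annotations") are dropped.
#'
#' @param path Path to an .edf file.
#' @return List with `data` (channels x samples matrix, physical units),
#'   `channel_names`, `sample_rate_hz` (per retained channel; must agree),
#'   and `header` (selected fields).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_s <- function(nc) trimws(rawToChar(readBin(con, "raw", nc)))
  version <- hdr_s(8); patient <- hdr_s(80); recording <- hdr_s(80)
  startdate <- hdr_s(8); starttime <- hdr_s(8)
  n_header <- as.integer(hdr_s(8)); hdr_s(44)
  n_records <- as.integer(hdr_s(8))
  dur_s <- as.numeric(hdr_s(8))
  ns <- as.integer(hdr_s(4))
  fld <- function(nc) vapply(seq_len(ns), function(i) hdr_s(nc), "")
  labels <- fld(16); transducer <- fld(80); phys_dim <- fld(8)
  phys_min <- as.numeric(fld(8)); phys_max <- as.numeric(fld(8))
  dig_min <- as.numeric(fld(8)); dig_max <- as.numeric(fld(8))
  prefilter <- fld(80); nsamp <- as.integer(fld(8)); fld(32)
  keep <- !grepl("Annotations", labels)
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  out <- lapply(seq_len(ns), function(i) numeric(0))
  for (rec in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      raw <- readBin(con, "integer", n = nsamp[i], size = 2, signed = TRUE,
                     endian = "little")
      if (keep[i]) out[[i]] <- c(out[[i]], gain[i] * raw + offset[i])
    }
  }
  data <- do.call(rbind, out[keep])
  rownames(data) <- labels[keep]
  list(data = data, channel_names = labels[keep],
       sample_rate_hz = nsamp[keep] / dur_s,
       header = list(version = version, patient = patient,
                     recording = recording, startdate = startdate,
                     starttime = starttime, n_records = n_records,
                     record_duration_s = dur_s))
}

#' Segment continuous data into stimulus-locked epochs
#'
#' @param data Channels x samples matrix.
#' @param fs Sampling rate.
#' @param events Stimulus-onset sample indices.
#' @param window_s Epoch window relative to onsets (default -1..2 s).
#' @return Array trials x channels x samples (onsets too close to the edges
#'   are dropped).
#' @export
segment_epochs <- function(data, fs, events, window_s = c(-1, 2)) {
  lo <- round(window_s[1] * fs); hi <- round(window_s[2] * fs) - 1
  ok <- events + lo >= 1 & events + hi <= ncol(data)
  events <- events[ok]
  out <- array(0, c(length(events), nrow(data), hi - lo + 1))
  for (i in seq_along(events)) {
    out[i, , ] <- data[, (events[i] + lo):(events[i] + hi)]
  }
  out
}
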