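#' Head-model geometry defaults
#'
#' Three concentric spherical shells (brain / skull / scalp) with the classic
#' 1/80 skull-to-brain conductivity ratio. All radii in millimetres.
#'
#' @return A list with fields `radii` (brain, skull, scalp), `sigma`
#'   (conductivities, arbitrary units), and `gray_matter_radius_mm`, the
#'   radial bound used as a geometric stand-in for a gray-matter test.
#' @export
head_model <- function() {
  list(
    radii = c(brain = 80, skull = 85, scalp = 92),
    sigma = c(brain = 1, skull = 1 / 80, scalp = 1),
    gray_matter_radius_mm = 78,
    ventricle_radius_mm = 8
  )
}

#' Build an electrode montage on the scalp sphere
#'
#' Places `n` electrodes on the upper part of the scalp sphere using a
#' Fibonacci lattice, mimicking the coverage of a 64-channel cap. The
#' geometry is synthetic: labels are positional, not 10-20 names.
#'
#' @param n Number of electrodes (default 64).
#' @param scalp_radius_mm Scalp sphere radius in mm.
#' @param reference Reference label; `"average"` for common average.
#' @return An object of class `montage`: list with `channel_names`,
#'   `positions` (n x 3 matrix, mm), `reference`, `scalp_radius_mm`.
#' @export
build_montage <- function(n = 64, scalp_radius_mm = head_model()$radii[["scalp"]],
                          reference = "average") {
  stopifnot(n >= 4)
  # Fibonacci lattice over the full sphere, keep the n most superior points
  # (a cap extending a little below the equator, like a real EEG cap).
  m <- ceiling(n * 1.55)
  i <- seq_len(m) - 0.5
  phi <- acos(1 - 2 * i / m)           # polar angle from +z
  theta <- pi * (1 + sqrt(5)) * i      # golden-angle azimuth
  pts <- cbind(
    sin(phi) * cos(theta),
    sin(phi) * sin(theta),
    cos(phi)
  )
  ord <- order(pts[, 3], decreasing = TRUE)
  pts <- pts[ord[seq_len(n)], , drop = FALSE] * scalp_radius_mm
  names <- sprintf("E%02d", seq_len(n))
  structure(
    list(
      channel_names = names,
      positions = `rownames<-`(pts, names),
      reference = reference,
      scalp_radius_mm = scalp_radius_mm
    ),
    class = "montage"
  )
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d channels on a %.0f mm scalp sphere, reference: %s\n",
              length(x$channel_names), x$scalp_radius_mm, x$reference))
  invisible(x)
}

validate_montage <- function(montage) {
  stopifnot(inherits(montage, "montage"))
  r <- sqrt(rowSums(montage$positions^2))
  if (any(abs(r - montage$scalp_radius_mm) > 1e-6)) {
    stop("montage positions must lie on the scalp shell", call. = FALSE)
  }
  if (anyDuplicated(montage$channel_names) > 0) {
    stop("montage channel names must be unique", call. = FALSE)
  }
  invisible(montage)
}
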