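# Three-shell spherical EEG forward model.
#
# Exact series solution of the Poisson problem for a current dipole inside
# three concentric conductive spheres (brain / skull / scalp). For each
# spherical-harmonic order n the radial coefficients of the potential in the
# three shells follow from continuity of potential and radial current at the
# two interfaces plus a no-current condition at the scalp surface; that is a
# 5x5 linear solve per order, done once per dipole location and cached over
# electrodes. All radii are expressed in units of the scalp radius so the
# series is numerically stable up to high orders.

# Legendre P_n(x) and the derivative-based associated function
# P_n^1(x) = sqrt(1-x^2) * dP_n/dx (no Condon-Shortley phase), for n = 1..N.
legendre_terms <- function(x, n_max) {
  p <- matrix(0, n_max + 1, length(x))   # rows: n = 0..n_max
  dp <- matrix(0, n_max + 1, length(x))
  p[1, ] <- 1
  if (n_max >= 1) {
    p[2, ] <- x
    dp[2, ] <- 1
  }
  if (n_max >= 2) {
    for (n in 2:n_max) {
      p[n + 1, ] <- ((2 * n - 1) * x * p[n, ] - (n - 1) * p[n - 1, ]) / n
      dp[n + 1, ] <- dp[n - 1, ] + (2 * n - 1) * p[n, ]
    }
  }
  s <- sqrt(pmax(0, 1 - x^2))
  list(p = p[-1, , drop = FALSE],
       p1 = sweep(dp[-1, , drop = FALSE], 2, s, `*`))
}

# Radial transfer factors: for order n, the scalp-surface potential produced
# by a unit source coefficient (b1 = 1 in scalp-radius units). Returns a
# vector over n = 1..n_max.
shell_transfer <- function(model, n_max) {
  rho <- model$radii / model$radii[["scalp"]]
  s <- model$sigma
  r1 <- rho[["brain"]]; r2 <- rho[["skull"]]
  v <- numeric(n_max)
  for (n in seq_len(n_max)) {
    # unknowns: a1, a2, b2, a3, b3 (potential = a rho^n + b rho^-(n+1))
    A <- matrix(0, 5, 5)
    b <- numeric(5)
    pw <- function(r) c(r^n, r^(-(n + 1)))
    dw <- function(r) c(n * r^(n - 1), -(n + 1) * r^(-(n + 2)))
    # continuity of potential at r1:  a1 r1^n + 1*r1^-(n+1) = a2 r1^n + b2 r1^-(n+1)
    A[1, ] <- c(pw(r1)[1], -pw(r1)[1], -pw(r1)[2], 0, 0)
    b[1] <- -pw(r1)[2]
    # continuity of radial current at r1
    A[2, ] <- c(s[["brain"]] * dw(r1)[1], -s[["skull"]] * dw(r1)[1],
                -s[["skull"]] * dw(r1)[2], 0, 0)
    b[2] <- -s[["brain"]] * dw(r1)[2]
    # continuity of potential at r2
    A[3, ] <- c(0, pw(r2)[1], pw(r2)[2], -pw(r2)[1], -pw(r2)[2])
    # continuity of radial current at r2
    A[4, ] <- c(0, s[["skull"]] * dw(r2)[1], s[["skull"]] * dw(r2)[2],
                -s[["scalp"]] * dw(r2)[1], -s[["scalp"]] * dw(r2)[2])
    # no radial current through the scalp surface (rho = 1)
    A[5, ] <- c(0, 0, 0, dw(1)[1], dw(1)[2])
    x <- solve(A, b)
    v[n] <- x[4] + x[5]                  # scalp potential at rho = 1
  }
  v
}

# Scalp potential of a dipole at `loc` (mm) with moment `moment` (3-vector,
# arbitrary units) at the electrode positions of `montage`. Unreferenced.
dipole_potential <- function(montage, loc, moment, model = head_model(),
                             n_terms = 60L, gain = 1e4) {
  R <- model$radii[["scalp"]]
  r0 <- sqrt(sum(loc^2))
  elec <- montage$positions / R
  f <- r0 / R
  tf <- shell_transfer_cached(model, n_terms)
  if (r0 < 1e-9) {
    # central dipole: pure order-1 pattern about the moment axis
    qn <- sqrt(sum(moment^2))
    if (qn == 0) return(rep(0, nrow(elec)))
    rhat0 <- moment / qn
    q_r <- qn
    q_tvec <- c(0, 0, 0)
  } else {
    rhat0 <- loc / r0
    q_r <- sum(moment * rhat0)
    q_tvec <- moment - q_r * rhat0
  }
  q_t <- sqrt(sum(q_tvec^2))
  ehat <- elec / sqrt(rowSums(elec^2))
  cg <- pmin(1, pmax(-1, as.numeric(ehat %*% rhat0)))
  # azimuth of each electrode about the dipole axis, from the tangential moment
  if (q_t > 0) {
    that <- q_tvec / q_t
    perp <- ehat - cg %*% t(rhat0)
    pn <- sqrt(rowSums(perp^2))
    cphi <- ifelse(pn > 1e-12, as.numeric(perp %*% that) / pn, 0)
  } else {
    cphi <- rep(0, nrow(ehat))
  }
  leg <- legendre_terms(cg, n_terms)
  n <- seq_len(n_terms)
  fpow <- if (f == 0) c(1, rep(0, n_terms - 1)) else f^(n - 1)
  w_rad <- tf * fpow * n * q_r
  w_tan <- tf * fpow * q_t
  v <- as.numeric(t(leg$p) %*% w_rad + (t(leg$p1) %*% w_tan) * cphi)
  v * gain / (4 * pi * model$sigma[["brain"]] * R^2)
}

# Factory: fast evaluator loc -> (channels x 3) free-orientation lead field,
# sharing the Legendre recursion and transfer factors across the three
# moment directions. Used heavily inside the dipole-fit optimizer.
leadfield_evaluator <- function(montage, model = head_model(), n_terms = 60L,
                                gain = 1e4) {
  R <- model$radii[["scalp"]]
  elec <- montage$positions / R
  ehat <- elec / sqrt(rowSums(elec^2))
  tf <- shell_transfer_cached(model, n_terms)
  n <- seq_len(n_terms)
  scale <- gain / (4 * pi * model$sigma[["brain"]] * R^2)
  function(loc) {
    r0 <- sqrt(sum(loc^2))
    if (r0 < 1e-9) loc <- c(1e-9, 0, 0)
    r0 <- max(r0, 1e-9)
    rhat0 <- loc / r0
    f <- r0 / R
    cg <- pmin(1, pmax(-1, as.numeric(ehat %*% rhat0)))
    leg <- legendre_terms(cg, n_terms)
    fpow <- f^(n - 1)
    rad <- as.numeric(t(leg$p) %*% (tf * fpow * n))      # x q_r
    tan_ <- as.numeric(t(leg$p1) %*% (tf * fpow))        # x q_t cos(phi)
    perp <- ehat - cg %*% t(rhat0)
    pn <- sqrt(rowSums(perp^2))
    pn[pn < 1e-12] <- Inf
    L <- matrix(0, nrow(ehat), 3)
    for (d in 1:3) {
      e_d <- c(0, 0, 0); e_d[d] <- 1
      qr <- rhat0[d]
      qt_vec <- e_d - qr * rhat0
      L[, d] <- rad * qr + tan_ * as.numeric(perp %*% qt_vec) / pn
    }
    L * scale
  }
}

transfer_cache <- new.env(parent = emptyenv())
shell_transfer_cached <- function(model, n_terms) {
  key <- paste(c(model$radii, model$sigma, n_terms), collapse = "_")
  if (is.null(transfer_cache[[key]])) {
    transfer_cache[[key]] <- shell_transfer(model, n_terms)
  }
  transfer_cache[[key]]
}

#' Build a lead-field matrix for a set of dipolar sources
#'
#' Evaluates the three-shell spherical forward model at the montage
#' electrodes for each source. With `orientations = NULL` the dipoles have
#' free orientation and the matrix has three columns (x, y, z moment) per
#' source; with fixed orientations it has one column per source. All columns
#' are average-referenced (they sum to zero over channels).
#'
#' @param montage A `montage` object.
#' @param sources A list of source specifications, each with a `location`
#'   field (3-vector, mm); see [source_spec()].
#' @param orientations Optional list of unit 3-vectors fixing each dipole's
#'   orientation.
#' @param model Head model geometry, see [head_model()].
#' @return Matrix of size n_channels x (3 n_sources) (free) or
#'   n_channels x n_sources (fixed).
#' @export
build_forward_model <- function(montage, sources, orientations = NULL,
                                model = head_model()) {
  validate_montage(montage)
  brain_r <- model$radii[["brain"]]
  for (s in sources) {
    if (sqrt(sum(s$location^2)) >= brain_r) {
      stop(errorCondition(
        sprintf("source '%s' lies outside the brain shell", s$label %||% "?"),
        class = c("ersplearn_source_outside", "error")
      ))
    }
  }
  nch <- length(montage$channel_names)
  if (is.null(orientations)) {
    L <- matrix(0, nch, 3 * length(sources))
    for (i in seq_along(sources)) {
      for (d in 1:3) {
        m <- c(0, 0, 0); m[d] <- 1
        L[, 3 * (i - 1) + d] <- dipole_potential(montage, sources[[i]]$location, m,
                                                 model = model)
      }
    }
    colnames(L) <- paste0(rep(vapply(sources, function(s) s$label, ""), each = 3),
                          c(".x", ".y", ".z"))
  } else {
    stopifnot(length(orientations) == length(sources))
    L <- matrix(0, nch, length(sources))
    for (i in seq_along(sources)) {
      L[, i] <- dipole_potential(montage, sources[[i]]$location, orientations[[i]],
                                 model = model)
    }
    colnames(L) <- vapply(sources, function(s) s$label, "")
  }
  rownames(L) <- montage$channel_names
  sweep(L, 2, colMeans(L))               # average reference
}

`%||%` <- function(a, b) if (is.null(a)) b else a
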