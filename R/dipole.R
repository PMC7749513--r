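# Single equivalent-dipole fits of component scalp maps, residual-variance
# screening, and nearest-dipole matching across cross-validation folds.

#' Fit a single equivalent dipole to a scalp map
#'
#' Nonlinear search over dipole location (grid-seeded Nelder-Mead inside the
#' brain shell) with a linear least-squares solve for the moment at each
#' candidate location, under the three-shell spherical head model. Residual
#' variance is the unexplained fraction of the map's sum of squares.
#'
#' @param scalp_map Numeric vector over channels (average-referenced).
#' @param montage A `montage`.
#' @param model Head model, see [head_model()].
#' @param n_seeds Number of grid seeds refined by Nelder-Mead.
#' @return A `dipole_fit`: `location` (mm), `moment`, `rv`, `inside_brain`.
#' @export
fit_dipole <- function(scalp_map, montage, model = head_model(), n_seeds = 3L) {
  stopifnot(length(scalp_map) == length(montage$channel_names))
  map <- scalp_map - mean(scalp_map)
  ss <- sum(map^2)
  if (ss == 0) {
    return(structure(list(location = c(0, 0, 0), moment = c(0, 0, 0), rv = 1,
                          inside_brain = FALSE), class = "dipole_fit"))
  }
  brain_r <- model$radii[["brain"]]
  # 30-term series: truncation error < 1e-3 in amplitude for sources up to
  # 72 mm, well below the rv resolution the screen needs
  lf <- leadfield_evaluator(montage, model, n_terms = 30L)
  rv_at <- function(loc) {
    r <- sqrt(sum(loc^2))
    if (r >= brain_r - 0.5) return(list(rv = 1 + r / brain_r, moment = c(0, 0, 0)))
    L <- lf(loc)
    L <- sweep(L, 2, colMeans(L))
    q <- tryCatch(qr.solve(L, map), error = function(e) rep(0, 3))
    res <- map - L %*% q
    list(rv = sum(res^2) / ss, moment = as.numeric(q))
  }
  # coarse grid seeds
  dirs <- rbind(c(0, 0, 1), c(0, 0, -1), c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), expand_dirs())
  cand <- unique(rbind(c(0, 0, 0),
                       do.call(rbind, lapply(c(20, 40, 60, 72), function(r) dirs * r))))
  rvs <- apply(cand, 1, function(p) rv_at(p)$rv)
  seeds <- cand[order(rvs)[seq_len(min(n_seeds, nrow(cand)))], , drop = FALSE]
  best <- list(rv = Inf, par = c(0, 0, 0))
  for (i in seq_len(nrow(seeds))) {
    o <- stats::optim(seeds[i, ], function(p) rv_at(p)$rv, method = "Nelder-Mead",
                      control = list(maxit = 180, reltol = 1e-12))
    if (o$value < best$rv) best <- list(rv = o$value, par = o$par)
    if (best$rv < 1e-10) break           # already an essentially exact fit
    if (i == 1 && best$rv > 0.5) break   # clearly not dipolar; screen decides
  }
  # polish the best seed only (pointless for clearly non-dipolar maps)
  if (best$rv < 0.5) {
    o <- stats::optim(best$par, function(p) rv_at(p)$rv, method = "Nelder-Mead",
                      control = list(maxit = 150, reltol = 1e-14))
    if (o$value < best$rv) best <- list(rv = o$value, par = o$par)
  }
  fin <- rv_at(best$par)
  loc <- as.numeric(best$par)
  inside <- is.finite(fin$rv) && sqrt(sum(loc^2)) < brain_r
  if (!all(is.finite(loc)) || !is.finite(fin$rv)) {
    return(structure(list(location = c(NA, NA, NA), moment = c(0, 0, 0), rv = 1,
                          inside_brain = FALSE), class = "dipole_fit"))
  }
  structure(list(location = loc, moment = fin$moment,
                 rv = min(1, max(0, fin$rv)), inside_brain = inside),
            class = "dipole_fit")
}

expand_dirs <- function() {
  a <- 1 / sqrt(2)
  rbind(c(a, 0, a), c(-a, 0, a), c(0, a, a), c(0, -a, a),
        c(a, a, 0), c(a, -a, 0), c(-a, a, 0), c(-a, -a, 0),
        c(a, 0, -a), c(0, a, -a))
}

#' Fit dipoles to every component of an ICA result
#'
#' @param ica An `ica_result` with a montage.
#' @param montage Montage (taken from the ICA result if present).
#' @return A `component_catalog`: data frame with component, x, y, z, rv,
#'   inside_brain, keep, label, plus the fits and ICA as attributes.
#' @export
fit_component_dipoles <- function(ica, montage = ica$montage) {
  stopifnot(!is.null(montage))
  k <- ncol(ica$mixing)
  fits <- lapply(seq_len(k), function(i) fit_dipole(ica$mixing[, i], montage))
  catalog_from_fits(ica, fits)
}

catalog_from_fits <- function(ica, fits) {
  df <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(component = i, x = f$location[1], y = f$location[2],
               z = f$location[3], rv = f$rv, inside_brain = f$inside_brain,
               stringsAsFactors = FALSE)
  }))
  df$keep <- FALSE
  df$label <- sprintf("IC%d", df$component)
  structure(list(table = df, fits = fits, ica = ica),
            class = "component_catalog")
}

#' Screen components by dipole fit quality and location
#'
#' A component is kept iff its residual variance is at most `rv_max` and its
#' equivalent dipole lies in the plausible-source region: inside the
#' gray-matter radial bound and outside a small central ventricle sphere
#' (a geometric stand-in for a gray-matter test).
#'
#' @param catalog A `component_catalog`.
#' @param rv_max Residual-variance threshold (default 0.15).
#' @param model Head model.
#' @return The catalog with `keep` flags set.
#' @export
screen_components <- function(catalog, rv_max = 0.15, model = head_model()) {
  df <- catalog$table
  r <- sqrt(df$x^2 + df$y^2 + df$z^2)
  plausible <- is.finite(r) & r <= model$gray_matter_radius_mm &
    r >= model$ventricle_radius_mm
  df$keep <- df$rv <= rv_max & plausible
  catalog$table <- df
  catalog
}

#' Match component catalogs across folds by dipole proximity
#'
#' Greedy nearest-neighbour matching of kept components between a reference
#' catalog and another catalog; pairs farther than `max_dist_mm` apart stay
#' unmatched. One-to-one within the pair.
#'
#' @param ref,other `component_catalog`s (screened).
#' @param max_dist_mm Matching radius (default 5 mm).
#' @return Data frame with `ref_component`, `other_component`, `dist_mm`
#'   (unmatched reference components get `NA`).
#' @export
match_components <- function(ref, other, max_dist_mm = 5) {
  rt <- ref$table[ref$table$keep, , drop = FALSE]
  ot <- other$table[other$table$keep, , drop = FALSE]
  out <- data.frame(ref_component = rt$component,
                    other_component = NA_integer_, dist_mm = NA_real_)
  if (nrow(rt) == 0 || nrow(ot) == 0) return(out)
  D <- as.matrix(stats::dist(rbind(as.matrix(rt[, c("x", "y", "z")]),
                                   as.matrix(ot[, c("x", "y", "z")]))))
  D <- D[seq_len(nrow(rt)), nrow(rt) + seq_len(nrow(ot)), drop = FALSE]
  used <- rep(FALSE, nrow(ot))
  repeat {
    m <- which(D == min(D), arr.ind = TRUE)[1, , drop = TRUE]
    if (!is.finite(D[m[1], m[2]]) || D[m[1], m[2]] > max_dist_mm) break
    out$other_component[m[1]] <- ot$component[m[2]]
    out$dist_mm[m[1]] <- D[m[1], m[2]]
    D[m[1], ] <- Inf
    D[, m[2]] <- Inf
    if (all(!is.finite(D))) break
  }
  out
}

#' Label catalog components by proximity to named reference locations
#'
#' Used to attach region labels (e.g., the planted sources' labels) to
#' fitted components; components farther than `max_dist_mm` from every
#' reference keep their IC label.
#'
#' @param catalog A `component_catalog`.
#' @param locations Named list of 3-vectors (mm).
#' @param max_dist_mm Labelling radius.
#' @return The catalog with `label` updated.
#' @export
label_components <- function(catalog, locations, max_dist_mm = 20) {
  df <- catalog$table
  for (i in seq_len(nrow(df))) {
    p <- c(df$x[i], df$y[i], df$z[i])
    if (!all(is.finite(p))) next
    d <- vapply(locations, function(q) sqrt(sum((p - q)^2)), 0)
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= max_dist_mm) df$label[i] <- names(locations)[j]
  }
  catalog$table <- df
  catalog
}
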