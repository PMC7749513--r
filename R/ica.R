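# Group ICA: subject-wise scaling and concatenation, extended-infomax
# decomposition with PCA pre-whitening, and projection of (possibly
# held-out) subjects into the derived component space.

#' Prepare the group data matrix for ICA
#'
#' Per subject: mean-center each retained trial per channel, concatenate
#' both conditions, and scale the concatenated block to equal total
#' variance across subjects; then concatenate all subjects column-wise.
#'
#' @param esets List of `epoch_set` (subject x condition blocks).
#' @return List with `matrix` (channels x time), `scaling` (named per-subject
#'   divisors), `subjects` (subject of each block), `blocks` (column index
#'   ranges per epoch set).
#' @export
prepare_group_matrix <- function(esets) {
  stopifnot(length(esets) >= 1)
  mont <- esets[[1]]$montage
  fs <- esets[[1]]$sample_rate_hz
  for (e in esets) {
    if (!identical(e$montage$channel_names, mont$channel_names) ||
        e$sample_rate_hz != fs) {
      stop(errorCondition("all epoch sets must share montage and sample rate",
                          class = c("ersplearn_montage_mismatch", "error")))
    }
  }
  subjects <- vapply(esets, function(e) e$subject_id, 0)
  per_subj <- split(seq_along(esets), subjects)
  cols <- list(); scaling <- c(); block_ids <- character()
  for (sid in names(per_subj)) {
    mats <- lapply(per_subj[[sid]], function(i) {
      e <- retained(esets[[i]])
      ntr <- dim(e$data)[1]
      do.call(cbind, lapply(seq_len(ntr), function(tr) {
        x <- e$data[tr, , , drop = TRUE]
        x - rowMeans(x)                  # mean-center each trial per channel
      }))
    })
    block <- do.call(cbind, mats)
    v <- stats::var(as.numeric(block))
    sc <- if (v > 0) sqrt(v) else 1      # guard: zero block contributes as-is
    scaling[sid] <- sc
    cols[[sid]] <- block / sc
  }
  ord <- order(as.numeric(names(cols)))
  mat <- do.call(cbind, cols[ord])
  list(matrix = mat, scaling = scaling[ord], subjects = as.numeric(names(cols))[ord],
       montage = mont, sample_rate_hz = fs)
}

#' Fit extended-infomax ICA
#'
#' PCA pre-whitening (rank chosen by explained variance or given directly)
#' followed by extended-infomax with natural-gradient block updates and
#' kurtosis-sign switching for sub-Gaussian sources. Deterministic under a
#' fixed seed. Components are ordered by explained variance and scaled to
#' unit activation variance.
#'
#' @param mat Channels x time matrix (or the list from
#'   [prepare_group_matrix()]).
#' @param n_components Number of components; `NULL` picks the PCA rank
#'   explaining `var_explained` of the variance.
#' @param var_explained PCA variance fraction retained when `n_components`
#'   is `NULL` (default 0.999).
#' @param max_cols Columns are subsampled (seeded) to at most this many for
#'   weight estimation; the full data are still used for scaling/ordering.
#' @param max_iter,tol Stopping rule: weight-change norm below `tol` or
#'   `max_iter` passes.
#' @param seed Integer seed (column shuffling).
#' @return An `ica_result`: `unmixing` (components x channels), `mixing`
#'   (channels x components), `channel_names`, `subjects`, `scaling`,
#'   diagnostics (`converged`, `iterations`, `n_subgaussian`).
#' @export
fit_ica <- function(mat, n_components = NULL, var_explained = 0.999,
                    max_cols = 30000L, max_iter = 512L, tol = 1e-7, seed = 1L) {
  meta <- NULL
  if (is.list(mat)) { meta <- mat; mat <- mat$matrix }
  nch <- nrow(mat)
  ctr <- rowMeans(mat)
  Xc <- mat - ctr
  # PCA via the channel covariance (cheap for wide matrices)
  eg <- eigen(tcrossprod(Xc) / (ncol(Xc) - 1), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  if (is.null(n_components)) {
    n_components <- max(2L, which(cumsum(ev) / sum(ev) >= var_explained)[1])
  }
  k <- min(n_components, sum(ev > max(ev) * 1e-12))
  U <- eg$vectors[, seq_len(k), drop = FALSE]
  dscale <- sqrt(ev[seq_len(k)])
  wh <- sweep(t(U), 1, dscale, `/`)      # whitening: k x channels
  Z <- wh %*% Xc
  sub <- seq_len(ncol(Z))
  with_seed(seed_stream(seed, 77L), {
    sub <- sample(sub)
    if (length(sub) > max_cols) sub <- sub[seq_len(max_cols)]
  })
  Zs <- Z[, sub, drop = FALSE]
  fit <- infomax_core(Zs, max_iter = max_iter, tol = tol)
  W <- fit$W %*% wh                      # components x channels
  # unit activation variance on the full data; order by map norm (variance
  # explained per component)
  act <- W %*% Xc
  s <- apply(act, 1, stats::sd)
  s[s == 0] <- 1
  W <- W / s
  A <- MASS_ginv(W)                      # channels x components
  ord <- order(colSums(A^2), decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  A <- sweep(A, 2, colMeans(A))          # average-reference scalp maps
  rownames(W) <- colnames(A) <- paste0("IC", seq_len(nrow(W)))
  structure(list(unmixing = W, mixing = A,
                 channel_names = if (!is.null(meta)) meta$montage$channel_names else rownames(mat),
                 montage = if (!is.null(meta)) meta$montage else NULL,
                 subjects = if (!is.null(meta)) meta$subjects else NULL,
                 scaling = if (!is.null(meta)) meta$scaling else NULL,
                 center = ctr,
                 converged = fit$converged, iterations = fit$iterations,
                 n_subgaussian = fit$n_subgaussian, seed = seed),
            class = "ica_result")
}

# Moore-Penrose pseudoinverse via SVD (small matrices only)
MASS_ginv <- function(X, tol = 1e-10) {
  s <- svd(X)
  pos <- s$d > max(s$d) * tol
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Extended-infomax natural-gradient loop on whitened data (k x T).
infomax_core <- function(Z, max_iter = 512L, tol = 1e-7, lrate = NULL,
                         block = NULL, anneal = 0.95, max_angle = 60) {
  k <- nrow(Z); T_ <- ncol(Z)
  if (is.null(lrate)) lrate <- 0.00065 / log(k + 1)
  if (is.null(block)) block <- max(8L, floor(sqrt(T_ / 3)))
  W <- diag(k)
  I <- diag(k)
  oldW <- W
  olddelta <- NULL
  signs <- rep(1, k)                     # +1 supergaussian, -1 subgaussian
  converged <- FALSE
  it <- 0L
  kurt_cols <- seq_len(min(6000L, T_))
  for (it in seq_len(max_iter)) {
    # refresh kurtosis signs from current activations
    u_all <- W %*% Z[, kurt_cols, drop = FALSE]
    kt <- rowMeans(u_all^4) / rowMeans(u_all^2)^2 - 3
    signs <- ifelse(kt >= 0, 1, -1)
    K <- diag(signs, k)
    starts <- seq(1, T_ - block + 1, by = block)
    blowup <- FALSE
    for (st in starts) {
      u <- W %*% Z[, st:(st + block - 1), drop = FALSE]
      y <- tanh(u)
      # natural-gradient block update, runica step scaling
      dW <- (I * block - K %*% (y %*% t(u)) - u %*% t(u)) %*% W
      W <- W + lrate * dW
      if (!all(is.finite(W)) || max(abs(W)) > 1e8) {
        W <- diag(k); oldW <- W; olddelta <- NULL
        lrate <- lrate * 0.5
        blowup <- TRUE
        break
      }
    }
    if (blowup) next
    delta <- W - oldW
    change <- sqrt(sum(delta^2))
    if (!is.null(olddelta)) {
      dot <- sum(delta * olddelta)
      denom <- sqrt(sum(delta^2) * sum(olddelta^2))
      if (denom > 0 && acos(pmin(1, pmax(-1, dot / denom))) * 180 / pi > max_angle) {
        lrate <- lrate * anneal
      }
    }
    olddelta <- delta
    oldW <- W
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("extended-infomax did not reach the weight-change tolerance; ",
            "returning the final iterate", call. = FALSE)
  }
  list(W = W, converged = converged, iterations = it,
       n_subgaussian = sum(signs < 0))
}

#' Project a subject's epochs into the component space
#'
#' Activations are `unmixing %*% (subject-scaled channel data)`; works for
#' subjects that were not part of the ICA training set (held-out folds),
#' using the subject's own variance as the scale.
#'
#' @param ica An `ica_result`.
#' @param eset An `epoch_set`.
#' @return Array trials x components x samples.
#' @export
project_subject <- function(ica, eset) {
  if (!identical(ica$channel_names, eset$montage$channel_names)) {
    stop(errorCondition("epoch set channels do not match the ICA channels",
                        class = c("ersplearn_channel_mismatch", "error")))
  }
  e <- retained(eset)
  ntr <- dim(e$data)[1]
  sid <- as.character(e$subject_id)
  sc <- if (!is.null(ica$scaling) && sid %in% names(ica$scaling)) {
    ica$scaling[[sid]]
  } else {
    # held-out subject: self-scaling from its own mean-centered trials
    v <- 0; n <- 0
    for (tr in seq_len(ntr)) {
      x <- e$data[tr, , , drop = TRUE]
      x <- x - rowMeans(x)
      v <- v + sum(x^2); n <- n + length(x)
    }
    if (v > 0) sqrt(v / max(1, n - 1)) else 1
  }
  k <- nrow(ica$unmixing)
  out <- array(0, c(ntr, k, dim(e$data)[3]))
  for (tr in seq_len(ntr)) {
    x <- e$data[tr, , , drop = TRUE]
    x <- (x - rowMeans(x)) / sc
    out[tr, , ] <- ica$unmixing %*% x
  }
  out
}
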