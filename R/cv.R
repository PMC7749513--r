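# Nested fivefold cross-validation. Every estimation stage -- group ICA,
# dipole fitting and screening, the component-subset search, the RT window
# regression, feature scaling, and classifier training -- is refit inside
# each fold using only the training samples; held-out subject x condition
# samples are projected through the fold's ICA weights and self-normalized.
# A manifest records the sample lists entering each stage so leakage is
# auditable.

#' Pipeline configuration
#'
#' @param n_folds Number of CV folds.
#' @param pca_rank PCA rank before ICA (`NULL`: keep 99.9% variance).
#' @param rv_max Dipole residual-variance screen threshold.
#' @param grid_M,grid_lambda Tuning grid for hidden units and penalty.
#' @param restarts Random initializations per training run.
#' @param robustness_threshold CV-error level for the restart-robustness
#'   proportion (default 0.09).
#' @param select_components Run the greedy component-subset search (if
#'   `FALSE`, all screened components are used).
#' @param batch_sizes Forward-selection batch sizes.
#' @param inner_folds Folds of the inner CV used by the subset search.
#' @param M_select,lambda_select Network settings used during subset search;
#'   the heavy default penalty makes the held-out cross-entropy a smooth,
#'   low-variance selection statistic.
#' @param select_z,select_ce_z Move-acceptance thresholds of the search:
#'   the paired (McNemar-style) z-score a move's error improvement must
#'   reach, and the paired per-sample log-probability z that breaks error
#'   ties.
#' @param seed_locations Named list of locations whose nearest components
#'   are always kept in the subset (the a-priori seed components).
#' @param stratify Stratify folds by condition.
#' @param select_repeats Number of inner-CV fold partitions averaged per
#'   candidate score (reduces selection noise at proportional cost).
#' @param ica_max_cols Column cap for ICA weight estimation.
#' @param ica_max_iter Infomax pass cap.
#' @param maxit Classifier BFGS cap.
#' @param rt_adjust Apply the reaction-time window adjustment.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(n_folds = 5, pca_rank = NULL, rv_max = 0.15,
                            grid_M = c(2, 3, 4, 6),
                            grid_lambda = c(5e-4, 1e-3, 5e-3, 1e-2, 5e-2, 1e-1),
                            restarts = 1L, robustness_threshold = 0.09,
                            select_components = TRUE,
                            batch_sizes = c(3, 4, 5), inner_folds = 5L,
                            M_select = 2, lambda_select = 1,
                            select_z = 3.2, select_ce_z = 2.8,
                            select_repeats = 2L,
                            seed_locations = list(
                              right_thalamus = c(9, -14, 19),
                              left_preSMA = c(-1, -24, 62)),
                            stratify = TRUE,
                            ica_max_cols = 20000L, ica_max_iter = 512L,
                            maxit = 500L, rt_adjust = TRUE) {
  as.list(environment())
}

#' Partition samples into folds
#'
#' Random, roughly equal partition (sizes differ by at most one), by
#' default stratified by condition so each fold keeps the class balance.
#'
#' @param sample_names Character ids (`"<subject>.<condition>"`).
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @param stratify Stratify by the condition suffix.
#' @return Integer vector of fold assignments, named by sample.
#' @export
make_folds <- function(sample_names, n_folds = 5, seed = 1L, stratify = TRUE) {
  n <- length(sample_names)
  stopifnot(n >= 2 * n_folds)
  fold <- integer(n)
  names(fold) <- sample_names
  with_seed(seed_stream(seed, 5L), {
    if (stratify) {
      cond <- sub("^.*\\.", "", sample_names)
      for (cv in unique(cond)) {
        idx <- which(cond == cv)
        fold[idx[sample(length(idx))]] <- rep_len(sample(n_folds), length(idx))
      }
    } else {
      fold[sample(n)] <- rep_len(sample(n_folds), n)
    }
  })
  fold
}

# Fit the full estimation stream on the training samples of one fold and
# produce scaled features for both training and held-out samples.
fold_context <- function(esets, test_ids, config, seed) {
  train_ids <- setdiff(names(esets), test_ids)
  gm <- prepare_group_matrix(esets[train_ids])
  # non-convergence at the iteration cap is tolerated here (flagged on the
  # result); desk-scale runs use a reduced cap
  ica <- suppressWarnings(fit_ica(gm, n_components = config$pca_rank,
                                  max_cols = config$ica_max_cols,
                                  max_iter = config$ica_max_iter, seed = seed))
  catalog <- screen_components(fit_component_dipoles(ica), rv_max = config$rv_max)
  kept <- catalog$table$component[catalog$table$keep]
  fallback <- FALSE
  if (length(kept) < 2) {                # degenerate screen: keep best maps
    kept <- utils::head(order(catalog$table$rv), 4)
    fallback <- TRUE
  }
  seed_comps <- seed_components(catalog, kept, config$seed_locations)
  # ERSPs for every sample, kept components only
  ersps <- lapply(esets, function(e) {
    act <- project_subject(ica, e)[, kept, , drop = FALSE]
    compute_ersp(act, fs = e$sample_rate_hz, times = e$times)
  })
  # RT regression on training Go samples only
  shifts <- rep(0, length(esets)); names(shifts) <- names(esets)
  rt_fit <- NULL
  if (config$rt_adjust) {
    go_train <- train_ids[endsWith(train_ids, ".Go")]
    rts <- vapply(esets[go_train], function(e) mean(e$rts), 0)
    names(rts) <- go_train
    if (length(go_train) >= 3 && stats::sd(rts) > 1e-12) {
      rt_fit <- estimate_rt_adjustment(ersps[go_train], rts,
                                       components = match(seed_comps, kept))
      mean_rt <- mean(rts)
      for (nm in names(esets)) {
        sid <- sub("\\..*$", "", nm)
        go_nm <- paste0(sid, ".Go")
        rt_s <- if (!is.null(esets[[go_nm]]$rts)) mean(esets[[go_nm]]$rts) else mean_rt
        shifts[nm] <- clamp_shift(rt_fit$slope * (rt_s - mean_rt))
      }
    }
  }
  blocks <- lapply(names(esets), function(nm) bandtime_reduce(ersps[[nm]],
                                                              shift_s = shifts[nm]))
  names(blocks) <- names(esets)
  # scale training subjects and held-out subjects separately (self-scaling)
  fvs <- c(scale_features(blocks[train_ids]),
           if (length(test_ids)) scale_features(blocks[test_ids]))
  fvs <- fvs[names(esets)]
  list(ica = ica, catalog = catalog, kept = kept, seed_comps = seed_comps,
       features = fvs, blocks = blocks, ersps = ersps,
       train_ids = train_ids, test_ids = test_ids, rt_fit = rt_fit,
       shifts = shifts, fallback_screen = fallback, seed = seed)
}

# components (by kept id) nearest to the configured seed locations
seed_components <- function(catalog, kept, seed_locations, max_dist_mm = 25) {
  df <- catalog$table[catalog$table$component %in% kept, , drop = FALSE]
  out <- integer(0)
  for (loc in seed_locations) {
    d <- sqrt((df$x - loc[1])^2 + (df$y - loc[2])^2 + (df$z - loc[3])^2)
    d[!is.finite(d)] <- Inf
    j <- which.min(d)
    if (length(j) == 1 && d[j] <= max_dist_mm) out <- c(out, df$component[j])
  }
  out <- unique(out)
  if (length(out) == 0) out <- df$component[utils::head(order(df$rv), 2)]
  out
}

feature_cols <- function(index_map, comps) {
  which(index_map$component %in% comps)
}

# Inner CV over the training samples: misclassification rate plus the
# held-out cross-entropy per sample. Error is the selection criterion; the
# cross-entropy resolves ties that the quantized error cannot.
inner_cv_error <- function(X, y, comps, index_map, config, seed) {
  cols <- feature_cols(index_map, comps)
  n <- nrow(X)
  k <- min(config$inner_folds, n)
  reps <- config$select_repeats %||% 1L
  wrong <- rep(0, n)
  lp <- rep(0, n)
  names(wrong) <- names(lp) <- rownames(X)
  for (r in seq_len(reps)) {
    fold <- make_folds(rownames(X), n_folds = k,
                       seed = seed_stream(seed, 31L, r),
                       stratify = config$stratify)
    w1 <- rep(NA, n); lp1 <- rep(NA_real_, n)
    for (f in seq_len(k)) {
      te <- fold == f
      if (!any(te) || length(unique(y[!te])) < 2) next
      m <- nn_train(X[!te, cols, drop = FALSE], y[!te], M = config$M_select,
                    lambda = config$lambda_select,
                    seed = seed_stream(seed, 32L, f, r), restarts = 1L,
                    maxit = min(config$maxit, 150L))
      pr <- nn_forward(m, X[te, cols, drop = FALSE])
      w1[te] <- pr$chat != y[te]
      # capped probabilities keep one overconfident miss from dominating
      pcorr <- pmin(1 - 1e-3, pmax(1e-3, ifelse(y[te] == "NoGo", pr$f_nogo,
                                                pr$f_go)))
      lp1[te] <- log(pcorr)
    }
    w1[is.na(w1)] <- FALSE
    lp1[is.na(lp1)] <- log(0.5)
    wrong <- wrong + w1 / reps
    lp <- lp + lp1 / reps
  }
  list(err = mean(wrong), ce = -mean(lp), wrong = wrong, lp = lp)
}

# paired z-scores between two inner-CV evaluations (same samples, same folds)
sel_err_z <- function(new, cur) {
  d <- cur$wrong - new$wrong           # per-sample error reduction (0..1)
  b <- sum(pmax(d, 0))                 # errors fixed by the move
  cc <- sum(pmax(-d, 0))               # errors introduced
  if (b + cc < 1e-12) return(0)
  (b - cc) / sqrt(b + cc)
}
sel_ce_z <- function(new, cur) {
  d <- new$lp - cur$lp                 # per-sample log-probability gain
  se <- stats::sd(d) / sqrt(length(d))
  if (se < 1e-12) return(0)
  mean(d) / se
}

# Move-acceptance comparators. Inner-CV error estimates on a few dozen
# samples are noisy, so a move is accepted only when it flips significantly
# more errors than it introduces (paired McNemar-style z on the discordant
# samples); with identical predictions the held-out cross-entropy breaks
# the tie, again with a relative margin. Removals are kept whenever they do
# not significantly worsen the fit (ties break toward smaller subsets).
sel_better_add <- function(new, cur, z = 3.2, z_ce = 2.8) {
  if (sel_err_z(new, cur) >= z) return(TRUE)
  sel_err_z(new, cur) > -1.28 && sel_ce_z(new, cur) >= z_ce
}
sel_ok_drop <- function(new, cur, z = 1.28, z_ce = 1.64) {
  sel_err_z(new, cur) > -z && sel_ce_z(new, cur) > -z_ce
}

#' Greedy component-subset search
#'
#' Forward selection in batches of 3-5 components (best batch by inner CV
#' error), then backward elimination of 1-2, iterated until no single add
#' or remove lowers the inner CV error; ties break toward smaller subsets.
#' The seed components are always retained.
#'
#' @param X,y Training feature matrix and labels.
#' @param index_map Feature index map (j -> component, band, bin).
#' @param candidates Component ids available (the screened set).
#' @param seeds Component ids fixed a priori.
#' @param config A [pipeline_config()].
#' @param seed Integer seed for the inner folds and fits.
#' @return List with `subset` (component ids) and `trace` (data frame).
#' @export
select_component_subset <- function(X, y, index_map, candidates, seeds,
                                    config = pipeline_config(), seed = 1L) {
  seeds <- intersect(seeds, candidates)
  current <- seeds
  if (length(current) == 0) current <- candidates[1]
  z_add <- config$select_z %||% 3.2
  z_ce <- config$select_ce_z %||% 2.8
  better_add <- function(new, cur) sel_better_add(new, cur, z_add, z_ce)
  ok_drop <- function(new, cur) sel_ok_drop(new, cur)
  score <- function(comps) inner_cv_error(X, y, comps, index_map, config, seed)
  cur <- score(current)
  log_step <- function(trace, step) {
    rbind(trace, data.frame(step = step,
                            subset = paste(sort(current), collapse = ","),
                            error = cur$err, ce = cur$ce))
  }
  trace <- log_step(NULL, "init")
  improved <- TRUE
  round <- 0L
  while (improved && round < 10L) {
    round <- round + 1L
    improved <- FALSE
    pool <- setdiff(candidates, current)
    # forward: best accepted batch (sizes from config, capped by the pool)
    sizes <- config$batch_sizes[config$batch_sizes <= length(pool)]
    if (length(pool) > 0 && length(sizes) == 0) sizes <- length(pool)
    best_add <- NULL
    for (s in sizes) {
      for (cb in utils::combn(pool, s, simplify = FALSE)) {
        e <- score(c(current, cb))
        if (better_add(e, cur) &&
            (is.null(best_add) ||
             e$err + 1e-3 * e$ce < best_add$e$err + 1e-3 * best_add$e$ce)) {
          best_add <- list(cb = cb, e = e)
        }
      }
    }
    if (!is.null(best_add)) {
      current <- c(current, best_add$cb); cur <- best_add$e; improved <- TRUE
      trace <- log_step(trace, "add")
    }
    # backward: drop 1-2 non-seed components while the fit does not degrade
    for (dropn in 1:2) {
      droppable <- setdiff(current, seeds)
      if (length(droppable) == 0) break
      scores <- lapply(droppable, function(cmp) score(setdiff(current, cmp)))
      ok <- vapply(scores, function(e) ok_drop(e, cur), TRUE)
      if (!any(ok)) break
      j <- which(ok)[which.min(vapply(scores[ok], function(e) e$err + 1e-3 * e$ce, 0))]
      current <- setdiff(current, droppable[j]); cur <- scores[[j]]
      improved <- TRUE
      trace <- log_step(trace, "drop")
    }
  }
  # 1-swap polish: no remaining single add (or seed-free drop) is accepted;
  # visited subsets are never revisited, which also rules out cycles
  seen <- paste(sort(current), collapse = ",")
  moves <- 0L
  repeat {
    moves <- moves + 1L
    if (moves > 20L) break
    pool <- setdiff(candidates, current)
    moved <- FALSE
    for (cmp in pool) {
      key <- paste(sort(c(current, cmp)), collapse = ",")
      if (key %in% seen) next
      e <- score(c(current, cmp))
      if (better_add(e, cur)) {
        current <- c(current, cmp); cur <- e; moved <- TRUE
        seen <- c(seen, key)
        trace <- log_step(trace, "swap_add")
        break
      }
    }
    if (!moved) {
      for (cmp in setdiff(current, seeds)) {
        key <- paste(sort(setdiff(current, cmp)), collapse = ",")
        if (key %in% seen) next
        e <- score(setdiff(current, cmp))
        if (e$err < cur$err - 1e-12) {
          current <- setdiff(current, cmp); cur <- e; moved <- TRUE
          seen <- c(seen, key)
          trace <- log_step(trace, "swap_drop")
          break
        }
      }
    }
    if (!moved) break
  }
  list(subset = sort(current), error = cur$err, ce = cur$ce, trace = trace)
}

#' Run the nested cross-validation
#'
#' @param esets Named list of preprocessed epoch sets
#'   (`"<subject>.<condition>"`).
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @return A `cv_result`: `metrics` (a `cv_metrics`), `predictions` (pooled
#'   held-out data frame), `grid` (per grid point restart error
#'   distributions), `winner`, `robustness`, `fold_subsets`, `manifest`.
#' @export
run_cv <- function(esets, config = pipeline_config(), seed = 1L) {
  samples <- names(esets)
  fold <- make_folds(samples, n_folds = config$n_folds, seed = seed,
                     stratify = config$stratify)
  contexts <- list()
  manifest <- list(seed = seed, folds = fold, stages = list())
  for (k in seq_len(config$n_folds)) {
    test_ids <- samples[fold == k]
    ctx <- fold_context(esets, test_ids, config, seed = seed_stream(seed, 40L, k))
    contexts[[k]] <- ctx
    manifest$stages[[k]] <- list(
      fold = k, test = test_ids,
      ica_training = ctx$train_ids,
      dipole_fitting = ctx$train_ids,
      rt_regression = ctx$train_ids[endsWith(ctx$train_ids, ".Go")],
      subset_search = ctx$train_ids,
      classifier_training = ctx$train_ids,
      scaling_cohorts = list(train = ctx$train_ids, test = ctx$test_ids))
  }
  # per-fold subset search (nested; uses training features only)
  fold_subsets <- vector("list", config$n_folds)
  for (k in seq_len(config$n_folds)) {
    ctx <- contexts[[k]]
    fm <- feature_matrix(ctx$features[ctx$train_ids])
    fold_subsets[[k]] <- if (config$select_components) {
      select_component_subset(fm$X, fm$y, fm$index_map,
                              candidates = seq_along(ctx$kept),
                              seeds = match(ctx$seed_comps, ctx$kept),
                              config = config,
                              seed = seed_stream(seed, 41L, k))$subset
    } else seq_along(ctx$kept)
  }
  tuned <- tune_and_evaluate(contexts, fold_subsets, esets, fold, config, seed)
  tuned$manifest <- manifest
  tuned$fold_subsets <- fold_subsets
  tuned$contexts <- contexts
  tuned$fold <- fold
  class(tuned) <- "cv_result"
  tuned
}

#' Tune (M, lambda) over the grid and evaluate the winner
#'
#' For each grid point the pooled CV error is computed once per restart
#' seed (restarting the per-fold training); the winner minimizes the median
#' error over restarts, with ties broken by the restart-robustness
#' proportion (fraction of restarts with error above the robustness
#' threshold) and then by smaller M. Returns the pooled metrics at the
#' winner's median restart together with the per-grid-point error
#' distributions.
#'
#' @param contexts Per-fold contexts from the fold pipeline.
#' @param fold_subsets Per-fold component subsets (indices into the fold's
#'   kept components).
#' @param esets,fold Sample list and fold assignment.
#' @param config A [pipeline_config()].
#' @param seed Master seed.
#' @return List with `grid`, `winner`, `metrics`, `predictions`,
#'   `robustness`.
#' @export
tune_and_evaluate <- function(contexts, fold_subsets, esets, fold, config, seed) {
  samples <- names(esets)
  truth <- factor(sub("^.*\\.", "", samples), levels = c("Go", "NoGo"))
  names(truth) <- samples
  grid <- expand.grid(M = config$grid_M, lambda = config$grid_lambda)
  n_restart <- config$restarts
  # errors[g, r]; predictions stored per grid point and restart
  errs <- matrix(NA_real_, nrow(grid), n_restart)
  preds <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    preds[[g]] <- vector("list", n_restart)
    for (r in seq_len(n_restart)) {
      scores <- setNames(rep(NA_real_, length(samples)), samples)
      chat <- setNames(rep(NA_character_, length(samples)), samples)
      for (k in seq_along(contexts)) {
        ctx <- contexts[[k]]
        fm <- feature_matrix(ctx$features)
        cols <- feature_cols(fm$index_map, fold_subsets[[k]])
        tr <- ctx$train_ids; te <- ctx$test_ids
        if (length(te) == 0) next
        m <- nn_train(fm$X[tr, cols, drop = FALSE], truth[tr],
                      M = grid$M[g], lambda = grid$lambda[g],
                      seed = seed_stream(seed, 50L, k, g, r), restarts = 1L,
                      maxit = config$maxit)
        pr <- nn_forward(m, fm$X[te, cols, drop = FALSE])
        scores[te] <- pr$f_nogo
        chat[te] <- as.character(pr$chat)
      }
      errs[g, r] <- mean(chat != as.character(truth), na.rm = TRUE)
      preds[[g]][[r]] <- data.frame(sample = samples, fold = fold[samples],
                                    truth = truth,
                                    chat = factor(chat, levels = c("Go", "NoGo")),
                                    f_nogo = scores)
    }
  }
  med <- apply(errs, 1, stats::median)
  robust <- rowMeans(errs > config$robustness_threshold)
  ordering <- order(med, robust, grid$M)
  win <- ordering[1]
  # restart whose error attains the median at the winner
  r_med <- which.min(abs(errs[win, ] - med[win]))
  pw <- preds[[win]][[r_med]]
  metrics <- compute_metrics(pw$chat, pw$truth, pw$f_nogo)
  grid_out <- cbind(grid, median_error = med, robustness_prop = robust)
  robustness <- data.frame(
    lambda = grid$lambda[grid$M == grid$M[win]],
    M = grid$M[win],
    median_error = med[grid$M == grid$M[win]],
    prop_above = robust[grid$M == grid$M[win]])
  list(grid = grid_out, errors = errs, winner = list(
         M = grid$M[win], lambda = grid$lambda[win],
         median_error = med[win], restart = r_med),
       metrics = metrics, predictions = pw, robustness = robustness)
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> winner M = %d, lambda = %g; ", x$winner$M,
              x$winner$lambda))
  print(x$metrics)
  invisible(x)
}

#' Audit a CV manifest for leakage
#'
#' Checks that no held-out sample of a fold appears in any of that fold's
#' estimation-stage sample lists.
#'
#' @param manifest The `manifest` element of a `cv_result`.
#' @return TRUE (invisibly) if clean; otherwise stops with the offending
#'   stage.
#' @export
audit_manifest <- function(manifest) {
  for (st in manifest$stages) {
    for (stage in c("ica_training", "dipole_fitting", "rt_regression",
                    "subset_search", "classifier_training")) {
      bad <- intersect(st$test, st[[stage]])
      if (length(bad)) {
        stop(sprintf("leakage: fold %d stage %s contains held-out samples %s",
                     st$fold, stage, paste(bad, collapse = ", ")), call. = FALSE)
      }
    }
    bad <- intersect(st$test, st$scaling_cohorts$train)
    if (length(bad)) stop("leakage: held-out sample in training scaling cohort",
                          call. = FALSE)
  }
  invisible(TRUE)
}
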