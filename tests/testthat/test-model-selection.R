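# Fold construction, metrics, subset search, grid tuning.

test_that("folds are roughly equal, stratified, and reproducible", {
  samp <- c(paste0(1:57, ".Go"), paste0(1:57, ".NoGo"))
  f <- make_folds(samp, 5, seed = 1)
  expect_equal(as.integer(sort(table(f))), c(22L, 23L, 23L, 23L, 23L))
  # stratification keeps near class balance per fold
  cond <- sub("^.*\\.", "", samp)
  bal <- table(f, cond)
  expect_true(all(abs(bal[, "Go"] - bal[, "NoGo"]) <= 1))
  expect_identical(f, make_folds(samp, 5, seed = 1))
  f10 <- make_folds(sprintf("%d.Go", 1:10), 5, seed = 2, stratify = FALSE)
  expect_true(all(table(f10) == 2))
})

test_that("metrics reproduce hand-computed values from a fixed confusion matrix", {
  # counts for a 114-sample pooled CV with proportions (.473, .052, .026, .447)
  counts <- matrix(c(54, 3, 6, 51), 2,
                   dimnames = list(pred = c("Go", "NoGo"),
                                   true = c("Go", "NoGo")))
  m <- compute_metrics(counts)
  expect_equal(round(m$error, 3), 0.079)
  expect_equal(round(m$accuracy, 3), 0.921)
  expect_equal(round(m$se, 3), 0.025)
  expect_equal(round(unname(m$go["precision"]), 3), 0.900)
  expect_equal(round(unname(m$go["recall"]), 3), 0.947)
  expect_equal(round(unname(m$go["f"]), 3), 0.923)
  expect_equal(round(unname(m$nogo["precision"]), 3), 0.944)
  expect_equal(round(unname(m$nogo["recall"]), 3), 0.895)
  expect_equal(round(unname(m$nogo["f"]), 3), 0.919)
  expect_equal(sum(m$confusion), 1, tolerance = 1e-12)
})

test_that("metrics handle perfect, random, and degenerate predictions", {
  y <- factor(rep(c("Go", "NoGo"), 57), levels = c("Go", "NoGo"))
  sc <- ifelse(y == "NoGo", 0.9, 0.1)
  m <- compute_metrics(y, y, sc)
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  expect_equal(unname(diag(m$confusion)), c(0.5, 0.5))
  set.seed(11)
  yr <- factor(sample(c("Go", "NoGo"), 400, TRUE), levels = c("Go", "NoGo"))
  mr <- compute_metrics(yr, y[rep(1:114, length.out = 400)], runif(400))
  expect_lt(abs(mr$auc - 0.5), 0.1)
  expect_error(compute_metrics(y, factor(rep("Go", 114),
                                         levels = c("Go", "NoGo")), sc),
               class = "ersplearn_single_class")
})

test_that("pooled CV error equals the fold-size-weighted mean of fold errors", {
  run <- tiny_cv_run()
  pr <- run$cv$predictions
  pooled <- mean(pr$chat != pr$truth)
  per_fold <- tapply(pr$chat != pr$truth, pr$fold, mean)
  sizes <- table(pr$fold)
  expect_equal(pooled, sum(per_fold * sizes) / sum(sizes), tolerance = 1e-12)
  expect_equal(unname(run$cv$metrics$error), pooled, tolerance = 1e-12)
})

# synthetic feature cohort: `signal` components carry a condition contrast on
# a few of their cells, the rest are noise
make_feature_cohort <- function(n_subj, comps, signal, delta, seed, ncell = 3) {
  set.seed(seed)
  fvs <- list()
  for (s in seq_len(n_subj)) {
    for (cond in c("Go", "NoGo")) {
      z <- matrix(rnorm(comps * 40, 0, 1), comps,
                  dimnames = list(paste0("IC", seq_len(comps)), NULL))
      if (cond == "NoGo") {
        for (cmp in signal) {
          cells <- (cmp %% 5) * 3 + seq_len(ncell)
          z[cmp, cells] <- z[cmp, cells] + delta
        }
      }
      fvs[[paste0(s, ".", cond)]] <- ersplearn:::feature_vector(z, as.character(s), cond)
    }
  }
  fvs
}

test_that("the greedy subset search recovers planted signal components", {
  cfg <- pipeline_config(inner_folds = 3, M_select = 2, batch_sizes = c(2, 3),
                         maxit = 200, select_repeats = 3)
  hits <- 0
  for (r in 1:10) {
    fvs <- make_feature_cohort(40, comps = 8, signal = 1:6, delta = 2.5,
                               seed = 100 + r, ncell = 6)
    fm <- feature_matrix(fvs)
    sel <- select_component_subset(fm$X, fm$y, fm$index_map,
                                   candidates = 1:8, seeds = c(1, 2),
                                   config = cfg, seed = r)
    if (setequal(sel$subset, 1:6)) hits <- hits + 1
  }
  expect_gte(hits, 8)   # >= 80% of seeded runs
})

test_that("with all-noise candidates the subset collapses to the seeds", {
  cfg <- pipeline_config(inner_folds = 3, M_select = 2, batch_sizes = c(2, 3),
                         maxit = 200, select_repeats = 3)
  fvs <- make_feature_cohort(16, comps = 6, signal = integer(0), delta = 0,
                             seed = 55)
  fm <- feature_matrix(fvs)
  sel <- select_component_subset(fm$X, fm$y, fm$index_map, candidates = 1:6,
                                 seeds = c(1, 5), config = cfg, seed = 9)
  expect_setequal(sel$subset, c(1, 5))
  # local optimality: no single addition is accepted post hoc
  score <- function(comps) ersplearn:::inner_cv_error(fm$X, fm$y, comps,
                                                      fm$index_map, cfg, 9)
  base <- score(sel$subset)
  for (add in setdiff(1:6, sel$subset)) {
    expect_false(ersplearn:::sel_better_add(score(c(sel$subset, add)), base))
  }
})

test_that("grid tuning collapses to prevalence at huge penalties", {
  fvs <- make_feature_cohort(16, comps = 3, signal = 1:3, delta = 1.2,
                             seed = 77)
  esets_names <- names(fvs)
  fold <- make_folds(esets_names, 4, seed = 3)
  ctxs <- lapply(1:4, function(k) {
    list(features = fvs, train_ids = esets_names[fold != k],
         test_ids = esets_names[fold == k])
  })
  cfg <- pipeline_config(grid_M = 2, grid_lambda = c(0.005, 1e4),
                         restarts = 4, maxit = 200)
  esets_stub <- setNames(vector("list", length(fvs)), esets_names)
  tn <- tune_and_evaluate(ctxs, rep(list(1:3), 4), esets_stub, fold, cfg,
                          seed = 5)
  big <- which(tn$grid$lambda == 1e4)
  expect_true(all(abs(tn$errors[big, ] - 0.5) <= 0.1))
  expect_lt(stats::sd(tn$errors[big, ]), 0.05)     # degenerate distribution
  expect_equal(tn$winner$lambda, 0.005)            # signal wins the grid
  expect_true(all(tn$grid$robustness_prop >= 0 & tn$grid$robustness_prop <= 1))
})
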