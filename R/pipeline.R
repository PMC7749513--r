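# End-to-end orchestration: simulate (or load) -> preprocess -> nested CV ->
# final full-data fit -> signatures -> report, with a run manifest tying
# every random draw to named seeds.

#' Read a pipeline configuration from a YAML file
#'
#' Fields under `pipeline:` override [pipeline_config()] defaults; fields
#' under `simulation:` override [sim_config()] defaults. Unknown fields are
#' rejected so typos fail fast.
#'
#' @param path Path to a YAML file.
#' @return List with `pipeline` (a `pipeline_config`) and `simulation`
#'   (argument list for [sim_config()]).
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pc <- y$pipeline %||% list()
  bad <- setdiff(names(pc), names(formals(pipeline_config)))
  if (length(bad)) stop("unknown pipeline config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  sc <- y$simulation %||% list()
  bad <- setdiff(names(sc), names(formals(sim_config)))
  if (length(bad)) stop("unknown simulation config fields: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  list(pipeline = do.call(pipeline_config, pc), simulation = sc)
}

#' Run the full pipeline on a simulated scenario
#'
#' @param scenario List with `cfg` and `truth` (e.g. [scaled_scenario()]);
#'   alternatively pass `esets` directly.
#' @param config A [pipeline_config()].
#' @param esets Optional pre-made named list of epoch sets (skips
#'   simulation).
#' @param boot_B Bootstrap replicates for the signature stage.
#' @param seed Master seed.
#' @param stages Last stage to run: `"cv"` stops after cross-validation,
#'   `"signatures"` (default) runs everything.
#' @return A `pipeline_result`: `cv` (a `cv_result`), `final` (model and
#'   full-data context), `signatures`, `summary`, `manifest`.
#' @export
run_pipeline <- function(scenario = NULL, config = pipeline_config(),
                         esets = NULL, boot_B = 5000L, seed = 1L,
                         stages = c("signatures", "cv")) {
  stages <- match.arg(stages)
  manifest <- list(seed = seed, created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                   config = config[setdiff(names(config), "seed_locations")])
  if (is.null(esets)) {
    if (is.null(scenario) || scenario$cfg$n_subjects < 1) {
      stop("a scenario with at least one subject (or esets) is required",
           call. = FALSE)
    }
    manifest$sim_seed <- scenario$cfg$seed
    esets <- simulate_cohort(scenario$cfg, scenario$truth)
  }
  esets <- lapply(esets, preprocess_epochs)
  cv <- run_cv(esets, config = config, seed = seed)
  manifest$cv <- cv$manifest
  out <- list(cv = cv, manifest = manifest, scenario = scenario)
  if (stages == "cv") return(structure(out, class = "pipeline_result"))

  # final full-data fit at the CV winner
  ctx <- fold_context(esets, character(0), config, seed = seed_stream(seed, 90L))
  fm <- feature_matrix(ctx$features)
  subset <- if (config$select_components) {
    select_component_subset(fm$X, fm$y, fm$index_map,
                            candidates = seq_along(ctx$kept),
                            seeds = match(ctx$seed_comps, ctx$kept),
                            config = config, seed = seed_stream(seed, 91L))$subset
  } else seq_along(ctx$kept)
  cols <- feature_cols(fm$index_map, subset)
  model <- nn_train(fm$X[, cols, drop = FALSE], fm$y, M = cv$winner$M,
                    lambda = cv$winner$lambda, seed = seed_stream(seed, 92L),
                    restarts = config$restarts, maxit = config$maxit,
                    index_map = fm$index_map[cols, ])
  fvs_sub <- lapply(ctx$features, function(fv) {
    fv$x <- fv$x[cols]; fv$p <- length(cols)
    fv$index_map <- remap_components(fm$index_map[cols, ])
    fv
  })
  manifest$final <- list(subset = ctx$kept[subset],
                         training = names(esets))
  if (!is.null(scenario)) {
    ctx$catalog <- label_components(
      ctx$catalog,
      stats::setNames(lapply(scenario$truth$sources, `[[`, "location"),
                      vapply(scenario$truth$sources, `[[`, "", "label")))
  }
  canonical <- build_canonical(model, fvs_sub)
  profiles <- bootstrap_significance(model, fvs_sub, canonical, B = boot_B,
                                     seed = seed_stream(seed, 93L))
  comp_labels <- ctx$catalog$table$label[match(ctx$kept[subset],
                                               ctx$catalog$table$component)]
  canonical_blocks <- canonical_db_blocks(ctx$blocks, canonical, subset)
  summary <- summarize_signatures(profiles, canonical_blocks, comp_labels)
  out$final <- list(model = model, context = ctx, subset = subset,
                    comp_labels = comp_labels, features = fvs_sub)
  out$canonical <- canonical
  out$signatures <- profiles
  out$summary <- summary
  out$manifest <- manifest
  structure(out, class = "pipeline_result")
}

# renumber components 1..k inside a subset index map
remap_components <- function(im) {
  im$component <- match(im$component, sort(unique(im$component)))
  im
}

# per-condition mean raw dB band x time blocks over qualifying subjects
canonical_db_blocks <- function(blocks, canonical, subset) {
  out <- list()
  for (cond in c("Go", "NoGo")) {
    nms <- paste0(canonical$qualifying, ".", cond)
    nms <- intersect(nms, names(blocks))
    acc <- Reduce(`+`, lapply(blocks[nms], function(b) b[subset, , drop = FALSE]))
    out[[cond]] <- acc / length(nms)
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n  ")
  print(x$cv$metrics)
  if (!is.null(x$summary)) {
    cat(sprintf("  signature summary: %d rows over %d components\n",
                nrow(x$summary), length(x$final$comp_labels)))
  }
  invisible(x)
}

#' Render a plain-text report of a pipeline run
#'
#' Sections: dipole table, confusion matrix, accuracy metrics, ROC/AUC,
#' robustness distribution, signature summary. Metric values are re-derived
#' from the pooled predictions, not cached. Missing artifacts produce an
#' "absent" note rather than an error.
#'
#' @param result A `pipeline_result`.
#' @return Character vector of report lines (markdown-ish).
#' @export
render_report <- function(result) {
  out <- c("# Pipeline report", "")
  sec <- function(title, body) c(paste("##", title), "", body, "")
  cat_tbl <- function(df) utils::capture.output(print(df, row.names = FALSE))
  if (!is.null(result$final$context$catalog)) {
    tb <- result$final$context$catalog$table
    tb$rv <- round(tb$rv, 4)
    out <- c(out, sec("Equivalent-dipole catalog", cat_tbl(tb)))
  } else out <- c(out, sec("Equivalent-dipole catalog", "(absent)"))
  if (!is.null(result$cv)) {
    pr <- result$cv$predictions
    m <- compute_metrics(pr$chat, pr$truth, pr$f_nogo)
    out <- c(out, sec("Confusion matrix (proportions of total)",
                      cat_tbl(as.data.frame(round(m$confusion, 3)))))
    met <- data.frame(class = c("Go", "NoGo"),
                      precision = round(c(m$go["precision"], m$nogo["precision"]), 3),
                      recall = round(c(m$go["recall"], m$nogo["recall"]), 3),
                      f = round(c(m$go["f"], m$nogo["f"]), 3))
    out <- c(out, sec("Accuracy metrics", c(
      sprintf("error = %.3f, accuracy = %.3f (se %.3f)", m$error, m$accuracy, m$se),
      cat_tbl(met))))
    out <- c(out, sec("ROC", sprintf("AUC = %.3f (%d pooled held-out scores)",
                                     m$auc, m$n)))
    out <- c(out, sec("Restart robustness",
                      cat_tbl(result$cv$robustness)))
  } else {
    out <- c(out, sec("Cross-validation", "(absent)"))
  }
  if (!is.null(result$summary) && nrow(result$summary) > 0) {
    out <- c(out, sec("Signature summary", cat_tbl(result$summary)))
  } else {
    out <- c(out, sec("Signature summary", "(absent)"))
  }
  out
}

#' Hash the deterministic artifacts of a run (reproducibility check)
#'
#' @param result A `pipeline_result`.
#' @return Named md5 character vector.
#' @export
result_hashes <- function(result) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  h <- function(obj) {
    writeLines(paste(utils::capture.output(print(obj, digits = 12)),
                     collapse = "\n"), tmp)
    unname(tools::md5sum(tmp))
  }
  c(predictions = h(result$cv$predictions),
    grid = h(result$cv$grid),
    summary = if (!is.null(result$summary)) h(result$summary) else NA_character_)
}
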