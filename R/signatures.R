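# Hidden-unit signatures: interpretation of the trained network.
#
# A "canonical" input X* per condition averages the feature vectors of
# subjects that are confidently and correctly classified in both of their
# conditions (winning/losing probability ratio >= 3). Each hidden unit m
# yields a classifier-filtered profile s_jm = alpha_jm * X*_j; peaks whose
# bootstrap interval (over qualifying subjects) excludes zero at the
# Bonferroni-adjusted level are significant, and the sign of the underlying
# band x time ERSP value -- not the sign of s -- gives the direction.

#' Build the canonical inputs
#'
#' @param model Trained `nn_model` (fit on the full data).
#' @param fvs Named list of `feature_vector`s (`"<subject>.<condition>"`).
#' @param threshold Qualification ratio (default 3): a subject qualifies iff
#'   both of its conditions are correctly predicted with
#'   `max(f)/min(f) >= threshold`.
#' @return A `canonical_input`: per-condition mean vectors `x_go`, `x_nogo`,
#'   `qualifying` subject ids, `fraction` qualifying.
#' @export
build_canonical <- function(model, fvs, threshold = 3) {
  fm <- feature_matrix(fvs)
  pr <- nn_forward(model, fm$X)
  ok <- pr$chat == fm$y & pr$margin_ratio >= threshold
  subj <- fm$subjects
  qual <- intersect(subj[ok & fm$y == "Go"], subj[ok & fm$y == "NoGo"])
  if (length(qual) == 0) {
    stop(errorCondition("no subject satisfies the qualification criterion",
                        class = c("ersplearn_no_qualifying", "error")))
  }
  sel_go <- subj %in% qual & fm$y == "Go"
  sel_nogo <- subj %in% qual & fm$y == "NoGo"
  structure(list(
    x_go = colMeans(fm$X[sel_go, , drop = FALSE]),
    x_nogo = colMeans(fm$X[sel_nogo, , drop = FALSE]),
    qualifying = qual,
    fraction = length(qual) / length(unique(subj)),
    threshold = threshold, index_map = fm$index_map),
    class = "canonical_input")
}

#' Attribute each hidden unit to a condition
#'
#' A unit's resting activation is its response to the neutral input x = 0
#' (features are per-subject z-scores, so 0 is the subject average). The
#' unit's contribution to the output logit, `|beta_m|`-weighted, is how far
#' its activation moves from rest on each condition's canonical input; the
#' unit is attributed to a condition when at least `solely` (default 90%)
#' of its total movement is driven by that condition's canonical, else
#' "mixed".
#'
#' @param model An `nn_model`.
#' @param canonical A `canonical_input`.
#' @param solely Dominance fraction operationalizing "solely due to".
#' @return Data frame: unit, contribution_go, contribution_nogo, attribution.
#' @export
unit_attribution <- function(model, canonical, solely = 0.9) {
  z_go <- as.numeric(hidden_activations(model, canonical$x_go))
  z_nogo <- as.numeric(hidden_activations(model, canonical$x_nogo))
  z_rest <- as.numeric(hidden_activations(model, rep(0, model$p)))
  b <- abs(model$beta[-1])
  contrib_go <- b * abs(z_go - z_rest)
  contrib_nogo <- b * abs(z_nogo - z_rest)
  tot <- contrib_go + contrib_nogo
  attribution <- ifelse(tot < 1e-12, "mixed",
                 ifelse(contrib_nogo / pmax(tot, 1e-300) >= solely, "NoGo",
                 ifelse(contrib_go / pmax(tot, 1e-300) >= solely, "Go", "mixed")))
  data.frame(unit = seq_len(model$M), contribution_go = contrib_go,
             contribution_nogo = contrib_nogo, attribution = attribution,
             stringsAsFactors = FALSE)
}

#' Bootstrap significance of the classifier-filtered profiles
#'
#' Resamples the qualifying subjects with replacement `B` times, recomputes
#' the mean signature `s_jm = alpha_jm * mean_j(X)` per unit each time, and
#' flags feature j for unit m when the two-sided percentile interval at the
#' Bonferroni single-test level `alpha / (2p)` excludes zero. The model is
#' not refit inside replicates: alpha is fixed, the subject means are
#' resampled.
#'
#' @param model An `nn_model`.
#' @param fvs Feature vectors of the full cohort.
#' @param canonical A `canonical_input` (defines qualifying subjects and the
#'   per-unit condition attribution via [unit_attribution()]).
#' @param B Bootstrap replicates (default 50000).
#' @param alpha Familywise level (default 0.05).
#' @param seed Integer seed.
#' @return A `signature_profiles` list: per unit, the profile `s`, the
#'   significance mask, interval bounds, and the attributed condition.
#' @export
bootstrap_significance <- function(model, fvs, canonical, B = 50000L,
                                   alpha = 0.05, seed = 1L) {
  stopifnot(B >= 1000, length(canonical$qualifying) >= 5)
  fm <- feature_matrix(fvs)
  attr_df <- unit_attribution(model, canonical)
  p <- model$p
  level <- alpha / (2 * p)
  qlo <- level / 2; qhi <- 1 - level / 2
  nq <- length(canonical$qualifying)
  units <- list()
  for (m in seq_len(model$M)) {
    attr_m <- attr_df$attribution[m]
    # attributed units are read on their condition's canonical; a mixed
    # unit contributes a profile for each condition
    conds <- if (attr_m == "mixed") c("Go", "NoGo") else attr_m
    for (cond in conds) {
      sel <- fm$subjects %in% canonical$qualifying & fm$y == cond
      Xq <- fm$X[sel, , drop = FALSE]
      a <- model$alpha[m, -1]
      s <- a * colMeans(Xq)
      # multinomial-weight bootstrap of the subject mean
      Wb <- with_seed(seed_stream(seed, 60L, m, match(cond, c("Go", "NoGo"))),
                      stats::rmultinom(B, nq, rep(1 / nq, nq)))  # nq x B
      boots <- crossprod(Wb / nq, Xq)                # B x p resampled means
      boots <- sweep(boots, 2, a, `*`)
      lo <- apply(boots, 2, boot_tail_quantile, prob = qlo, lower = TRUE)
      hi <- apply(boots, 2, boot_tail_quantile, prob = qhi, lower = FALSE)
      sig <- lo > 0 | hi < 0
      units[[length(units) + 1]] <-
        list(unit = m, condition = cond, attribution = attr_m, s = s,
             sig = sig, lower = lo, upper = hi)
    }
  }
  structure(list(units = units, B = B, alpha = alpha, level = level,
                 index_map = fm$index_map, attribution = attr_df),
            class = "signature_profiles")
}

#' Order-statistic percentile endpoint for extreme bootstrap tails
#'
#' Interpolated sample quantiles are anti-conservative at probabilities near
#' or below the bootstrap's 1/B resolution (exactly the regime of a
#' Bonferroni level 0.05/(2p)); the interval endpoint is therefore taken at
#' the outward order statistic, falling back to the extreme value when the
#' requested level is below the resolution.
#'
#' @param x Bootstrap draws.
#' @param prob Tail probability of the endpoint.
#' @param lower TRUE for the lower endpoint (outward = smaller).
#' @return The endpoint value.
#' @export
boot_tail_quantile <- function(x, prob, lower = TRUE) {
  b <- length(x)
  s <- sort(x)
  if (lower) {
    s[max(1L, as.integer(floor(prob * b)))]
  } else {
    s[min(b, as.integer(ceiling(prob * b)) + 1L)]
  }
}

# local |s| peaks within each band segment of the concatenated profile
profile_peaks <- function(s, index_map) {
  peaks <- logical(length(s))
  seg <- paste(index_map$component, index_map$band)
  for (g in unique(seg)) {
    idx <- which(seg == g)
    v <- abs(s[idx])
    for (i in seq_along(idx)) {
      left <- if (i == 1) -Inf else v[i - 1]
      right <- if (i == length(idx)) -Inf else v[i + 1]
      peaks[idx[i]] <- v[i] >= left & v[i] >= right & v[i] > 0
    }
  }
  peaks
}

#' Summarize significant signatures as region x band x epoch rows
#'
#' Each significant profile peak maps to (region label from the component
#' catalog, condition from the unit attribution, band, epoch from the time
#' bin, direction from the sign of the canonical band x time ERSP value at
#' that feature); rows are deduplicated. Bins map to epochs as early =
#' bins 1-2 (< 0.25 s), mid = bins 3-5 (0.25-0.55 s), late = bins 6-8.
#'
#' @param profiles A `signature_profiles`.
#' @param canonical_blocks Named list per condition (`Go`, `NoGo`) of
#'   component x 40 raw dB matrices averaged over qualifying subjects (the
#'   un-scaled ERSP panel values).
#' @param component_labels Character vector of region labels per component
#'   (in the feature index-map's component order).
#' @param min_panel_db Minimum absolute canonical panel value (dB) for a
#'   significant peak to be reported; peaks whose underlying time-frequency
#'   deviation is not visible on the panel (sub-dB artifacts of scaling,
#'   window smearing, or component crosstalk) are dropped.
#' @return A data frame (`signature_summary`): region, condition, band,
#'   epoch, direction, n_features.
#' @export
summarize_signatures <- function(profiles, canonical_blocks, component_labels,
                                 min_panel_db = 1.5) {
  im <- profiles$index_map
  rows <- list()
  for (u in profiles$units) {
    keep <- u$sig & profile_peaks(u$s, im)
    if (!any(keep)) next
    blk <- canonical_blocks[[u$condition]]
    for (j in which(keep)) {
      comp <- im$component[j]; band <- im$band[j]; bin <- im$bin[j]
      col <- (match(band, band_scheme()$labels) - 1) * 8 + bin
      dbval <- blk[comp, col]
      if (abs(dbval) < min_panel_db) next
      rows[[length(rows) + 1]] <- data.frame(
        region = component_labels[comp], condition = u$condition, band = band,
        epoch = bin_epoch(bin), direction = if (dbval >= 0) "increase" else "decrease",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(region = character(), condition = character(),
                      band = character(), epoch = character(),
                      direction = character(), n_features = integer()))
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(list(n_features = rep(1, nrow(df))),
                          df[, c("region", "condition", "band", "epoch",
                                 "direction")], FUN = sum)
  agg[order(agg$region, agg$condition, agg$band, agg$epoch), ]
}

bin_epoch <- function(bin) {
  c("early", "early", "mid", "mid", "mid", "late", "late", "late")[bin]
}

#' Score a signature summary against planted effects
#'
#' @param summary A signature summary data frame.
#' @param truth_table Planted effect table (region, condition, band, epoch,
#'   direction), e.g. from the scenario builders.
#' @return List with `recovered` (fraction of planted rows present),
#'   `spurious` (fraction of summary rows matching no planted effect),
#'   `n_rows`.
#' @export
score_signature_recovery <- function(summary, truth_table) {
  key <- function(df) paste(df$region, df$condition, df$band, df$epoch,
                            df$direction)
  tk <- key(truth_table)
  sk <- unique(key(summary))
  # a planted effect is recovered if a summary row matches it exactly, or in
  # an adjacent epoch with matching everything else (window smearing)
  relax <- function(k) {
    parts <- strsplit(k, " ")[[1]]
    eps <- list(early = c("early", "mid"), mid = c("early", "mid", "late"),
                late = c("mid", "late"))[[parts[4]]]
    vapply(eps, function(e) paste(parts[1], parts[2], parts[3], e, parts[5]), "")
  }
  rec <- vapply(tk, function(k) any(relax(k) %in% sk), TRUE)
  spur <- vapply(sk, function(k) !any(vapply(tk, function(t) k %in% relax(t), TRUE)), TRUE)
  list(recovered = mean(rec), spurious = if (length(sk)) mean(spur) else 0,
       n_rows = length(sk))
}
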