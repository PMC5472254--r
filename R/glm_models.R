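#' Fit the Poisson GLM model set for coordinate-frame comparison
#'
#' Maximum-likelihood Poisson (log link) fits of evoked spike counts on:
#' nothing (constant), the sound angle relative to the head, the sound angle
#' in the world, and both (additive full model). The default encoding treats
#' angle as a continuous circular variable through its first harmonic
#' (sin/cos, 2 parameters per frame), which keeps the parameter count — and
#' hence the share of deviance each frame can absorb by chance — identical
#' across frames; `encoding = "binned"` instead uses categorical 30-degree
#' bins (head: 12 full-circle bins; world: the discrete speaker angles), the
#' encoding used by the aligned-condition screening GLM.
#'
#' @param trials data frame from [trial_responses()].
#' @param encoding `"harmonic"` (default) or `"binned"`.
#' @param bin_width_deg bin width for the binned encoding.
#' @param count_col response column.
#' @return object of class `glm_fit_set`: per model (`const`, `head`, `world`,
#'   `full`) the deviance, the number of estimated parameters, the AIC on the
#'   deviance scale (`deviance + 2 * n_params`), and the chi-squared
#'   analysis-of-deviance p value against the constant model.
#' @export
fit_glm_set <- function(trials, encoding = c("harmonic", "binned"),
                        bin_width_deg = 30, count_col = "evoked_count") {
  encoding <- match.arg(encoding)
  y <- trials[[count_col]]
  if (encoding == "binned") {
    Xh <- data.frame(h = factor(angle_bin(trials$theta_hs_deg, bin_width_deg,
                                          range_deg = 180)))
    Xw <- data.frame(w = factor(angle_bin(trials$theta_ws_deg, bin_width_deg,
                                          range_deg = 180)))
  } else {
    rad_h <- trials$theta_hs_deg * pi / 180
    rad_w <- trials$theta_ws_deg * pi / 180
    Xh <- data.frame(h1 = sin(rad_h), h2 = cos(rad_h))
    Xw <- data.frame(w1 = sin(rad_w), w2 = cos(rad_w))
  }
  dat <- cbind(data.frame(y = y), Xh, Xw)
  fh <- paste(names(Xh), collapse = " + ")
  fw <- paste(names(Xw), collapse = " + ")
  forms <- list(
    const = "y ~ 1",
    head = paste("y ~", fh),
    world = paste("y ~", fw),
    full = paste("y ~", fh, "+", fw)
  )
  fits <- lapply(forms, function(f) {
    stats::glm(stats::as.formula(f), data = dat, family = stats::poisson())
  })
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  d <- vapply(fits, stats::deviance, numeric(1))
  k <- vapply(fits, function(f) f$rank, numeric(1))
  p_vs_const <- vapply(names(fits), function(nm) {
    if (nm == "const") return(NA_real_)
    df <- k[[nm]] - k[["const"]]
    if (df <= 0) return(1)
    stats::pchisq(pmax(d[["const"]] - d[[nm]], 0), df, lower.tail = FALSE)
  }, numeric(1))
  structure(
    list(deviance = d, n_params = k, aic = d + 2 * k, p_vs_const = p_vs_const,
         converged = all(conv), encoding = encoding, n_trials = length(y)),
    class = "glm_fit_set"
  )
}

#' @export
print.glm_fit_set <- function(x, ...) {
  cat(sprintf("<glm_fit_set> %s encoding, %d trials%s\n", x$encoding,
              x$n_trials, if (x$converged) "" else " (non-converged!)"))
  print(data.frame(deviance = x$deviance, k = x$n_params, aic = x$aic,
                   p_vs_const = signif(x$p_vs_const, 3)))
  invisible(x)
}

#' Model fit: proportion of explainable deviance
#'
#' `(D_const - D_test) / (D_const - D_full) * 100`, the deviance reduction of
#' a one-frame model as a percentage of the reduction achieved by the
#' two-frame full model. Bounded in \[0, 100\] by model nesting.
#'
#' @param d_const,d_test,d_full deviances of the constant, test, and full
#'   models (must satisfy `d_full <= d_test <= d_const`).
#' @return model fit in percent; `NA` with a warning when
#'   `d_const == d_full` (no explainable deviance).
#' @export
model_fit <- function(d_const, d_test, d_full) {
  if (any(d_test > d_const + 1e-8) || any(d_full > d_test + 1e-8)) {
    stop("deviances violate model nesting", call. = FALSE)
  }
  denom <- d_const - d_full
  out <- ifelse(denom > 0, (d_const - d_test) / denom * 100, NA_real_)
  if (any(is.na(out) & !is.na(denom))) {
    warning("no explainable deviance: model fit undefined")
  }
  pmin(pmax(out, 0), 100)
}

#' Model preference: head-frame fit minus world-frame fit
#'
#' Positive values indicate that sound angle relative to the head explains
#' more of the explainable deviance (egocentric preference); negative values
#' indicate a world-frame (allocentric) preference. Bounded in \[-100, 100\].
#'
#' @param fit_head_pct,fit_world_pct model fits in percent.
#' @return preference in percent.
#' @export
model_preference <- function(fit_head_pct, fit_world_pct) {
  fit_head_pct - fit_world_pct
}

#' Model scores of a fitted GLM set
#'
#' @param fits a `glm_fit_set`.
#' @return list with `fit_head_pct`, `fit_world_pct`, `preference_pct`.
#' @export
model_scores <- function(fits) {
  stopifnot(inherits(fits, "glm_fit_set"))
  fh <- model_fit(fits$deviance[["const"]], fits$deviance[["head"]],
                  fits$deviance[["full"]])
  fw <- model_fit(fits$deviance[["const"]], fits$deviance[["world"]],
                  fits$deviance[["full"]])
  list(fit_head_pct = fh, fit_world_pct = fw,
       preference_pct = model_preference(fh, fw))
}

#' AIC classification of a unit's coordinate frame
#'
#' A unit is `"excluded"` when neither one-frame model improves on the
#' constant model (analysis of deviance, Bonferroni-corrected for the two
#' comparisons); otherwise it is labeled by the frame with the smaller AIC.
#' Exact AIC ties are broken toward the larger model fit and flagged.
#'
#' @param fits a `glm_fit_set`.
#' @param alpha significance level before the 2-way Bonferroni correction.
#' @return list with `label` (`"egocentric"`, `"allocentric"`, `"excluded"`),
#'   `aic_head`, `aic_world`, `tie` (logical).
#' @export
classify_aic <- function(fits, alpha = 0.05) {
  stopifnot(inherits(fits, "glm_fit_set"))
  thr <- alpha / 2
  any_sig <- (!is.na(fits$p_vs_const[["head"]]) &&
                fits$p_vs_const[["head"]] < thr) ||
    (!is.na(fits$p_vs_const[["world"]]) && fits$p_vs_const[["world"]] < thr)
  ah <- fits$aic[["head"]]
  aw <- fits$aic[["world"]]
  tie <- FALSE
  if (!any_sig) {
    label <- "excluded"
  } else if (ah == aw) {
    tie <- TRUE
    sc <- model_scores(fits)
    label <- if (isTRUE(sc$fit_head_pct >= sc$fit_world_pct)) "egocentric"
             else "allocentric"
  } else {
    label <- if (ah < aw) "egocentric" else "allocentric"
  }
  list(label = label, aic_head = ah, aic_world = aw, tie = tie)
}

#' Shuffle control for the GLM frame comparison
#'
#' Destroys the association between neural activity and one spatial variable
#' while preserving the other: `mode = "speaker"` permutes speaker identity
#' across trials (recomputing both the world angle and, through the geometry,
#' the head-relative angle), `mode = "head_direction"` permutes the head
#' direction across trials (recomputing the head-relative angle only). The
#' GLM set is refitted on every shuffle and the model scores recorded.
#'
#' @param trials data frame from [trial_responses()].
#' @param arena the `arena_model` used to recompute stimulus geometry.
#' @param mode which variable to shuffle.
#' @param n number of shuffles (>= 1).
#' @param seed integer seed.
#' @param ... passed to [fit_glm_set()].
#' @return object of class `shuffle_result`: `median_fit_head`,
#'   `median_fit_world`, `median_preference`, `preference_limits` (2.5 and
#'   97.5 percentiles of the shuffled preference), and the per-shuffle score
#'   table `scores`.
#' @export
shuffle_control <- function(trials, arena, mode = c("speaker", "head_direction"),
                            n = 1000, seed = 1, ...) {
  mode <- match.arg(mode)
  if (n < 1) stop("need n >= 1 shuffles", call. = FALSE)
  set.seed(seed)
  sp <- speaker_positions(arena)
  res <- matrix(NA_real_, nrow = n, ncol = 3,
                dimnames = list(NULL, c("fit_head_pct", "fit_world_pct",
                                        "preference_pct")))
  for (i in seq_len(n)) {
    perm <- sample.int(nrow(trials))
    tr <- trials
    if (mode == "speaker") {
      tr$speaker_id <- trials$speaker_id[perm]
    } else {
      tr$head_dir_deg <- trials$head_dir_deg[perm]
    }
    g <- stimulus_geometry(tr$head_x_mm, tr$head_y_mm, tr$head_dir_deg,
                           sp$x_mm[tr$speaker_id], sp$y_mm[tr$speaker_id],
                           arena)
    tr$theta_hs_deg <- g$theta_hs_deg
    tr$theta_ws_deg <- g$theta_ws_deg
    sc <- model_scores(fit_glm_set(tr, ...))
    res[i, ] <- c(sc$fit_head_pct, sc$fit_world_pct, sc$preference_pct)
  }
  structure(
    list(
      mode = mode, n_shuffles = n,
      median_fit_head = stats::median(res[, 1], na.rm = TRUE),
      median_fit_world = stats::median(res[, 2], na.rm = TRUE),
      median_preference = stats::median(res[, 3], na.rm = TRUE),
      preference_limits = stats::quantile(res[, 3], c(0.025, 0.975),
                                          na.rm = TRUE, names = FALSE),
      scores = as.data.frame(res)
    ),
    class = "shuffle_result"
  )
}

#' @export
print.shuffle_result <- function(x, ...) {
  cat(sprintf(
    "<shuffle_result> %s shuffle (n = %d): median fits %.1f / %.1f%%, preference %.1f%% [%.1f, %.1f]\n",
    x$mode, x$n_shuffles, x$median_fit_head, x$median_fit_world,
    x$median_preference, x$preference_limits[1], x$preference_limits[2]))
  invisible(x)
}

#' Time-resolved GLM model scores
#'
#' Slides a short counting window across time relative to click onset
#' (centers from `span_ms[1]` to `span_ms[2]` in `step_ms` steps, width
#' `window_ms`), recounts spikes per trial in each window, refits the GLM set
#' and records the model scores — the timecourse of spatial information in
#' each coordinate frame.
#'
#' @param spikes spike-time vector, seconds.
#' @param trials data frame from [trial_responses()] (supplies click times
#'   and angles).
#' @param window_ms counting-window width, ms.
#' @param step_ms window-center spacing, ms.
#' @param span_ms range of window centers relative to click onset, ms.
#' @param ... passed to [fit_glm_set()].
#' @return object of class `timecourse_result`: data frame `scores` with
#'   columns `center_ms`, `fit_head_pct`, `fit_world_pct`, `preference_pct`.
#' @export
timecourse_fits <- function(spikes, trials, window_ms = 20, step_ms = 2,
                            span_ms = c(-60, 90), ...) {
  centers <- seq(span_ms[1], span_ms[2], by = step_ms)
  spikes <- sort(spikes)
  half <- window_ms / 2 / 1000
  out <- lapply(centers, function(cm) {
    lo <- trials$t_s + cm / 1000 - half
    hi <- trials$t_s + cm / 1000 + half
    cnt <- findInterval(hi, spikes) - findInterval(lo, spikes)
    tr <- trials
    tr$evoked_count <- cnt
    sc <- if (all(cnt == 0)) {
      list(fit_head_pct = NA_real_, fit_world_pct = NA_real_,
           preference_pct = NA_real_)
    } else {
      model_scores(fit_glm_set(tr, ...))
    }
    data.frame(center_ms = cm, fit_head_pct = sc$fit_head_pct,
               fit_world_pct = sc$fit_world_pct,
               preference_pct = sc$preference_pct)
  })
  structure(list(scores = do.call(rbind, out), window_ms = window_ms),
            class = "timecourse_result")
}

#' Cluster-based permutation test between two groups of time series
#'
#' Pointwise Welch t statistics between groups of per-unit time series are
#' thresholded at the two-sided critical t for `alpha`; contiguous
#' supra-threshold samples form clusters scored by their summed t. The null
#' distribution of the maximum absolute cluster mass is built by permuting
#' group labels; each observed cluster's p value is
#' `(# null maxima >= observed + 1) / (n_perm + 1)`.
#'
#' @param series_a,series_b matrices (units x time) on the same time grid.
#' @param n_perm number of label permutations (>= 19 for alpha = 0.05).
#' @param alpha cluster-forming (and reporting) significance level.
#' @param seed integer seed.
#' @return object of class `cluster_test`: data frame `clusters` with
#'   `start_idx`, `end_idx`, `mass`, `p`, plus the pointwise `t` vector.
#' @export
cluster_test <- function(series_a, series_b, n_perm = 500, alpha = 0.05,
                         seed = 1) {
  series_a <- as.matrix(series_a)
  series_b <- as.matrix(series_b)
  if (ncol(series_a) != ncol(series_b)) stop("time grids differ", call. = FALSE)
  if (nrow(series_a) < 2 || nrow(series_b) < 2) {
    stop("need >= 2 units per group", call. = FALSE)
  }
  if (n_perm < ceiling(1 / alpha) - 1) {
    stop("n_perm too small to resolve alpha", call. = FALSE)
  }
  set.seed(seed)
  all_series <- rbind(series_a, series_b)
  na <- nrow(series_a)
  ntot <- nrow(all_series)

  welch_t <- function(idx_a) {
    A <- all_series[idx_a, , drop = FALSE]
    B <- all_series[-idx_a, , drop = FALSE]
    ma <- colMeans(A); mb <- colMeans(B)
    va <- apply(A, 2, stats::var) / nrow(A)
    vb <- apply(B, 2, stats::var) / nrow(B)
    (ma - mb) / sqrt(va + vb)
  }
  # conservative common threshold: df = min group size - 1
  t_crit <- stats::qt(1 - alpha / 2, min(na, ntot - na) - 1)
  cluster_masses <- function(tv) {
    above <- abs(tv) > t_crit & !is.na(tv)
    if (!any(above)) return(data.frame(start_idx = integer(0),
                                       end_idx = integer(0),
                                       mass = numeric(0)))
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values
    data.frame(
      start_idx = starts[keep], end_idx = ends[keep],
      mass = mapply(function(s, e) sum(tv[s:e]), starts[keep], ends[keep])
    )
  }
  t_obs <- welch_t(seq_len(na))
  obs <- cluster_masses(t_obs)
  null_max <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(ntot, na)
    cm <- cluster_masses(welch_t(idx))
    if (nrow(cm) == 0) 0 else max(abs(cm$mass))
  }, numeric(1))
  obs$p <- vapply(obs$mass, function(m) {
    (sum(null_max >= abs(m)) + 1) / (n_perm + 1)
  }, numeric(1))
  obs$significant <- obs$p <= alpha
  structure(list(clusters = obs, t = t_obs, t_crit = t_crit, n_perm = n_perm),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d clusters (|t| > %.2f), %d permutations\n",
              nrow(x$clusters), x$t_crit, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
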