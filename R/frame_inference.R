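#' Screen a unit for sound responsiveness
#'
#' Poisson regression of window spike counts on a period indicator (evoked
#' 0-50 ms vs background -50-0 ms), tested against the constant model by
#' chi-squared analysis of deviance. A unit is sound-responsive when the
#' evoked rate differs significantly from background (p <= alpha).
#'
#' @param trials data frame from [trial_responses()].
#' @param alpha significance level.
#' @return list with `p`, `responsive`, `rate_evoked_hz`, `rate_background_hz`.
#' @export
screen_sound_responsive <- function(trials, alpha = 0.05) {
  if (nrow(trials) < 2) stop("need >= 2 trials", call. = FALSE)
  counts <- c(trials$evoked_count, trials$background_count)
  if (all(counts == 0)) {
    return(list(p = 1, responsive = FALSE, rate_evoked_hz = 0,
                rate_background_hz = 0))
  }
  period <- rep(c("evoked", "background"), each = nrow(trials))
  fit <- stats::glm(counts ~ period, family = stats::poisson())
  p <- stats::anova(fit, test = "Chisq")[["Pr(>Chi)"]][2]
  w <- attr(trials, "window_s")
  if (is.null(w)) w <- 0.05
  list(
    p = p,
    responsive = p <= alpha,
    rate_evoked_hz = mean(trials$evoked_count) / w,
    rate_background_hz = mean(trials$background_count) / w
  )
}

#' Restrict trials to the aligned condition
#'
#' Keeps trials on which the head was within `radius_mm` of a reference point
#' `offset_mm` behind the arena center (accounting for the snout-to-head-center
#' distance) and facing within `half_angle_deg` of the arena midline. Under
#' these constraints the head and world coordinate frames approximately
#' coincide, mimicking classical head-fixed receptive-field mapping.
#'
#' @param trials data frame from [trial_responses()].
#' @param radius_mm inclusion radius around the reference point, mm.
#' @param offset_mm distance of the reference point behind the arena center
#'   (along -x), mm.
#' @param half_angle_deg maximum absolute head direction re the midline, deg.
#' @return the aligned subset (possibly empty), with attribute `n_excluded`.
#' @export
aligned_subset <- function(trials, radius_mm = 50, offset_mm = 25,
                           half_angle_deg = 15) {
  d <- sqrt((trials$head_x_mm + offset_mm)^2 + trials$head_y_mm^2)
  keep <- d <= radius_mm & abs(wrap_angle(trials$head_dir_deg)) <= half_angle_deg
  out <- trials[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Screen a unit for spatial tuning in the aligned condition
#'
#' Poisson GLM of evoked spike counts on the sound angle relative to the head
#' binned at 30 degrees (the +/-90-degree grid), tested against the constant
#' model by chi-squared analysis of deviance. The unit is only testable when
#' every angular bin holds at least `min_per_bin` presentations.
#'
#' @param aligned_trials output of [aligned_subset()].
#' @param alpha significance level.
#' @param min_per_bin minimum presentations per angular bin.
#' @param bin_width_deg,range_deg binning of the head-frame angle.
#' @return list with `testable`, `p`, `tuned`, `n_per_bin`.
#' @export
screen_spatial_tuning <- function(aligned_trials, alpha = 0.05,
                                  min_per_bin = 5, bin_width_deg = 30,
                                  range_deg = 90) {
  b <- angle_bin(aligned_trials$theta_hs_deg, bin_width_deg, range_deg)
  keep <- !is.na(b)
  b <- b[keep]
  counts <- aligned_trials$evoked_count[keep]
  expected_bins <- wrap_angle(seq(-range_deg, range_deg, by = bin_width_deg))
  expected_bins <- sort(unique(expected_bins[abs(expected_bins) <= range_deg + 1e-9]))
  tab <- table(factor(b, levels = expected_bins))
  if (any(tab < min_per_bin)) {
    return(list(testable = FALSE, p = NA_real_, tuned = NA,
                n_per_bin = as.numeric(tab)))
  }
  fit <- stats::glm(counts ~ factor(b), family = stats::poisson())
  p <- stats::anova(fit, test = "Chisq")[["Pr(>Chi)"]][2]
  list(testable = TRUE, p = p, tuned = p <= alpha, n_per_bin = as.numeric(tab))
}

# Bin center (multiple of bin_width) for each angle, NA outside +/- range.
angle_bin <- function(theta, bin_width_deg = 30, range_deg = 90) {
  ctr <- wrap_angle(round(wrap_angle(theta) / bin_width_deg) * bin_width_deg)
  ctr[abs(ctr) > range_deg + 1e-9] <- NA_real_
  ctr
}

#' Residual modulation ratio
#'
#' Modulation depth in the coordinate frame irrelevant to a unit's tuning,
#' expressed as a ratio of the modulation depth in the relevant frame.
#'
#' @param md_irrelevant_pct,md_relevant_pct modulation depths, percent.
#' @return the ratio; `NA` with a warning when the relevant MD is zero.
#' @export
residual_modulation <- function(md_irrelevant_pct, md_relevant_pct) {
  out <- md_irrelevant_pct / md_relevant_pct
  bad <- !is.na(md_relevant_pct) & md_relevant_pct <= 0
  if (any(bad)) {
    warning("relevant-frame modulation depth is zero: ratio undefined")
    out[bad] <- NA_real_
  }
  out
}

#' Simulated residual modulation for a set of behavioral sessions
#'
#' For each session, plays the session's clicks through the canonical
#' egocentric and allocentric fields (deterministic expected tuning in both
#' coordinate frames on the +/-90-degree grid), computes modulation depths
#' and the residual modulation of each field, and pairs them with the
#' session's head-direction spread.
#'
#' @param sessions list of `session_bundle`s (or lists with `poses`, `clicks`,
#'   `arena`).
#' @param ego,allo the template fields (defaults: the canonical matched pair).
#' @param bin_width_deg,range_deg tuning-curve grid.
#' @param circular_sd passed to [behavior_summary()].
#' @return data frame with one row per usable session: `sigma_dir_deg`,
#'   `residual_ego` (world MD / head MD of the egocentric template),
#'   `residual_allo` (head MD / world MD of the allocentric template).
#'   Sessions with empty bins are dropped with a warning.
#' @export
simulate_session_residuals <- function(sessions, ego = ego_field(),
                                       allo = allo_field(),
                                       bin_width_deg = 30, range_deg = 90,
                                       circular_sd = TRUE) {
  rows <- lapply(sessions, function(s) {
    arena <- s$arena
    idx <- nearest_frame(s$poses$t_s, s$clicks$t_s)
    traj_at <- s$poses[idx, , drop = FALSE]
    epochs <- stimulus_epochs(traj_at, arena, speaker_ids = s$clicks$speaker_id)
    curves <- lapply(list(ego = ego, allo = allo), function(f) {
      lapply(c(head = "head", world = "world"), function(fr) {
        expected_tuning(f, epochs, frame = fr, bin_width_deg = bin_width_deg,
                        range_deg = range_deg)
      })
    })
    n_empty <- sum(vapply(unlist(curves, recursive = FALSE),
                          function(cv) attr(cv, "n_empty_bins"), numeric(1)))
    if (n_empty > 0) return(NULL)
    md <- lapply(curves, function(fc) lapply(fc, modulation_depth))
    bs <- behavior_summary(s$poses, s$clicks, arena, circular_sd = circular_sd)
    data.frame(
      sigma_dir_deg = bs$sigma_dir_deg,
      residual_ego = residual_modulation(md$ego$world, md$ego$head),
      residual_allo = residual_modulation(md$allo$head, md$allo$world)
    )
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (any(dropped)) {
    warning(sum(dropped), " sessions dropped (empty angular bins)")
  }
  do.call(rbind, rows[!dropped])
}

#' Fit the residual-modulation regression
#'
#' Ordinary least squares of residual modulation on the head-direction spread
#' across behavioral sessions. The fitted line predicts how much spurious
#' modulation a purely single-frame unit shows in the irrelevant frame given
#' how non-uniformly the head was oriented.
#'
#' @param sigma_dir_deg per-session head-direction spread, degrees.
#' @param residual per-session residual modulation ratios.
#' @return object of class `residual_regression`: the `lm` fit plus `slope`,
#'   `intercept`, `r2`, `p`.
#' @export
fit_residual_regression <- function(sigma_dir_deg, residual) {
  ok <- is.finite(sigma_dir_deg) & is.finite(residual)
  if (sum(ok) < 3) stop("need >= 3 sessions", call. = FALSE)
  if (stats::sd(sigma_dir_deg[ok]) == 0) {
    stop("degenerate spread of sigma_dir", call. = FALSE)
  }
  fit <- stats::lm(residual ~ sigma_dir_deg,
                   data = data.frame(sigma_dir_deg = sigma_dir_deg[ok],
                                     residual = residual[ok]))
  sm <- summary(fit)
  structure(
    list(fit = fit,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = sm$r.squared,
         p = sm$coefficients[2, 4],
         n = sum(ok)),
    class = "residual_regression"
  )
}

#' @export
print.residual_regression <- function(x, ...) {
  cat(sprintf(
    "<residual_regression> residual = %.4f %+.5f * sigma (n = %d, r2 = %.3f, p = %.3g)\n",
    x$intercept, x$slope, x$n, x$r2, x$p))
  invisible(x)
}

#' Simultaneous prediction bound for a new residual-modulation observation
#'
#' Upper bound of the prediction interval for a single new observation at a
#' given head-direction spread, widened for simultaneous coverage over the
#' whole regression line (Scheffe / Working-Hotelling multiplier
#' `sqrt(2 F(level; 2, n - 2))`) — the most conservative interval, minimizing
#' false positives when observed modulation depths are compared against it.
#'
#' @param model a `residual_regression`.
#' @param sigma_dir_deg head-direction spread(s) at which to predict.
#' @param level coverage level (e.g. 0.95, or 0.9995 after Bonferroni
#'   correction across 92 units).
#' @param simultaneous if `FALSE`, use the pointwise t multiplier instead.
#' @return data frame with `fit`, `upper`, `lower`.
#' @export
predict_residual_ci <- function(model, sigma_dir_deg, level = 0.95,
                                simultaneous = TRUE) {
  stopifnot(inherits(model, "residual_regression"))
  fit <- model$fit
  xbar <- mean(fit$model$sigma_dir_deg)
  sxx <- sum((fit$model$sigma_dir_deg - xbar)^2)
  n <- model$n
  s <- sqrt(sum(stats::residuals(fit)^2) / stats::df.residual(fit))
  pred <- model$intercept + model$slope * sigma_dir_deg
  se_new <- s * sqrt(1 + 1 / n + (sigma_dir_deg - xbar)^2 / sxx)
  mult <- if (simultaneous) {
    sqrt(2 * stats::qf(level, 2, n - 2))
  } else {
    stats::qt(1 - (1 - level) / 2, n - 2)
  }
  data.frame(fit = pred, lower = pred - mult * se_new,
             upper = pred + mult * se_new)
}

#' Classify a unit's spatial modulation per coordinate frame
#'
#' Compares the unit's observed modulation-depth ratio in each frame
#' (MD of that frame over MD of the other frame) against the upper
#' simultaneous prediction bound of the residual modulation expected from the
#' session's head-direction spread alone. The head-frame test uses the
#' regression fitted on allocentric-template residuals (for which the head
#' frame is irrelevant), and vice versa. Flags are reported at `alpha` and at
#' the Bonferroni-corrected level `alpha / n_tests`.
#'
#' @param md_head_pct,md_world_pct observed modulation depths on
#'   free-movement data, percent.
#' @param sigma_dir_deg head-direction spread of the unit's session, degrees.
#' @param model_head `residual_regression` for the head-as-irrelevant frame
#'   (fitted on allocentric-template residuals).
#' @param model_world `residual_regression` for the world-as-irrelevant frame
#'   (fitted on egocentric-template residuals).
#' @param alpha nominal significance level.
#' @param n_tests number of units tested (Bonferroni divisor).
#' @return list of class `frame_classification`: observed ratios, CI upper
#'   bounds, significance flags at both levels, and `dominant_frame`.
#' @export
classify_modulation <- function(md_head_pct, md_world_pct, sigma_dir_deg,
                                model_head, model_world, alpha = 0.05,
                                n_tests = 1) {
  if (missing(model_head) || missing(model_world)) {
    stop("both residual regression models are required", call. = FALSE)
  }
  ratio_head <- residual_modulation(md_head_pct, md_world_pct)
  ratio_world <- residual_modulation(md_world_pct, md_head_pct)
  lv1 <- 1 - alpha
  lv2 <- 1 - alpha / n_tests
  ub_h1 <- predict_residual_ci(model_head, sigma_dir_deg, lv1)$upper
  ub_h2 <- predict_residual_ci(model_head, sigma_dir_deg, lv2)$upper
  ub_w1 <- predict_residual_ci(model_world, sigma_dir_deg, lv1)$upper
  ub_w2 <- predict_residual_ci(model_world, sigma_dir_deg, lv2)$upper
  structure(
    list(
      md_head_pct = md_head_pct,
      md_world_pct = md_world_pct,
      ratio_head = ratio_head,
      ratio_world = ratio_world,
      upper_head = ub_h1,
      upper_world = ub_w1,
      upper_head_bonf = ub_h2,
      upper_world_bonf = ub_w2,
      significant_head = !is.na(ratio_head) & ratio_head > ub_h1,
      significant_world = !is.na(ratio_world) & ratio_world > ub_w1,
      significant_head_bonf = !is.na(ratio_head) & ratio_head > ub_h2,
      significant_world_bonf = !is.na(ratio_world) & ratio_world > ub_w2,
      dominant_frame = ifelse(md_head_pct >= md_world_pct, "head", "world")
    ),
    class = "frame_classification"
  )
}

#' @export
print.frame_classification <- function(x, ...) {
  cat(sprintf(
    "<frame_classification> MD head %.1f%%, world %.1f%% -> dominant %s (head sig: %s, world sig: %s)\n",
    x$md_head_pct, x$md_world_pct, x$dominant_frame,
    x$significant_head, x$significant_world))
  invisible(x)
}
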