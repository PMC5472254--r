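#' Extract single-trial responses around each click
#'
#' For every click with a trackable pose, counts spikes in the evoked window
#' (0, 50] ms and the background window \[-50, 0) ms around click onset,
#' converts both to rates, and attaches the stimulus geometry (head- and
#' world-frame angles, distance, level at the head) and head state (position,
#' direction, speed) at the nearest video frame (lag 0).
#'
#' @param spikes numeric vector of spike times, seconds.
#' @param clicks click schedule data frame (`t_s`, `speaker_id`, optionally
#'   `nominal_level_db`).
#' @param traj pose data frame (`t_s`, `x_mm`, `y_mm`, `dir_deg`, optionally
#'   `speed_cm_s`); rows with `NA` pose cause the overlapping trials to be
#'   dropped (the count is recorded in `attr(, "n_dropped")`).
#' @param arena an `arena_model`.
#' @param window_s evoked/background window length, seconds.
#' @return data frame with one row per usable click: `t_s`, `speaker_id`,
#'   `theta_hs_deg`, `theta_ws_deg`, `hs_distance_mm`, `level_at_head_db`,
#'   `head_x_mm`, `head_y_mm`, `head_dir_deg`, `speed_cm_s`, `evoked_count`,
#'   `background_count`, `evoked_rate_hz`, `background_rate_hz`.
#' @export
trial_responses <- function(spikes, clicks, traj, arena = make_arena(),
                            window_s = 0.05) {
  idx <- nearest_frame(traj$t_s, clicks$t_s)
  ok <- !is.na(traj$x_mm[idx]) & !is.na(traj$dir_deg[idx]) &
    abs(traj$t_s[idx] - clicks$t_s) <= 2 * median(diff(traj$t_s))
  n_dropped <- sum(!ok)
  clicks <- clicks[ok, , drop = FALSE]
  idx <- idx[ok]
  sp <- speaker_positions(arena)
  lev <- if (!is.null(clicks$nominal_level_db)) clicks$nominal_level_db
         else arena$cal_level_db
  g <- stimulus_geometry(traj$x_mm[idx], traj$y_mm[idx], traj$dir_deg[idx],
                         sp$x_mm[clicks$speaker_id], sp$y_mm[clicks$speaker_id],
                         arena, nominal_level_db = lev)
  spikes <- sort(spikes)
  count_in <- function(lo, hi) {
    findInterval(hi, spikes) - findInterval(lo, spikes)
  }
  # evoked (t, t + w]; background [t - w, t): half-open away from the onset
  ec <- count_in(clicks$t_s, clicks$t_s + window_s)
  bc <- count_in(clicks$t_s - window_s - 1e-12, clicks$t_s - 1e-12)
  out <- data.frame(
    t_s = clicks$t_s,
    speaker_id = clicks$speaker_id,
    theta_hs_deg = g$theta_hs_deg,
    theta_ws_deg = g$theta_ws_deg,
    hs_distance_mm = g$hs_distance_mm,
    level_at_head_db = g$level_at_head_db,
    head_x_mm = traj$x_mm[idx],
    head_y_mm = traj$y_mm[idx],
    head_dir_deg = traj$dir_deg[idx],
    speed_cm_s = if (!is.null(traj$speed_cm_s)) traj$speed_cm_s[idx] else NA_real_,
    evoked_count = ec,
    background_count = bc,
    evoked_rate_hz = ec / window_s,
    background_rate_hz = bc / window_s
  )
  attr(out, "n_dropped") <- n_dropped
  attr(out, "window_s") <- window_s
  out
}

#' Binned tuning curve of trial firing rates
#'
#' Mean and SEM of the evoked rate within angular bins of the requested
#' coordinate frame. Bins are centered at integer multiples of
#' `bin_width_deg`; with the default 30-degree bins over +/-90 degrees the
#' world-frame bin centers coincide with the 7 speaker angles, so head- and
#' world-frame curves are computed on congruent grids.
#'
#' @param trials data frame from [trial_responses()] (or any table with
#'   `theta_hs_deg` / `theta_ws_deg` and a `rate` column).
#' @param frame `"head"` or `"world"`.
#' @param bin_width_deg bin width, degrees.
#' @param range_deg half-range of bin centers: 90 (default) for the
#'   +/-90-degree grid, 180 for a full-circle head-frame curve.
#' @param min_n bins with fewer trials are flagged (`below_min`); they remain
#'   in the curve.
#' @param rate_col which rate column to average.
#' @return a `tuning_curve` data frame: `frame`, `bin_center_deg`,
#'   `mean_rate`, `sem`, `n`, `bin_width_deg`, `below_min`.
#' @export
tuning_curve <- function(trials, frame = c("head", "world"),
                         bin_width_deg = 30, range_deg = 90, min_n = 1,
                         rate_col = "evoked_rate_hz") {
  frame <- match.arg(frame)
  theta <- if (frame == "head") trials$theta_hs_deg else trials$theta_ws_deg
  curve <- bin_average(theta, trials[[rate_col]], bin_width_deg, range_deg,
                       frame = frame)
  curve$below_min <- curve$n < min_n
  curve
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s frame, %d bins of %g deg\n",
              x$frame[1], nrow(x), x$bin_width_deg[1]))
  print.data.frame(x, ...)
  invisible(x)
}

#' Modulation depth of a tuning curve
#'
#' `MD = (max - min) / max * 100`, computed over the curve's bin means
#' (conventionally the 30-degree bins between +/-90 degrees). Invariant to
#' multiplicative rescaling of the rates.
#'
#' @param curve a `tuning_curve` (or numeric vector of bin rates).
#' @return modulation depth in percent, in \[0, 100\]; `NA` with a warning if
#'   the curve is all zero or has fewer than 2 bins.
#' @export
modulation_depth <- function(curve) {
  x <- if (is.data.frame(curve)) curve$mean_rate else as.numeric(curve)
  if (length(x) < 2) {
    warning("modulation depth needs >= 2 bins")
    return(NA_real_)
  }
  if (max(x) <= 0) {
    warning("modulation depth undefined for an all-zero curve")
    return(NA_real_)
  }
  (max(x) - min(x)) / max(x) * 100
}

#' Classical receptive-field metrics of a full-circle tuning curve
#'
#' Computes, from a 360-degree head-frame curve: the preferred location
#' (argmax bin center; ties broken by the circular mean of tied centers and
#' flagged), the 360-degree modulation depth, the tuning width (contiguous
#' circular extent around the peak over which the rate exceeds
#' `min + threshold * (max - min)`), and the equivalent rectangular
#' receptive-field (ERRF) width (area under the curve divided by its peak).
#'
#' @param curve a full-circle `tuning_curve`.
#' @param threshold tuning-width height fraction between min and max
#'   (default half-height).
#' @return list with `preferred_location_deg`, `md_360_pct`,
#'   `tuning_width_deg`, `errf_width_deg`, `tied_peak` (logical).
#' @export
tuning_metrics <- function(curve, threshold = 0.5) {
  x <- curve$mean_rate
  ctr <- curve$bin_center_deg
  bw <- curve$bin_width_deg[1]
  if (max(x) <= min(x)) {
    warning("constant curve: preferred location undefined")
    return(list(preferred_location_deg = NA_real_,
                md_360_pct = modulation_depth(curve),
                tuning_width_deg = NA_real_,
                errf_width_deg = sum(x) * bw / max(x),
                tied_peak = FALSE))
  }
  is_peak <- x == max(x)
  tied <- sum(is_peak) > 1
  pref <- if (tied) circ_mean_deg(ctr[is_peak]) else ctr[which.max(x)]
  # contiguous circular run of supra-threshold bins containing the peak
  lev <- min(x) + threshold * (max(x) - min(x))
  above <- x >= lev
  n <- length(x)
  run <- 0
  i <- which.max(x)
  j <- i
  while (run < n) {
    nxt <- if (j %% n) j + 1 else 1
    if (!above[nxt] || nxt == i) break
    j <- nxt; run <- run + 1
  }
  k <- i
  while (run < n) {
    prv <- if (k > 1) k - 1 else n
    if (!above[prv] || prv == j) break
    k <- prv; run <- run + 1
  }
  n_above <- if (run >= n - 1) n else ((j - k) %% n) + 1
  list(
    preferred_location_deg = pref,
    md_360_pct = modulation_depth(curve),
    tuning_width_deg = n_above * bw,
    errf_width_deg = sum(x) * bw / max(x),
    tied_peak = tied
  )
}

circ_mean_deg <- function(deg) {
  th <- deg * pi / 180
  wrap_angle(atan2(mean(sin(th)), mean(cos(th))) * 180 / pi)
}

#' Correlation between tuning curves in the two coordinate frames
#'
#' Squared Pearson correlation of bin means over the shared grid, with the
#' correlation sign retained.
#'
#' @param curve_a,curve_b `tuning_curve`s on matching bin grids.
#' @return list with `r2`, `r`, `n_bins`.
#' @export
curve_correlation <- function(curve_a, curve_b) {
  shared <- intersect(curve_a$bin_center_deg, curve_b$bin_center_deg)
  if (length(shared) < 3) stop("need >= 3 shared bins", call. = FALSE)
  a <- curve_a$mean_rate[match(shared, curve_a$bin_center_deg)]
  b <- curve_b$mean_rate[match(shared, curve_b$bin_center_deg)]
  r <- stats::cor(a, b)
  list(r2 = r^2, r = r, n_bins = length(shared))
}

#' Population tuning curve
#'
#' Peak-normalizes each unit's curve (divides by its maximum) and averages the
#' normalized rates without weighting. Units whose curve peaks at zero are
#' excluded with a warning.
#'
#' @param curves list of `tuning_curve`s on a common grid.
#' @return a `tuning_curve` whose `mean_rate` is the unweighted mean of the
#'   normalized curves, with `n` the number of contributing units and an
#'   `argmax_deg` attribute marking the population peak.
#' @export
population_tuning <- function(curves) {
  if (length(curves) < 1) stop("need >= 1 curve", call. = FALSE)
  grid <- curves[[1]]$bin_center_deg
  mats <- lapply(curves, function(cv) {
    stopifnot(identical(cv$bin_center_deg, grid))
    pk <- max(cv$mean_rate)
    if (pk <= 0) return(NULL)
    cv$mean_rate / pk
  })
  drop <- vapply(mats, is.null, logical(1))
  if (any(drop)) warning(sum(drop), " zero-peak units excluded")
  mats <- mats[!drop]
  if (length(mats) == 0) stop("no usable curves", call. = FALSE)
  m <- do.call(rbind, mats)
  out <- data.frame(
    frame = curves[[1]]$frame[1],
    bin_center_deg = grid,
    mean_rate = colMeans(m),
    sem = apply(m, 2, stats::sd) / sqrt(nrow(m)),
    n = nrow(m),
    bin_width_deg = curves[[1]]$bin_width_deg[1]
  )
  attr(out, "argmax_deg") <- grid[which.max(out$mean_rate)]
  class(out) <- c("tuning_curve", "data.frame")
  out
}
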