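#' Occupancy-normalized baseline speed-rate function
#'
#' Takes all exploration time excluding the 50 ms after each click onset,
#' looks up the head speed at the time of each background spike, and divides
#' the spike count per speed bin by the time spent in that bin — an unbiased
#' rate-versus-speed function regardless of how speed was sampled.
#'
#' @param spikes spike times, seconds.
#' @param clicks click schedule (its evoked windows are excluded).
#' @param traj trajectory with `speed_cm_s`.
#' @param bin_width_cm_s speed bin width, cm/s.
#' @param exclude_s length of the post-click exclusion window, seconds.
#' @return data frame (`speed_mid_cm_s`, `occupancy_s`, `n_spikes`,
#'   `rate_hz`); empty bins are dropped.
#' @export
baseline_speed_rate <- function(spikes, clicks, traj, bin_width_cm_s = 1,
                                exclude_s = 0.05) {
  stopifnot(!is.null(traj$speed_cm_s))
  dt <- diff(traj$t_s)
  dt <- c(dt, dt[length(dt)])
  # frames whose time falls inside any (click, click + exclude] window
  in_evoked <- function(t) {
    i <- findInterval(t, clicks$t_s)
    i > 0 & (t - clicks$t_s[pmax(i, 1)]) <= exclude_s &
      (t - clicks$t_s[pmax(i, 1)]) > 0
  }
  keep_frame <- !in_evoked(traj$t_s) & !is.na(traj$speed_cm_s)
  spikes <- spikes[!in_evoked(spikes)]
  sp_speed <- traj$speed_cm_s[nearest_frame(traj$t_s, spikes)]
  sp_speed <- sp_speed[!is.na(sp_speed)]
  brk <- function(v) floor(v / bin_width_cm_s)
  occ <- tapply(dt[keep_frame], brk(traj$speed_cm_s[keep_frame]), sum)
  cnt <- table(brk(sp_speed))
  bins <- sort(as.numeric(names(occ)))
  n_spk <- as.numeric(cnt[as.character(bins)])
  n_spk[is.na(n_spk)] <- 0
  out <- data.frame(
    speed_mid_cm_s = (bins + 0.5) * bin_width_cm_s,
    occupancy_s = as.numeric(occ[as.character(bins)]),
    n_spikes = n_spk
  )
  out <- out[out$occupancy_s > 0, , drop = FALSE]
  out$rate_hz <- out$n_spikes / out$occupancy_s
  out
}

#' Exponential fit of a speed-rate function
#'
#' Fits `rate = r0 * exp(beta * speed)` by ordinary least squares on the log
#' rates of positive-rate bins. `beta > 0` indicates firing increases with
#' head speed; `beta = log(2) / 10` corresponds to a rate doubling every
#' 10 cm/s.
#'
#' @param fn a speed-rate function from [baseline_speed_rate()].
#' @return list with `beta` (per cm/s), `r0_hz`, `r2`.
#' @export
fit_exponential_speed <- function(fn) {
  pos <- fn$rate_hz > 0
  if (sum(pos) < 3) stop("need >= 3 positive-rate bins", call. = FALSE)
  fit <- stats::lm(log(rate_hz) ~ speed_mid_cm_s, data = fn[pos, ])
  sm <- summary(fit)
  list(beta = unname(stats::coef(fit)[2]),
       r0_hz = exp(unname(stats::coef(fit)[1])),
       r2 = sm$r.squared)
}

#' Poisson GLM of evoked responses on head speed
#'
#' Measures both the strength (analysis-of-deviance p value) and direction
#' (coefficient beta) of the relationship between evoked spike counts and the
#' head speed at stimulus onset.
#'
#' @param trials data frame from [trial_responses()] with `speed_cm_s`.
#' @param alpha significance criterion (the conventional strict level 0.001).
#' @return list with `beta` (per cm/s), `p`, `significant`.
#' @export
evoked_speed_glm <- function(trials, alpha = 0.001) {
  v <- trials$speed_cm_s
  s <- stats::sd(v, na.rm = TRUE)
  if (all(is.na(v)) || is.na(s) || s == 0) {
    stop("degenerate speed spread", call. = FALSE)
  }
  ok <- !is.na(v)
  fit <- stats::glm(trials$evoked_count[ok] ~ v[ok],
                    family = stats::poisson())
  p <- stats::anova(fit, test = "Chisq")[["Pr(>Chi)"]][2]
  list(beta = unname(stats::coef(fit)[2]), p = p, significant = p < alpha)
}

#' Tuning curves conditioned on distance or speed strata
#'
#' Splits trials into strata of head-source distance (default edges 100, 200,
#' 300, 400 mm) or head speed (default 6 quantile bins of the session speed
#' distribution), and computes the head-frame tuning curve, modulation depth,
#' preferred location, and min/max rates within each stratum.
#'
#' @param trials data frame from [trial_responses()].
#' @param condition `"distance"` or `"speed"`.
#' @param edges stratum edges; `NULL` uses the defaults above.
#' @param frame,bin_width_deg,range_deg tuning-curve parameters.
#' @param min_per_bin strata in which any angular bin holds fewer trials are
#'   flagged (`complete = FALSE`) and should be excluded from group stats.
#' @return data frame with one row per stratum: `stratum`, `lo`, `hi`,
#'   `n_trials`, `md_pct`, `preferred_deg`, `min_hz`, `max_hz`, `complete`;
#'   the per-stratum curves are in `attr(, "curves")`.
#' @export
conditioned_tuning <- function(trials, condition = c("distance", "speed"),
                               edges = NULL, frame = "head",
                               bin_width_deg = 30, range_deg = 90,
                               min_per_bin = 5) {
  condition <- match.arg(condition)
  v <- if (condition == "distance") trials$hs_distance_mm else trials$speed_cm_s
  if (is.null(edges)) {
    edges <- if (condition == "distance") {
      c(100, 200, 300, 400)
    } else {
      unique(stats::quantile(v, probs = seq(0, 1, length.out = 7),
                             na.rm = TRUE, names = FALSE))
    }
  }
  strata <- cut(v, breaks = edges, include.lowest = TRUE)
  n_bins_expected <- length(seq(-range_deg, range_deg, by = bin_width_deg))
  curves <- list()
  rows <- lapply(levels(strata), function(lv) {
    tr <- trials[!is.na(strata) & strata == lv, , drop = FALSE]
    i <- which(levels(strata) == lv)
    if (nrow(tr) == 0) {
      return(data.frame(stratum = lv, lo = edges[i], hi = edges[i + 1],
                        n_trials = 0, md_pct = NA_real_,
                        preferred_deg = NA_real_, min_hz = NA_real_,
                        max_hz = NA_real_, complete = FALSE))
    }
    cv <- tuning_curve(tr, frame = frame, bin_width_deg = bin_width_deg,
                       range_deg = range_deg, min_n = min_per_bin)
    curves[[lv]] <<- cv
    complete <- nrow(cv) == n_bins_expected && !any(cv$below_min)
    data.frame(
      stratum = lv, lo = edges[i], hi = edges[i + 1], n_trials = nrow(tr),
      md_pct = modulation_depth(cv),
      preferred_deg = cv$bin_center_deg[which.max(cv$mean_rate)],
      min_hz = min(cv$mean_rate), max_hz = max(cv$mean_rate),
      complete = complete
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "curves") <- curves
  out
}
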