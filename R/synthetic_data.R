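#' Deterministic pirouette trajectory
#'
#' The head translates around a circle while rotating continuously: position
#' angle advances `trans_step_deg` per step on a circle of radius `radius_mm`,
#' and head direction advances `rot_step_deg` per step. With the defaults
#' (50 mm, 30 deg/step, 10 deg/step, 7200 steps) every 10-degree head
#' direction bin is visited exactly 200 times, so head direction is sampled
#' perfectly uniformly — the behavior under which tuning in the irrelevant
#' coordinate frame averages flat.
#'
#' @param radius_mm circle radius, mm.
#' @param trans_step_deg translation angular speed, degrees per step.
#' @param rot_step_deg rotation angular speed, degrees per step.
#' @param n_steps number of steps.
#' @param fps nominal frame rate used to assign times, frames/s.
#' @return trajectory data frame (`t_s`, `x_mm`, `y_mm`, `dir_deg`).
#' @export
pirouette_trajectory <- function(radius_mm = 50, trans_step_deg = 30,
                                 rot_step_deg = 10, n_steps = 7200,
                                 fps = 30) {
  i <- seq_len(n_steps) - 1
  pos_ang <- (i * trans_step_deg) * pi / 180
  data.frame(
    t_s = i / fps,
    x_mm = radius_mm * cos(pos_ang),
    y_mm = radius_mm * sin(pos_ang),
    dir_deg = wrap_angle(i * rot_step_deg)
  )
}

#' Stochastic foraging trajectory with a front-facing bias
#'
#' Smooth random head movement inside the arena. Head direction and movement
#' direction are modeled separately, as in a foraging animal that scans with
#' its head while its body drifts: head direction follows a Langevin
#' diffusion on the circle whose stationary distribution is von Mises
#' centered on the arena front (+x) — drift `-D * kappa * sin(theta)`,
#' diffusion `sqrt(2 D)` — so `dir_bias_kappa` is the von Mises concentration
#' (0 = uniform). The position advances along an independent, unbiased
#' heading diffusion at a speed drawn from a smooth log-normal AR(1) process;
#' steps that would leave the arena are redirected toward the center.
#'
#' @param duration_s session length, seconds (> 0).
#' @param dir_bias_kappa von Mises concentration of the head-direction
#'   stationary distribution (>= 0).
#' @param speed_mean_cm_s,speed_cv mean and coefficient of variation of the
#'   log-normal marginal speed distribution.
#' @param speed_ar lag-1 autocorrelation of log-speed between frames.
#' @param dir_diffusion D, angular diffusion constant, rad^2/s.
#' @param arena an `arena_model` providing the bounds.
#' @param fps frame rate, frames/s.
#' @param seed integer seed; identical seeds give identical trajectories.
#' @return trajectory data frame (`t_s`, `x_mm`, `y_mm`, `dir_deg`,
#'   `speed_cm_s`).
#' @export
foraging_trajectory <- function(duration_s, dir_bias_kappa = 1.5,
                                speed_mean_cm_s = 8, speed_cv = 0.8,
                                speed_ar = 0.97, dir_diffusion = 1.5,
                                arena = make_arena(), fps = 30, seed = 1) {
  if (duration_s <= 0) stop("duration must be positive", call. = FALSE)
  if (dir_bias_kappa < 0) stop("kappa must be >= 0", call. = FALSE)
  set.seed(seed)
  dt <- 1 / fps
  n <- max(2L, floor(duration_s * fps))
  # log-speed AR(1) with log-normal marginal
  sdlog <- sqrt(log(1 + speed_cv^2))
  mulog <- log(speed_mean_cm_s) - sdlog^2 / 2
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  innov <- stats::rnorm(n)
  for (i in 2:n) z[i] <- speed_ar * z[i - 1] + sqrt(1 - speed_ar^2) * innov[i]
  speed <- exp(mulog + sdlog * z)  # cm/s
  th <- numeric(n)   # head direction, radians
  ph <- numeric(n)   # movement heading, radians
  x <- numeric(n); y <- numeric(n)
  th[1] <- stats::runif(1, -pi, pi)
  ph[1] <- stats::runif(1, -pi, pi)
  head_noise <- stats::rnorm(n, sd = sqrt(2 * dir_diffusion * dt))
  move_noise <- stats::rnorm(n, sd = sqrt(2 * dir_diffusion * dt))
  bounce_noise <- stats::rnorm(n, sd = 0.3)
  for (i in 2:n) {
    th[i] <- th[i - 1] -
      dir_diffusion * dir_bias_kappa * sin(th[i - 1]) * dt + head_noise[i]
    ph_i <- ph[i - 1] + move_noise[i]
    step <- speed[i] * 10 * dt  # mm per frame
    xp <- x[i - 1] + step * cos(ph_i)
    yp <- y[i - 1] + step * sin(ph_i)
    if (!in_arena(arena, xp, yp)) {
      # redirect the walk toward the arena center
      ph_i <- atan2(-y[i - 1], -x[i - 1]) + bounce_noise[i]
      xp <- x[i - 1] + step * cos(ph_i)
      yp <- y[i - 1] + step * sin(ph_i)
      if (!in_arena(arena, xp, yp)) { xp <- x[i - 1]; yp <- y[i - 1] }
    }
    ph[i] <- ph_i
    x[i] <- xp
    y[i] <- yp
  }
  t_s <- (seq_len(n) - 1) * dt
  traj <- data.frame(
    t_s = t_s, x_mm = x, y_mm = y,
    dir_deg = wrap_angle(th * 180 / pi)
  )
  traj$speed_cm_s <- head_speed(traj$x_mm, traj$y_mm, traj$t_s)
  traj
}

#' Pseudo-random click schedule
#'
#' Clicks with inter-stimulus intervals uniform on \[250, 500\] ms, speaker
#' identity drawn uniformly from the arena's speakers, and nominal level roved
#' uniformly over \[54, 60\] dB SPL (a +/- 3 dB rove either side of 57; the
#' calibrated 60 dB level is the rove ceiling).
#'
#' @param duration_s schedule length, seconds (> 0.5).
#' @param arena an `arena_model`.
#' @param isi_range_s inter-click interval range, seconds.
#' @param level_range_db nominal level range, dB SPL.
#' @param seed integer seed.
#' @return data frame (`t_s`, `speaker_id`, `nominal_level_db`).
#' @export
click_schedule <- function(duration_s, arena = make_arena(),
                           isi_range_s = c(0.25, 0.5),
                           level_range_db = c(54, 60), seed = 1) {
  if (duration_s <= 0.5) stop("duration must exceed 0.5 s", call. = FALSE)
  set.seed(seed)
  n_max <- ceiling(duration_s / isi_range_s[1]) + 1
  isi <- stats::runif(n_max, isi_range_s[1], isi_range_s[2])
  t <- cumsum(isi)
  t <- t[t < duration_s]
  n <- length(t)
  data.frame(
    t_s = t,
    speaker_id = sample.int(length(arena$speaker_angles_deg), n, replace = TRUE),
    nominal_level_db = stats::runif(n, level_range_db[1], level_range_db[2])
  )
}

#' Specification of a synthetic spiking unit
#'
#' @param field a `receptive_field` or `NULL` for an untuned unit.
#' @param baseline_rate_hz background firing rate at zero speed, Hz.
#' @param evoked_gain_hz evoked rate (Hz) per unit spike probability; each
#'   click contributes a Poisson count with mean
#'   `evoked_gain_hz * P(stimulus) * 0.05` in the 50 ms after onset.
#' @param speed_beta exponential speed coefficient on the baseline, per cm/s.
#' @param speed_on_evoked if `TRUE` the evoked gain is also scaled by
#'   `exp(speed_beta * v)`.
#' @param seed integer seed for spike generation.
#' @return object of class `synthetic_unit`.
#' @export
synthetic_unit <- function(field = NULL, baseline_rate_hz = 5,
                           evoked_gain_hz = 60, speed_beta = 0,
                           speed_on_evoked = FALSE, seed = 1) {
  if (baseline_rate_hz < 0 || evoked_gain_hz < 0) {
    stop("rates must be non-negative", call. = FALSE)
  }
  structure(list(field = field, baseline_rate_hz = baseline_rate_hz,
                 evoked_gain_hz = evoked_gain_hz, speed_beta = speed_beta,
                 speed_on_evoked = speed_on_evoked, seed = seed),
            class = "synthetic_unit")
}

#' Simulate a spike train for a synthetic unit
#'
#' Background spikes arise from an inhomogeneous Poisson process with rate
#' `baseline * exp(speed_beta * v(t))` evaluated per video frame; each click
#' adds an evoked Poisson count placed uniformly within the 50 ms after click
#' onset, with mean `evoked_gain * P(stimulus) * 0.05 s`, where `P` is the
#' unit's deterministic field response to the click's stimulus geometry
#' (`P = 1` for an untuned unit).
#'
#' @param unit a `synthetic_unit`.
#' @param traj trajectory data frame; must carry `speed_cm_s` if
#'   `speed_beta != 0`.
#' @param clicks click schedule data frame.
#' @param arena an `arena_model`.
#' @return sorted numeric vector of spike times, seconds. Clicks outside the
#'   tracked span are skipped with a warning.
#' @export
simulate_spikes <- function(unit, traj, clicks, arena = make_arena()) {
  stopifnot(inherits(unit, "synthetic_unit"))
  set.seed(unit$seed)
  n <- nrow(traj)
  dt <- diff(traj$t_s)
  dt <- c(dt, dt[length(dt)])
  v <- if (!is.null(traj$speed_cm_s)) traj$speed_cm_s else numeric(n)
  lambda <- unit$baseline_rate_hz * exp(unit$speed_beta * v)
  counts <- stats::rpois(n, lambda * dt)
  bg <- rep(traj$t_s, counts) + stats::runif(sum(counts)) * rep(dt, counts)

  span <- range(traj$t_s)
  in_span <- clicks$t_s >= span[1] & clicks$t_s <= span[2]
  if (any(!in_span)) {
    warning(sum(!in_span), " clicks outside the tracked span were skipped")
    clicks <- clicks[in_span, , drop = FALSE]
  }
  idx <- nearest_frame(traj$t_s, clicks$t_s)
  sp <- speaker_positions(arena)
  g <- stimulus_geometry(traj$x_mm[idx], traj$y_mm[idx], traj$dir_deg[idx],
                         sp$x_mm[clicks$speaker_id], sp$y_mm[clicks$speaker_id],
                         arena)
  p <- if (is.null(unit$field)) {
    rep(1, nrow(clicks))
  } else {
    field_response(unit$field, data.frame(theta_hs_deg = g$theta_hs_deg,
                                          src_x_mm = sp$x_mm[clicks$speaker_id],
                                          src_y_mm = sp$y_mm[clicks$speaker_id]))
  }
  gain <- unit$evoked_gain_hz
  if (unit$speed_on_evoked) gain <- gain * exp(unit$speed_beta * v[idx])
  ev_counts <- stats::rpois(nrow(clicks), gain * p * 0.05)
  ev <- rep(clicks$t_s, ev_counts) + stats::runif(sum(ev_counts)) * 0.05
  sort(c(bg, ev))
}

# Index of the nearest frame time for each query time.
nearest_frame <- function(frame_times, query_times) {
  idx <- findInterval(query_times, frame_times, all.inside = TRUE)
  lower_closer <- (query_times - frame_times[idx]) <=
    (frame_times[pmin(idx + 1, length(frame_times))] - query_times)
  ifelse(lower_closer, idx, pmin(idx + 1, length(frame_times)))
}

#' Summarize session behavior
#'
#' Computes the circular (default) or linear standard deviation of head
#' directions, the squared Pearson correlation between the sound angle in the
#' head and in the world across clicks, and occupancy histograms of position,
#' direction, speed, head-source distance and level at the head. All
#' click-locked values are taken at the nearest video frame (lag 0).
#'
#' @param traj trajectory data frame.
#' @param clicks click schedule data frame.
#' @param arena an `arena_model`.
#' @param circular_sd if `FALSE`, use the linear SD of wrapped directions
#'   (fidelity-check fallback) instead of the circular SD.
#' @return object of class `behavior_summary`: list with `sigma_dir_deg`,
#'   `r2_head_world`, and a `histograms` list.
#' @export
behavior_summary <- function(traj, clicks, arena = make_arena(),
                             circular_sd = TRUE) {
  ok <- !is.na(traj$dir_deg) & !is.na(traj$x_mm)
  if (!any(ok)) stop("no valid poses", call. = FALSE)
  sigma <- if (circular_sd) {
    circ_sd_deg(traj$dir_deg[ok])
  } else {
    stats::sd(wrap_angle(traj$dir_deg[ok]))
  }
  idx <- nearest_frame(traj$t_s, clicks$t_s)
  sp <- speaker_positions(arena)
  g <- stimulus_geometry(traj$x_mm[idx], traj$y_mm[idx], traj$dir_deg[idx],
                         sp$x_mm[clicks$speaker_id], sp$y_mm[clicks$speaker_id],
                         arena, nominal_level_db = clicks$nominal_level_db)
  r2 <- suppressWarnings(stats::cor(g$theta_hs_deg, g$theta_ws_deg)^2)
  if (is.na(r2)) r2 <- if (stats::sd(g$theta_hs_deg) == 0 &&
                           stats::sd(g$theta_ws_deg) == 0) 1 else 0
  hist_of <- function(x, breaks) {
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    data.frame(mid = h$mids, count = h$counts)
  }
  hs <- list(
    direction = hist_of(wrap_angle(traj$dir_deg[ok]), seq(-180, 180, by = 10)),
    position_x = hist_of(traj$x_mm[ok], 25),
    position_y = hist_of(traj$y_mm[ok], 25),
    distance = hist_of(g$hs_distance_mm, 25),
    level = hist_of(g$level_at_head_db, 25)
  )
  if (!is.null(traj$speed_cm_s)) {
    hs$speed <- hist_of(traj$speed_cm_s[ok], 25)
  }
  structure(list(sigma_dir_deg = sigma, r2_head_world = r2, histograms = hs),
            class = "behavior_summary")
}

#' @export
print.behavior_summary <- function(x, ...) {
  cat(sprintf("<behavior_summary> sigma_dir = %.1f deg, r2(head, world) = %.3f\n",
              x$sigma_dir_deg, x$r2_head_world))
  invisible(x)
}

# Circular standard deviation in degrees: sqrt(-2 log R).
circ_sd_deg <- function(dir_deg) {
  th <- dir_deg * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  sqrt(-2 * log(pmax(R, .Machine$double.xmin))) * 180 / pi
}

#' Generate a complete synthetic session bundle
#'
#' Composes a foraging trajectory, a click schedule, and one spike train per
#' requested unit into an in-memory session bundle that passes the same schema
#' validation as a recorded session (see [read_session()]).
#'
#' @param duration_s session length, seconds.
#' @param units named list of `synthetic_unit` objects.
#' @param arena an `arena_model`.
#' @param dir_bias_kappa head-direction bias passed to
#'   [foraging_trajectory()]; the default reproduces the moderately
#'   front-biased behavioral regime in which the head/world angle correlation
#'   is about 0.25.
#' @param seed master seed; trajectory, clicks and each unit derive distinct
#'   sub-seeds from it.
#' @param ... further arguments to [foraging_trajectory()].
#' @return object of class `session_bundle` with elements `arena`, `poses`,
#'   `clicks`, `spikes` (named list of spike-time vectors), `meta`.
#' @export
simulate_session <- function(duration_s = 600,
                             units = list(u1 = synthetic_unit(ego_field())),
                             arena = make_arena(), dir_bias_kappa = 1.5,
                             seed = 1, ...) {
  traj <- foraging_trajectory(duration_s, dir_bias_kappa = dir_bias_kappa,
                              arena = arena, seed = seed, ...)
  clicks <- click_schedule(duration_s, arena, seed = seed + 1000L)
  spikes <- list()
  for (i in seq_along(units)) {
    u <- units[[i]]
    u$seed <- seed + 2000L + i
    spikes[[i]] <- simulate_spikes(u, traj, clicks, arena)
  }
  names(spikes) <- names(units)
  structure(
    list(arena = arena, poses = traj, clicks = clicks, spikes = spikes,
         meta = list(source = "synthetic", seed = seed,
                     dir_bias_kappa = dir_bias_kappa,
                     duration_s = duration_s)),
    class = "session_bundle"
  )
}

#' Simulate a cohort of egocentric and allocentric spiking units
#'
#' Builds a set of foraging sessions and populates them with synthetic
#' spiking units of known coordinate frame: egocentric units with preferred
#' head-relative angles spread over the frontal and lateral field, and
#' allocentric units with spatial loci spread around and beyond the speaker
#' ring. Evoked gain is normalized per unit so the best speaker drives
#' approximately the same peak rate for every unit. This is the standard
#' test bed for end-to-end frame-recovery studies.
#'
#' @param n_ego,n_allo number of units of each type.
#' @param n_sessions number of behavioral sessions the units are spread over.
#' @param duration_s session length, seconds (~2.7 clicks/s).
#' @param dir_bias_kappa head-direction bias of the foraging behavior.
#' @param arena an `arena_model`.
#' @param peak_rate_hz evoked rate at the best speaker, Hz.
#' @param baseline_rate_hz background rate, Hz.
#' @param seed master seed.
#' @return list with `sessions` (list of `session_bundle`s) and `truth`
#'   (data frame: `unit_id`, `session`, `type`, `pref_deg` — the generating
#'   preferred head angle for ego units, the world angle of the locus for
#'   allo units).
#' @export
simulate_frame_cohort <- function(n_ego = 20, n_allo = 20, n_sessions = 4,
                                  duration_s = 750, dir_bias_kappa = 1.5,
                                  arena = make_arena(), peak_rate_hz = 60,
                                  baseline_rate_hz = 5, seed = 1) {
  sp <- speaker_positions(arena)
  specs <- list()
  truth <- list()
  for (i in seq_len(n_ego)) {
    b <- seq(-120, 120, length.out = n_ego)[i]
    cw <- 40 + 40 * (i - 1) / max(1, n_ego - 1)
    f <- ego_field(a = 1, b = b, c_deg = cw)
    id <- sprintf("ego%02d", i)
    specs[[id]] <- synthetic_unit(f, baseline_rate_hz, peak_rate_hz)
    truth[[id]] <- data.frame(unit_id = id, type = "ego", pref_deg = b)
  }
  for (i in seq_len(n_allo)) {
    phi <- seq(-90, 90, length.out = n_allo)[i] * pi / 180
    r <- 700 + 500 * (i %% 4) / 3
    f <- allo_field(mu_x = r * cos(phi), s_x = 300 + 60 * (i %% 5),
                    mu_y = r * sin(phi), s_y = 500 + 100 * (i %% 4))
    peak_p <- max(allo_response(f, sp$x_mm, sp$y_mm))
    id <- sprintf("allo%02d", i)
    specs[[id]] <- synthetic_unit(f, baseline_rate_hz, peak_rate_hz / peak_p)
    truth[[id]] <- data.frame(unit_id = id, type = "allo",
                              pref_deg = wrap_angle(phi * 180 / pi))
  }
  assignment <- rep(seq_len(n_sessions), length.out = length(specs))
  sessions <- lapply(seq_len(n_sessions), function(s) {
    simulate_session(duration_s = duration_s,
                     units = specs[assignment == s],
                     arena = arena, dir_bias_kappa = dir_bias_kappa,
                     seed = seed + s * 37L)
  })
  tr <- do.call(rbind, truth)
  tr$session <- assignment[match(tr$unit_id, names(specs))]
  rownames(tr) <- NULL
  list(sessions = sessions, truth = tr)
}
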