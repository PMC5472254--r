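# Lazily computed, cached fixtures shared across test files. Everything is
# generated in code at test time; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx, inherits = FALSE)) {
    assign(name, expr, envir = .fx)
  }
  get(name, envir = .fx, inherits = FALSE)
}

# A 36-speaker ring arena (1000 mm) and pirouette epochs: the deterministic
# setting for noise-free receptive-field simulations.
fx_ring <- function() fixture("ring", make_ring_arena())

fx_pirouette_epochs <- function() {
  fixture("pirouette_epochs",
          stimulus_epochs(pirouette_trajectory(), fx_ring()))
}

# One moderately front-biased foraging session carrying an egocentric, an
# allocentric and an untuned synthetic unit (10 min, ~1600 clicks).
fx_session <- function() {
  fixture("session", simulate_session(
    duration_s = 600,
    units = list(
      ego = synthetic_unit(ego_field(), baseline_rate_hz = 5,
                           evoked_gain_hz = 60),
      allo = synthetic_unit(allo_field(), baseline_rate_hz = 5,
                            evoked_gain_hz = 60 / allo_response(allo_field(),
                                                                1000, 0)),
      flat = synthetic_unit(NULL, baseline_rate_hz = 5, evoked_gain_hz = 20)
    ),
    seed = 101
  ))
}

fx_trials <- function(unit = "ego") {
  s <- fx_session()
  fixture(paste0("trials_", unit),
          trial_responses(s$spikes[[unit]], s$clicks, s$poses, s$arena))
}

# Construct aligned-condition trials directly: head at the aligned reference
# point facing forward, speakers at the 7 ring angles, Poisson counts from a
# supplied rate function of the head-frame angle.
make_aligned_trials <- function(n_per_bin, rate_hz_fun, seed = 1,
                                window_s = 0.05) {
  set.seed(seed)
  th <- rep(seq(-90, 90, by = 30), each = n_per_bin)
  counts <- stats::rpois(length(th), rate_hz_fun(th) * window_s)
  out <- data.frame(
    t_s = seq_along(th),
    speaker_id = rep(1:7, each = n_per_bin),
    theta_hs_deg = th,
    theta_ws_deg = th,
    hs_distance_mm = 260,
    level_at_head_db = 60,
    head_x_mm = -25, head_y_mm = 0, head_dir_deg = 0,
    speed_cm_s = 5,
    evoked_count = counts,
    background_count = 0,
    evoked_rate_hz = counts / window_s,
    background_rate_hz = 0
  )
  attr(out, "window_s") <- window_s
  out
}

# Circular cross-correlation lag (in bins) maximizing the correlation of two
# curves on the same circular grid; positive lag means `a` is `b` shifted
# forward (a[i] ~ b[i - lag]).
circular_best_lag <- function(a, b) {
  n <- length(a)
  lags <- 0:(n - 1)
  cc <- vapply(lags, function(l) {
    stats::cor(a, b[((seq_len(n) - 1 - l) %% n) + 1])
  }, numeric(1))
  best <- lags[which.max(cc)]
  if (best > n / 2) best - n else best
}

# Sigma ladder of behavioral sessions (poses + clicks only) used to fit the
# residual-modulation regressions: 30 sessions spanning weak to strong
# front-facing bias.
fx_ladder <- function() {
  fixture("ladder", {
    kappas <- rep(c(0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 12), 3)
    a <- make_arena()
    lapply(seq_along(kappas), function(i) {
      list(arena = a,
           poses = foraging_trajectory(300, dir_bias_kappa = kappas[i],
                                       arena = a, seed = 700 + i),
           clicks = click_schedule(300, a, seed = 800 + i))
    })
  })
}

fx_ladder_residuals <- function() {
  fixture("ladder_residuals",
          suppressWarnings(simulate_session_residuals(fx_ladder())))
}

fx_residual_models <- function() {
  fixture("residual_models", {
    r <- fx_ladder_residuals()
    list(
      # head frame irrelevant for the allocentric template
      head = fit_residual_regression(r$sigma_dir_deg, r$residual_allo),
      # world frame irrelevant for the egocentric template
      world = fit_residual_regression(r$sigma_dir_deg, r$residual_ego)
    )
  })
}

# Frame-recovery cohort: 20 ego + 20 allo spiking units across 4 foraging
# sessions (~2000 clicks each), analyzed end to end.
fx_cohort <- function() {
  fixture("cohort", simulate_frame_cohort(seed = 501))
}

fx_cohort_results <- function() {
  fixture("cohort_results", {
    co <- fx_cohort()
    rows <- list()
    for (s_idx in seq_along(co$sessions)) {
      s <- co$sessions[[s_idx]]
      for (u in names(s$spikes)) {
        tr <- trial_responses(s$spikes[[u]], s$clicks, s$poses, s$arena)
        ch <- tuning_curve(tr, "head")
        cw <- tuning_curve(tr, "world")
        ch360 <- tuning_curve(tr, "head", range_deg = 180)
        fits <- fit_glm_set(tr)
        rows[[u]] <- data.frame(
          unit_id = u, session = s_idx, n_trials = nrow(tr),
          md_head = modulation_depth(ch), md_world = modulation_depth(cw),
          pref_head_deg = ch360$bin_center_deg[which.max(ch360$mean_rate)],
          aic_label = classify_aic(fits)$label,
          fit_head = model_scores(fits)$fit_head_pct,
          fit_world = model_scores(fits)$fit_world_pct
        )
      }
    }
    res <- do.call(rbind, rows)
    rownames(res) <- NULL
    merge(res, fx_cohort()$truth[, c("unit_id", "type", "pref_deg")],
          by = "unit_id")
  })
}
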