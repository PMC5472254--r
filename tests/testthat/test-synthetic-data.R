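test_that("pirouette trajectory is on-circle, direction-uniform and periodic", {
  tr <- pirouette_trajectory()
  expect_equal(sqrt(tr$x_mm^2 + tr$y_mm^2), rep(50, 7200), tolerance = 1e-9)
  tab <- table(tr$dir_deg)
  expect_equal(length(tab), 36)
  expect_true(all(tab == 200))
  # step 0 and step 36: direction advanced 360, position advanced 1080
  expect_equal(tr$dir_deg[1], tr$dir_deg[37])
  expect_equal(c(tr$x_mm[1], tr$y_mm[1]), c(tr$x_mm[37], tr$y_mm[37]),
               tolerance = 1e-9)
})

test_that("foraging trajectory: seeded determinism, in-bounds, kappa controls spread", {
  a <- make_arena()
  t1 <- foraging_trajectory(60, seed = 5, arena = a)
  t2 <- foraging_trajectory(60, seed = 5, arena = a)
  expect_identical(t1, t2)
  expect_true(all(in_arena(a, t1$x_mm, t1$y_mm)))
  expect_true(all(t1$dir_deg > -180 & t1$dir_deg <= 180))
  expect_error(foraging_trajectory(0), "positive")

  # kappa = 0: uniform direction histogram. The heading diffusion mixes over
  # ~1 s, so subsample every 5 s for approximately independent draws before
  # the chi-squared test.
  t0 <- foraging_trajectory(3600, dir_bias_kappa = 0, seed = 11, arena = a)
  sub <- t0$dir_deg[seq(1, nrow(t0), by = 150)]
  bins <- cut(sub, seq(-180, 180, by = 10))
  p <- suppressWarnings(chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)

  # concentration shrinks the circular spread monotonically
  sig <- vapply(c(0, 1.5, 4), function(k) {
    tr <- foraging_trajectory(600, dir_bias_kappa = k, seed = 13, arena = a)
    behavior_summary(tr, click_schedule(600, a, seed = 14), a)$sigma_dir_deg
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
})

test_that("click schedule honors ISI, level rove and speaker uniformity", {
  a <- make_arena()
  cl <- click_schedule(600, a, seed = 3)
  isi <- diff(cl$t_s)
  expect_true(all(isi >= 0.25 & isi <= 0.5))
  expect_true(all(cl$nominal_level_db >= 54 & cl$nominal_level_db <= 60))
  expect_gte(nrow(cl), 1200)
  expect_lte(nrow(cl), 2400)
  big <- click_schedule(4000, a, seed = 4)  # ~1e4 clicks
  p <- suppressWarnings(chisq.test(table(big$speaker_id))$p.value)
  expect_gt(p, 0.01)
  expect_error(click_schedule(0.3), "duration")
})

test_that("untuned unit's empirical rate matches its Poisson baseline", {
  a <- make_arena()
  tr <- foraging_trajectory(600, seed = 21, arena = a)
  cl <- click_schedule(600, a, seed = 22)
  u <- synthetic_unit(NULL, baseline_rate_hz = 5, evoked_gain_hz = 0, seed = 23)
  spk <- simulate_spikes(u, tr, cl, a)
  rate <- length(spk) / 600
  se <- sqrt(5 / 600)
  expect_lt(abs(rate - 5), 3 * se)
})

test_that("evoked counts follow the egocentric field: all at the peak, none opposite", {
  a <- make_arena()
  n <- 400
  traj <- data.frame(t_s = seq(0, by = 1 / 30, length.out = 30 * 400),
                     x_mm = 0, y_mm = 0, dir_deg = 0)
  # alternate clicks at the preferred speaker (0 deg) and at +/-180 impossible
  # on the 7-speaker ring; instead compare 0 deg vs 90 deg with a narrow field
  cl <- data.frame(t_s = seq(1, by = 0.35, length.out = n),
                   speaker_id = rep(c(4L, 7L), n / 2),
                   nominal_level_db = 57)
  u <- synthetic_unit(ego_field(a = 1, b = 0, c_deg = 30), baseline_rate_hz = 0,
                      evoked_gain_hz = 100, seed = 9)
  spk <- simulate_spikes(u, traj, cl, a)
  tt <- trial_responses(spk, cl, traj, a)
  m_pref <- mean(tt$evoked_count[tt$speaker_id == 4])
  m_orth <- mean(tt$evoked_count[tt$speaker_id == 7])
  expected_ratio <- exp(-90^2 / (2 * 30^2))
  expect_gt(m_pref, 3)
  expect_lt(m_orth / m_pref, expected_ratio + 0.05)
})

test_that("speed-modulated baseline is recovered by the downstream exponential fit", {
  a <- make_arena()
  tr <- foraging_trajectory(600, seed = 31, arena = a)
  cl <- click_schedule(600, a, seed = 32)
  beta_true <- 0.0693  # doubling per 10 cm/s
  u <- synthetic_unit(NULL, baseline_rate_hz = 8, evoked_gain_hz = 0,
                      speed_beta = beta_true, seed = 33)
  spk <- simulate_spikes(u, tr, cl, a)
  fn <- baseline_speed_rate(spk, cl, tr, bin_width_cm_s = 2)
  fit <- fit_exponential_speed(fn[fn$occupancy_s > 2, ])
  expect_lt(abs(fit$beta - beta_true) / beta_true, 0.2)
})

test_that("behavior summary captures frame alignment and decorrelation", {
  a <- make_arena()
  # pirouette: uniform head direction decorrelates the frames
  tr <- pirouette_trajectory()
  cl <- click_schedule(200, a, seed = 41)
  bs <- behavior_summary(tr, cl, a)
  expect_lt(bs$r2_head_world, 0.02)
  # head fixed facing front at center: frames coincide
  trf <- data.frame(t_s = seq(0, 240, by = 1 / 30), x_mm = 0, y_mm = 0,
                    dir_deg = 0)
  bsf <- behavior_summary(trf, click_schedule(200, a, seed = 42), a)
  expect_equal(bsf$r2_head_world, 1, tolerance = 1e-9)
  expect_equal(bsf$sigma_dir_deg, 0, tolerance = 1e-6)
})

test_that("clicks outside the tracked span are skipped with a warning", {
  a <- make_arena()
  tr <- foraging_trajectory(30, seed = 51, arena = a)
  cl <- click_schedule(60, a, seed = 52)
  u <- synthetic_unit(NULL, baseline_rate_hz = 1, evoked_gain_hz = 10, seed = 53)
  expect_warning(simulate_spikes(u, tr, cl, a), "skipped")
})
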