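test_that("responsiveness screen: detects strong responses, controls type I error", {
  # strong response: 20 Hz evoked vs 5 Hz background
  tr <- make_aligned_trials(72, function(th) rep(20, length(th)), seed = 1)
  set.seed(2)
  tr$background_count <- rpois(nrow(tr), 5 * 0.05)
  scr <- screen_sound_responsive(tr)
  expect_lt(scr$p, 1e-6)
  expect_true(scr$responsive)

  # all-zero unit is non-responsive by definition
  tr0 <- tr
  tr0$evoked_count <- 0
  tr0$background_count <- 0
  expect_false(screen_sound_responsive(tr0)$responsive)
  expect_error(screen_sound_responsive(tr[1, ]), ">= 2")

  # null: evoked and background identically distributed
  set.seed(3)
  rej <- vapply(1:400, function(i) {
    n <- 150
    tr <- data.frame(evoked_count = rpois(n, 0.5),
                     background_count = rpois(n, 0.5))
    attr(tr, "window_s") <- 0.05
    screen_sound_responsive(tr)$responsive
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("aligned-condition filter applies the position and direction gates", {
  base <- data.frame(head_x_mm = -25, head_y_mm = 0, head_dir_deg = 0)
  tr <- rbind(
    base,                                              # at reference, facing front
    data.frame(head_x_mm = -25, head_y_mm = 55, head_dir_deg = 0),   # 55 mm off
    data.frame(head_x_mm = 0, head_y_mm = 0, head_dir_deg = 20),     # 20 deg off
    data.frame(head_x_mm = 20, head_y_mm = 20, head_dir_deg = -14)   # inside both
  )
  out <- aligned_subset(tr)
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_excluded"), 2)
})

test_that("tuning screen: power on the canonical field, bin-count gate, type I error", {
  f <- ego_field()
  tuned <- make_aligned_trials(100, function(th) 60 * ego_response(f, th),
                               seed = 4)
  res <- screen_spatial_tuning(tuned)
  expect_true(res$testable)
  expect_true(res$tuned)

  # 4 presentations in one bin -> untestable
  few <- make_aligned_trials(5, function(th) rep(10, length(th)), seed = 5)
  few <- few[-(1:1), ]  # knock one trial out of the first bin
  res2 <- screen_spatial_tuning(few)
  expect_false(res2$testable)
  expect_true(is.na(res2$tuned))

  set.seed(6)
  rej <- vapply(1:300, function(i) {
    tr <- make_aligned_trials(25, function(th) rep(10, length(th)),
                              seed = 1e6 + i)
    isTRUE(screen_spatial_tuning(tr)$tuned)
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.035)
})

test_that("residual modulation ratio handles the degenerate denominator", {
  expect_equal(residual_modulation(10, 40), 0.25)
  expect_equal(residual_modulation(30, 30), 1)
  expect_warning(r <- residual_modulation(10, 0), "undefined")
  expect_true(is.na(r))
})

test_that("session residuals: uniform behavior near zero, fixed head at one", {
  a <- make_arena()
  # head scanning uniformly at the arena center: 252 steps balance the
  # 36-point direction lattice against the 7 speakers exactly, so the
  # irrelevant-frame curves are flat by construction
  traj <- data.frame(t_s = (0:251) / 30, x_mm = 0, y_mm = 0,
                     dir_deg = wrap_angle((0:251) * 10))
  pir <- list(arena = a, poses = traj,
              clicks = data.frame(t_s = traj$t_s,
                                  speaker_id = rep(1:7, length.out = 252),
                                  nominal_level_db = 57))
  fixed <- list(arena = a,
                poses = data.frame(t_s = seq(0, 120, by = 1 / 30), x_mm = 0,
                                   y_mm = 0, dir_deg = 0),
                clicks = click_schedule(110, a, seed = 8))
  res <- simulate_session_residuals(list(pir, fixed))
  expect_lt(res$residual_ego[1], 0.01)
  expect_lt(res$residual_allo[1], 0.01)
  expect_equal(res$residual_ego[2], 1, tolerance = 1e-6)
  expect_equal(res$residual_allo[2], 1, tolerance = 1e-6)
})

test_that("residual regression: exact on noiseless data, interval ordering and coverage", {
  sig <- seq(20, 120, by = 10)
  resid <- 0.9 - 0.005 * sig
  m <- suppressWarnings(fit_residual_regression(sig, resid))
  expect_equal(m$slope, -0.005, tolerance = 1e-10)
  expect_equal(m$intercept, 0.9, tolerance = 1e-10)
  ci <- predict_residual_ci(m, 70, 0.95)
  expect_lt(ci$lower, ci$fit)
  expect_gt(ci$upper, ci$fit)
  ci_hi <- predict_residual_ci(m, 70, 0.9995)
  expect_gt(ci_hi$upper, ci$upper)
  expect_error(fit_residual_regression(rep(50, 5), runif(5)), "degenerate")
  expect_error(fit_residual_regression(sig[1:2], resid[1:2]), ">= 3")

  # simultaneous prediction interval covers new observations at >= nominal rate
  set.seed(9)
  covered <- vapply(1:2000, function(i) {
    x <- runif(20, 20, 120)
    y <- 0.8 - 0.004 * x + rnorm(20, sd = 0.1)
    mi <- fit_residual_regression(x, y)
    xn <- runif(1, 20, 120)
    yn <- 0.8 - 0.004 * xn + rnorm(1, sd = 0.1)
    ci <- predict_residual_ci(mi, xn, 0.95)
    yn >= ci$lower && yn <= ci$upper
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("modulation classification flags frames against their residual bounds", {
  # tight regressions: residual expectation ~0.2 everywhere
  set.seed(10)
  x <- seq(30, 120, length.out = 20)
  mk <- function() fit_residual_regression(x, 0.2 + rnorm(20, sd = 0.01))
  mh <- mk(); mw <- mk()
  # Bonferroni level for 92 units reproduces the conventional threshold
  expect_equal(0.05 / 92, 5.43e-4, tolerance = 0.01)

  cls <- classify_modulation(40, 6, 70, model_head = mh, model_world = mw,
                             n_tests = 92)
  expect_true(cls$significant_head)       # ratio 6.7 >> bound ~0.23
  expect_false(cls$significant_world)     # ratio 0.15 within bound
  expect_equal(cls$dominant_frame, "head")

  # equal MDs with a tight bound below 1: mixed sensitivity, both flags on
  cls2 <- classify_modulation(30, 30, 70, model_head = mh, model_world = mw)
  expect_true(cls2$significant_head && cls2$significant_world)
  expect_error(classify_modulation(30, 30, 70), "required")
})
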