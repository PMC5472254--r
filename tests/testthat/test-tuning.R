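test_that("trial responses recover planted per-click counts exactly", {
  a <- make_arena()
  traj <- data.frame(t_s = seq(0, 100, by = 1 / 30), x_mm = 0, y_mm = 0,
                     dir_deg = 0)
  clicks <- data.frame(t_s = c(10, 20, 30), speaker_id = c(1L, 4L, 7L),
                       nominal_level_db = 57)
  # plant 3 evoked spikes on click 1, 1 background on click 2, none on click 3
  spikes <- c(10.01, 10.02, 10.049, 19.96, 55)
  tt <- trial_responses(spikes, clicks, traj, a)
  expect_equal(tt$evoked_count, c(3, 0, 0))
  expect_equal(tt$background_count, c(0, 1, 0))
  expect_equal(tt$evoked_rate_hz, c(60, 0, 0))
  expect_equal(tt$background_rate_hz, c(0, 20, 0))
  expect_equal(tt$theta_hs_deg, c(-90, 0, 90))
})

test_that("trials with untrackable pose are dropped and counted", {
  a <- make_arena()
  traj <- data.frame(t_s = seq(0, 100, by = 1 / 30), x_mm = 0, y_mm = 0,
                     dir_deg = 0)
  traj$dir_deg[250:400] <- NA
  clicks <- data.frame(t_s = c(5, 9, 50), speaker_id = c(1L, 2L, 3L))
  tt <- trial_responses(numeric(0), clicks, traj, a)
  expect_equal(nrow(tt), 2)
  expect_equal(attr(tt, "n_dropped"), 1)
})

test_that("tuning curve binning: single-bin stats and congruent 7-bin grids", {
  tr <- data.frame(theta_hs_deg = c(0, 0), theta_ws_deg = c(0, 0),
                   evoked_rate_hz = c(10, 20))
  cv <- tuning_curve(tr, "head")
  expect_equal(nrow(cv), 1)
  expect_equal(cv$mean_rate, 15)
  expect_equal(cv$sem, 5)

  s <- fx_session()
  tt <- fx_trials("ego")
  cw <- tuning_curve(tt, "world")
  expect_equal(cw$bin_center_deg, seq(-90, 90, by = 30))
  ch <- tuning_curve(tt, "head")
  expect_true(all(abs(ch$bin_center_deg) <= 90))
})

test_that("super-resolution curve of a simulated ego unit peaks at the preferred angle", {
  tt <- fx_trials("ego")
  cv <- tuning_curve(tt, "head", bin_width_deg = 5, range_deg = 180, min_n = 3)
  cv <- cv[!cv$below_min, ]
  pk <- cv$bin_center_deg[which.max(cv$mean_rate)]
  expect_lte(abs(wrap_angle(pk - 0)), 20)
  # coarse curve peak within one bin of the generating preferred angle
  c30 <- tuning_curve(tt, "head", 30, 180)
  expect_lte(abs(wrap_angle(c30$bin_center_deg[which.max(c30$mean_rate)])), 30)
})

test_that("modulation depth follows its formula and scale invariance", {
  expect_equal(modulation_depth(c(5, 10, 20, 10, 5, 10, 15)), 75)
  expect_equal(modulation_depth(rep(4, 7)), 0)
  expect_warning(md0 <- modulation_depth(rep(0, 7)), "all-zero")
  expect_true(is.na(md0))
  expect_warning(md1 <- modulation_depth(3), ">= 2")
  expect_true(is.na(md1))
  set.seed(2)
  for (i in 1:10) {
    x <- runif(7, 0, 50)
    expect_equal(modulation_depth(x), modulation_depth(x * runif(1, 0.1, 10)),
                 tolerance = 1e-9)
  }
})

test_that("tuning metrics: rectangular and Gaussian closed forms", {
  rect <- data.frame(frame = "head",
                     bin_center_deg = seq(-165, 180, by = 30),
                     mean_rate = c(rep(0, 5), 20, 20, 20, rep(0, 4)),
                     sem = 0, n = 10, bin_width_deg = 30)
  class(rect) <- c("tuning_curve", "data.frame")
  m <- tuning_metrics(rect)
  expect_equal(m$tuning_width_deg, 90)
  expect_equal(m$errf_width_deg, 90)
  expect_equal(m$md_360_pct, 100)

  # Gaussian curve from the canonical ego field: ERRF ~ c * sqrt(2*pi)
  ctr <- seq(-179.5, 179.5, by = 1)
  gauss <- data.frame(frame = "head", bin_center_deg = ctr,
                      mean_rate = ego_response(ego_field(), ctr),
                      sem = 0, n = 10, bin_width_deg = 1)
  class(gauss) <- c("tuning_curve", "data.frame")
  mg <- tuning_metrics(gauss)
  expect_equal(mg$errf_width_deg, 75.7 * sqrt(2 * pi), tolerance = 0.02)
  expect_lte(abs(mg$preferred_location_deg), 0.5)

  flat <- rect
  flat$mean_rate <- rep(7, 12)
  expect_warning(mf <- tuning_metrics(flat), "undefined")
  expect_true(is.na(mf$preferred_location_deg))
})

test_that("curve correlation keeps the sign and rejects tiny grids", {
  grid <- seq(-90, 90, by = 30)
  a <- structure(data.frame(frame = "head", bin_center_deg = grid,
                            mean_rate = c(1, 2, 5, 9, 5, 2, 1)),
                 class = c("tuning_curve", "data.frame"))
  b <- a
  expect_equal(curve_correlation(a, b)$r2, 1)
  neg <- a
  neg$mean_rate <- 2 * mean(a$mean_rate) - a$mean_rate
  cc <- curve_correlation(a, neg)
  expect_equal(cc$r2, 1, tolerance = 1e-12)
  expect_lt(cc$r, 0)
  tiny <- a[1:2, ]
  expect_error(curve_correlation(tiny, tiny), ">= 3")
})

test_that("population tuning averages peak-normalized curves", {
  grid <- seq(-90, 90, by = 30)
  mk <- function(scale) {
    structure(data.frame(frame = "head", bin_center_deg = grid,
                         mean_rate = scale * c(1, 2, 5, 9, 5, 2, 1),
                         sem = 0, n = 5, bin_width_deg = 30),
              class = c("tuning_curve", "data.frame"))
  }
  pop <- population_tuning(list(mk(1), mk(10), mk(0.2)))
  expect_equal(pop$mean_rate, c(1, 2, 5, 9, 5, 2, 1) / 9, tolerance = 1e-12)
  expect_lte(max(pop$mean_rate), 1)
  expect_equal(attr(pop, "argmax_deg"), 0)
  zero <- mk(0)
  expect_warning(p2 <- population_tuning(list(mk(1), zero)), "excluded")
  expect_equal(p2$n[1], 1)
})

test_that("head-frame tuning of an ego unit is behavior-invariant; world-frame is not", {
  s <- fx_session()
  tt <- fx_trials("ego")
  ch_free <- tuning_curve(tt, "head")
  # same field, pirouette behavior (expected curves, +/-90 grid)
  ep <- fx_pirouette_epochs()
  ch_pir <- expected_tuning(ego_field(), ep, "head", 30, 90)
  r_head <- cor(ch_free$mean_rate, ch_pir$mean_rate)
  expect_gt(r_head, 0.9)
  md_w_free <- modulation_depth(tuning_curve(tt, "world"))
  md_w_pir <- modulation_depth(expected_tuning(ego_field(), ep, "world", 30, 90))
  expect_gt(md_w_free, md_w_pir + 5)  # biased behavior leaks world modulation
})
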