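test_that("model fit and preference follow their definitions and bounds", {
  expect_equal(model_fit(200, 150, 100), 50)
  expect_equal(model_fit(200, 100, 100), 100)
  expect_equal(model_fit(200, 200, 100), 0)
  expect_error(model_fit(200, 250, 100), "nesting")
  expect_warning(mf <- model_fit(100, 100, 100), "undefined")
  expect_true(is.na(mf))
  expect_equal(model_preference(80, 20), 60)
  expect_equal(model_preference(33, 33), 0)
  expect_equal(model_preference(100, 0), 100)
  expect_equal(model_preference(0, 100), -100)
})

test_that("GLM set on a simulated ego unit prefers the head frame; nesting holds", {
  tt <- fx_trials("ego")
  fits <- fit_glm_set(tt)
  d <- fits$deviance
  expect_lte(d[["full"]], d[["head"]] + 1e-8)
  expect_lte(d[["full"]], d[["world"]] + 1e-8)
  expect_lte(d[["head"]], d[["const"]] + 1e-8)
  expect_lte(d[["world"]], d[["const"]] + 1e-8)
  expect_lt(fits$p_vs_const[["head"]], 0.05)
  expect_lt(fits$aic[["head"]], fits$aic[["world"]])
  sc <- model_scores(fits)
  expect_true(sc$fit_head_pct >= 0 && sc$fit_head_pct <= 100)
  expect_true(sc$fit_world_pct >= 0 && sc$fit_world_pct <= 100)
  expect_gt(sc$preference_pct, 0)
  # binned encoding agrees on the preferred frame and also nests properly
  fb <- fit_glm_set(tt, encoding = "binned")
  expect_lte(fb$deviance[["full"]], min(fb$deviance[["head"]],
                                        fb$deviance[["world"]]) + 1e-8)
  expect_gt(model_scores(fb)$preference_pct, 0)
})

test_that("GLM set on the allocentric and untuned units behaves as designed", {
  fits_a <- fit_glm_set(fx_trials("allo"))
  expect_lt(fits_a$aic[["world"]], fits_a$aic[["head"]])
  expect_equal(classify_aic(fits_a)$label, "allocentric")

  # angle-independent unit: p roughly uniform across replicate draws
  set.seed(20)
  ps <- vapply(1:200, function(i) {
    tr <- make_aligned_trials(20, function(th) rep(12, length(th)),
                              seed = 2e6 + i)
    tr$theta_hs_deg <- wrap_angle(tr$theta_hs_deg + runif(nrow(tr), -15, 15))
    fit_glm_set(tr)$p_vs_const[["head"]]
  }, numeric(1))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.04)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
})

test_that("AIC classification excludes units that never beat the constant model", {
  tt <- fx_trials("ego")
  fits <- fit_glm_set(tt)
  expect_equal(classify_aic(fits)$label, "egocentric")
  null_fits <- fits
  null_fits$p_vs_const[c("head", "world")] <- c(0.4, 0.7)
  expect_equal(classify_aic(null_fits)$label, "excluded")
  tie_fits <- fits
  tie_fits$p_vs_const[["head"]] <- 1e-6
  tie_fits$aic[c("head", "world")] <- c(100, 100)
  res <- classify_aic(tie_fits)
  expect_true(res$tie)
  expect_true(res$label %in% c("egocentric", "allocentric"))
})

test_that("shuffle controls are deterministic and collapse the relevant frame", {
  s <- fx_session()
  tt <- fx_trials("ego")
  obs <- model_scores(fit_glm_set(tt))
  sh1 <- shuffle_control(tt, s$arena, "speaker", n = 20, seed = 3)
  sh2 <- shuffle_control(tt, s$arena, "speaker", n = 20, seed = 3)
  expect_identical(sh1$scores, sh2$scores)
  # speaker shuffle reduces head-frame fit and preference for the ego unit
  # (head-direction information is retained by design, so the decline is
  # partial, not total)
  expect_lt(sh1$median_fit_head, obs$fit_head_pct - 5)
  expect_lt(sh1$median_preference, obs$preference_pct)
  expect_error(shuffle_control(tt, s$arena, "speaker", n = 0), ">= 1")

  # head-direction shuffle strongly reduces the ego unit's head fit
  sh_hd <- shuffle_control(tt, s$arena, "head_direction", n = 20, seed = 3)
  expect_lt(sh_hd$median_fit_head, obs$fit_head_pct - 30)

  # ... but leaves the allocentric unit's world fit intact
  ta <- fx_trials("allo")
  obs_a <- model_scores(fit_glm_set(ta))
  sh_a <- shuffle_control(ta, s$arena, "head_direction", n = 20, seed = 4)
  expect_gt(sh_a$median_fit_world, obs_a$fit_world_pct - 15)
})

test_that("timecourse grid is correct and separation is confined post-onset", {
  s <- fx_session()
  tt <- fx_trials("ego")
  tt <- tt[1:400, ]
  tc <- timecourse_fits(s$spikes$ego, tt, step_ms = 10)
  expect_equal(tc$scores$center_ms, seq(-60, 90, by = 10))
  pre <- tc$scores$center_ms < -10
  post <- tc$scores$center_ms >= 10 & tc$scores$center_ms <= 40
  expect_gt(mean(tc$scores$fit_head_pct[post], na.rm = TRUE),
            mean(tc$scores$fit_head_pct[pre], na.rm = TRUE))
})

test_that("cluster test: no clusters under exchangeability, planted cluster at the p floor", {
  set.seed(30)
  A <- matrix(rnorm(10 * 40), 10)
  res0 <- cluster_test(A[1:5, ], A[6:10, ], n_perm = 99)
  expect_true(all(!res0$clusters$significant))

  B <- matrix(rnorm(12 * 40), 12)
  C <- matrix(rnorm(12 * 40), 12)
  C[, 15:25] <- C[, 15:25] + 3  # planted difference over a known window
  res1 <- cluster_test(B, C, n_perm = 500, seed = 5)
  sig <- res1$clusters[res1$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  top <- sig[which.max(abs(sig$mass)), ]
  expect_lte(top$start_idx, 25)
  expect_gte(top$end_idx, 15)
  expect_equal(top$p, 1 / 501, tolerance = 1e-9)
  expect_error(cluster_test(B, C, n_perm = 10), "n_perm")
  expect_error(cluster_test(B[1, , drop = FALSE], C, n_perm = 99), ">= 2")
})
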