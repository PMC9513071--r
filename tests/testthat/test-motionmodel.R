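test_that("impulse RF reproduces the stimulus time course at its location", {
  stim <- make_1d_noise(5, 20, 20, duration_s = 2, seed = 3, dx = 20, dt = 0.05)
  W <- matrix(0, 5, 4); W[3, 1] <- 1
  rf <- spacetime_rf(W, dx = 20, dt = 0.05, origin_um = stim$origin_um,
                     center_um = stim$origin_um + 2 * 20, polarity = "On")
  pred <- conv_predict(rf, stim)
  expect_equal(pred$values, stim$values[3, ])
})

test_that("conv_predict matches the triple-loop oracle on random RF/stimulus pairs", {
  set.seed(5)
  for (i in 1:8) {
    nx <- sample(3:7, 1); nl <- sample(2:5, 1); nt <- sample(10:25, 1)
    W <- matrix(rnorm(nx * nl), nx, nl)
    S <- matrix(runif(nx * nt, -1, 1), nx, nt)
    rf <- spacetime_rf(W, dx = 10, dt = 0.01, origin_um = -20, polarity = "On")
    stim <- spacetime_stim(S, dx = 10, dt = 0.01, origin_um = -20)
    expect_equal(conv_predict(rf, stim)$values, oracle_conv(rf, stim),
                 tolerance = 1e-12)
  }
})

test_that("conv_predict is linear in RF and stimulus (superposition)", {
  set.seed(6)
  nx <- 6; nl <- 4; nt <- 30
  mk_rf <- function() spacetime_rf(matrix(rnorm(nx * nl), nx, nl), 10, 0.01,
                                   origin_um = 0, polarity = "On")
  mk_st <- function() spacetime_stim(matrix(runif(nx * nt, -1, 1), nx, nt),
                                     10, 0.01, origin_um = 0)
  r1 <- mk_rf(); r2 <- mk_rf(); s1 <- mk_st(); s2 <- mk_st()
  r12 <- r1; r12$weights <- r1$weights + r2$weights
  expect_equal(conv_predict(r12, s1)$values,
               conv_predict(r1, s1)$values + conv_predict(r2, s1)$values)
  s12 <- s1; s12$values <- (s1$values + s2$values) / 2
  expect_equal(conv_predict(r1, s12)$values,
               (conv_predict(r1, s1)$values + conv_predict(r1, s2)$values) / 2)
})

test_that("grid mismatch errors without resampling; resampling preserves scale", {
  rf <- make_test_rf(dx = 10, dt = 0.01)
  stim <- make_moving_bar(20, 500, 100, dx = 5, dt = 0.005,
                          extent_um = c(-100, 150))
  expect_error(conv_predict(rf, stim, resample = FALSE), "grid")
  p_fine <- conv_predict(rf, stim)
  stim2 <- make_moving_bar(20, 500, 100, dx = 10, dt = 0.01,
                           extent_um = c(-100, 150))
  p_native <- conv_predict(rf, stim2)
  expect_equal(max(p_fine$values), max(p_native$values), tolerance = 0.05)
})

test_that("preference index algebra", {
  mk <- function(v) predicted_response(v, 0.01)
  expect_equal(preference_index(mk(c(0, 3)), mk(c(0, 3))), 0)
  expect_equal(preference_index(mk(c(0, 2)), mk(c(0, 0))), 1)
  expect_equal(preference_index(mk(c(0, 3)), mk(c(0, 1))), 0.5)
  expect_error(preference_index(mk(c(-1, 0)), mk(c(0, 0))), "undefined")
})

test_that("mirror-symmetric RF shows no left-right preference", {
  rf <- make_test_rf(dx = 10, dt = 0.01)
  tun <- rds_tuning(rf, c(250, 500, 1000), pairing = "left_vs_right")
  expect_true(all(abs(tun$preference) < 0.05))
})

test_that("surround-free symmetric-kernel RF has zero originate/terminate preference", {
  rf0 <- make_test_rf(surround_strength = 0, biphasic_weight = 0,
                      dx = 10, dt = 0.01)
  tun <- rds_tuning(rf0, c(250, 500, 1000))
  expect_true(all(abs(tun$preference) < 1e-8))
})

test_that("rDS RF prefers originating motion across velocities", {
  rf <- make_test_rf(surround_strength = 0.5, surround_latency_s = 0.06,
                     dx = 10, dt = 0.01)
  tun <- rds_tuning(rf, c(100, 250, 500, 1000, 2000))
  expect_true(all(tun$preference > 0))
  # loom/recede pairing runs and stays in range (its sign depends on how
  # the onset transient is treated; see the methods vignette)
  loom <- rds_tuning(rf, c(400, 800), pairing = "loom_vs_recede")
  expect_true(all(is.finite(loom$preference) & abs(loom$preference) <= 1))
})

test_that("surround scaling: identity, zeroing, and a hand-computed 3x3 case", {
  rf <- make_test_rf(dx = 10, dt = 0.01)
  expect_equal(scale_surround(rf, 1)$weights, rf$weights)
  z <- scale_surround(rf, 0)
  masks <- rdsbc:::rf_region_masks(rf)
  surr_opp <- (rf$weights < 0) & matrix(masks$surround, nrow(rf$weights),
                                        ncol(rf$weights))
  expect_true(all(z$weights[surr_opp] == 0))
  expect_equal(z$weights[!surr_opp], rf$weights[!surr_opp])
  # explicit 3x3: centre bin is row 2; flank rows are surround
  W <- matrix(c(0.1, -0.2, 0.3,
                1.0, 0.5, -0.1,
                -0.4, 0.2, -0.6), nrow = 3, byrow = TRUE)
  rf3 <- spacetime_rf(W, dx = 20, dt = 0.1, origin_um = -20, center_um = 0,
                      polarity = "On")
  out <- scale_surround(rf3, 2, boundary_um = 10)
  expected <- W
  expected[1, ] <- c(0.1 * 1, -0.2 * 2, 0.3 * 1)   # negative flank values doubled
  expected[3, ] <- c(-0.4 * 2, 0.2 * 1, -0.6 * 2)
  expect_equal(out$weights, expected)
  expect_error(scale_surround(rf3, -1), ">= 0")
})

test_that("centre/surround decomposition sums to the full prediction", {
  rf <- make_test_rf(dx = 10, dt = 0.01)
  stim <- pad_stimulus(make_moving_bar(20, 500, 150, dx = 10, dt = 0.01,
                                       extent_um = c(-150, 200)), after_s = 0.4)
  parts <- decompose_center_surround(rf, stim)
  full <- conv_predict(rf, stim)
  expect_equal(parts$center$values + parts$surround$values, full$values,
               tolerance = 1e-12)
  rf0 <- make_test_rf(surround_strength = 0, biphasic_weight = 0,
                      dx = 10, dt = 0.01)
  parts0 <- decompose_center_surround(rf0, stim)
  expect_lt(max(abs(parts0$surround$values)), 1e-9 * max(abs(parts0$center$values)))
})

test_that("surround trough lags the centre peak more for outward than inward motion", {
  rf <- make_test_rf(surround_strength = 0.5, surround_latency_s = 0.06,
                     dx = 10, dt = 0.01)
  c0 <- rf$center_um; span <- 150; w <- 20
  ext <- c(c0 - w, c0 + span + 2 * w)
  outw <- pad_stimulus(make_moving_bar(w, 500, span, +1, start_um = c0 + w,
                                       dx = 10, dt = 0.01, extent_um = ext),
                       after_s = 0.4)
  inw <- pad_stimulus(make_moving_bar(w, 500, span, -1, start_um = c0 + span,
                                      dx = 10, dt = 0.01, extent_um = ext),
                      after_s = 0.4)
  offset <- function(stim) {
    parts <- decompose_center_surround(rf, stim)
    t_c <- which.max(parts$center$values)
    t_s <- which.min(parts$surround$values)
    (t_s - t_c) * stim$dt
  }
  expect_gt(offset(outw), offset(inw))
})

test_that("prediction-observation correlation behaves and bounds under noise", {
  rf <- make_test_rf(dx = 10, dt = 0.01)
  stim <- pad_stimulus(make_moving_bar(20, 500, 150, dx = 10, dt = 0.01,
                                       extent_um = c(-150, 200)), after_s = 0.3)
  pred <- conv_predict(rf, stim)
  self <- response_trace(pred$values, 1 / stim$dt)
  expect_equal(validate_prediction(pred, self), 1)
  neg <- response_trace(-pred$values, 1 / stim$dt)
  expect_equal(validate_prediction(pred, neg), -1)
  # noisy observation: r should sit near the analytic attenuation
  # r_expected = 1 / sqrt(1 + noise_var / signal_var)
  snr <- 2
  nsd <- sd(pred$values) / snr
  rs <- vapply(1:30, function(i)
    validate_prediction(pred, simulate_response(rf, stim, noise_sd = nsd,
                                                seed = 400 + i)), numeric(1))
  r_exp <- 1 / sqrt(1 + 1 / snr^2)
  expect_equal(mean(rs), r_exp, tolerance = 0.05)
  flat <- response_trace(rep(1, length(pred$values)), 1 / stim$dt)
  expect_error(validate_prediction(pred, flat), "zero variance")
})

test_that("coherence scan: amplitude increases with motion coherence for rDS RFs", {
  rfs <- default_cluster_rfs(dt = 0.01)
  for (rf in rfs[c("c1", "c4")]) {
    cs <- coherence_scan(rf, n = 60, seed = 2)
    expect_gt(cor(cs$coherence, cs$peak, method = "spearman"), 0.2)
  }
})
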