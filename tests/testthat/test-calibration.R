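test_that("probe calibration recovers exact linear relations", {
  # identical probes
  log <- toy_control_log(c(40, 45, 50, 55), c(40, 45, 50, 55))
  fit <- fit_probe_calibration(log)
  expect_equal(fit$W, 1)
  expect_equal(fit$M, 0)
  expect_equal(fit$r_squared, 1)

  # background = 0.9 * focal + 3, exactly
  log <- toy_control_log(c(40, 45, 50, 55), 0.9 * c(40, 45, 50, 55) + 3)
  fit <- fit_probe_calibration(log)
  expect_equal(fit$W, 0.9)
  expect_equal(fit$M, 3)
})

test_that("probe calibration is within OLS sampling error under noise", {
  set.seed(4821)
  focal <- runif(400, 40, 60)
  bg <- 0.9 * focal + 3 + rnorm(400, 0, 0.1)
  log <- toy_control_log(focal, bg)
  fit <- fit_probe_calibration(log)
  expect_lt(abs(fit$W - 0.9), 0.02)
  expect_lt(abs(fit$M - 3), 1)
})

test_that("calibration failure modes are reported", {
  expect_error(fit_probe_calibration(toy_control_log(c(50, 51), c(50, 51))),
               "fewer than 3")
  expect_error(fit_probe_calibration(toy_control_log(rep(50, 5), rnorm(5, 50))),
               "degenerate focal")
  log <- toy_log(toy_period(c(50, 51, 52)))   # no probe-control periods
  expect_error(fit_probe_calibration(log), "no probe-control")
})

test_that("applying a calibration transforms focal readings affinely", {
  ctrl <- toy_control_log(c(40, 45, 50, 55), 0.9 * c(40, 45, 50, 55) + 3)
  fit <- fit_probe_calibration(ctrl)
  log <- toy_log(toy_period(c(50, 47.3, 52)))
  corrected <- apply_calibration(log, fit)
  foc <- corrected$probe_role == "focal"
  expect_equal(corrected$rh_corrected[foc], 0.9 * c(50, 47.3, 52) + 3)
  expect_equal(corrected$rh_corrected[!foc], corrected$rh_pct[!foc])

  # identity calibration leaves readings untouched
  id_fit <- fit_probe_calibration(toy_control_log(c(40, 45, 50), c(40, 45, 50)))
  corrected <- apply_calibration(log, id_fit)
  expect_equal(corrected$rh_corrected[foc], c(50, 47.3, 52))

  # cross-day application is refused
  other_day <- toy_log(toy_period(c(50, 51, 52), day = "d2"))
  expect_error(apply_calibration(other_day, fit), "d2.*refused|refused")
})

test_that("calibration fitted on exact data corrects those readings exactly", {
  focal <- c(40, 44, 48, 52, 56)
  log <- toy_control_log(focal, 0.95 * focal + 2)
  fit <- fit_probe_calibration(log)
  corrected <- apply_calibration(log, fit)
  foc <- corrected$probe_role == "focal"
  expect_equal(corrected$rh_corrected[foc], corrected$rh_pct[!foc])
})

test_that("per-period humidity differences equal the mean paired difference", {
  ctrl <- toy_control_log(c(40, 45, 50, 55), c(40, 45, 50, 55))
  fit <- fit_probe_calibration(ctrl)

  # corrected focal == background -> exactly zero
  log <- toy_log(ctrl, toy_period(rep(50, 5), rep(50, 5)))
  drh <- compute_delta_rh(log, fit)
  expect_equal(drh$delta_rh, 0)
  expect_equal(drh$within_period_sd, 0)

  # constant excess of 2.5
  log <- toy_log(ctrl, toy_period(rep(52.5, 5), rep(50, 5)))
  expect_equal(compute_delta_rh(log, fit)$delta_rh, 2.5)

  # aligned timestamps: mean of paired differences == difference of means
  set.seed(77)
  f <- rnorm(50, 51, 0.5)
  b <- rnorm(50, 50, 0.5)
  log <- toy_log(ctrl, toy_period(f, b))
  expect_equal(compute_delta_rh(log, fit)$delta_rh, mean(f) - mean(b))
})

test_that("calibration is affine-equivariant and leaves humidity differences unchanged", {
  log <- simulate_probe_log(transect_truth(reading_sd = 0.05), n_flowers = 2,
                            n_replicates = 2, seed = 31, cadence_s = 10)
  drh1 <- compute_delta_rh(log, fit_probe_calibration(log))
  # an extra affine distortion of the recorded focal scale
  log2 <- log
  foc <- log2$probe_role == "focal"
  log2$rh_pct[foc] <- (log2$rh_pct[foc] - 5) / 1.1
  drh2 <- compute_delta_rh(log2, fit_probe_calibration(log2))
  expect_equal(drh2$delta_rh, drh1$delta_rh, tolerance = 1e-10)
})

test_that("probe-control periods after self-calibration have humidity difference ~0", {
  log <- simulate_probe_log(n_flowers = 3, n_replicates = 2, seed = 12,
                            cadence_s = 4)
  calib <- fit_probe_calibration(log)
  drh <- compute_delta_rh(log, calib, include_controls = TRUE)
  ctrl <- drh$delta_rh[drh$axis == "probe_control"]
  expect_lt(abs(mean(ctrl)), 0.02)
})
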