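cal_table <- function(noise_sd = 0, seed = 1) {
  simulate_calibration_dataset(fx_cal$gt, fx_cal$wavelength,
                               fx_cal$temperatures, noise_sd = noise_sd,
                               seed = seed)
}

test_that("noiseless calibration fit recovers the generating curve", {
  fit <- fit_biphasic(cal_table())
  co <- coef(fit)
  expect_equal(unname(co["plateau_high"]), 18, tolerance = 0.01)
  expect_equal(unname(co["plateau_low"]), 10, tolerance = 0.01)
  expect_equal(unname(co["t_mid1"]), 36.8, tolerance = 0.01)
  expect_lt(fit$sigma, 1e-6)
  # fitted curve reproduces the data everywhere
  expect_lt(max(abs(residuals(fit))), 1e-5)
})

test_that("noisy calibration fit recovers the plateaus within 0.5 ns", {
  fit <- fit_biphasic(cal_table(noise_sd = 0.15, seed = 7))
  co <- coef(fit)
  expect_lt(abs(co["plateau_high"] - 18), 0.5)
  expect_lt(abs(co["plateau_low"] - 10), 0.5)
})

test_that("parameter recovery is stable across noisy replicates", {
  errs <- t(vapply(1:25, function(s) {
    co <- coef(fit_biphasic(cal_table(noise_sd = 0.15, seed = 100 + s)))
    c(abs(co["plateau_high"] - 18), abs(co["plateau_low"] - 10),
      abs(co["t_mid1"] - 36.8))
  }, numeric(3)))
  med <- apply(errs, 2, stats::median)
  expect_lt(med[1], 0.25)
  expect_lt(med[2], 0.25)
  expect_lt(med[3], 0.25)
})

test_that("degenerate or insufficient calibration data are rejected", {
  flat <- data.frame(temperature_C = seq(25, 50, by = 2),
                     tau_ns = rep(14, 13))
  expect_error(fit_biphasic(flat), "degenerate")
  expect_error(fit_biphasic(cal_table()[1:5, ]), ">= 8")
})

test_that("sensitivity profile of the fitted curve peaks near 37 C at ~19 %/C", {
  fit <- fit_biphasic(cal_table(noise_sd = 0.15, seed = 7))
  sp <- sensitivity_profile(fit, seq(30, 45, by = 0.01))
  expect_lt(abs(attr(sp, "max_sensitivity") - 19), 1.5)
  expect_lt(abs(attr(sp, "argmax_temperature") - 37), 0.5)
  # plateau region is flat
  expect_lt(sp$sr_pct_per_C[sp$temperature_C == 31], 0.5)
  # analytic derivative against finite differences on the fitted curve
  Tg <- seq(33, 41, by = 0.5)
  fd <- (predict(fit, Tg + 1e-5) - predict(fit, Tg - 1e-5)) / 2e-5
  an <- cnstherm:::biphasic_deriv(coef(fit), Tg)
  expect_equal(unname(an), fd, tolerance = 1e-6)
})

test_that("calibration inversion round-trips inside the valid range", {
  fit <- fit_biphasic(cal_table())
  Tg <- seq(25.5, 49.5, by = 0.25)
  tau <- predict(fit, Tg)
  back <- invert_calibration(fit, tau)
  expect_equal(back$temperature_C, Tg, tolerance = 1e-6)
  expect_false(any(back$clipped))
  # out-of-range lifetimes clip to the range edges and get flagged
  hi <- invert_calibration(fit, coef(fit)["plateau_high"] + 1)
  expect_true(hi$clipped)
  expect_equal(hi$temperature_C, 25, tolerance = 1e-6)
  lo <- invert_calibration(fit, coef(fit)["plateau_low"] - 1)
  expect_true(lo$clipped)
  expect_equal(lo$temperature_C, 50, tolerance = 1e-6)
})

test_that("temperature readout of noiseless curves recovers the temperature", {
  fit <- fit_biphasic(cal_table())
  cv <- simulate_decay(fx_cal$gt, 614, 38, noiseless = TRUE)
  ro <- temperature_readout(list(cv), fit)
  expect_lt(abs(ro$temperature_C - 38), 0.05)
  expect_false(ro$clipped)
})

test_that("precision report follows Poisson scaling and the delta-T relation", {
  fit <- fit_biphasic(cal_table())
  gt <- small_gt(bins = 256, cps = 2000)
  rep1 <- precision_vs_integration(gt, c(0.1, 0.4, 1.6), 36.5, fit,
                                   n_reps = 60, seed = 9)
  # delta-tau decreases with integration time
  expect_true(all(diff(rep1$delta_tau_ns) < 0))
  # quadrupling the counts halves delta-tau (within sampling error)
  gt4 <- small_gt(bins = 256, cps = 8000)
  rep4 <- precision_vs_integration(gt4, 0.4, 36.5, fit, n_reps = 60,
                                   seed = 9)
  ratio <- rep1$delta_tau_ns[2] / rep4$delta_tau_ns[1]
  expect_gt(ratio, 1.5); expect_lt(ratio, 2.7)
  # delta_T * |dtau/dT| = delta_tau exactly as computed
  slope <- abs(cnstherm:::biphasic_deriv(coef(fit), 36.5))
  expect_equal(rep1$delta_T_C * slope, rep1$delta_tau_ns)
  expect_equal(rep1$product_Cs, rep1$integration_time_s * rep1$delta_T_C)
  # low sensitivity at the plateau blows up the thermal resolution
  rep_plateau <- precision_vs_integration(gt, 0.4, 30, fit, n_reps = 40,
                                          seed = 9)
  expect_gt(rep_plateau$delta_T_C, 10 * rep1$delta_T_C[2])
})

test_that("calibration serializes to YAML and back", {
  fit <- fit_biphasic(cal_table(noise_sd = 0.15, seed = 7))
  p <- withr::local_tempfile(fileext = ".yml")
  write_calibration(fit, p)
  cal2 <- read_calibration(p)
  expect_equal(coef(cal2), coef(fit))
  expect_equal(predict(cal2, c(30, 37, 44)), predict(fit, c(30, 37, 44)))
})
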