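test_that("average lifetime recovers known first moments", {
  # point mass: all counts in the bin containing t = 7 ns
  edges <- seq(0, 20, by = 0.5)
  counts <- numeric(40); counts[15] <- 100   # bin [7, 7.5), midpoint 7.25
  cv <- decay_curve(edges, counts, wavelength_em = 614)
  expect_equal(average_lifetime(cv), 7.25)
  # noiseless exponential over a 20-lifetime window: < 0.1 % truncation
  cv10 <- single_exp_curve(10, window = 200)
  expect_equal(average_lifetime(cv10), 10, tolerance = 1e-3)
  # window restriction
  expect_error(average_lifetime(cv, window = c(15, 20)), "no counts")
  expect_error(average_lifetime(decay_curve(edges, numeric(40), 614)),
               "no counts")
})

test_that("model lifetime reproduces closed-form special cases", {
  m <- fx_gt$model
  # pure monomer channel: g_A = 0 below the aggregate band
  expect_equal(model_lifetime(m, 500, 50), m$tau_M)
  # equal intensities: arithmetic mean of the two lifetimes
  cross <- line_shape_crossing(fx_shapes)[1]
  mid_pop <- population_model(1 - 1e-9, 1e-9, 36.8, 0.9)
  m_eq <- two_state_model(25, 3, fx_shapes, mid_pop)
  # at the crossing with N_A = 0.5 the weights are equal
  m_half <- two_state_model(25, 3, fx_shapes,
                            population_model(0.5 + 1e-9, 0.5 - 1e-9,
                                             36.8, 0.9))
  expect_equal(model_lifetime(m_half, cross, 36.8), 14, tolerance = 1e-6)
  narrow <- make_line_shapes(data.frame(center = 520, width = 2, weight = 1),
                             data.frame(center = 650, width = 2, weight = 1))
  m_narrow <- two_state_model(25, 3, narrow, fx_pop)
  expect_error(model_lifetime(m_narrow, 749, 25), "zero total intensity")
})

test_that("model lifetime is bounded and monotone in the aggregate fraction", {
  wl_grid <- seq(500, 700, by = 10)
  Tg <- seq(25, 50, by = 2.5)
  for (wl in wl_grid) {
    for (T in Tg) {
      tau <- try(model_lifetime(fx_gt$model, wl, T), silent = TRUE)
      if (inherits(tau, "try-error")) next
      expect_gte(tau, fx_gt$model$tau_M)
      expect_lte(tau, fx_gt$model$tau_A)
    }
  }
  # strictly increasing in N_A at a wavelength where both states emit
  taus <- vapply(seq(0.05, 0.95, by = 0.1), function(na) {
    m <- two_state_model(25, 3, fx_shapes,
                         population_model(na + 1e-9, na - 1e-9, 36.8, 0.9))
    model_lifetime(m, 614, 36.8)
  }, numeric(1))
  expect_true(all(diff(taus) > 0))
})

test_that("analytic temperature derivative matches the finite-difference oracle", {
  m <- fx_cal$gt$model
  wls <- seq(560, 680, length.out = 20)
  Ts <- seq(30, 45, length.out = 20)
  h <- 1e-4
  for (wl in wls) {
    for (T in Ts) {
      an <- lifetime_temperature_derivative(m, wl, T)
      fd <- (model_lifetime(m, wl, T + h) -
               model_lifetime(m, wl, T - h)) / (2 * h)
      # 1e-6 relative, with an absolute floor of 1e-8 ns/C where the
      # derivative vanishes and the finite difference is pure
      # cancellation noise (~1e-10)
      expect_lt(abs(an - fd), pmax(1e-6 * abs(fd), 1e-8))
    }
  }
})

test_that("derivative reduces to dN_A/dT (tau_A - tau_M) at the crossing", {
  m <- fx_cal$gt$model
  cross <- line_shape_crossing(m$shapes)[1]
  for (T in c(35, 36.8, 38)) {
    expect_equal(lifetime_temperature_derivative(m, cross, T),
                 population_fraction_deriv(m$population, T) *
                   (m$tau_A - m$tau_M),
                 tolerance = 1e-3)  # crossing located to ~0.004 nm
  }
  # frozen populations far below the transition: derivative ~ 0
  expect_lt(abs(lifetime_temperature_derivative(m, 614, 20)), 1e-6)
})

test_that("relative sensitivity is the normalized absolute derivative", {
  m <- fx_cal$gt$model
  sr <- relative_sensitivity(m, 614, 37)
  expect_equal(sr, 100 *
                 abs(lifetime_temperature_derivative(m, 614, 37)) /
                 model_lifetime(m, 614, 37))
  expect_lt(relative_sensitivity(m, 614, 25), 1e-4)  # flat plateau
})

test_that("wavelength scan finds the optimum at the line-shape crossing", {
  scan <- wavelength_scan(fx_gt$model, t_low = 25, t_high = 50)
  cross <- line_shape_crossing(fx_shapes)[1]
  expect_lt(abs(attr(scan, "argmax_delta_tau") - cross), 5)
  expect_lt(abs(attr(scan, "argmin_g_diff") - cross), 5)
  # monomer-only band: no contrast
  band <- scan$wavelength_nm >= 500 & scan$wavelength_nm <= 540
  expect_true(all(abs(scan$delta_tau_ns[band]) < 0.5))
  # swapping the roles of the two line shapes preserves the contrast
  # magnitude at the crossing
  swapped <- two_state_model(fx_gt$model$tau_A, fx_gt$model$tau_M,
                             list(monomer = fx_shapes$aggregate,
                                  aggregate = fx_shapes$monomer),
                             fx_gt$model$population)
  s2 <- wavelength_scan(swapped, t_low = 25, t_high = 50)
  i <- which.min(abs(scan$wavelength_nm - cross))
  expect_equal(abs(s2$delta_tau_ns[i]), abs(scan$delta_tau_ns[i]),
               tolerance = 0.02)
})

test_that("estimator applied to noiseless forward-model curves matches the model", {
  for (T in c(30, 36.8, 42)) {
    cv <- simulate_decay(fx_cal$gt, 614, T, noiseless = TRUE)
    tau_model <- model_lifetime(fx_cal$gt$model, 614, T)
    # finite-window truncation keeps the discrete estimate slightly low
    expect_equal(average_lifetime(cv), tau_model, tolerance = 5e-3)
  }
})
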