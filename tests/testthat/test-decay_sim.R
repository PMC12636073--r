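test_that("identical seed and config give byte-identical curves", {
  a <- simulate_decay(fx_gt, 614, 36.5, seed = 5)
  b <- simulate_decay(fx_gt, 614, 36.5, seed = 5)
  expect_identical(a, b)
  c <- simulate_decay(fx_gt, 614, 36.5, seed = 6)
  expect_false(identical(a$counts, c$counts))
})

test_that("per-bin counts follow Poisson mean-variance over replicates", {
  gt <- small_gt(bins = 32, cps = 5000)
  n_rep <- 1200
  counts <- with(list(), {
    set.seed(101)
    t(vapply(seq_len(n_rep), function(i)
      simulate_decay(gt, 614, 36.5, integration_time = 1)$counts,
      numeric(32)))
  })
  m <- colMeans(counts)
  v <- apply(counts, 2, stats::var)
  keep <- m > 20   # relative comparison needs enough counts
  expect_true(all(abs(v[keep] / m[keep] - 1) < 0.10))
})

test_that("expected total counts scale linearly with integration time", {
  for (dt in c(0.5, 2, 7)) {
    mu <- cnstherm:::expected_decay_counts(fx_gt, 614, 36.5, dt)$mu
    expect_equal(sum(mu), fx_gt$budget$counts_per_second * dt,
                 tolerance = 1e-2)
  }
})

test_that("mixture weights sum to one wherever there is signal", {
  for (wl in c(520, 560, 614, 650, 700)) {
    for (T in c(25, 36.5, 50)) {
      w <- cnstherm:::mixture_weights(fx_gt$model, wl, T)
      expect_equal(w$w_A + w$w_M, 1, tolerance = 1e-12)
    }
  }
})

test_that("degenerate mixtures reduce to single exponentials", {
  # population forced to pure aggregate: noiseless curve has lifetime tau_A
  pure <- ground_truth_config(
    two_state_model(25, 3, fx_shapes, population_model(1, 0, 36.8, 0.9)),
    fx_gt$budget)
  cv <- simulate_decay(pure, 655, 20, noiseless = TRUE)
  tau_trunc <- 25 * (1 - (1 + 200 / 25) * exp(-200 / 25)) /
    (1 - exp(-200 / 25))
  expect_equal(average_lifetime(cv), tau_trunc, tolerance = 1e-3)
})

test_that("zero-signal wavelengths warn, dead channels come back empty", {
  # width-2 peaks underflow to exactly zero at the red end of the grid
  narrow <- make_line_shapes(data.frame(center = 520, width = 2, weight = 1),
                             data.frame(center = 650, width = 2, weight = 1))
  gt <- ground_truth_config(
    two_state_model(25, 3, narrow, fx_pop), photon_budget(800, 128, 200))
  expect_warning(cv <- simulate_decay(gt, 745, 25, seed = 1),
                 "zero expected signal")
  expect_equal(sum(cv$counts), 0)
  # width-5 peaks leave a ~1e-86 tail: negligible but defined signal
  faint <- make_line_shapes(data.frame(center = 520, width = 5, weight = 1),
                            data.frame(center = 650, width = 5, weight = 1))
  gt2 <- ground_truth_config(
    two_state_model(25, 3, faint, fx_pop), photon_budget(800, 128, 200))
  expect_warning(cv2 <- simulate_decay(gt2, 745, 25, seed = 1),
                 "negligible expected signal")
  expect_s3_class(cv2, "decay_curve")
})

test_that("calibration datasets are exact when noiseless, reproducible when not", {
  temps <- seq(25, 50, by = 2.5)
  tab0 <- simulate_calibration_dataset(fx_cal$gt, 614, temps, noise_sd = 0)
  expect_equal(tab0$tau_ns,
               vapply(temps, function(T)
                 model_lifetime(fx_cal$gt$model, 614, T), numeric(1)))
  t1 <- simulate_calibration_dataset(fx_cal$gt, 614, temps,
                                     noise_sd = 0.15, seed = 7)
  t2 <- simulate_calibration_dataset(fx_cal$gt, 614, temps,
                                     noise_sd = 0.15, seed = 7)
  expect_identical(t1, t2)
  expect_error(simulate_calibration_dataset(fx_cal$gt, 614, numeric(0)),
               "non-empty")
})

test_that("calibration plateaus sit at 18 and 10 ns at the crossing", {
  tab <- simulate_calibration_dataset(fx_cal$gt, 614,
                                      fx_cal$temperatures, noise_sd = 0)
  expect_equal(tab$tau_ns[1], 18, tolerance = 1e-2)
  expect_equal(tab$tau_ns[nrow(tab)], 10, tolerance = 1e-2)
})

test_that("photothermal series matches repeated single-shot simulation", {
  trace <- data.frame(time_s = seq(0.1, 2, by = 0.1),
                      temperature_C = 36.5)
  gt <- small_gt()
  curves <- simulate_photothermal_series(gt, trace, seed = 3)
  expect_length(curves, nrow(trace))
  taus <- vapply(curves, average_lifetime, numeric(1))
  # statistically identical to repeated simulate_decay at the same T
  set.seed(4)
  ref <- replicate(40, average_lifetime(
    simulate_decay(gt, 614, 36.5, integration_time = 0.1)))
  expect_lt(abs(mean(taus) - mean(ref)),
            4 * sqrt(sd(taus)^2 / length(taus) + sd(ref)^2 / length(ref)))
  expect_error(simulate_photothermal_series(gt, trace[0, ]), "non-empty")
  bad <- data.frame(time_s = c(0.1, 0.2, 0.4), temperature_C = 36.5)
  expect_error(simulate_photothermal_series(gt, bad), "equally spaced")
})

test_that("decay curves and calibration tables round-trip through text files", {
  cv <- simulate_decay(fx_gt, 614, 36.5, seed = 12)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_decay_curve(cv, p)
  cv2 <- read_decay_curve(p)
  expect_equal(cv2$counts, cv$counts)
  expect_equal(cv2$bin_edges, cv$bin_edges, tolerance = 1e-9)
  expect_equal(cv2$temperature, cv$temperature)
  tab <- simulate_calibration_dataset(fx_cal$gt, 614, seq(25, 50, 5),
                                      noise_sd = 0.1, seed = 2)
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_calibration_table(tab, p2)
  expect_equal(read_calibration_table(p2), tab, tolerance = 1e-10)
  # bundled series container
  gt <- small_gt()
  trace <- data.frame(time_s = seq(0.1, 0.5, by = 0.1),
                      temperature_C = c(36.5, 36.6, 36.8, 37, 37.1))
  series <- simulate_photothermal_series(gt, trace, seed = 8)
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_decay_series(series, p3)
  back <- read_decay_series(p3)
  expect_length(back, 5)
  expect_equal(back[[3]]$counts, series[[3]]$counts)
  expect_equal(back[[3]]$temperature, 36.8)
  expect_equal(back[[5]]$integration_time, series[[5]]$integration_time)
})
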