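#' Fit a biphasic dose-response calibration curve
#'
#' Least-squares fit of the double-logistic (biphasic dose-response)
#' function
#' \deqn{\tau(T) = low + (high - low)\left[\frac{f}{1 + 10^{s_1 (T - m_1)}}
#'   + \frac{1 - f}{1 + 10^{s_2 (T - m_2)}}\right]}
#' to a lifetime-vs-temperature table, the standard parameterization for a
#' melting transition with (possibly) two overlapping steps. Initialization
#' uses the 10th/90th percentiles of the lifetimes for the plateaus and the
#' steepest-gradient temperature for the midpoints; optimisation is bounded
#' Levenberg-Marquardt ([minpack.lm::nlsLM()]).
#'
#' @param table Data frame with columns `temperature_C` and `tau_ns`
#'   (>= 8 points spanning both plateaus).
#' @return An object of class `cns_calibration` with components
#'   `coefficients` (named vector: `plateau_high`, `plateau_low`,
#'   `fraction`, `t_mid1`, `t_mid2`, `slope1`, `slope2`), `valid_range`,
#'   `data`, `fit` (the underlying `nls` object) and `sigma` (residual
#'   standard deviation).
#' @seealso [predict.cns_calibration()], [sensitivity_profile()],
#'   [temperature_readout()].
#' @export
fit_biphasic <- function(table) {
  if (!all(c("temperature_C", "tau_ns") %in% names(table))) {
    stop("`table` needs columns temperature_C and tau_ns", call. = FALSE)
  }
  tab <- table[order(table$temperature_C), , drop = FALSE]
  if (nrow(tab) < 8L) stop("need >= 8 calibration points", call. = FALSE)
  T <- tab$temperature_C; tau <- tab$tau_ns
  span <- diff(range(tau))
  if (span < max(1e-8, 0.02 * mean(abs(tau)))) {
    stop("degenerate calibration: no lifetime transition in the data",
         call. = FALSE)
  }
  hi0 <- stats::quantile(tau, 0.9, names = FALSE)
  lo0 <- stats::quantile(tau, 0.1, names = FALSE)
  # steepest descent location from a lightly smoothed gradient
  sm <- stats::lowess(T, tau, f = max(0.15, 8 / length(T)))
  grad <- diff(sm$y) / diff(sm$x)
  m0 <- sm$x[which.min(grad)]
  if (m0 <= T[2] || m0 >= T[length(T) - 1L]) {
    warning("calibration data may not span the transition")
  }
  dat <- data.frame(T = T, tau = tau)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500)
  # single-transition special case (fraction = 1); also the fallback when
  # the second component is not supported by the data
  fit1 <- try(minpack.lm::nlsLM(
    tau ~ low + (high - low) / (1 + 10^(s1 * (T - m1))),
    data = dat, start = list(high = hi0, low = lo0, m1 = m0, s1 = 0.5),
    lower = c(high = lo0, low = min(tau) - span, m1 = min(T) - 5,
              s1 = 0.01),
    upper = c(high = max(tau) + span, low = hi0, m1 = max(T) + 5, s1 = 5),
    control = ctrl), silent = TRUE)
  fit2 <- try(minpack.lm::nlsLM(
    tau ~ low + (high - low) * (f / (1 + 10^(s1 * (T - m1))) +
                                  (1 - f) / (1 + 10^(s2 * (T - m2)))),
    data = dat,
    start = list(high = hi0, low = lo0, f = 0.5,
                 m1 = m0 - 0.5, m2 = m0 + 0.5, s1 = 0.5, s2 = 0.5),
    lower = c(high = lo0, low = min(tau) - span, f = 0,
              m1 = min(T) - 5, m2 = min(T) - 5, s1 = 0.01, s2 = 0.01),
    upper = c(high = max(tau) + span, low = hi0, f = 1,
              m1 = max(T) + 5, m2 = max(T) + 5, s1 = 5, s2 = 5),
    control = ctrl), silent = TRUE)
  ok1 <- !inherits(fit1, "try-error"); ok2 <- !inherits(fit2, "try-error")
  if (!ok1 && !ok2) {
    stop("biphasic fit failed to converge: ",
         attr(fit2, "condition")$message, call. = FALSE)
  }
  # keep the second transition only when AIC clearly supports it; an
  # over-parameterized double logistic on single-step data otherwise
  # invents a spurious sharp component
  use2 <- ok2 && (!ok1 || stats::AIC(fit2) < stats::AIC(fit1) - 2)
  fit <- if (use2) fit2 else fit1
  cf <- stats::coef(fit)
  co <- if (use2) {
    c(plateau_high = unname(cf["high"]), plateau_low = unname(cf["low"]),
      fraction = unname(cf["f"]), t_mid1 = unname(cf["m1"]),
      t_mid2 = unname(cf["m2"]), slope1 = unname(cf["s1"]),
      slope2 = unname(cf["s2"]))
  } else {
    c(plateau_high = unname(cf["high"]), plateau_low = unname(cf["low"]),
      fraction = 1, t_mid1 = unname(cf["m1"]), t_mid2 = unname(cf["m1"]),
      slope1 = unname(cf["s1"]), slope2 = unname(cf["s1"]))
  }
  structure(list(coefficients = co, valid_range = range(T),
                 data = tab, fit = fit,
                 sigma = sqrt(mean(stats::residuals(fit)^2))),
            class = "cns_calibration")
}

biphasic_eval <- function(co, T) {
  co["plateau_low"] + (co["plateau_high"] - co["plateau_low"]) *
    (co["fraction"] / (1 + 10^(co["slope1"] * (T - co["t_mid1"]))) +
       (1 - co["fraction"]) / (1 + 10^(co["slope2"] * (T - co["t_mid2"]))))
}

biphasic_deriv <- function(co, T) {
  q1 <- 1 / (1 + 10^(co["slope1"] * (T - co["t_mid1"])))
  q2 <- 1 / (1 + 10^(co["slope2"] * (T - co["t_mid2"])))
  -(co["plateau_high"] - co["plateau_low"]) * log(10) *
    (co["fraction"] * co["slope1"] * q1 * (1 - q1) +
       (1 - co["fraction"]) * co["slope2"] * q2 * (1 - q2))
}

#' @export
print.cns_calibration <- function(x, ...) {
  co <- x$coefficients
  cat("Biphasic lifetime-temperature calibration\n")
  cat(sprintf("  plateaus: %.2f -> %.2f ns; valid %g-%g C\n",
              co["plateau_high"], co["plateau_low"],
              x$valid_range[1], x$valid_range[2]))
  cat(sprintf("  midpoints %.2f / %.2f C (fraction %.2f), decade slopes %.2f / %.2f per C\n",
              co["t_mid1"], co["t_mid2"], co["fraction"],
              co["slope1"], co["slope2"]))
  cat(sprintf("  residual sd %.3g ns on %d points\n", x$sigma, nrow(x$data)))
  invisible(x)
}

#' @export
summary.cns_calibration <- function(object, ...) {
  sp <- sensitivity_profile(object)
  structure(list(cal = object,
                 max_sr = attr(sp, "max_sensitivity"),
                 max_sr_at = attr(sp, "argmax_temperature")),
            class = "summary.cns_calibration")
}

#' @export
print.summary.cns_calibration <- function(x, ...) {
  print(x$cal)
  cat(sprintf("  max relative sensitivity %.1f %%/C at %.2f C\n",
              x$max_sr, x$max_sr_at))
  invisible(x)
}

#' @export
coef.cns_calibration <- function(object, ...) object$coefficients

#' @export
residuals.cns_calibration <- function(object, ...) {
  object$data$tau_ns - biphasic_eval(object$coefficients,
                                     object$data$temperature_C)
}

#' Predict lifetime from a fitted calibration
#'
#' @param object A `cns_calibration`.
#' @param temperature Temperatures in degrees C (default the calibration
#'   data's temperatures).
#' @param ... Unused.
#' @return Fitted lifetimes in ns.
#' @export
predict.cns_calibration <- function(object, temperature = NULL, ...) {
  if (is.null(temperature)) temperature <- object$data$temperature_C
  unname(biphasic_eval(object$coefficients, temperature))
}

#' @export
plot.cns_calibration <- function(x, ...) {
  Tg <- seq(x$valid_range[1], x$valid_range[2], length.out = 400)
  graphics::plot(x$data$temperature_C, x$data$tau_ns,
                 xlab = "temperature (C)", ylab = "average lifetime (ns)",
                 main = "biphasic calibration", ...)
  graphics::lines(Tg, predict(x, Tg), col = 2, lwd = 2)
  invisible(x)
}

#' Relative-sensitivity profile of a fitted calibration
#'
#' S_r(T) = 100 |d tau/dT| / tau evaluated with the analytic derivative of
#' the biphasic form on a temperature grid.
#'
#' @param cal A `cns_calibration`.
#' @param temperatures Temperature grid in degrees C (default: the valid
#'   range sampled at 0.01 C).
#' @return Data frame with columns `temperature_C`, `sr_pct_per_C` and
#'   `dtau_dT_ns_per_C`; attributes `max_sensitivity` (%/C) and
#'   `argmax_temperature` (C).
#' @export
sensitivity_profile <- function(cal, temperatures = NULL) {
  stopifnot(inherits(cal, "cns_calibration"))
  if (is.null(temperatures)) {
    temperatures <- seq(cal$valid_range[1], cal$valid_range[2], by = 0.01)
  }
  tau <- biphasic_eval(cal$coefficients, temperatures)
  d <- biphasic_deriv(cal$coefficients, temperatures)
  sr <- 100 * abs(d) / tau
  out <- data.frame(temperature_C = temperatures,
                    sr_pct_per_C = unname(sr),
                    dtau_dT_ns_per_C = unname(d))
  i <- which.max(out$sr_pct_per_C)
  attr(out, "max_sensitivity") <- out$sr_pct_per_C[i]
  attr(out, "argmax_temperature") <- out$temperature_C[i]
  out
}

#' Invert a calibration: lifetime to temperature
#'
#' Numeric inversion by monotone interpolation of the fitted curve sampled
#' at 1000 points across the valid range. Lifetimes outside the calibrated
#' range are clipped to the range edge and flagged; ties on flat segments
#' resolve to the lower temperature.
#'
#' @param cal A `cns_calibration`.
#' @param tau Lifetimes in ns.
#' @return Data frame with columns `tau_ns`, `temperature_C`, `clipped`.
#' @export
invert_calibration <- function(cal, tau) {
  stopifnot(inherits(cal, "cns_calibration"))
  Tg <- seq(cal$valid_range[1], cal$valid_range[2], length.out = 1000)
  taug <- predict(cal, Tg)
  if (any(diff(taug) > 1e-9 * max(abs(taug)))) {
    stop("calibration is not monotone non-increasing; cannot invert",
         call. = FALSE)
  }
  lo <- min(taug); hi <- max(taug)
  clipped <- tau > hi | tau < lo
  tc <- pmin(pmax(tau, lo), hi)
  # taug is non-increasing in T; ties = min picks the lower temperature
  Tout <- stats::approx(x = taug, y = Tg, xout = tc, ties = min)$y
  # refine the interpolated guess by root finding on the fitted curve;
  # skip flat segments, where the tie rule already fixed the answer
  half <- diff(cal$valid_range) / 999
  co <- cal$coefficients
  for (i in seq_along(Tout)) {
    lb <- max(Tout[i] - half, cal$valid_range[1])
    ub <- min(Tout[i] + half, cal$valid_range[2])
    f_lb <- biphasic_eval(co, lb) - tc[i]
    f_ub <- biphasic_eval(co, ub) - tc[i]
    if (is.finite(f_lb) && is.finite(f_ub) && f_lb * f_ub < 0 &&
        abs(f_lb - f_ub) > 1e-12) {
      Tout[i] <- stats::uniroot(function(T) biphasic_eval(co, T) - tc[i],
                                c(lb, ub), tol = 1e-9)$root
    }
  }
  data.frame(tau_ns = tau, temperature_C = Tout, clipped = clipped)
}

#' Temperature readout of a decay-curve sequence
#'
#' For each curve, estimates the average lifetime (directly with
#' [average_lifetime()], or -- when a trained denoiser is supplied -- from
#' the denoised square-spiral image of the curve) and inverts the fitted
#' calibration to a temperature. Out-of-range lifetimes are clipped to the
#' calibrated range and flagged.
#'
#' @param curves A list of [decay_curve()]s (or a single curve).
#' @param cal A `cns_calibration`.
#' @param denoiser Optional trained denoiser from [train_denoiser()].
#' @param side Spiral image side used with the denoiser (default from the
#'   denoiser spec).
#' @return Data frame with columns `time_s` (cumulative acquisition time),
#'   `tau_ns`, `temperature_C`, `clipped`.
#' @export
temperature_readout <- function(curves, cal, denoiser = NULL, side = NULL) {
  stopifnot(inherits(cal, "cns_calibration"))
  if (inherits(curves, "decay_curve")) curves <- list(curves)
  tau <- vapply(curves, function(cv) {
    if (is.null(denoiser)) {
      average_lifetime(cv)
    } else {
      s <- if (is.null(side)) denoiser$spec$side else side
      lifetime_from_image(denoise(denoiser, spiral_encode(cv, s)))
    }
  }, numeric(1))
  inv <- invert_calibration(cal, tau)
  dt <- vapply(curves, function(cv) cv$integration_time, numeric(1))
  data.frame(time_s = cumsum(dt), tau_ns = tau,
             temperature_C = inv$temperature_C, clipped = inv$clipped)
}

#' Lifetime precision versus integration time
#'
#' For each integration time, simulates repeated acquisitions, computes
#' the spread delta_tau (sample standard deviation of the average-lifetime
#' estimates), converts it to a thermal resolution
#' delta_T = delta_tau / |d tau/dT| using the calibration slope at the
#' acquisition temperature (equivalently S_r^-1 delta_tau / tau), and
#' reports the temporal-thermal figure of merit delta_t * delta_T.
#'
#' @param gt A [ground_truth_config()].
#' @param integration_times Vector of integration times in s.
#' @param temperature Acquisition temperature in degrees C.
#' @param cal A `cns_calibration` used for the slope.
#' @param wavelength Emission wavelength in nm (default 614).
#' @param n_reps Repeats per integration time (>= 30).
#' @param seed Optional integer seed.
#' @return Data frame of class `precision_report` with columns
#'   `integration_time_s`, `mean_tau_ns`, `delta_tau_ns`, `delta_T_C`,
#'   `product_Cs`.
#' @export
precision_vs_integration <- function(gt, integration_times, temperature,
                                     cal, wavelength = 614, n_reps = 100,
                                     seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_config"),
            inherits(cal, "cns_calibration"))
  if (n_reps < 30) stop("need n_reps >= 30", call. = FALSE)
  w <- mixture_weights(gt$model, wavelength, temperature)
  if (!is.finite(w$w_A) || w$intensity <= 0) {
    stop("zero expected signal at this wavelength", call. = FALSE)
  }
  slope <- abs(biphasic_deriv(cal$coefficients, temperature))
  with_seed(seed, {
    rows <- lapply(integration_times, function(dt) {
      taus <- vapply(seq_len(n_reps), function(i) {
        average_lifetime(simulate_decay(gt, wavelength, temperature,
                                        integration_time = dt))
      }, numeric(1))
      dtau <- stats::sd(taus)
      data.frame(integration_time_s = dt, mean_tau_ns = mean(taus),
                 delta_tau_ns = dtau, delta_T_C = dtau / slope,
                 product_Cs = dt * dtau / slope)
    })
    out <- do.call(rbind, rows)
    class(out) <- c("precision_report", "data.frame")
    out
  })
}

#' Write / read a fitted calibration as a structured config file
#'
#' Serializes the fitted parameters and valid range to YAML.
#'
#' @param cal A `cns_calibration`.
#' @param path File path.
#' @return `write_calibration` returns `path` invisibly;
#'   `read_calibration` returns a `cns_calibration` (without the original
#'   `nls` fit object).
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "cns_calibration"))
  yaml::write_yaml(list(coefficients = as.list(cal$coefficients),
                        valid_range = cal$valid_range,
                        sigma = cal$sigma), path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  y <- yaml::read_yaml(path)
  co <- unlist(y$coefficients)
  Tg <- seq(y$valid_range[1], y$valid_range[2], length.out = 50)
  structure(list(coefficients = co, valid_range = as.numeric(y$valid_range),
                 data = data.frame(temperature_C = Tg,
                                   tau_ns = unname(biphasic_eval(co, Tg))),
                 fit = NULL, sigma = y$sigma),
            class = "cns_calibration")
}
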