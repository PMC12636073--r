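#' Configuration of the laser-heated cuvette simulation
#'
#' Geometry, material, laser and boundary parameters for the conduction
#' model of a thermostatted cuvette heated by an infrared laser through
#' water absorption. The liquid column is `volume_uL` microlitres in a
#' square cross-section of `cross_section` metres per side; the beam
#' enters through one side wall (along x) at mid-height with Beer-Lambert
#' attenuation exp(-mu_a x) inside its footprint.
#'
#' Walls exchange heat with the thermostat either through a perfect
#' contact (`boundary = "dirichlet"`, walls clamped at
#' `wall_temperature`) or through a finite film conductance
#' (`boundary = "robin"`, heat-transfer coefficient `wall_h` in
#' W m-2 K-1 representing the glass wall plus imperfect holder contact);
#' the free top surface is adiabatic.
#'
#' @param cross_section Inner cuvette side in m (default 3e-3).
#' @param volume_uL Liquid volume in microlitres (default 100).
#' @param nx,ny,nz Grid cells per axis (defaults 30, 30, 56).
#' @param dt Time step in s (default 0.05; the ADI scheme is
#'   unconditionally stable, the step is for temporal accuracy).
#' @param conductivity Thermal conductivity in W m-1 K-1 (water, 0.6).
#' @param density Density in kg m-3 (998).
#' @param heat_capacity Specific heat in J kg-1 K-1 (4182).
#' @param absorption_coefficient Absorption coefficient in 1/m at the
#'   laser wavelength (3000 at 1450 nm).
#' @param laser_power Laser power in W (0.015).
#' @param beam_radius Beam radius in m (default 0.5e-3).
#' @param beam_profile `"tophat"` or `"gaussian"` (1/e^2 radius =
#'   `beam_radius`).
#' @param boundary `"robin"` (default) or `"dirichlet"`.
#' @param wall_h Film coefficient for the Robin condition in W m-2 K-1
#'   (default 80; see the methods vignette for the film estimate).
#' @param wall_temperature Thermostat temperature in degrees C (36.5).
#' @param initial_temperature Initial liquid temperature in degrees C
#'   (default equal to the wall temperature).
#' @return An object of class `heat_sim_config`.
#' @export
heat_sim_config <- function(cross_section = 3e-3, volume_uL = 100,
                            nx = 30, ny = 30, nz = 56, dt = 0.05,
                            conductivity = 0.6, density = 998,
                            heat_capacity = 4182,
                            absorption_coefficient = 3000,
                            laser_power = 0.015, beam_radius = 0.5e-3,
                            beam_profile = c("tophat", "gaussian"),
                            boundary = c("robin", "dirichlet"),
                            wall_h = 80, wall_temperature = 36.5,
                            initial_temperature = wall_temperature) {
  beam_profile <- match.arg(beam_profile)
  boundary <- match.arg(boundary)
  height <- volume_uL * 1e-9 / cross_section^2
  phys <- c(cross_section = cross_section, volume_uL = volume_uL, dt = dt,
            conductivity = conductivity, density = density,
            heat_capacity = heat_capacity,
            absorption_coefficient = absorption_coefficient,
            beam_radius = beam_radius, wall_h = wall_h)
  if (any(phys <= 0)) stop("all physical parameters must be positive",
                           call. = FALSE)
  if (laser_power < 0) stop("`laser_power` must be >= 0", call. = FALSE)
  dy <- cross_section / ny; dz <- height / nz
  if (2 * beam_radius / min(dy, dz) < 4) {
    stop("grid does not resolve the beam (need >= 4 cells across)",
         call. = FALSE)
  }
  structure(list(cross_section = cross_section, volume_uL = volume_uL,
                 height = height, nx = as.integer(nx), ny = as.integer(ny),
                 nz = as.integer(nz), dt = dt, conductivity = conductivity,
                 density = density, heat_capacity = heat_capacity,
                 absorption_coefficient = absorption_coefficient,
                 laser_power = laser_power, beam_radius = beam_radius,
                 beam_profile = beam_profile, boundary = boundary,
                 wall_h = wall_h, wall_temperature = wall_temperature,
                 initial_temperature = initial_temperature),
            class = "heat_sim_config")
}

# allow zero laser power explicitly (homogeneous problem)
#' @export
print.heat_sim_config <- function(x, ...) {
  cat(sprintf(
    "<heat_sim_config: %g x %g x %.3g mm, %dx%dx%d grid, dt %g s, %s walls at %g C, %g mW %s beam>\n",
    x$cross_section * 1e3, x$cross_section * 1e3, x$height * 1e3,
    x$nx, x$ny, x$nz, x$dt, x$boundary, x$wall_temperature,
    x$laser_power * 1e3, x$beam_profile))
  invisible(x)
}

# ghost coefficient beta (ghost = beta * u) per boundary type
ghost_beta <- function(cfg, h_step, face_adiabatic = FALSE) {
  if (face_adiabatic) return(1)
  if (cfg$boundary == "dirichlet") return(-1)
  a <- cfg$conductivity / h_step
  (a - cfg$wall_h / 2) / (a + cfg$wall_h / 2)
}

# volumetric source in K/s on the cell-centred grid
heat_source <- function(cfg) {
  dx <- cfg$cross_section / cfg$nx
  dy <- cfg$cross_section / cfg$ny
  dz <- cfg$height / cfg$nz
  x <- (seq_len(cfg$nx) - 0.5) * dx
  y <- (seq_len(cfg$ny) - 0.5) * dy
  z <- (seq_len(cfg$nz) - 0.5) * dz
  y0 <- cfg$cross_section / 2; z0 <- cfg$height / 2
  r2 <- outer((y - y0)^2, (z - z0)^2, "+")
  foot <- if (cfg$beam_profile == "tophat") {
    i0 <- cfg$laser_power / (pi * cfg$beam_radius^2)
    i0 * (r2 <= cfg$beam_radius^2)
  } else {
    i0 <- 2 * cfg$laser_power / (pi * cfg$beam_radius^2)
    i0 * exp(-2 * r2 / cfg$beam_radius^2)
  }
  mu <- cfg$absorption_coefficient
  q <- array(0, c(cfg$nx, cfg$ny, cfg$nz))
  ax <- mu * exp(-mu * x)
  for (i in seq_len(cfg$nx)) q[i, , ] <- ax[i] * foot
  q / (cfg$density * cfg$heat_capacity)   # K/s
}

# explicit second-difference operator along one axis with ghost betas
axis_lap <- function(u, axis, h_step, b_lo, b_hi) {
  n <- dim(u)[axis]
  um <- up <- u
  if (axis == 1) {
    um[2:n, , ] <- u[1:(n - 1), , ]; um[1, , ] <- b_lo * u[1, , ]
    up[1:(n - 1), , ] <- u[2:n, , ]; up[n, , ] <- b_hi * u[n, , ]
  } else if (axis == 2) {
    um[, 2:n, ] <- u[, 1:(n - 1), ]; um[, 1, ] <- b_lo * u[, 1, ]
    up[, 1:(n - 1), ] <- u[, 2:n, ]; up[, n, ] <- b_hi * u[, n, ]
  } else {
    um[, , 2:n] <- u[, , 1:(n - 1)]; um[, , 1] <- b_lo * u[, , 1]
    up[, , 1:(n - 1)] <- u[, , 2:n]; up[, , n] <- b_hi * u[, , n]
  }
  (up - 2 * u + um) / h_step^2
}

# Thomas-algorithm factorization for (I - c D2) with ghost betas; solves
# many right-hand sides (columns) simultaneously.
tridiag_plan <- function(n, c_coef, b_lo, b_hi) {
  diag <- c(1 + c_coef * (2 - b_lo), rep(1 + 2 * c_coef, n - 2),
            1 + c_coef * (2 - b_hi))
  off <- -c_coef
  cp <- numeric(n - 1)
  denom <- numeric(n)
  denom[1] <- diag[1]
  for (i in 2:n) {
    cp[i - 1] <- off / denom[i - 1]
    denom[i] <- diag[i] - off * cp[i - 1]
  }
  list(n = n, off = off, cp = cp, denom = denom)
}

tridiag_solve <- function(plan, B) {
  n <- plan$n
  D <- B
  D[1, ] <- B[1, ] / plan$denom[1]
  for (i in 2:n) {
    D[i, ] <- (B[i, ] - plan$off * D[i - 1, ]) / plan$denom[i]
  }
  for (i in (n - 1):1) {
    D[i, ] <- D[i, ] - plan$cp[i] * D[i + 1, ]
  }
  D
}

solve_axis <- function(plan, rhs, axis) {
  d <- dim(rhs)
  perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
  m <- aperm(rhs, perm)
  dm <- dim(m)
  sol <- tridiag_solve(plan, matrix(m, nrow = dm[1]))
  dim(sol) <- dm
  aperm(sol, order(perm))
}

#' Solve the 3D heat equation for the laser-heated cuvette
#'
#' Advances rho c dT/dt = k lap(T) + Q with the Douglas
#' alternating-direction-implicit scheme (unconditionally stable,
#' second-order in space and time). The source Q is the Beer-Lambert
#' deposition of the laser beam; boundaries follow the configured wall
#' condition with an adiabatic free top surface.
#'
#' @param config A [heat_sim_config()].
#' @param t_end Simulated time in s.
#' @param trace_stride Record the volume-average temperature every this
#'   many steps (default 1).
#' @return An object of class `heat_sim_result`: `field` (3D array of
#'   absolute temperatures in degrees C at `t_end`), `trace` (data frame
#'   `time_s`, `temperature_C` of volume averages), `config`.
#' @export
solve_heat <- function(config, t_end = 100, trace_stride = 1L) {
  stopifnot(inherits(config, "heat_sim_config"))
  if (t_end <= 0) stop("`t_end` must be positive", call. = FALSE)
  cfg <- config
  dx <- cfg$cross_section / cfg$nx
  dy <- cfg$cross_section / cfg$ny
  dz <- cfg$height / cfg$nz
  alpha <- cfg$conductivity / (cfg$density * cfg$heat_capacity)
  dt <- cfg$dt
  n_steps <- max(1L, round(t_end / dt))
  s <- heat_source(cfg) * dt
  bx <- ghost_beta(cfg, dx); by <- ghost_beta(cfg, dy)
  bz_lo <- ghost_beta(cfg, dz); bz_hi <- ghost_beta(cfg, dz, TRUE)
  cx <- alpha * dt / (2 * dx^2); cy <- alpha * dt / (2 * dy^2)
  cz <- alpha * dt / (2 * dz^2)
  px <- tridiag_plan(cfg$nx, cx, bx, bx)
  py <- tridiag_plan(cfg$ny, cy, by, by)
  pz <- tridiag_plan(cfg$nz, cz, bz_lo, bz_hi)
  u <- array(cfg$initial_temperature - cfg$wall_temperature,
             c(cfg$nx, cfg$ny, cfg$nz))
  times <- avg <- numeric(ceiling(n_steps / trace_stride))
  k_out <- 0L
  for (step in seq_len(n_steps)) {
    ax <- alpha * axis_lap(u, 1, dx, bx, bx)
    ay <- alpha * axis_lap(u, 2, dy, by, by)
    az <- alpha * axis_lap(u, 3, dz, bz_lo, bz_hi)
    rhs <- u + dt * (ax + ay + az) + s
    u1 <- solve_axis(px, rhs - dt / 2 * ax, 1)
    u2 <- solve_axis(py, u1 - dt / 2 * ay, 2)
    u <- solve_axis(pz, u2 - dt / 2 * az, 3)
    if (step %% trace_stride == 0L) {
      k_out <- k_out + 1L
      times[k_out] <- step * dt
      avg[k_out] <- mean(u) + cfg$wall_temperature
    }
  }
  structure(list(field = u + cfg$wall_temperature,
                 trace = data.frame(time_s = times[seq_len(k_out)],
                                    temperature_C = avg[seq_len(k_out)]),
                 config = cfg),
            class = "heat_sim_result")
}

#' @export
print.heat_sim_result <- function(x, ...) {
  cat(sprintf(
    "<heat_sim_result: %d trace points to %g s; final avg %.3f C, max %.3f C>\n",
    nrow(x$trace), max(x$trace$time_s),
    utils::tail(x$trace$temperature_C, 1), max(x$field)))
  invisible(x)
}

#' Steady-state statistics of a heat simulation
#'
#' Volume-average and maximum temperature rise over the initial
#' temperature, the mid-plane (y = centre) cross-section through the beam
#' axis, and the discrete energy balance: absorbed laser power versus
#' conductive power leaving through the walls (equal at steady state).
#'
#' @param result A `heat_sim_result`.
#' @param map_path Optional TIFF path for the cross-section map
#'   (16-bit grayscale, normalized to the maximum rise).
#' @return List with `avg_dT`, `max_dT` (degrees C), `map` (nx x nz
#'   matrix of temperature rise), `power_absorbed_W`, `power_out_W`.
#' @export
steady_state_stats <- function(result, map_path = NULL) {
  stopifnot(inherits(result, "heat_sim_result"))
  cfg <- result$config
  u <- result$field - cfg$initial_temperature
  dx <- cfg$cross_section / cfg$nx
  dy <- cfg$cross_section / cfg$ny
  dz <- cfg$height / cfg$nz
  map <- u[, ceiling(cfg$ny / 2), ]
  # discrete wall heat flow consistent with the stencil: for ghost = beta*u,
  # the flux out through the face is k * u * (1 - beta) / h per unit area
  uw <- result$field - cfg$wall_temperature
  flux <- function(slab, h_step, beta, area) {
    sum(cfg$conductivity * slab * (1 - beta) / h_step * area)
  }
  bx <- ghost_beta(cfg, dx); by <- ghost_beta(cfg, dy)
  bz <- ghost_beta(cfg, dz)
  p_out <- flux(uw[1, , ], dx, bx, dy * dz) +
    flux(uw[cfg$nx, , ], dx, bx, dy * dz) +
    flux(uw[, 1, ], dy, by, dx * dz) +
    flux(uw[, cfg$ny, ], dy, by, dx * dz) +
    flux(uw[, , 1], dz, bz, dx * dy)   # top face adiabatic
  p_abs <- sum(heat_source(cfg)) * cfg$density * cfg$heat_capacity *
    dx * dy * dz
  if (!is.null(map_path)) {
    mx <- max(map, 1e-12)
    tiff::writeTIFF(pmin(pmax(map / mx, 0), 1), map_path,
                    bits.per.sample = 16L)
  }
  list(avg_dT = mean(u), max_dT = max(u), map = map,
       power_absorbed_W = p_abs, power_out_W = p_out)
}

#' Fit an exponential-rise function to a temperature trace
#'
#' Least-squares fit of T(t) = T0 + dT_inf (1 - exp(-t / tau_heat)),
#' the single-time-constant description of laser heating toward a steady
#' state.
#'
#' @param trace Data frame with columns `time_s`, `temperature_C`.
#' @return Object of class `exp_rise_fit` with `coefficients` (named:
#'   `T0`, `dT_inf`, `tau_heat`), `sigma` (residual sd) and `fit`.
#' @export
fit_exponential_rise <- function(trace) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "temperature_C") %in% names(trace)))
  t <- trace$time_s; y <- trace$temperature_C
  if (length(t) < 4L) stop("trace too short to fit", call. = FALSE)
  rng <- diff(range(y))
  if (rng < 1e-12 || utils::tail(y, 1) <= y[1] + 0.1 * rng) {
    stop("trace is not rising; exponential-rise fit undefined",
         call. = FALSE)
  }
  fit <- try(minpack.lm::nlsLM(
    y ~ T0 + dT * (1 - exp(-t / tau)),
    data = data.frame(t = t, y = y),
    start = list(T0 = y[1], dT = utils::tail(y, 1) - y[1],
                 tau = diff(range(t)) / 3),
    lower = c(T0 = -Inf, dT = 0, tau = 1e-9),
    control = minpack.lm::nls.lm.control(maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) {
    stop("exponential-rise fit failed: ", attr(fit, "condition")$message,
         call. = FALSE)
  }
  cf <- stats::coef(fit)
  if (max(t) < 3 * cf["tau"]) {
    warning("trace covers fewer than 3 characteristic times; ",
            "fitted amplitude is an extrapolation")
  }
  structure(list(coefficients = c(T0 = unname(cf["T0"]),
                                  dT_inf = unname(cf["dT"]),
                                  tau_heat = unname(cf["tau"])),
                 sigma = sqrt(mean(stats::residuals(fit)^2)), fit = fit),
            class = "exp_rise_fit")
}

#' @export
print.exp_rise_fit <- function(x, ...) {
  co <- x$coefficients
  cat(sprintf(
    "Exponential rise: T0 = %.3f C, dT_inf = %.3f C, tau = %.2f s (residual sd %.2g C)\n",
    co["T0"], co["dT_inf"], co["tau_heat"], x$sigma))
  invisible(x)
}

#' @export
coef.exp_rise_fit <- function(object, ...) object$coefficients

#' Write / read a heat-simulation trace as delimited text
#'
#' @param trace Data frame with `time_s`, `temperature_C`.
#' @param path File path.
#' @return `write_trace` returns `path` invisibly; `read_trace` the data
#'   frame.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(trace[, c("time_s", "temperature_C")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) utils::read.delim(path)
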