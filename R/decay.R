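#' Binned photon-count decay curve
#'
#' Container for a time-correlated single-photon-counting (TCSPC)
#' histogram: photon counts per uniform time bin, together with the
#' acquisition metadata the analysis needs (emission wavelength,
#' temperature if known, integration time).
#'
#' @param bin_edges Ascending, uniformly spaced bin edges in ns
#'   (`length(counts) + 1`).
#' @param counts Non-negative counts per bin.
#' @param wavelength_em Emission wavelength in nm.
#' @param wavelength_exc Excitation wavelength in nm (default 405).
#' @param temperature Sample temperature in degrees C, or `NA` if unknown.
#' @param integration_time Integration time in s.
#' @return An object of class `decay_curve`.
#' @export
decay_curve <- function(bin_edges, counts, wavelength_em,
                        wavelength_exc = 405, temperature = NA_real_,
                        integration_time = 1) {
  bin_edges <- as.numeric(bin_edges)
  counts <- as.numeric(counts)
  if (length(bin_edges) != length(counts) + 1L) {
    stop("need length(bin_edges) == length(counts) + 1", call. = FALSE)
  }
  w <- diff(bin_edges)
  if (any(w <= 0) || diff(range(w)) > 1e-9 * mean(w)) {
    stop("bin edges must be ascending and uniform", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  structure(
    list(bin_edges = bin_edges, counts = counts,
         wavelength_em = wavelength_em, wavelength_exc = wavelength_exc,
         temperature = temperature, integration_time = integration_time),
    class = "decay_curve"
  )
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf(
    "<decay_curve: %d bins over %g-%g ns, %.3g counts, em %g nm, %s, dt %g s>\n",
    length(x$counts), min(x$bin_edges), max(x$bin_edges), sum(x$counts),
    x$wavelength_em,
    if (is.na(x$temperature)) "T unknown" else sprintf("%.2f C", x$temperature),
    x$integration_time))
  invisible(x)
}

bin_midpoints <- function(curve) {
  (curve$bin_edges[-1] + curve$bin_edges[-length(curve$bin_edges)]) / 2
}

#' Photon budget of the simulated instrument
#'
#' Expected total detected photons for a 1 s integration, together with the
#' histogram geometry. Expected counts scale linearly with integration
#' time. The default budget (5e5 counts/s, 1024 bins over 0-200 ns, i.e.
#' ~0.195 ns bins) is the canonical simulation setting.
#'
#' @param counts_per_second Expected detected photons per second (> 0).
#' @param bin_count Number of histogram bins (>= 2).
#' @param window Histogram span in ns.
#' @return An object of class `photon_budget`.
#' @export
photon_budget <- function(counts_per_second = 5e5, bin_count = 1024L,
                          window = 200) {
  if (counts_per_second <= 0) stop("`counts_per_second` must be > 0",
                                   call. = FALSE)
  if (bin_count < 2L) stop("`bin_count` must be >= 2", call. = FALSE)
  if (window <= 0) stop("`window` must be > 0", call. = FALSE)
  structure(list(counts_per_second = counts_per_second,
                 bin_count = as.integer(bin_count), window = window),
            class = "photon_budget")
}

#' Two-population (monomer/excimer) emission model
#'
#' The forward model for the average lifetime: at wavelength lambda and
#' temperature T the emitted intensities of the aggregated and monomeric
#' states are I_A = alpha N_A(T) g_A(lambda) and
#' I_M = alpha N_M(T) g_M(lambda), with N_M = 1 - N_A, and the average
#' lifetime is their intensity-weighted mean of tau_A and tau_M. The
#' coupling alpha (quantum yield times detection efficiency) is taken
#' equal for both states, so it cancels from all lifetime expressions.
#'
#' @param tau_A Excimer (aggregate) lifetime in ns; must exceed `tau_M`.
#' @param tau_M Monomer lifetime in ns (> 0).
#' @param shapes List with `monomer` and `aggregate`
#'   [emission_line_shape()]s.
#' @param population A [population_model()].
#' @param alpha Positive coupling constant (default 1).
#' @return An object of class `two_state_model`.
#' @export
two_state_model <- function(tau_A, tau_M, shapes, population, alpha = 1) {
  if (!(tau_A > tau_M && tau_M > 0)) stop("need tau_A > tau_M > 0",
                                          call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be positive", call. = FALSE)
  stopifnot(inherits(shapes$monomer, "emission_line_shape"),
            inherits(shapes$aggregate, "emission_line_shape"),
            inherits(population, "population_model"))
  structure(list(tau_A = tau_A, tau_M = tau_M, shapes = shapes,
                 population = population, alpha = alpha),
            class = "two_state_model")
}

#' @export
print.two_state_model <- function(x, ...) {
  cat(sprintf("<two_state_model: tau_A %g ns, tau_M %g ns, alpha %g>\n",
              x$tau_A, x$tau_M, x$alpha))
  print(x$population)
  invisible(x)
}

#' Ground-truth configuration for the synthetic-data generator
#'
#' Bundles a [two_state_model()] with a [photon_budget()] and an optional
#' constant dark-count rate; every simulated dataset derives from one of
#' these.
#'
#' @param model A [two_state_model()].
#' @param budget A [photon_budget()].
#' @param dark_rate Constant dark counts per second spread uniformly over
#'   the histogram (default 0).
#' @return An object of class `ground_truth_config`.
#' @export
ground_truth_config <- function(model, budget = photon_budget(),
                                dark_rate = 0) {
  stopifnot(inherits(model, "two_state_model"),
            inherits(budget, "photon_budget"))
  if (dark_rate < 0) stop("`dark_rate` must be >= 0", call. = FALSE)
  structure(list(model = model, budget = budget, dark_rate = dark_rate),
            class = "ground_truth_config")
}

# Intensity weights (w_A, w_M) of the two states at (lambda, T); sum to 1.
mixture_weights <- function(model, wavelength, temperature) {
  n_a <- population_fraction(model$population, temperature)
  i_a <- model$alpha * n_a * line_shape_at(model$shapes$aggregate, wavelength)
  i_m <- model$alpha * (1 - n_a) * line_shape_at(model$shapes$monomer,
                                                 wavelength)
  tot <- i_a + i_m
  list(w_A = if (tot > 0) i_a / tot else NA_real_,
       w_M = if (tot > 0) i_m / tot else NA_real_,
       intensity = tot)
}

# Peak emitted intensity across the wavelength grid at temperature T,
# the reference against which a channel counts as "zero signal".
peak_intensity <- function(model, temperature) {
  n_a <- population_fraction(model$population, temperature)
  model$alpha * max(n_a * max(model$shapes$aggregate$density),
                    (1 - n_a) * max(model$shapes$monomer$density))
}

# Expected counts per bin for one acquisition. Each state contributes a
# bin-normalized exponential profile weighted by its intensity fraction,
# so the discrete first moment of the expectation reproduces the
# two-population average lifetime (up to finite-window truncation).
expected_decay_counts <- function(gt, wavelength, temperature,
                                  integration_time) {
  b <- gt$budget
  edges <- seq(0, b$window, length.out = b$bin_count + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- mixture_weights(gt$model, wavelength, temperature)
  total <- b$counts_per_second * integration_time
  if (!is.finite(w$w_A)) {
    shape <- rep(0, b$bin_count)
  } else {
    p_a <- exp(-mid / gt$model$tau_A); p_a <- p_a / sum(p_a)
    p_m <- exp(-mid / gt$model$tau_M); p_m <- p_m / sum(p_m)
    shape <- w$w_A * p_a + w$w_M * p_m
  }
  mu <- total * shape + gt$dark_rate * integration_time / b$bin_count
  list(edges = edges, mu = mu, weights = w)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv())) set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Simulate one TCSPC decay curve
#'
#' Draws independent Poisson counts in each time bin around the
#' two-population expected decay at the requested emission wavelength and
#' temperature, with the expected total scaled by the integration time.
#' Identical configuration and seed give identical curves.
#'
#' @param gt A [ground_truth_config()].
#' @param wavelength Emission wavelength in nm.
#' @param temperature Sample temperature in degrees C.
#' @param integration_time Integration time in s (> 0).
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @param noiseless If `TRUE`, return the (non-integer) expected counts
#'   instead of a Poisson draw.
#' @return A [decay_curve()].
#' @export
simulate_decay <- function(gt, wavelength, temperature,
                           integration_time = 1, seed = NULL,
                           noiseless = FALSE) {
  stopifnot(inherits(gt, "ground_truth_config"))
  if (integration_time <= 0) stop("`integration_time` must be > 0",
                                  call. = FALSE)
  e <- expected_decay_counts(gt, wavelength, temperature, integration_time)
  if (!is.finite(e$weights$w_A) || sum(e$mu) == 0) {
    warning(sprintf("zero expected signal at %g nm; returning empty curve",
                    wavelength))
    counts <- rep(0, length(e$mu))
  } else if (e$weights$intensity <
             1e-6 * peak_intensity(gt$model, temperature)) {
    warning(sprintf(
      "negligible expected signal at %g nm (both line shapes ~0 there)",
      wavelength))
    counts <- if (noiseless) e$mu else
      with_seed(seed, stats::rpois(length(e$mu), e$mu))
  } else if (noiseless) {
    counts <- e$mu
  } else {
    counts <- with_seed(seed, stats::rpois(length(e$mu), e$mu))
  }
  decay_curve(e$edges, counts, wavelength_em = wavelength,
              temperature = temperature,
              integration_time = integration_time)
}

#' Simulate a noisy lifetime-vs-temperature calibration table
#'
#' Evaluates the two-population forward model lifetime on a temperature
#' grid and adds Gaussian measurement noise, emulating a calibration sweep
#' in which the average lifetime is measured every fraction of a degree.
#'
#' @param gt A [ground_truth_config()].
#' @param wavelength Emission wavelength in nm.
#' @param temperatures Ascending temperature grid in degrees C.
#' @param noise_sd Standard deviation of additive lifetime noise in ns.
#' @param seed Optional integer seed.
#' @return Data frame with columns `temperature_C` and `tau_ns`.
#' @export
simulate_calibration_dataset <- function(gt, wavelength, temperatures,
                                         noise_sd = 0, seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_config"))
  if (!length(temperatures)) stop("`temperatures` must be non-empty",
                                  call. = FALSE)
  if (is.unsorted(temperatures, strictly = FALSE)) {
    stop("`temperatures` must be ascending", call. = FALSE)
  }
  tau <- vapply(temperatures, function(T)
    model_lifetime(gt$model, wavelength, T), numeric(1))
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(length(tau), sd = noise_sd))
  } else rep(0, length(tau))
  data.frame(temperature_C = as.numeric(temperatures), tau_ns = tau + noise)
}

#' Simulate a photothermal decay-curve series
#'
#' One decay curve per time point of a driving temperature trace (as
#' produced by [solve_heat()]), acquired back-to-back with integration
#' time equal to the trace spacing.
#'
#' @param gt A [ground_truth_config()].
#' @param trace Data frame with columns `time_s` (equally spaced) and
#'   `temperature_C`.
#' @param wavelength Emission wavelength in nm (default 614).
#' @param integration_time Integration time in s; must match the trace
#'   spacing within 1e-9.
#' @param seed Optional integer seed for the whole series.
#' @return List of [decay_curve()]s, one per trace row.
#' @export
simulate_photothermal_series <- function(gt, trace, wavelength = 614,
                                         integration_time = NULL,
                                         seed = NULL) {
  stopifnot(inherits(gt, "ground_truth_config"))
  if (!is.data.frame(trace) ||
      !all(c("time_s", "temperature_C") %in% names(trace)) ||
      nrow(trace) == 0L) {
    stop("`trace` must be a non-empty data frame with time_s, temperature_C",
         call. = FALSE)
  }
  if (nrow(trace) > 1L) {
    dt <- diff(trace$time_s)
    if (diff(range(dt)) > 1e-9 * mean(dt)) {
      stop("trace times must be equally spaced", call. = FALSE)
    }
    spacing <- mean(dt)
  } else {
    if (is.null(integration_time)) {
      stop("`integration_time` is required for a single-point trace",
           call. = FALSE)
    }
    spacing <- integration_time
  }
  if (is.null(integration_time)) integration_time <- spacing
  if (abs(integration_time - spacing) > 1e-9) {
    stop("`integration_time` must equal the trace spacing", call. = FALSE)
  }
  with_seed(seed, lapply(seq_len(nrow(trace)), function(i) {
    simulate_decay(gt, wavelength, trace$temperature_C[i],
                   integration_time = integration_time, seed = NULL)
  }))
}

#' Write / read a decay curve as delimited text
#'
#' Tab-separated columns `time_ns` (bin midpoint) and `counts`, with the
#' acquisition metadata stored in `#`-prefixed header lines.
#'
#' @param curve A [decay_curve()].
#' @param path File path.
#' @return `write_decay_curve` returns `path` invisibly;
#'   `read_decay_curve` returns a [decay_curve()].
#' @export
write_decay_curve <- function(curve, path) {
  stopifnot(inherits(curve, "decay_curve"))
  hdr <- c(
    sprintf("# wavelength_em_nm: %g", curve$wavelength_em),
    sprintf("# wavelength_exc_nm: %g", curve$wavelength_exc),
    sprintf("# temperature_C: %g", curve$temperature),
    sprintf("# integration_time_s: %g", curve$integration_time),
    sprintf("# bin_width_ns: %.12g", diff(curve$bin_edges)[1]),
    "time_ns\tcounts")
  body <- sprintf("%.12g\t%.12g", bin_midpoints(curve), curve$counts)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_decay_curve
#' @export
read_decay_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- function(key, default = NA_real_) {
    m <- grep(paste0("^# ", key, ":"), hdr, value = TRUE)
    if (!length(m)) return(default)
    as.numeric(sub(".*: *", "", m[1]))
  }
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)])
  width <- meta("bin_width_ns", default = diff(tab$time_ns)[1])
  edges <- c(tab$time_ns - width / 2, tab$time_ns[nrow(tab)] + width / 2)
  decay_curve(edges, tab$counts,
              wavelength_em = meta("wavelength_em_nm"),
              wavelength_exc = meta("wavelength_exc_nm", 405),
              temperature = meta("temperature_C"),
              integration_time = meta("integration_time_s", 1))
}

#' Write / read a decay-curve series as one bundled delimited file
#'
#' Long-format TSV with columns `curve`, `time_ns`, `counts` plus one
#' `#`-prefixed metadata line per curve, for photothermal series and
#' other multi-curve acquisitions.
#'
#' @param curves List of [decay_curve()]s sharing one histogram geometry.
#' @param path File path.
#' @return `write_decay_series` returns `path` invisibly;
#'   `read_decay_series` returns a list of [decay_curve()]s.
#' @export
write_decay_series <- function(curves, path) {
  stopifnot(length(curves) > 0,
            all(vapply(curves, inherits, logical(1), "decay_curve")))
  hdr <- vapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    sprintf("# curve %d: em_nm=%g exc_nm=%g temperature_C=%g dt_s=%g bin_width_ns=%.12g",
            i, cv$wavelength_em, cv$wavelength_exc, cv$temperature,
            cv$integration_time, diff(cv$bin_edges)[1])
  }, character(1))
  rows <- unlist(lapply(seq_along(curves), function(i) {
    cv <- curves[[i]]
    sprintf("%d\t%.12g\t%.12g", i, bin_midpoints(cv), cv$counts)
  }))
  writeLines(c(hdr, "curve\ttime_ns\tcounts", rows), path)
  invisible(path)
}

#' @rdname write_decay_series
#' @export
read_decay_series <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# curve ", lines, value = TRUE)
  tab <- utils::read.delim(text = lines[!grepl("^#", lines)])
  meta_val <- function(line, key) {
    as.numeric(sub(paste0(".*", key, "="), "",
                   regmatches(line, regexpr(paste0(key, "=[^ ]+"), line))))
  }
  lapply(seq_along(hdr), function(i) {
    sub_tab <- tab[tab$curve == i, ]
    w <- meta_val(hdr[i], "bin_width_ns")
    edges <- c(sub_tab$time_ns - w / 2,
               sub_tab$time_ns[nrow(sub_tab)] + w / 2)
    decay_curve(edges, sub_tab$counts,
                wavelength_em = meta_val(hdr[i], "em_nm"),
                wavelength_exc = meta_val(hdr[i], "exc_nm"),
                temperature = meta_val(hdr[i], "temperature_C"),
                integration_time = meta_val(hdr[i], "dt_s"))
  })
}

#' Write / read a calibration table as delimited text
#'
#' Tab-separated columns `temperature_C` and `tau_ns`.
#'
#' @param table Data frame with columns `temperature_C`, `tau_ns`.
#' @param path File path.
#' @return `write_calibration_table` returns `path` invisibly;
#'   `read_calibration_table` returns the data frame.
#' @export
write_calibration_table <- function(table, path) {
  stopifnot(all(c("temperature_C", "tau_ns") %in% names(table)))
  utils::write.table(table[, c("temperature_C", "tau_ns")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_calibration_table
#' @export
read_calibration_table <- function(path) {
  utils::read.delim(path)
}
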