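# End-to-end orchestration: experiment configs, run manifests, and the
# two composite commands (synthetic dataset generation and the
# photothermal proof-of-concept).

md5_of <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Write a run manifest
#'
#' Records what a pipeline command did: the command name, a hash of its
#' configuration, the seeds used, input/output paths, a timestamp and the
#' package version. Reruns with an identical manifest configuration and
#' seed reproduce the outputs bit-for-bit.
#'
#' @param path JSON file path.
#' @param command Command name.
#' @param config Configuration list (hashed into the manifest).
#' @param seed Integer seed(s) used.
#' @param inputs,outputs Character vectors of file paths.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed,
                           inputs = character(0), outputs = character(0)) {
  manifest <- list(
    command = command,
    config_hash = md5_of(config),
    config = config,
    seed = seed,
    inputs = inputs,
    outputs = outputs,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "cnstherm",
    version = as.character(utils::packageVersion("cnstherm")))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Generate the synthetic calibration dataset and decay curves
#'
#' Composite command: builds the requested fixture, writes a noisy
#' calibration table, a small set of representative decay curves, and a
#' run manifest into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param fixture Fixture name (default `"CAL-1"`).
#' @param seed Integer seed.
#' @param noise_sd Calibration noise in ns (default the fixture's value).
#' @return Invisibly, a list with the written paths.
#' @export
run_simulation <- function(out_dir, fixture = "CAL-1", seed = 1,
                           noise_sd = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- cns_fixture(fixture)
  if (fixture == "CAL-1") {
    gt <- fx$gt; wl <- fx$wavelength; temps <- fx$temperatures
    if (is.null(noise_sd)) noise_sd <- fx$noise_sd
  } else if (fixture == "CNS-A") {
    gt <- fx; wl <- 614; temps <- seq(25, 50, by = 0.5)
    if (is.null(noise_sd)) noise_sd <- 0.15
  } else {
    stop("`fixture` must be a ground-truth fixture (CNS-A or CAL-1)",
         call. = FALSE)
  }
  cal_path <- file.path(out_dir, "calibration.tsv")
  tab <- simulate_calibration_dataset(gt, wl, temps, noise_sd = noise_sd,
                                      seed = seed)
  write_calibration_table(tab, cal_path)
  curve_paths <- character(0)
  for (T in c(temps[1], stats::median(temps), temps[length(temps)])) {
    cv <- simulate_decay(gt, wl, T, integration_time = 1,
                         seed = seed + round(10 * T))
    p <- file.path(out_dir, sprintf("decay_%gnm_%gC.tsv", wl, T))
    write_decay_curve(cv, p)
    curve_paths <- c(curve_paths, p)
  }
  cfg <- list(fixture = fixture, wavelength = wl,
              temperatures = range(temps), noise_sd = noise_sd)
  write_manifest(file.path(out_dir, "manifest.json"), "simulate", cfg,
                 seed, outputs = c(cal_path, curve_paths))
  invisible(list(calibration = cal_path, curves = curve_paths,
                 manifest = file.path(out_dir, "manifest.json")))
}

#' Photothermal proof-of-concept experiment
#'
#' Composite command mirroring the laser-heating validation: solves the
#' heat equation for the thermostatted cuvette, samples the
#' volume-average temperature every `dt_readout` seconds (preceded by a
#' pre-heating hold at the wall temperature), simulates one low-SNR decay
#' curve per time point, reads temperatures back through the fitted
#' calibration -- raw, and optionally through the denoiser -- and fits an
#' exponential rise to the heated segment.
#'
#' @param out_dir Output directory for traces, readouts and the manifest
#'   (`NULL` to skip writing).
#' @param seed Integer seed.
#' @param cal A `cns_calibration`; by default fitted to a noisy CAL-1
#'   table generated with `seed`.
#' @param denoiser Optional trained `cns_denoiser` for the denoised
#'   readout channel.
#' @param heat_config A [heat_sim_config()] (default: the printed
#'   proof-of-concept parameters).
#' @param t_pre Pre-heating hold in s (default 10).
#' @param t_heat Heating time in s (default 100).
#' @param dt_readout Acquisition spacing / integration time in s (0.1).
#' @return Object of class `cns_poc` with the driving trace, per-channel
#'   readouts, pre-heating and plateau summaries (mean, sd), and the
#'   exponential-rise fit of each readout channel.
#' @export
run_poc <- function(out_dir = NULL, seed = 1, cal = NULL, denoiser = NULL,
                    heat_config = heat_sim_config(), t_pre = 10,
                    t_heat = 100, dt_readout = 0.1) {
  fx <- cns_fixture("CAL-1")
  if (is.null(cal)) {
    tab <- simulate_calibration_dataset(fx$gt, fx$wavelength,
                                        fx$temperatures,
                                        noise_sd = fx$noise_sd,
                                        seed = seed)
    cal <- fit_biphasic(tab)
  }
  sim <- solve_heat(heat_config, t_end = t_heat,
                    trace_stride = max(1L, round(dt_readout /
                                                   heat_config$dt)))
  heat_trace <- sim$trace
  pre <- data.frame(
    time_s = seq(dt_readout, t_pre, by = dt_readout),
    temperature_C = heat_config$initial_temperature)
  drive <- rbind(pre,
                 data.frame(time_s = t_pre + heat_trace$time_s,
                            temperature_C = heat_trace$temperature_C))
  curves <- simulate_photothermal_series(fx$gt, drive,
                                         wavelength = fx$wavelength,
                                         seed = seed + 1L)
  channels <- list(raw = temperature_readout(curves, cal))
  if (!is.null(denoiser)) {
    channels$denoised <- temperature_readout(curves, cal,
                                             denoiser = denoiser)
  }
  pre_idx <- seq_len(nrow(pre))
  plateau_idx <- which(drive$time_s > t_pre + 0.7 * t_heat)
  summarize <- function(ro) {
    data.frame(
      segment = c("pre_heating", "plateau"),
      mean_C = c(mean(ro$temperature_C[pre_idx]),
                 mean(ro$temperature_C[plateau_idx])),
      sd_C = c(stats::sd(ro$temperature_C[pre_idx]),
               stats::sd(ro$temperature_C[plateau_idx])))
  }
  summaries <- lapply(channels, summarize)
  fits <- lapply(channels, function(ro) {
    seg <- ro[ro$time_s > t_pre, ]
    try(fit_exponential_rise(data.frame(time_s = seg$time_s - t_pre,
                                        temperature_C = seg$temperature_C)),
        silent = TRUE)
  })
  out <- structure(list(drive = drive, heat_sim = sim, cal = cal,
                        readouts = channels, summaries = summaries,
                        rise_fits = fits, dt_readout = dt_readout,
                        t_pre = t_pre),
                   class = "cns_poc")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(drive = file.path(out_dir, "drive_trace.tsv"))
    write_trace(drive, paths[["drive"]])
    for (nm in names(channels)) {
      p <- file.path(out_dir, sprintf("readout_%s.tsv", nm))
      utils::write.table(channels[[nm]], p, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      paths[[nm]] <- p
    }
    cfg <- list(heat = unclass(heat_config), t_pre = t_pre,
                t_heat = t_heat, dt_readout = dt_readout,
                denoised = !is.null(denoiser))
    write_manifest(file.path(out_dir, "manifest.json"), "poc", cfg, seed,
                   outputs = unname(unlist(paths)))
  }
  out
}

#' @export
print.cns_poc <- function(x, ...) {
  cat("Photothermal proof-of-concept readout\n")
  for (nm in names(x$summaries)) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %s: pre-heating %.2f +/- %.2f C; plateau %.2f +/- %.2f C\n",
                nm, s$mean_C[1], s$sd_C[1], s$mean_C[2], s$sd_C[2]))
    f <- x$rise_fits[[nm]]
    if (inherits(f, "exp_rise_fit")) {
      co <- f$coefficients
      cat(sprintf("     rise fit: dT_inf %.2f C, tau %.1f s\n",
                  co["dT_inf"], co["tau_heat"]))
    }
  }
  invisible(x)
}
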