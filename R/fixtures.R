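#' Canonical fixtures of the synthetic-data generator
#'
#' Returns the versioned fixture objects used throughout the package's
#' examples and tests. Available names:
#' \describe{
#'   \item{`CNS-SHAPES`}{Monomer/aggregate emission line shapes (two
#'     vibronic Gaussians near 520/562 nm vs one broad Gaussian near
#'     655 nm) whose densities cross at 614 nm.}
#'   \item{`CNS-POP`}{Logistic aggregate-population model with plateaus
#'     0.97/0.03, midpoint 36.8 C, width 0.9 C.}
#'   \item{`CNS-A`}{Full ground-truth configuration: tau_A = 25 ns,
#'     tau_M = 3 ns, the canonical shapes and population, 5e5 counts/s
#'     over 1024 bins spanning 0-200 ns.}
#'   \item{`CAL-1`}{Calibration scenario at 614 nm, 25-50 C every 0.5 C
#'     with 0.15 ns lifetime noise; its effective population plateaus
#'     (15/22, 7/22, width 0.768 C) put the model lifetime at 18 -> 10 ns
#'     across the transition with max S_r = 19 %/C at 37 C. Returned as a
#'     list with elements `gt`, `wavelength`, `temperatures`, `noise_sd`.}
#'   \item{`TRAIN-1`}{Denoiser training specification (see
#'     [denoiser_spec()]).}
#' }
#'
#' @param name Fixture name.
#' @return The fixture object (type depends on `name`).
#' @export
cns_fixture <- function(name = c("CNS-A", "CNS-SHAPES", "CNS-POP", "CAL-1",
                                 "TRAIN-1")) {
  name <- match.arg(name)
  y <- yaml::read_yaml(system.file("extdata", "fixtures.yaml",
                                   package = "cnstherm", mustWork = TRUE))
  grid <- seq(y$wavelength_grid$from, y$wavelength_grid$to,
              by = y$wavelength_grid$by)
  shapes <- make_line_shapes(
    monomer_peaks = do.call(rbind, lapply(y$`CNS-SHAPES`$monomer,
                                          as.data.frame)),
    aggregate_peaks = do.call(rbind, lapply(y$`CNS-SHAPES`$aggregate,
                                            as.data.frame)),
    wavelength_grid = grid)
  pop <- function(p) population_model(p$n_solid, p$n_liquid, p$t_mid,
                                      p$width)
  budget <- photon_budget(y$photon_budget$counts_per_second,
                          y$photon_budget$bin_count,
                          y$photon_budget$window)
  switch(name,
    "CNS-SHAPES" = shapes,
    "CNS-POP" = pop(y$`CNS-POP`),
    "CNS-A" = ground_truth_config(
      two_state_model(y$`CNS-A`$tau_A, y$`CNS-A`$tau_M, shapes,
                      pop(y$`CNS-POP`), y$`CNS-A`$alpha),
      budget),
    "CAL-1" = {
      cal <- y$`CAL-1`
      list(gt = ground_truth_config(
             two_state_model(cal$tau_A, cal$tau_M, shapes,
                             pop(cal$population), cal$alpha),
             budget),
           wavelength = cal$wavelength,
           temperatures = seq(cal$temperatures$from, cal$temperatures$to,
                              by = cal$temperatures$by),
           noise_sd = cal$noise_sd)
    },
    "TRAIN-1" = {
      tr <- y$`TRAIN-1`
      denoiser_spec(
        side = tr$side, depth = tr$depth,
        base_channels = tr$base_channels,
        temperatures = seq(tr$temperatures$from, tr$temperatures$to,
                           by = tr$temperatures$by),
        integration_times = tr$integration_times,
        wavelength = tr$wavelength,
        ground_truth_integration = tr$ground_truth_integration,
        n_pairs = tr$n_pairs, epochs = tr$epochs,
        batch_size = tr$batch_size, learning_rate = tr$learning_rate,
        val_fraction = tr$val_fraction, seed = tr$seed)
    })
}
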