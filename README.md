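# cnstherm

Simulation and analysis toolkit for **fluorescence-lifetime
nanothermometry** with phase-change nanocapsules ("chromatic
nanoswitchers"): silica shells filled with a paraffin mixture that melts
near 37 °C and a perylenediimide dye whose emission switches between an
aggregated excimer state (red, long lifetime) and a monomeric state
(green, short lifetime) as the paraffin changes phase. The package is
aimed at people developing luminescent thermometers or lifetime-based
readout pipelines who want a fully synthetic, end-to-end testbed: every
stage — photon counting, spectral overlap, calibration, denoising,
photothermal heating — is generated and analysed in code.

## What it computes

**Average lifetime (estimator).** From a TCSPC histogram with counts
c_k in bins centred at t_k,

    tau_av = sum(c_k t_k) / sum(c_k),

the intensity-weighted first moment of the decay.

**Two-population forward model.** With an aggregate fraction N_A(T)
(logistic melting curve) and normalized emission line shapes g_A, g_M,
the emitted intensities are I_A = alpha N_A g_A(lambda) and
I_M = alpha (1 - N_A) g_M(lambda), and

    tau(lambda, T) = (I_A tau_A + I_M tau_M) / (I_A + I_M).

Its analytic temperature derivative d tau/dT identifies the optimal
readout wavelength: the contrast is maximal where |g_A - g_M| = 0 (the
line-shape crossing, engineered at 614 nm in the canonical fixture).

**Calibration.** tau_av(T) tables are fitted with a biphasic
dose–response (double-logistic) curve; the relative sensitivity
S_r = 100 |d tau/dT| / tau and the thermal resolution
delta_T = delta_tau / |d tau/dT| follow from the fit. Temperature is
read back by monotone inversion of the fitted curve.

**Spiral-image denoising.** Low photon-count decay curves are mapped
onto square grayscale images along an inward clockwise spiral and
denoised with a U-shaped convolutional network (implemented natively on
BLAS matrix operations: 3x3 convolutions, max pooling, skip
connections, Adam, RMSE loss) trained against long-integration
noiseless references. This cuts the lifetime spread delta_tau at 0.1 s
integration by more than 4x.

**Heat transfer.** A Douglas alternating-direction-implicit solver for
the 3D heat equation with a Beer–Lambert volumetric source models the
photothermal proof of concept: a 1450 nm, 15 mW laser heating 100 µL of
water in a thermostatted 3 × 3 mm cuvette.

## Worked example

```r
library(cnstherm)

# canonical fixtures: line shapes crossing at 614 nm, melting near 36.8 C
shapes <- cns_fixture("CNS-SHAPES")
line_shape_crossing(shapes)
#> [1] 613.9962

# where is the readout optimal?
gt <- cns_fixture("CNS-A")
scan <- wavelength_scan(gt$model, t_low = 25, t_high = 50)
attr(scan, "argmax_delta_tau")
#> [1] 614

# simulate a noisy calibration sweep and fit it
cal_fx <- cns_fixture("CAL-1")
tab <- simulate_calibration_dataset(cal_fx$gt, 614, cal_fx$temperatures,
                                    noise_sd = 0.15, seed = 7)
cal <- fit_biphasic(tab)
summary(cal)
#> Biphasic lifetime-temperature calibration
#>   plateaus: 18.07 -> 10.00 ns; valid 25-50 C
#>   midpoints 36.81 / 36.81 C (fraction 1.00), decade slopes 0.57 / 0.57 per C
#>   residual sd 0.144 ns on 51 points
#>   max relative sensitivity 19.1 %/C at 37.04 C

# read an unknown curve back to temperature (30 s acquisition,
# ~24 000 photons)
cv <- simulate_decay(cal_fx$gt, 614, temperature = 38,
                     integration_time = 30, seed = 42)
temperature_readout(cv, cal)
#>   time_s   tau_ns temperature_C clipped
#> 1     30 11.17092       38.1738   FALSE

# photothermal proof of concept: laser-heated cuvette
sim <- solve_heat(heat_sim_config(), t_end = 100)
mean(sim$field) - 36.5       # steady-state volume-average rise, deg C
#> [1] 1.346777
```

The calibration drops from ~18 ns below the melting transition to
~10 ns above it; the maximum relative sensitivity (~19 %/°C near 37 °C)
is where a lifetime-based readout resolves temperature best. The
simulated cuvette settles ~1.3–1.7 °C above the thermostat set point,
the heating being strongest in the first millimetre of the beam path
where the 1450 nm light is absorbed.

Training the spiral-image denoiser (several minutes on one CPU at the
canonical fixture scale) and the full proof-of-concept readout are shown
in the methods vignette (`vignettes/cnstherm-methods.Rmd`).

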