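---
title: "Models and methods behind cnstherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cnstherm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cnstherm)
```

This vignette explains the science and the design decisions inside
`cnstherm`: the two-population lifetime model, the synthetic TCSPC
generator and what it does (and does not) emulate, the calibration and
precision machinery, the spiral-image denoiser, and the heat-transfer
solver. Code chunks are illustrative; the test suite and
`scripts/acceptance.R` are the executable record of every number quoted
here.

## The two-population lifetime model

A chromatic nanoswitcher holds a perylenediimide dye inside a paraffin
mixture that melts near 37 °C. In the solid paraffin the dye is
aggregated and emits red with a long excimer lifetime
(`tau_A` = 25 ns); in the liquid it is monomeric and emits green with a
short lifetime (`tau_M` = 3 ns). With an aggregate population fraction
$N_A(T)$ and unit-area emission line shapes $g_A, g_M$, the emitted
intensities at wavelength $\lambda$ are

$$I_A = \alpha\,N_A(T)\,g_A(\lambda),\qquad
  I_M = \alpha\,(1-N_A(T))\,g_M(\lambda),$$

and the intensity-weighted average lifetime is

$$\tau(\lambda,T)=\frac{I_A\tau_A+I_M\tau_M}{I_A+I_M}.$$

The coupling $\alpha$ (quantum yield × detection efficiency) is assumed
equal for the two states and cancels. `model_lifetime()` evaluates this
forward model; `lifetime_temperature_derivative()` is its closed-form
quotient-rule derivative in terms of $dN_A/dT$, verified in the tests
against a central finite difference (step $10^{-4}$ °C, relative
tolerance $10^{-6}$, on a 20 × 20 wavelength–temperature grid). At a
wavelength where $g_A=g_M$ the derivative collapses to
$N_A'(T)(\tau_A-\tau_M)$ — which is why the readout is most sensitive
at the line-shape crossing, and why `wavelength_scan()` reports both the
contrast maximum and the $|g_A-g_M|$ minimum.

**Population model.** $N_A(T)$ is a logistic melting curve with
plateaus `n_solid`/`n_liquid`, midpoint `t_mid` (°C) and steepness
`width` (°C). The canonical plateaus are 0.97/0.03 rather than 1/0
because aggregate-dominated red emission survives well above the
transition and monomer emission is visible well below it; the
monomer fraction is always $1-N_A$.

**Line shapes.** Gaussian mixtures on a 480–750 nm grid (0.5 nm steps):
two vibronic monomer peaks at 520 nm (sd 14 nm) and 562 nm (sd 34 nm),
one broad aggregate peak at 655 nm (sd 20 nm). The widths were frozen by
a brute-force crossing search so the two normalized densities intersect
at 614.0 nm, the engineered optimum of the canonical system.

## The synthetic TCSPC generator

`simulate_decay()` draws independent Poisson counts around the expected
decay. Each state contributes a bin-normalized exponential profile
weighted by its intensity fraction, so the discrete first moment of the
expectation reproduces the forward-model lifetime up to finite-window
truncation (for a 200 ns window the bias on a 25 ns decay is about
0.3 %; the tests carry the closed-form bound). Defaults: 1024 bins over
0–200 ns (≈ 0.195 ns bins), no instrument response function (ns-scale
lifetimes, pulsed diode excitation), no background by default with an
optional constant dark rate.

**Photon budget.** The canonical brightness is **800 detected photons
per second**. It is derived from the printed precision of the raw
readout: the standard deviation of the first-moment estimator is
$\delta\tau \approx \sqrt{\mathrm{Var}(t)/N}$, and at 36.5 °C, 614 nm
the mixture has $\mathrm{Var}(t) \approx 460\ \mathrm{ns}^2$, so a raw
$\delta\tau$ of 2.4 ns at 0.1 s integration implies $N \approx 80$
photons per acquisition. This brightness puts the 0.1 s acquisitions in
the genuinely photon-starved regime the denoiser is meant for, while a
300 s reference acquisition (240 000 photons) is effectively noiseless.
A much brighter budget would make the raw readout nearly exact and
leave a denoiser nothing to do.

What the generator deliberately does *not* emulate: photobleaching,
FRET, solvent effects, capsule-to-capsule heterogeneity, detector
after-pulsing, and any cross-sensitivity to pH, viscosity or ionic
strength (the calibration is treated as environment-independent).
Passing tests therefore demonstrate the correctness of the analysis
pipeline under ideal two-state Poisson statistics, not robustness to
instrument artefacts in real data.

## Calibration, sensitivity, precision

`fit_biphasic()` fits the biphasic dose–response

$$\tau(T)=low+(high-low)\left[\frac{f}{1+10^{s_1(T-m_1)}}
  +\frac{1-f}{1+10^{s_2(T-m_2)}}\right]$$

with bounded Levenberg–Marquardt, plateaus initialized at the 10th/90th
lifetime percentiles and midpoints at the steepest-gradient temperature.
Because the full seven-parameter form is over-parameterized on
single-step data (the spurious second component converges to a
razor-sharp step that inflates the sensitivity maximum), the fitter
also fits the single-logistic special case ($f=1$) and keeps the second
component only when AIC supports it by more than 2. Decade slopes are
capped at 5 per °C — steps sharper than the 0.5 °C sampling cannot be
resolved anyway.

The **CAL-1 fixture** represents the calibration experiment at 614 nm.
Its effective population plateaus are 15/22 and 7/22 so that the model
lifetime at the crossing runs from exactly 18 ns to 10 ns across the
transition, and its transition width (0.768 °C) was chosen so that the
maximum relative sensitivity $S_r = 100\,|d\tau/dT|/\tau$ of the model
curve is 19 %/°C at 37.0 °C. These are deliberately *effective*
ensemble parameters: with the canonical 0.97/0.03 plateaus the lifetime
at the crossing would span 24.3 → 3.7 ns, which does not describe the
calibration experiment being emulated — ensemble averaging over capsule
melting ranges compresses the observable plateau span at a fixed
wavelength.

**Thermal resolution.** `precision_vs_integration()` defines
$\delta\tau$ as the sample standard deviation of repeated average
lifetime estimates and converts it with the calibration slope,
$\delta T = \delta\tau/|d\tau/dT|$. This is algebraically identical to
$S_r^{-1}\,\delta\tau/\tau$, so only one conversion exists. Note that a
$\delta\tau$/$\delta T$ pair quoted at 36.5 °C uses the *local* slope,
which is well below the slope at the 37 °C sensitivity peak; comparing
pairs quoted at different temperatures can therefore look inconsistent
by a factor of ~2–3 without being so.

Inversion (`invert_calibration()`) samples the fitted curve at 1000
points, checks monotonicity, interpolates, resolves flat ties to the
lower temperature, and clips + flags lifetimes outside the calibrated
range.

## Spiral images and the denoiser

`spiral_encode()` maps histogram bin $k$ to the $k$-th pixel of an
inward, clockwise square spiral starting at the top-left corner; a
1024-bin curve exactly fills a 32 × 32 image. The orientation is an
arbitrary fixed convention — any fixed spiral works as long as training
and inference share it — and the mapping is lossless (an exact
permutation; at most 1 LSB error after 16-bit TIFF quantization).
`lifetime_from_image()` walks the spiral back and applies the
first-moment estimator, so on raw images it equals `average_lifetime()`
of the source curve.

The denoiser is a standard U-shaped convolutional network implemented
natively in R on BLAS matrix operations (im2col gathers + one matrix
multiplication per 3 × 3 convolution, analytic backpropagation checked
against finite differences in the tests). Default architecture: 3
levels, 16 base channels doubling per level, 2 × 2 max pooling,
nearest-neighbour upsampling, skip connections by channel
concatenation, a linear 1 × 1 output head, He initialization, Adam
(lr $10^{-3}$). The minimized criterion is the mean squared error;
the recorded loss curves report its square root (RMSE), which has the
same minimizer. Training pairs are (Poisson acquisition at
$\delta t \in \{0.1, 0.3, 1.1\}$ s, noiseless expectation standing in
for the 300 s reference), at temperatures 36–39 °C in 0.5 °C steps,
both normalized to unit maximum per image — the first-moment estimator
is scale-invariant, so shape is all that matters. A 15 % validation
split is held out; training is seeded end to end.

At the canonical fixture scale (2000 pairs, 12 epochs) training takes
tens of minutes on one CPU. The acceptance test uses a reduced run
(800 pairs, 6 epochs) that the test suite can afford; the
lifetime-spread improvement it demonstrates at 0.1 s integration —
better than 4× with |bias| ≤ 0.3 ns at 36.5 °C — is the package's
scaled-down reproduction of the headline denoising result, not a claim
about any particular instrument. Statistically, the network approximates
the posterior-mean reconstruction under the training prior: with ~80
photons per curve the likelihood is weak and the learned prior over the
training temperature range supplies most of the precision gain. That is
exactly why the gain shrinks as integration time grows (more photons,
stronger likelihood) and why a denoiser trained on one temperature range
should not be trusted outside it.

## Heat transfer in the thermostatted cuvette

`solve_heat()` advances $\rho c\,\partial T/\partial t = k\nabla^2 T +
Q$ with the Douglas ADI scheme (three tridiagonal sweeps per step,
unconditionally stable, second order in space and time; the test suite
measures a spatial convergence order above 1.9 on a three-grid study
with a smooth, well-resolved source). The source is Beer–Lambert
deposition $Q = \mu_a I_0 e^{-\mu_a x}$ inside the beam footprint: a
collimated 1 mm top-hat beam (Gaussian available) entering one side
wall at mid-height, $\mu_a = 3000\ \mathrm{m}^{-1}$, P = 15 mW.
Geometry: 3 × 3 mm inner cross-section, 100 µL → 11.1 mm liquid
column; water properties k = 0.6 W m⁻¹K⁻¹, ρ = 998 kg m⁻³,
c = 4182 J kg⁻¹K⁻¹. Default grid 30 × 30 × 56, Δt = 0.05 s.
Convection is neglected (conduction only), as are radiative losses and
temperature-dependent properties.

**Boundary conditions.** Clamping all walls to the thermostat
(Dirichlet) short-circuits the source: with the beam depositing its
15 mW within ~0.3 mm of a clamped wall, the steady volume-average rise
is only ~0.06 °C — an order of magnitude below the ~1.7 °C the
experiment calls for. The default is therefore a Robin (film)
condition with an effective wall conductance of
h = 80 W m⁻²K⁻¹, the series estimate for a ~1 mm glass wall
($t/k \approx 9\times10^{-4}$ m²K/W) plus a ~0.3 mm contact air film
($\approx 1.2\times10^{-2}$ m²K/W); the free top surface is adiabatic.
With this default the paper-scale run settles ~1.3 °C above the set
point at 100 s.

**An energy-conservation limit on the rise time.** With the full beam
power absorbed in V = 100 µL of water, the average temperature cannot
rise faster than $P/(\rho c V) \approx 0.036$ K/s. Reaching 63 % of a
1.7 °C steady rise therefore takes at least ~30 s, and any conduction
model that reproduces a ~1.3–1.7 °C steady state necessarily has an
exponential-rise time constant of ~40 s or more — the package's
simulated transient fits to ≈ 40 s. A ~20 s time constant is only
compatible with a steady rise of ≲ 0.7 °C; quoted (rise, time-constant)
pairs that violate this bound cannot be reproduced by any
energy-conserving conduction model, whatever the boundary conditions.

The energy balance of the discrete solution (absorbed power vs
conductive wall outflow, computed with stencil-consistent fluxes)
closes to better than 1 % at steady state; zero laser power leaves the
field exactly at the wall temperature, and the rise is linear in laser
power to machine precision — all enforced by the tests.

## Problem sizes used by the tests

The suite chooses sizes that keep each property measurable in seconds:
1200 replicates for the Poisson mean–variance check on a 32-bin
histogram; 200 curves per channel for estimator recovery; 25 noisy
replicates for calibration-parameter stability; 12³/24³/48³ grids for
the convergence study; 800 pairs / 6 epochs for the denoiser
benchmark and 16 × 16 two-level networks for the unit tests. These are
the package's own fixture scales; the underlying generators accept
arbitrary sizes.

## Known limitations

* The two-state model has no intermediate aggregation states and a
  single, global coupling $\alpha$; real capsules show heterogeneity
  that broadens the calibration.
* The denoiser inherits the training prior: it is only valid inside
  the trained temperature range and photon-budget regime, and its
  output is biased toward the prior wherever the data are weak.
* The heat model is conduction-only; at ~1–2 °C excess over ambient in
  a 3 mm cuvette, convective mixing is plausibly non-negligible and
  would shorten the apparent rise time.
* No instrument response function: lifetimes below ~1 ns would need
  IRF deconvolution, which is out of scope.
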