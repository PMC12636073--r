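# Canonical fixture parameters for the cnstherm synthetic-data generator.
# The line-shape widths were frozen by a brute-force crossing search so the
# monomer/aggregate densities cross at 614.0 nm; the CAL-1 population was
# chosen so the model lifetime at the crossing runs from 18 to 10 ns with a
# maximum relative sensitivity of 19 %/C at 37.0 C.
wavelength_grid:
  from: 480.0
  to: 750.0
  by: 0.5
CNS-SHAPES:
  monomer:
    - {center: 520.0, width: 14.0, weight: 0.55}
    - {center: 562.0, width: 34.0, weight: 0.45}
  aggregate:
    - {center: 655.0, width: 20.0, weight: 1.0}
CNS-POP:
  n_solid: 0.97
  n_liquid: 0.03
  t_mid: 36.8
  width: 0.9
# Brightness derived from the printed raw lifetime spread at 0.1 s
# integration (delta_tau ~ sqrt(Var(t)/N) => N ~ 80 photons per 0.1 s).
photon_budget:
  counts_per_second: 800.0
  bin_count: 1024
  window: 200.0
CNS-A:
  tau_A: 25.0
  tau_M: 3.0
  alpha: 1.0
  population: CNS-POP
CAL-1:
  tau_A: 25.0
  tau_M: 3.0
  alpha: 1.0
  population:
    n_solid: 0.6818182   # 15/22: tau(614 nm) = 18 ns at the cold plateau
    n_liquid: 0.3181818  # 7/22: tau(614 nm) = 10 ns at the hot plateau
    t_mid: 36.8
    width: 0.768         # max S_r = 19 %/C at 37.0 C
  wavelength: 614.0
  temperatures: {from: 25.0, to: 50.0, by: 0.5}
  noise_sd: 0.15
TRAIN-1:
  temperatures: {from: 36.0, to: 39.0, by: 0.5}
  integration_times: [0.1, 0.3, 1.1]
  wavelength: 614.0
  ground_truth_integration: 300.0
  n_pairs: 2000
  side: 32
  depth: 3
  base_channels: 16
  epochs: 12
  batch_size: 16
  learning_rate: 0.001
  val_fraction: 0.15
  seed: 421
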