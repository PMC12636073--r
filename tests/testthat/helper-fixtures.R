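# Shared fixture objects, built once per test run.
fx_shapes <- cns_fixture("CNS-SHAPES")
fx_pop <- cns_fixture("CNS-POP")
fx_gt <- cns_fixture("CNS-A")
fx_cal <- cns_fixture("CAL-1")

# A small ground-truth config with a fast-to-simulate histogram, for
# property tests that need many replicates.
small_gt <- function(bins = 128, cps = 2000) {
  ground_truth_config(fx_gt$model,
                      photon_budget(counts_per_second = cps,
                                    bin_count = bins, window = 200))
}

# Noiseless single-exponential decay curve with given lifetime.
single_exp_curve <- function(tau, bins = 1024, window = 200, total = 1e6) {
  edges <- seq(0, window, length.out = bins + 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  p <- exp(-mid / tau)
  decay_curve(edges, total * p / sum(p), wavelength_em = 614,
              temperature = NA, integration_time = 1)
}
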