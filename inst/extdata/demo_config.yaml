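# Demonstration run: generate a small bulk titration and a synthetic-cell
# population, fit the full model variant, profile two parameters, and
# write Table-style parameter and population reports.
seed: 42
stages: [generate, fit, profile, summarize]
generate:
  bulk:
    dna_levels: [0.94, 3.75, 7.5]
    replicates: 3
    noise_cv: 0.02
    times: {from: 0, to: 8, by: 0.5}
  population:
    n_cells: 40
    radius_mean_um: 30.4
    radius_cv: 0.064
    expression_cv: 0.022
    dna_nM: 3.5
    times: {from: 0, to: 12, by: 0.5}
fit:
  free: [k_r, K_r, delta_r, k_p, K_p]
  fixed:
    k_mat: 2.15
    tau_l: 0
    delta_TsR: 0.231
    delta_TlR: 0.0884
    K_l: 1.21e-6
    a: 4.45e-4
    b: 1.78e-4
    tau_d: 0.433
  n_starts: 3
profile:
  parameters: [k_r, delta_r]
  n_grid: 7
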