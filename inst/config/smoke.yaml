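# Minutes-scale smoke grid for continuous checks.
maf: [0.25]
irr_disease: [1.0, 1.5]
irr_death: [0.5, 3.0]
disease_baselines:
  - {mode: 50, shape: 0.1}
death_baseline: {mode: 85, shape: 0.0004}
rarity_targets: [0.22]
n_individuals: 2000
n_replicates: 10
base_seed: 1
designs: [classical, incidence_density]
censor_age: 90
controls_per_case: 5
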