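# Full study grid: 3 MAF x 8 disease IRR x 10 death IRR x 2 disease
# baselines x 2 rarity targets = 960 scenarios, 1000 replicates each.
maf: [0.1, 0.25, 0.5]
irr_disease: [0.5, 1.0, 1.1, 1.2, 1.5, 1.7, 2.0, 3.0]
irr_death: [0.5, 0.75, 0.9, 1.0, 1.1, 1.2, 1.5, 1.7, 2.0, 3.0]
disease_baselines:
  - {mode: 25, shape: 0.95}
  - {mode: 50, shape: 0.1}
death_baseline: {mode: 85, shape: 0.0004}
rarity_targets: [0.22, 0.025]
n_individuals: 10000
n_replicates: 1000
base_seed: 1
designs: [classical, classical_age_adjusted, incidence_density]
censor_age: 90
controls_per_case: 5
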