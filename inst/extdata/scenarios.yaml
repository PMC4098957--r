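# Study scenario grid: the IGE magnitude is the contribution of indirect
# effects to phenotypic variance among unrelated group mates, (n-1)*sPS2.
# Knobs not listed fall back to the defaults block / scenario_config().
defaults:
  sigma_PD2: 1
  n_group: 8
  n_sires: 25
  n_dams: 50
  progeny_per_dam: 8
  generations: 20
  burn_in_generation: 10
  replicates: 100

base_h2_0.1: {ige_magnitude: 0, h2_direct: 0.1}
base_h2_0.3: {ige_magnitude: 0, h2_direct: 0.3}
base_h2_0.5: {ige_magnitude: 0, h2_direct: 0.5}

scenario1_neutral_h2_0.1: {ige_magnitude: 0.25, h2_direct: 0.1}
scenario1_neutral_h2_0.3: {ige_magnitude: 0.25, h2_direct: 0.3}
scenario1_neutral_h2_0.5: {ige_magnitude: 0.25, h2_direct: 0.5}
scenario2_neutral_h2_0.1: {ige_magnitude: 1.0, h2_direct: 0.1}
scenario2_neutral_h2_0.3: {ige_magnitude: 1.0, h2_direct: 0.3}
scenario2_neutral_h2_0.5: {ige_magnitude: 1.0, h2_direct: 0.5}
scenario3_neutral_h2_0.1: {ige_magnitude: 4.0, h2_direct: 0.1}
scenario3_neutral_h2_0.3: {ige_magnitude: 4.0, h2_direct: 0.3}
scenario3_neutral_h2_0.5: {ige_magnitude: 4.0, h2_direct: 0.5}

scenario1_competitive_h2_0.1: {ige_magnitude: 0.25, h2_direct: 0.1, r_ADS: -0.8, r_EDS: -0.8}
scenario3_competitive_h2_0.1: {ige_magnitude: 4.0, h2_direct: 0.1, r_ADS: -0.8, r_EDS: -0.8}
scenario1_cooperative_h2_0.1: {ige_magnitude: 0.25, h2_direct: 0.1, r_ADS: 0.8, r_EDS: 0.8}
scenario3_cooperative_h2_0.1: {ige_magnitude: 4.0, h2_direct: 0.1, r_ADS: 0.8, r_EDS: 0.8}
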