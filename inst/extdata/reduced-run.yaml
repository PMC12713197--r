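# Example run configuration: the full published grid at reduced replicates.
profile: reduced
truth_fraction: 0.1
q_threshold: 0.05
alpha_posthoc: 0.05
posthoc_scope: true_significant
power_targets: [0.05, 0.2, 0.8]
power_window: 0.025
min_sensitivity: 0.333333
base_seed: 1
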