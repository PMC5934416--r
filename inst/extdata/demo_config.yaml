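# Demo run configuration for run_pipeline(): a 12-target dual screen with
# one implanted coactivator and one corepressor effect (ct shifts in cycles).
seed: 1
n_targets: 12
shrnas_per_target: 5
z_threshold: 1.0
fold_threshold: 1.5
hk_shift_threshold: 0.5
network_min_score: 0.4
require_concordance: yes
knockdown_effects:
  - target: TGT01
    basal_shift: 2.0
    stim_shift: 2.0
  - target: TGT02
    basal_shift: -2.0
    stim_shift: -2.0
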