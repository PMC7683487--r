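design:
  conditions:
  - arabic
  - mandarin
  blocks_per_condition: 4
  trials_per_block: 120
  digits:
  - 1
  - 2
  - 3
  - 4
  - 6
  - 7
  - 8
  - 9
  deadline_ms: 1500.0
  n_groups: 4
  standard: 5
params:
  conditions:
  - arabic
  - mandarin
  intercept:
    arabic: 6.16
    mandarin: 6.19
  slopes:
    arabic:
      w: 0.04
      psm: 0.01
      psa: -0.01
    mandarin:
      w: 0.05
      psm: 0.01
      psa: -0.014
  sd_intercept:
  - 0.1
  sd_slope:
  - 0.02
  sd_resid:
  - 0.15
  error_rate_mean:
    arabic: 0.036
    mandarin: 0.04
  error_rate_sd:
    arabic: 0.026
    mandarin: 0.025
  cor_within:
    arabic: -0.43
    mandarin: -0.58
  cor_cross_psm:
  - 0.42
  cor_cross_psa:
  - 0.26
clean:
  trim_fraction: 0.005
  exclusion_error_rate: 0.5
  log_transform: yes
  trim_scope: condition
arabic_variant:
  '6': with_top
  '7': with_serif
  '9': open_tail
log_base: natural
seed: 1
n_participants: 63
n_reps: 20
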