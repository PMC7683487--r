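# digitsim run configuration template
# Read with read_config(); every field below has the package default shown.
design:
  conditions: [arabic, mandarin]   # the two format conditions
  blocks_per_condition: 4          # blocks per condition
  trials_per_block: 120            # must be divisible by the number of digits
  digits: [1, 2, 3, 4, 6, 7, 8, 9] # probe digits; the standard never appears
  deadline_ms: 1500.0              # response deadline (ms); slower trials time out
  n_groups: 4                      # counterbalancing groups (equal split)
  standard: 5                      # the fixed comparison quantity
params:
  intercept:                       # grand mean log RT (log-ms) per condition
    arabic: 6.16
    mandarin: 6.19
  slopes:                          # fixed slopes, log-ms per SD of predictor
    arabic: {w: 0.04, psm: 0.01, psa: -0.01}
    mandarin: {w: 0.05, psm: 0.01, psa: -0.014}
  sd_intercept: 0.1                # between-participant SD of the intercept
  sd_slope: 0.02                   # between-participant SD of each slope
  sd_resid: 0.15                   # trial-level residual SD of log RT
  error_rate_mean: {arabic: 0.036, mandarin: 0.04}
  error_rate_sd: {arabic: 0.026, mandarin: 0.025}
  cor_within: {arabic: -0.43, mandarin: -0.58} # corr(b_psm, b_psa) within condition
  cor_cross_psm: 0.42              # corr of PSM slopes across conditions
  cor_cross_psa: 0.26              # corr of PSA slopes across conditions
clean:
  trim_fraction: 0.005             # fraction trimmed from each RT tail
  exclusion_error_rate: 0.5        # exclude participant x condition above this
  log_transform: yes
  trim_scope: condition            # or "participant"
arabic_variant:                    # seven-segment display variants for 6/7/9
  '6': with_top
  '7': with_serif
  '9': open_tail
log_base: natural                  # Welford log base ("natural" or "base10")
seed: 1
n_participants: 63
n_reps: 20                         # replicates for run_recover()
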