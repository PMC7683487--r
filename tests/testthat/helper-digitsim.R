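# Shared fixtures, all generated in code.

default_table <- build_predictor_table()

# A small but fully structured experiment: 8 participants, default design.
small_experiment <- function(n = 8, seed = 101, params = population_params(),
                             design = design_spec()) {
  profiles <- sample_participants(n, params, seed = seed, design = design)
  trials <- generate_trials(profiles, design, default_table, params,
    seed = seed + 1000
  )
  list(profiles = profiles, trials = trials, params = params, design = design)
}

# Population with no between-participant variation and (near-)zero error
# probability: trial RTs are then the linear predictor plus residual noise
# (or fully deterministic when sd_resid = 0).
degenerate_params <- function(sd_resid = 0, slopes_zero = FALSE,
                              error_rate = 1e-12) {
  sl <- if (slopes_zero) {
    list(
      arabic = c(w = 0, psm = 0, psa = 0),
      mandarin = c(w = 0, psm = 0, psa = 0)
    )
  } else {
    eval(formals(population_params)$slopes)
  }
  population_params(
    slopes = sl,
    sd_intercept = 0, sd_slope = 0, sd_resid = sd_resid,
    error_rate_mean = c(arabic = error_rate, mandarin = error_rate),
    error_rate_sd = c(arabic = 0, mandarin = 0),
    cor_within = c(arabic = 0, mandarin = 0),
    cor_cross_psm = 0, cor_cross_psa = 0
  )
}

all_glyph_pairs <- function(script) {
  pairs <- utils::combn(1:9, 2)
  lapply(seq_len(ncol(pairs)), function(j) {
    list(
      g1 = encode_glyph(pairs[1, j], script),
      g2 = encode_glyph(pairs[2, j], script)
    )
  })
}
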