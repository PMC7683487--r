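#' Parameter-recovery experiment
#'
#' Repeatedly simulates a full experiment from known generating parameters
#' and runs the analysis pipeline on each replicate, summarising how well the
#' fixed effects and the inter-participant slope correlations are recovered.
#' This is the package's acceptance surface for its stochastic components:
#' with the canonical generating values the mean recovered slopes should sit
#' within Monte-Carlo error of the inputs, and the estimated slope
#' correlations should reproduce the generating sign pattern in most
#' replicates.
#'
#' @param params Generating [population_params()].
#' @param design A [design_spec()].
#' @param n_participants Participants per replicate.
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; replicate `i` uses `seed + i - 1`.
#' @param table A [build_predictor_table()].
#' @param config A [clean_config()] for preprocessing.
#' @param ... Passed on to [fit_condition()] (e.g. `mode`, `random_effects`).
#'
#' @return An object of class `digitsim_recovery`: list with `estimates`
#'   (per replicate x condition x term), `summary` (per condition x term:
#'   generating value, mean estimate, bias, empirical SD, Monte-Carlo SE),
#'   `correlations` (per replicate x correlation), `sign_rates` (per
#'   correlation: generating value, mean estimate and the share of replicates
#'   matching the generating sign), `n_reps`, `n_participants`, `seed`.
#' @export
#' @examples
#' \donttest{
#' rec <- recovery_experiment(n_participants = 12, n_reps = 2, seed = 1)
#' rec$summary
#' }
recovery_experiment <- function(params = population_params(),
                                design = design_spec(),
                                n_participants = 63L,
                                n_reps = 20L,
                                seed = 1L,
                                table = build_predictor_table(
                                  standard = design$standard
                                ),
                                config = clean_config(),
                                ...) {
  stopifnot(n_reps >= 1L, n_participants >= 2L)
  n_reps <- as.integer(n_reps)
  n_participants <- as.integer(n_participants)
  conds <- params$conditions
  term_map <- c(w_z = "w", psm_z = "psm", psa_z = "psa")

  one_rep <- function(rep_i) {
    rep_seed <- as.integer(seed) + rep_i - 1L
    prof <- sample_participants(n_participants, params, seed = rep_seed, design = design)
    trials <- generate_trials(prof, design, table, params, seed = rep_seed + 100000L)
    clean <- preprocess(trials, config)
    fits <- lapply(conds, function(cond) {
      suppressWarnings(fit_condition(clean, table, condition = cond, ...))
    })
    names(fits) <- conds
    est <- purrr::map_dfr(conds, function(cond) {
      fits[[cond]]$fixed |>
        dplyr::filter(.data$term != "(Intercept)") |>
        dplyr::transmute(
          rep = rep_i, condition = cond,
          term = unname(term_map[.data$term]),
          estimate = .data$estimate
        ) |>
        dplyr::bind_rows(tibble::tibble(
          rep = rep_i, condition = cond, term = "intercept",
          estimate = fits[[cond]]$fixed$estimate[fits[[cond]]$fixed$term == "(Intercept)"]
        ))
    })
    cors <- correlate_slopes(fits[[1]], fits[[2]]) |>
      dplyr::mutate(rep = rep_i, .before = 1) |>
      dplyr::select("rep", "correlation", "r")
    list(est = est, cors = cors)
  }

  reps <- purrr::map(seq_len(n_reps), one_rep)
  estimates <- purrr::map_dfr(reps, "est")
  correlations <- purrr::map_dfr(reps, "cors")

  generating <- purrr::map_dfr(conds, function(cond) {
    tibble::tibble(
      condition = cond,
      term = c("intercept", "w", "psm", "psa"),
      generating = c(params$intercept[[cond]], unname(params$slopes[[cond]]))
    )
  })
  summary <- estimates |>
    dplyr::group_by(.data$condition, .data$term) |>
    dplyr::summarise(
      mean_estimate = mean(.data$estimate),
      sd_estimate = stats::sd(.data$estimate),
      .groups = "drop"
    ) |>
    dplyr::left_join(generating, by = c("condition", "term")) |>
    dplyr::mutate(
      bias = .data$mean_estimate - .data$generating,
      mc_se = .data$sd_estimate / sqrt(n_reps)
    ) |>
    dplyr::select(
      "condition", "term", "generating", "mean_estimate",
      "bias", "sd_estimate", "mc_se"
    )

  gen_cors <- tibble::tibble(
    correlation = c(
      "psm_across", "psa_across",
      paste0("psm_psa_within_", conds[1]), paste0("psm_psa_within_", conds[2])
    ),
    generating = c(
      params$cor_cross_psm, params$cor_cross_psa,
      params$cor_within[[conds[1]]], params$cor_within[[conds[2]]]
    )
  )
  sign_rates <- correlations |>
    dplyr::group_by(.data$correlation) |>
    dplyr::summarise(mean_r = mean(.data$r), .groups = "drop") |>
    dplyr::left_join(gen_cors, by = "correlation") |>
    dplyr::left_join(
      correlations |>
        dplyr::left_join(gen_cors, by = "correlation") |>
        dplyr::group_by(.data$correlation) |>
        dplyr::summarise(
          sign_match_rate = mean(sign(.data$r) == sign(.data$generating)),
          .groups = "drop"
        ),
      by = "correlation"
    ) |>
    dplyr::select("correlation", "generating", "mean_r", "sign_match_rate")

  structure(
    list(
      estimates = estimates, summary = summary,
      correlations = correlations, sign_rates = sign_rates,
      n_reps = n_reps, n_participants = n_participants, seed = as.integer(seed)
    ),
    class = "digitsim_recovery"
  )
}

#' @export
print.digitsim_recovery <- function(x, ...) {
  cat(sprintf(
    "<digitsim_recovery> %d replicates of %d participants (seed %d)\n",
    x$n_reps, x$n_participants, x$seed
  ))
  print(as.data.frame(x$summary), digits = 3, row.names = FALSE)
  cat("slope-correlation sign reproduction:\n")
  print(as.data.frame(x$sign_rates), digits = 3, row.names = FALSE)
  invisible(x)
}
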