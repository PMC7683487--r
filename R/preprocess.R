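#' Cleaning configuration
#'
#' @param trim_fraction Fraction of trials removed from each tail of the RT
#'   distribution (pooled within condition); default .005, i.e. the fastest
#'   and slowest half-percent.
#' @param exclusion_error_rate Participant-by-condition error rate above which
#'   that participant's data in that condition are discarded (default 0.5:
#'   anything worse than chance signals e.g. reversed response keys).
#' @param log_transform Apply the natural-log transform to RT (default TRUE).
#' @param trim_scope `"condition"` pools RTs across participants within each
#'   condition before trimming (default); `"participant"` trims within each
#'   participant x condition instead.
#' @return An object of class `clean_config`.
#' @export
clean_config <- function(trim_fraction = 0.005, exclusion_error_rate = 0.5,
                         log_transform = TRUE,
                         trim_scope = c("condition", "participant")) {
  trim_scope <- match.arg(trim_scope)
  stopifnot(
    trim_fraction >= 0, trim_fraction < 0.5,
    exclusion_error_rate > 0, exclusion_error_rate <= 1,
    is.logical(log_transform)
  )
  structure(
    list(
      trim_fraction = trim_fraction,
      exclusion_error_rate = exclusion_error_rate,
      log_transform = log_transform,
      trim_scope = trim_scope
    ),
    class = "clean_config"
  )
}

#' Preprocess trial-level data for RT analysis
#'
#' Applies, in order: (1) drop timeout trials (they carry no response and
#' enter neither RT nor error-rate computations); (2) compute per
#' participant-by-condition error rates and exclude any cell whose error rate
#' exceeds the threshold (catching e.g. reversed response keys); (3) keep
#' correct trials only; (4) trim the fastest and slowest `trim_fraction` of
#' the remaining RTs, pooled within condition; (5) add the natural-log RT
#' column. The step-(2) error rates are retained for the accuracy analysis in
#' [compare_conditions()].
#'
#' Preprocessing is idempotent: running it on its own output changes nothing.
#'
#' @param trials A trial table as produced by [generate_trials()] or
#'   [read_trials()].
#' @param config A [clean_config()].
#'
#' @return A tibble of cleaned trials (class `digitsim_clean`) with added
#'   `log_rt`, carrying attributes `error_rates` (per participant x condition
#'   accuracy summary), `exclusions` (excluded participant x condition cells
#'   with reasons), `counts` (trials dropped at each step) and `config`.
#' @export
#' @examples
#' pop <- population_params()
#' trials <- generate_trials(sample_participants(4, pop, seed = 1), seed = 2)
#' clean <- preprocess(trials)
#' attr(clean, "counts")
preprocess <- function(trials, config = clean_config()) {
  stopifnot(inherits(config, "clean_config"), is.data.frame(trials))
  # already-cleaned data pass through untouched (idempotence)
  if (inherits(trials, "digitsim_clean")) {
    return(trials)
  }
  if (nrow(trials) == 0L) {
    stop("`trials` is empty", call. = FALSE)
  }
  trials <- tibble::as_tibble(trials)
  n_in <- nrow(trials)

  responded <- dplyr::filter(trials, !.data$timeout)
  error_rates <- responded |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(
      n_responded = dplyr::n(),
      n_errors = sum(!.data$correct),
      error_rate = mean(!.data$correct),
      .groups = "drop"
    )
  excluded <- dplyr::filter(error_rates, .data$error_rate > config$exclusion_error_rate) |>
    dplyr::mutate(reason = sprintf(
      "error rate %.3f > %.2f (likely response-key reversal)",
      .data$error_rate, config$exclusion_error_rate
    ))
  kept_rates <- dplyr::anti_join(
    error_rates, excluded,
    by = c("participant_id", "condition")
  )
  kept <- dplyr::anti_join(
    responded, excluded,
    by = c("participant_id", "condition")
  )
  correct_trials <- dplyr::filter(kept, .data$correct)
  n_correct <- nrow(correct_trials)

  trimmed <- trim_rts(correct_trials, config)
  if (nrow(trimmed) == 0L) {
    stop(sprintf(
      "no trials survive preprocessing (input %d, after timeouts %d, after exclusions %d, correct %d)",
      n_in, nrow(responded), nrow(kept), n_correct
    ), call. = FALSE)
  }
  if (config$log_transform && !"log_rt" %in% names(trimmed)) {
    trimmed <- dplyr::mutate(trimmed, log_rt = log(.data$rt_ms))
  }
  counts <- tibble::tibble(
    step = c("input", "after_timeout_drop", "after_exclusions", "correct_only", "after_trim"),
    n = c(n_in, nrow(responded), nrow(kept), n_correct, nrow(trimmed))
  )
  structure(
    trimmed,
    error_rates = kept_rates,
    exclusions = excluded,
    counts = counts,
    config = config,
    class = c("digitsim_clean", class(trimmed))
  )
}

# Rank-based tail trimming: drop exactly floor(n * f) trials from each tail.
trim_rts <- function(x, config) {
  f <- config$trim_fraction
  if (f == 0 || nrow(x) == 0L) {
    return(x)
  }
  scope <- if (config$trim_scope == "condition") {
    "condition"
  } else {
    c("participant_id", "condition")
  }
  x |>
    dplyr::group_by(dplyr::across(dplyr::all_of(scope))) |>
    dplyr::group_modify(function(g, key) {
      k <- floor(nrow(g) * f)
      if (k == 0L) {
        return(g)
      }
      ord <- order(g$rt_ms)
      g[sort(ord[(k + 1L):(nrow(g) - k)]), , drop = FALSE]
    }) |>
    dplyr::ungroup()
}
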