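#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fixed effects of a mixed fit
#'
#' @param x A [fit_condition()] result.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect term.
#' @method tidy digitsim_fit
#' @export
tidy.digitsim_fit <- function(x, ...) {
  dplyr::mutate(x$fixed, condition = x$condition, .before = 1)
}

#' @rdname tidy.digitsim_fit
#' @method glance digitsim_fit
#' @export
glance.digitsim_fit <- function(x, ...) {
  tibble::tibble(
    condition = x$condition,
    r2 = x$r2,
    n_obs = x$n_obs,
    n_participants = x$n_participants,
    mode = x$mode,
    re_structure = x$re_structure,
    fallback = x$fallback
  )
}

#' Tidy a condition comparison
#'
#' @param x A [compare_conditions()] result.
#' @param ... Unused.
#' @return `tidy()`: the paired tests, one row per measure; `glance()`: the
#'   per-condition summary in wide form.
#' @method tidy digitsim_comparison
#' @export
tidy.digitsim_comparison <- function(x, ...) {
  x$tests
}

#' @rdname tidy.digitsim_comparison
#' @method glance digitsim_comparison
#' @export
glance.digitsim_comparison <- function(x, ...) {
  dplyr::mutate(x$by_condition, n_paired = x$n_paired)
}

#' Tidy a slope-correlation table
#'
#' @param x A [correlate_slopes()] result.
#' @param ... Unused.
#' @return A plain tibble of the four correlations.
#' @method tidy digitsim_slope_cors
#' @export
tidy.digitsim_slope_cors <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Tidy a recovery experiment
#'
#' @param x A [recovery_experiment()] result.
#' @param ... Unused.
#' @return `tidy()`: per condition x term recovery summary (generating value,
#'   mean estimate, bias, SD, Monte-Carlo SE); `glance()`: one row with the
#'   experiment's dimensions and the slope-correlation sign-match rates.
#' @method tidy digitsim_recovery
#' @export
tidy.digitsim_recovery <- function(x, ...) {
  x$summary
}

#' @rdname tidy.digitsim_recovery
#' @method glance digitsim_recovery
#' @export
glance.digitsim_recovery <- function(x, ...) {
  wide <- tidyr::pivot_wider(
    dplyr::select(x$sign_rates, "correlation", "sign_match_rate"),
    names_from = "correlation", values_from = "sign_match_rate",
    names_prefix = "sign_"
  )
  dplyr::bind_cols(
    tibble::tibble(
      n_reps = x$n_reps, n_participants = x$n_participants, seed = x$seed
    ),
    wide
  )
}
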