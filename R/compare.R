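#' Overall performance comparison between the two format conditions
#'
#' Computes participant-level mean log RT (from the cleaned, correct,
#' trimmed trials) and participant-level error rates (from all responded
#' trials, retained by [preprocess()] as an attribute), then compares the two
#' conditions with paired t-tests over the participants present in both.
#' Cohen's d for the paired contrast is `t / sqrt(n)`. Mean log RTs are also
#' back-transformed to milliseconds as `exp(mean log RT)`.
#'
#' @param cleaned Output of [preprocess()] containing both conditions.
#' @param error_rates Optional participant x condition accuracy table
#'   (columns `participant_id`, `condition`, `error_rate`); defaults to the
#'   one attached by [preprocess()].
#'
#' @return An object of class `digitsim_comparison`: a list with
#'   `by_condition` (per-condition mean log RT, back-transformed ms, SD, mean
#'   error rate, error-rate SD), `tests` (paired t, df, p, Cohen's d for
#'   `log_rt` and `error_rate`), and `n_paired`.
#' @export
compare_conditions <- function(cleaned, error_rates = attr(cleaned, "error_rates")) {
  stopifnot(is.data.frame(cleaned))
  conds <- sort(unique(cleaned$condition))
  if (length(conds) != 2L) {
    stop(
      "`cleaned` must hold exactly two conditions, found: ",
      paste(conds, collapse = ", "),
      call. = FALSE
    )
  }
  rt_wide <- cleaned |>
    dplyr::group_by(.data$participant_id, .data$condition) |>
    dplyr::summarise(mean_log_rt = mean(.data$log_rt), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "condition", values_from = "mean_log_rt") |>
    stats::na.omit()
  if (nrow(rt_wide) < 2L) {
    stop("need at least 2 participants with data in both conditions", call. = FALSE)
  }

  paired_block <- function(wide, measure) {
    n <- nrow(wide)
    diffs <- wide[[conds[1]]] - wide[[conds[2]]]
    sd_diff <- stats::sd(diffs)
    t <- if (sd_diff == 0) 0 else mean(diffs) / (sd_diff / sqrt(n))
    tibble::tibble(
      measure = measure,
      n = n, t = t, df = n - 1L,
      p = 2 * stats::pt(-abs(t), n - 1L),
      d = cohens_d_from_t(t, n)
    )
  }
  tests <- paired_block(rt_wide, "log_rt")
  by_condition <- rt_wide |>
    tidyr::pivot_longer(dplyr::all_of(conds),
      names_to = "condition", values_to = "m"
    ) |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(
      mean_log_rt = mean(.data$m), sd_log_rt = stats::sd(.data$m),
      .groups = "drop"
    ) |>
    dplyr::mutate(mean_rt_ms = exp(.data$mean_log_rt))

  if (!is.null(error_rates)) {
    er_wide <- error_rates |>
      dplyr::select("participant_id", "condition", "error_rate") |>
      dplyr::semi_join(rt_wide["participant_id"], by = "participant_id") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "error_rate") |>
      stats::na.omit()
    if (nrow(er_wide) >= 2L) {
      tests <- dplyr::bind_rows(tests, paired_block(er_wide, "error_rate"))
      er_summary <- er_wide |>
        tidyr::pivot_longer(dplyr::all_of(conds),
          names_to = "condition", values_to = "e"
        ) |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(
          mean_error_rate = mean(.data$e), sd_error_rate = stats::sd(.data$e),
          .groups = "drop"
        )
      by_condition <- dplyr::left_join(by_condition, er_summary, by = "condition")
    }
  }
  structure(
    list(by_condition = by_condition, tests = tests, n_paired = nrow(rt_wide)),
    class = "digitsim_comparison"
  )
}

#' Effect-size and test-statistic conversions
#'
#' Closed forms used throughout the reporting: for a paired t-test on `n`
#' pairs, Cohen's d is `t / sqrt(n)` (identical to `mean(diff) / sd(diff)`);
#' a Pearson correlation `r` on `df = n - 2` degrees of freedom has
#' `t = r * sqrt(df) / sqrt(1 - r^2)`; and a mean log RT back-transforms to
#' milliseconds as `exp(m)`.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return `cohens_d_from_t()`: Cohen's d; `r_to_t()`: the t statistic;
#'   `log_rt_to_ms()`: milliseconds.
#' @export
#' @examples
#' cohens_d_from_t(4.16, 63) # 0.52
#' r_to_t(0.42, df = 61) # 3.6
#' log_rt_to_ms(6.16) # 473 ms
cohens_d_from_t <- function(t, n) {
  stopifnot(n >= 1)
  t / sqrt(n)
}

#' @rdname cohens_d_from_t
#' @param r Pearson correlation, |r| < 1.
#' @param df Degrees of freedom, `n - 2`.
#' @export
r_to_t <- function(r, df) {
  stopifnot(all(abs(r) < 1), all(df >= 1))
  r * sqrt(df) / sqrt(1 - r^2)
}

#' @rdname cohens_d_from_t
#' @param m Mean natural-log RT (log-ms).
#' @export
log_rt_to_ms <- function(m) {
  exp(m)
}

#' @export
print.digitsim_comparison <- function(x, ...) {
  cat(sprintf("<digitsim_comparison> %d paired participants\n", x$n_paired))
  print(as.data.frame(x$by_condition), digits = 4, row.names = FALSE)
  print(as.data.frame(x$tests), digits = 3, row.names = FALSE)
  invisible(x)
}
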