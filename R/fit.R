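#' Mixed-effects regression of log RT on the three predictors
#'
#' Fits, for one condition, `log_rt ~ W_z + PSM_z + PSA_z` with participant as
#' a random variable: by default a random intercept and random slopes for all
#' three predictors with a freely estimated covariance (REML, via
#' \pkg{lme4}). If that fit is singular or fails to converge the model is
#' refit with uncorrelated random effects, and as a last resort with a random
#' intercept only; any fallback is flagged in the result and raised as a
#' warning.
#'
#' Each fixed slope is tested with an F statistic (the squared Wald t) on
#' `(1, n_obs - n_participants - 3)` denominator degrees of freedom, with a
#' large-sample normal p-value reported alongside; flags compare the F-based
#' p-value against a Bonferroni-corrected alpha (default .017, three slopes).
#' Model fit `r2` is the squared Pearson correlation between fitted and
#' observed log RT over the data the model was fit to. Per-participant slopes
#' are, by default, fixed effect plus the participant's predicted (BLUP)
#' deviation; `slopes = "ols"` instead fits each participant's trials by
#' ordinary least squares.
#'
#' @param cleaned Output of [preprocess()] (or a data frame with `log_rt`,
#'   `digit`, `participant_id`, `condition`).
#' @param table A [build_predictor_table()] covering the observed digits.
#' @param condition Which condition to fit; may be omitted when `cleaned`
#'   holds a single condition.
#' @param alpha Significance threshold for the slope flags (default .017, the
#'   Bonferroni-corrected level for three tests).
#' @param mode `"trials"` fits the raw trial-level data (default);
#'   `"cells"` first averages log RT within participant x digit and fits the
#'   cell means, the granularity suggested by denominator dfs of the form
#'   `7 n - 3` seen in analyses of this design.
#' @param slopes `"blup"` or `"ols"` (see above).
#' @param random_effects `"full"` (correlated), `"diagonal"`, or
#'   `"intercept"`.
#'
#' @return An object of class `digitsim_fit`: a list with elements `fixed`
#'   (tibble: term, estimate, se, statistic, F, df1, df2, p_f, p_normal,
#'   significant), `participant_slopes` (tibble: participant_id, intercept,
#'   b_w, b_psm, b_psa), `r2`, `n_obs`, `n_participants`, `condition`,
#'   `alpha`, `mode`, `slope_method`, `re_structure`, `fallback`, and the
#'   underlying `model`.
#' @export
#' @examples
#' pop <- population_params()
#' trials <- generate_trials(sample_participants(8, pop, seed = 1), seed = 2)
#' fit <- fit_condition(preprocess(trials), build_predictor_table(), "arabic")
#' tidy(fit)
fit_condition <- function(cleaned, table = build_predictor_table(), condition = NULL,
                          alpha = 0.017, mode = c("trials", "cells"),
                          slopes = c("blup", "ols"),
                          random_effects = c("full", "diagonal", "intercept")) {
  mode <- match.arg(mode)
  slopes <- match.arg(slopes)
  random_effects <- match.arg(random_effects)
  stopifnot(is.data.frame(cleaned), is.data.frame(table))
  conds <- unique(cleaned$condition)
  if (is.null(condition)) {
    if (length(conds) > 1L) {
      stop(
        "`cleaned` holds several conditions (",
        paste(conds, collapse = ", "), "); pass `condition`",
        call. = FALSE
      )
    }
    condition <- conds
  }
  dat <- dplyr::filter(tibble::as_tibble(cleaned), .data$condition == !!condition)
  if (nrow(dat) == 0L) {
    stop(sprintf("no trials for condition `%s`", condition), call. = FALSE)
  }
  if (!"log_rt" %in% names(dat)) {
    dat <- dplyr::mutate(dat, log_rt = log(.data$rt_ms))
  }
  missing_digits <- setdiff(unique(dat$digit), table$digit)
  if (length(missing_digits)) {
    stop(
      "digit(s) not covered by the predictor table (is the standard present as a probe?): ",
      paste(sort(missing_digits), collapse = ", "),
      call. = FALSE
    )
  }
  dat <- dplyr::left_join(
    dat, dplyr::select(table, "digit", "w_z", "psm_z", "psa_z"),
    by = "digit"
  )
  n_participants <- dplyr::n_distinct(dat$participant_id)
  if (n_participants < 2L) {
    stop("need at least 2 participants", call. = FALSE)
  }
  if (any(vapply(dat[c("w_z", "psm_z", "psa_z")], stats::sd, numeric(1)) == 0)) {
    stop("all three standardized predictors must vary over the observed digits",
      call. = FALSE
    )
  }
  if (mode == "cells") {
    dat <- dat |>
      dplyr::group_by(
        .data$participant_id, .data$digit,
        .data$w_z, .data$psm_z, .data$psa_z
      ) |>
      dplyr::summarise(log_rt = mean(.data$log_rt), .groups = "drop")
  }
  dat$participant_id <- factor(dat$participant_id)

  fitted <- fit_with_fallback(dat, random_effects)
  model <- fitted$model

  fe <- lme4::fixef(model)
  se <- sqrt(diag(as.matrix(stats::vcov(model))))
  terms <- c("w_z", "psm_z", "psa_z")
  n_obs <- nrow(dat)
  df2 <- n_obs - n_participants - 3L
  all_terms <- c("(Intercept)", terms)
  est_vec <- unname(fe[all_terms])
  se_vec <- unname(se[all_terms])
  fixed <- tibble::tibble(
    term = all_terms,
    estimate = est_vec,
    se = se_vec,
    statistic = est_vec / se_vec
  ) |>
    dplyr::mutate(
      F = .data$statistic^2,
      df1 = 1L,
      df2 = df2,
      p_f = stats::pf(.data$F, 1, df2, lower.tail = FALSE),
      p_normal = 2 * stats::pnorm(-abs(.data$statistic)),
      significant = .data$term != "(Intercept)" & .data$p_f < alpha
    )

  participant_slopes <- extract_participant_slopes(model, dat, slopes)
  r2 <- stats::cor(stats::fitted(model), dat$log_rt)^2

  structure(
    list(
      condition = condition,
      fixed = fixed,
      participant_slopes = participant_slopes,
      r2 = r2,
      n_obs = n_obs,
      n_participants = n_participants,
      alpha = alpha,
      mode = mode,
      slope_method = slopes,
      re_structure = fitted$re_structure,
      fallback = fitted$fallback,
      model = model
    ),
    class = "digitsim_fit"
  )
}

fit_with_fallback <- function(dat, random_effects) {
  forms <- list(
    full = log_rt ~ w_z + psm_z + psa_z + (1 + w_z + psm_z + psa_z | participant_id),
    diagonal = log_rt ~ w_z + psm_z + psa_z + (1 + w_z + psm_z + psa_z || participant_id),
    intercept = log_rt ~ w_z + psm_z + psa_z + (1 | participant_id)
  )
  ladder <- switch(random_effects,
    full = c("full", "diagonal", "intercept"),
    diagonal = c("diagonal", "intercept"),
    intercept = "intercept"
  )
  requested <- ladder[1]
  for (re in ladder) {
    model <- tryCatch(
      suppressMessages(lme4::lmer(
        forms[[re]],
        data = dat, REML = TRUE,
        control = lme4::lmerControl(calc.derivs = FALSE)
      )),
      error = function(e) NULL
    )
    ok <- !is.null(model) && !lme4::isSingular(model, tol = 1e-5)
    if (ok || re == "intercept" && !is.null(model)) {
      if (re != requested) {
        warning(sprintf(
          "random-effect structure `%s` was singular or failed; fell back to `%s`",
          requested, re
        ), call. = FALSE)
      }
      return(list(model = model, re_structure = re, fallback = re != requested))
    }
  }
  stop("mixed model could not be fit under any random-effect structure", call. = FALSE)
}

extract_participant_slopes <- function(model, dat, slopes) {
  ids <- levels(dat$participant_id)
  if (slopes == "ols") {
    return(
      dat |>
        dplyr::group_by(participant_id = .data$participant_id) |>
        dplyr::group_modify(function(g, key) {
          co <- stats::coef(stats::lm(log_rt ~ w_z + psm_z + psa_z, data = g))
          tibble::tibble(
            intercept = co[["(Intercept)"]], b_w = co[["w_z"]],
            b_psm = co[["psm_z"]], b_psa = co[["psa_z"]]
          )
        }) |>
        dplyr::ungroup() |>
        dplyr::mutate(participant_id = as_participant_id(.data$participant_id))
    )
  }
  # fixed effect + predicted (BLUP) participant deviation; missing random
  # terms (fallback structures) contribute zero deviation
  fe <- lme4::fixef(model)
  re <- lme4::ranef(model, condVar = FALSE)$participant_id
  dev <- function(term) if (term %in% colnames(re)) re[ids, term] else 0
  tibble::tibble(
    participant_id = as_participant_id(ids),
    intercept = fe[["(Intercept)"]] + dev("(Intercept)"),
    b_w = fe[["w_z"]] + dev("w_z"),
    b_psm = fe[["psm_z"]] + dev("psm_z"),
    b_psa = fe[["psa_z"]] + dev("psa_z")
  )
}

# factor levels come back as character; restore integer ids when they are such
as_participant_id <- function(x) {
  x <- as.character(x)
  if (all(grepl("^[0-9]+$", x))) as.integer(x) else x
}

#' @export
print.digitsim_fit <- function(x, ...) {
  cat(sprintf(
    "<digitsim_fit> condition %s: %d trials, %d participants (mode %s, RE %s%s)\n",
    x$condition, x$n_obs, x$n_participants, x$mode, x$re_structure,
    if (x$fallback) ", fallback" else ""
  ))
  cat(sprintf("  r2 = %.3f; slope tests at alpha = %.3f\n", x$r2, x$alpha))
  print(as.data.frame(x$fixed), digits = 3, row.names = FALSE)
  invisible(x)
}
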