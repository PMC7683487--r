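#' Draw participant-level coefficient profiles
#'
#' Samples per-participant, per-condition regression coefficients (intercept
#' plus the three predictor slopes) from the multivariate normal implied by
#' [population_params()], together with a per-condition error probability
#' (Beta-distributed with the stated mean and SD) and a counterbalancing-group
#' assignment by equal split.
#'
#' @param n Number of participants (>= 2).
#' @param params A [population_params()].
#' @param seed Optional integer seed; when given the draw is reproducible and
#'   the caller's RNG state is left untouched.
#' @param design A [design_spec()] (supplies the number of groups).
#'
#' @return A tibble with one row per participant x condition: columns
#'   `participant_id`, `group`, `condition`, `intercept`, `b_w`, `b_psm`,
#'   `b_psa`, `error_rate`, `reversed`.
#' @export
#' @examples
#' sample_participants(4, population_params(), seed = 1)
sample_participants <- function(n, params = population_params(), seed = NULL,
                                design = design_spec()) {
  stopifnot(inherits(params, "population_params"), inherits(design, "design_spec"))
  if (length(n) != 1L || n < 2) {
    stop("`n` must be a single count >= 2", call. = FALSE)
  }
  n <- as.integer(n)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, sample_participants(n, params, NULL, design)))
  }
  conds <- params$conditions
  sds <- rep(c(params$sd_intercept, rep(params$sd_slope, 3L)), times = 2L)
  mu <- unlist(lapply(conds, function(cond) {
    c(params$intercept[[cond]], params$slopes[[cond]])
  }), use.names = FALSE)
  sigma <- diag(sds) %*% slope_cor_matrix(params) %*% diag(sds)
  draws <- MASS::mvrnorm(n, mu = mu, Sigma = sigma)
  groups <- sample(rep_len(seq_len(design$n_groups), n))
  long <- purrr::map_dfr(seq_along(conds), function(ci) {
    off <- (ci - 1L) * 4L
    tibble::tibble(
      participant_id = seq_len(n),
      group = groups,
      condition = conds[ci],
      intercept = draws[, off + 1L],
      b_w = draws[, off + 2L],
      b_psm = draws[, off + 3L],
      b_psa = draws[, off + 4L],
      error_rate = rbeta_meansd(
        n, params$error_rate_mean[[conds[ci]]],
        params$error_rate_sd[[conds[ci]]]
      ),
      reversed = FALSE
    )
  })
  dplyr::arrange(long, .data$participant_id, match(.data$condition, conds))
}

# Beta draw parameterized by mean and SD; degenerate SD = 0 gives the mean.
rbeta_meansd <- function(n, mean, sd) {
  if (sd == 0) {
    return(rep(mean, n))
  }
  max_sd <- sqrt(mean * (1 - mean))
  if (sd >= max_sd) {
    stop(sprintf(
      "error-rate sd %.3f is incompatible with mean %.3f (must be < %.3f)",
      sd, mean, max_sd
    ), call. = FALSE)
  }
  nu <- mean * (1 - mean) / sd^2 - 1
  stats::rbeta(n, shape1 = mean * nu, shape2 = (1 - mean) * nu)
}

#' Mark a participant as having reversed the response keys
#'
#' Flags one participant (in one condition, or all) so that
#' [generate_trials()] swaps their responses, producing an error rate near
#' `1 - nominal`, the signature (error rate > 0.96 at the default parameters)
#' that the preprocessing stage must catch and exclude.
#'
#' @param profiles Output of [sample_participants()].
#' @param which A `participant_id` present in `profiles`.
#' @param condition Condition(s) to reverse; default all.
#'
#' @return `profiles` with the `reversed` flag set on the matching rows.
#' @export
inject_reversal <- function(profiles, which, condition = NULL) {
  if (!which %in% profiles$participant_id) {
    stop(sprintf("unknown participant_id `%s`", which), call. = FALSE)
  }
  condition <- condition %||% unique(profiles$condition)
  if (!all(condition %in% profiles$condition)) {
    stop("unknown condition in `condition`", call. = FALSE)
  }
  dplyr::mutate(
    profiles,
    reversed = .data$reversed |
      (.data$participant_id == which & .data$condition %in% !!condition)
  )
}

#' Generate trial-level data for a simulated experiment
#'
#' Produces one row per trial. Within every block each probe digit appears
#' equally often in random order. Log RT follows the participant's linear
#' model on the standardized predictors plus normal residual noise; RTs at or
#' beyond the deadline become timeouts with no response recorded. Responses
#' are wrong with the participant's error probability (key-swapped first for
#' reversed profiles), independently of the digit.
#'
#' @param profiles Output of [sample_participants()] (possibly after
#'   [inject_reversal()]).
#' @param design A [design_spec()].
#' @param table A [build_predictor_table()] covering every digit in `design`.
#' @param params A [population_params()] (residual SD).
#' @param seed Optional integer seed.
#'
#' @return A tibble with columns `participant_id`, `condition`, `block`,
#'   `trial_index`, `digit`, `required_response`, `given_response`, `correct`,
#'   `rt_ms`, `timeout`. Timeout rows have `NA` response, correctness and RT.
#' @export
#' @examples
#' pop <- population_params()
#' prof <- sample_participants(2, pop, seed = 1)
#' trials <- generate_trials(prof, design_spec(), build_predictor_table(), pop, seed = 2)
generate_trials <- function(profiles, design = design_spec(),
                            table = build_predictor_table(), params = population_params(),
                            seed = NULL) {
  stopifnot(
    inherits(design, "design_spec"), inherits(params, "population_params"),
    is.data.frame(profiles), is.data.frame(table)
  )
  if (nrow(profiles) == 0L) {
    stop("`profiles` is empty", call. = FALSE)
  }
  missing_digits <- setdiff(design$digits, table$digit)
  if (length(missing_digits)) {
    stop(
      "predictor table does not cover digit(s): ",
      paste(missing_digits, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, generate_trials(profiles, design, table, params, NULL)
    ))
  }
  n_per_digit <- design$trials_per_block %/% length(design$digits)
  block_digits <- rep(design$digits, each = n_per_digit)
  pred <- table[match(design$digits, table$digit), c("w_z", "psm_z", "psa_z")]

  per_profile <- function(row) {
    digit <- as.vector(replicate(
      design$blocks_per_condition, sample(block_digits)
    ))
    n_tr <- length(digit)
    i <- match(digit, design$digits)
    log_rt <- row$intercept + row$b_w * pred$w_z[i] +
      row$b_psm * pred$psm_z[i] + row$b_psa * pred$psa_z[i] +
      stats::rnorm(n_tr, 0, params$sd_resid)
    rt_ms <- exp(log_rt)
    timeout <- rt_ms >= design$deadline_ms
    required <- ifelse(digit > design$standard, "greater", "less")
    err <- stats::runif(n_tr) < row$error_rate
    if (isTRUE(row$reversed)) err <- !err
    given <- ifelse(err, flip_response(required), required)
    given[timeout] <- NA_character_
    tibble::tibble(
      participant_id = row$participant_id,
      condition = row$condition,
      block = rep(seq_len(design$blocks_per_condition), each = design$trials_per_block),
      trial_index = seq_len(n_tr),
      digit = digit,
      required_response = required,
      given_response = given,
      correct = given == required,
      rt_ms = ifelse(timeout, NA_real_, rt_ms),
      timeout = timeout
    )
  }
  profiles |>
    dplyr::rowwise() |>
    dplyr::group_split() |>
    purrr::map_dfr(per_profile)
}

flip_response <- function(x) {
  ifelse(x == "greater", "less", "greater")
}
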