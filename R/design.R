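#' Experimental design of the two-format comparison task
#'
#' Describes the trial structure the generator reproduces: two format
#' conditions run in separate halves, four blocks of 120 trials per condition,
#' the eight probe digits sampled equally often within every block, a 1,500 ms
#' response deadline, and four counterbalancing groups (condition order
#' crossed with response-key assignment).
#'
#' @param conditions Character vector of condition names (order = testing
#'   order for group 1).
#' @param blocks_per_condition Blocks per condition.
#' @param trials_per_block Trials per block; must be divisible by the number
#'   of probe digits.
#' @param digits Probe digits; the standard must not be among them.
#' @param deadline_ms Response deadline in milliseconds.
#' @param n_groups Number of counterbalancing groups.
#' @param standard The standard digit the probes are judged against.
#'
#' @return An object of class `design_spec`.
#' @export
#' @examples
#' design_spec()
design_spec <- function(conditions = c("arabic", "mandarin"),
                        blocks_per_condition = 4L,
                        trials_per_block = 120L,
                        digits = c(1:4, 6:9),
                        deadline_ms = 1500,
                        n_groups = 4L,
                        standard = 5L) {
  stopifnot(
    length(conditions) == 2L, !anyDuplicated(conditions),
    blocks_per_condition >= 1L, trials_per_block >= 1L,
    deadline_ms > 0, n_groups >= 1L, length(standard) == 1L
  )
  digits <- sort(as.integer(digits))
  if (standard %in% digits) {
    stop("the standard digit cannot be a probe", call. = FALSE)
  }
  if (trials_per_block %% length(digits) != 0L) {
    stop(sprintf(
      "`trials_per_block` (%d) must be divisible by the number of digits (%d) for equal sampling",
      trials_per_block, length(digits)
    ), call. = FALSE)
  }
  structure(
    list(
      conditions = conditions,
      blocks_per_condition = as.integer(blocks_per_condition),
      trials_per_block = as.integer(trials_per_block),
      digits = digits,
      deadline_ms = deadline_ms,
      n_groups = as.integer(n_groups),
      standard = as.integer(standard)
    ),
    class = "design_spec"
  )
}

#' Population parameters of the generative response-time model
#'
#' The generator draws, for every participant, a per-condition coefficient
#' vector (intercept and three slopes on the standardized predictors) from a
#' multivariate normal, then produces trial-level log RTs as
#' `intercept + b_w * W_z + b_psm * PSM_z + b_psa * PSA_z + e`,
#' `e ~ N(0, sd_resid)`. Defaults are the canonical study conditions: Arabic
#' condition intercept 6.16 log-ms with slopes (W, PSM, PSA) =
#' (0.04, 0.01, -0.01); Mandarin intercept 6.19 with (0.05, 0.01, -0.014);
#' error-rate means .036 / .04 with dispersion matched to between-participant
#' SDs of .026 / .025; and a participant-level slope correlation structure
#' with within-condition corr(b_psm, b_psa) of -.43 (Arabic) and -.58
#' (Mandarin), cross-condition corr of +.42 for the PSM slopes and +.26 for
#' the PSA slopes.
#'
#' @param intercept Named numeric: grand mean log RT (log-ms) per condition.
#' @param slopes Named list, one numeric vector `c(w=, psm=, psa=)` per
#'   condition (log-ms per SD of predictor).
#' @param sd_intercept,sd_slope Between-participant SDs of the intercept and
#'   of each slope.
#' @param sd_resid Trial-level residual SD of log RT.
#' @param error_rate_mean,error_rate_sd Named numeric: mean and
#'   between-participant SD of the per-participant error probability.
#' @param cor_within Named numeric: within-condition correlation between the
#'   PSM and PSA slopes.
#' @param cor_cross_psm,cor_cross_psa Cross-condition correlations of the PSM
#'   (resp. PSA) slopes.
#'
#' @return An object of class `population_params`.
#' @export
#' @examples
#' population_params()
population_params <- function(intercept = c(arabic = 6.16, mandarin = 6.19),
                              slopes = list(
                                arabic = c(w = 0.04, psm = 0.01, psa = -0.01),
                                mandarin = c(w = 0.05, psm = 0.01, psa = -0.014)
                              ),
                              sd_intercept = 0.10,
                              sd_slope = 0.02,
                              sd_resid = 0.15,
                              error_rate_mean = c(arabic = 0.036, mandarin = 0.040),
                              error_rate_sd = c(arabic = 0.026, mandarin = 0.025),
                              cor_within = c(arabic = -0.43, mandarin = -0.58),
                              cor_cross_psm = 0.42,
                              cor_cross_psa = 0.26) {
  conds <- names(intercept)
  stopifnot(
    length(conds) == 2L, setequal(names(slopes), conds),
    all(vapply(slopes, function(s) setequal(names(s), c("w", "psm", "psa")), logical(1))),
    sd_intercept >= 0, sd_slope >= 0, sd_resid >= 0,
    setequal(names(error_rate_mean), conds), setequal(names(error_rate_sd), conds),
    all(error_rate_mean > 0), all(error_rate_mean < 1), all(error_rate_sd >= 0),
    setequal(names(cor_within), conds),
    all(abs(c(cor_within, cor_cross_psm, cor_cross_psa)) <= 1)
  )
  p <- structure(
    list(
      conditions = conds,
      intercept = intercept,
      slopes = lapply(slopes[conds], function(s) s[c("w", "psm", "psa")]),
      sd_intercept = sd_intercept,
      sd_slope = sd_slope,
      sd_resid = sd_resid,
      error_rate_mean = error_rate_mean[conds],
      error_rate_sd = error_rate_sd[conds],
      cor_within = cor_within[conds],
      cor_cross_psm = cor_cross_psm,
      cor_cross_psa = cor_cross_psa
    ),
    class = "population_params"
  )
  # fail fast: the slope correlation matrix must admit a joint normal
  ev <- eigen(slope_cor_matrix(p), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop(
      "slope correlation structure is not positive semidefinite ",
      sprintf("(min eigenvalue %.3g)", min(ev)),
      call. = FALSE
    )
  }
  p
}

# 8 x 8 correlation matrix over (intercept, b_w, b_psm, b_psa) x 2 conditions.
# Only the four similarity slopes are correlated.
slope_cor_matrix <- function(params) {
  conds <- params$conditions
  nm <- as.vector(outer(c("intercept", "w", "psm", "psa"), conds, function(a, b) paste(b, a, sep = ".")))
  m <- diag(length(nm))
  dimnames(m) <- list(nm, nm)
  idx <- function(cond, term) paste(cond, term, sep = ".")
  for (cond in conds) {
    m[idx(cond, "psm"), idx(cond, "psa")] <-
      m[idx(cond, "psa"), idx(cond, "psm")] <- params$cor_within[[cond]]
  }
  m[idx(conds[1], "psm"), idx(conds[2], "psm")] <-
    m[idx(conds[2], "psm"), idx(conds[1], "psm")] <- params$cor_cross_psm
  m[idx(conds[1], "psa"), idx(conds[2], "psa")] <-
    m[idx(conds[2], "psa"), idx(conds[1], "psa")] <- params$cor_cross_psa
  m
}
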