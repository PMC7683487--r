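#' Inter-participant correlations among the similarity slopes
#'
#' The individual-differences analysis: Pearson correlations, over
#' participants, of the per-participant PSM and PSA slopes within and across
#' the two conditions. Four correlations are computed -- PSM across
#' conditions, PSA across conditions, PSM-vs-PSA within each condition --
#' each with `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` df and a
#' significance flag at a Bonferroni-corrected alpha (default .0125, four
#' tests).
#'
#' @param fit1,fit2 [fit_condition()] results for the two conditions, over
#'   the same participant set.
#' @param alpha Significance threshold (default .0125).
#'
#' @return A tibble of class `digitsim_slope_cors` with columns
#'   `correlation`, `r`, `n`, `df`, `t`, `p`, `significant`; attribute
#'   `conditions`.
#' @export
correlate_slopes <- function(fit1, fit2, alpha = 0.0125) {
  stopifnot(inherits(fit1, "digitsim_fit"), inherits(fit2, "digitsim_fit"))
  if (identical(fit1$condition, fit2$condition)) {
    stop("`fit1` and `fit2` must come from different conditions", call. = FALSE)
  }
  s1 <- fit1$participant_slopes
  s2 <- fit2$participant_slopes
  only1 <- setdiff(s1$participant_id, s2$participant_id)
  only2 <- setdiff(s2$participant_id, s1$participant_id)
  if (length(only1) || length(only2)) {
    stop(
      "participant sets differ between fits; only in ", fit1$condition, ": {",
      paste(only1, collapse = ", "), "}, only in ", fit2$condition, ": {",
      paste(only2, collapse = ", "), "}",
      call. = FALSE
    )
  }
  merged <- dplyr::inner_join(s1, s2,
    by = "participant_id",
    suffix = paste0(".", c(fit1$condition, fit2$condition))
  )
  n <- nrow(merged)
  if (n < 3L) {
    stop("need at least 3 common participants to correlate slopes", call. = FALSE)
  }
  col <- function(term, cond) merged[[paste0(term, ".", cond)]]
  c1 <- fit1$condition
  c2 <- fit2$condition
  pairs <- list(
    psm_across = list(col("b_psm", c1), col("b_psm", c2)),
    psa_across = list(col("b_psa", c1), col("b_psa", c2))
  )
  pairs[[paste0("psm_psa_within_", c1)]] <- list(col("b_psm", c1), col("b_psa", c1))
  pairs[[paste0("psm_psa_within_", c2)]] <- list(col("b_psm", c2), col("b_psa", c2))

  out <- purrr::imap_dfr(pairs, function(xy, nm) {
    # degenerate (zero-variance) slope vectors -- e.g. after an
    # intercept-only fallback fit -- carry no individual differences
    if (stats::sd(xy[[1]]) == 0 || stats::sd(xy[[2]]) == 0) {
      return(tibble::tibble(
        correlation = nm, r = NA_real_, n = n, df = n - 2L,
        t = NA_real_, p = NA_real_, significant = NA
      ))
    }
    r <- stats::cor(xy[[1]], xy[[2]])
    t <- r_to_t(r, n - 2L)
    p <- 2 * stats::pt(-abs(t), n - 2L)
    tibble::tibble(
      correlation = nm, r = r, n = n, df = n - 2L, t = t,
      p = p, significant = p < alpha
    )
  })
  attr(out, "conditions") <- c(c1, c2)
  attr(out, "alpha") <- alpha
  class(out) <- c("digitsim_slope_cors", class(out))
  out
}
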