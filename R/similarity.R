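#' Segment-overlap physical similarity between two glyphs
#'
#' The physical similarity of two numerals rendered in the same script is
#' `P = O / D`, where `O` counts the line segments the two glyphs share and
#' `D` counts the remaining, non-overlapping segments (the symmetric
#' difference of the two segment sets). Identical segment sets make `D = 0`
#' and similarity undefined; that degenerate case is an error, not a score.
#'
#' @param g1,g2 Objects from [encode_glyph()], in the same script.
#'
#' @return A tibble row of class `similarity_score` with columns `value1`,
#'   `value2`, `script`, `O`, `D`, `P`.
#' @export
#' @examples
#' five <- encode_glyph(5, "arabic_sevenseg")
#' one <- encode_glyph(1, "arabic_sevenseg")
#' physical_similarity(one, five) # O = 1, D = 5, P = 0.2
physical_similarity <- function(g1, g2) {
  stopifnot(inherits(g1, "glyph_encoding"), inherits(g2, "glyph_encoding"))
  if (g1$script != g2$script) {
    stop(sprintf(
      "cannot compare glyphs across scripts (%s vs %s)",
      g1$script, g2$script
    ), call. = FALSE)
  }
  o <- length(intersect(g1$segment_ids, g2$segment_ids))
  d <- length(union(g1$segment_ids, g2$segment_ids)) - o
  if (d == 0L) {
    stop(sprintf(
      "glyphs %d and %d (%s) have identical segment sets; P = O/D is undefined",
      g1$value, g2$value, g1$script
    ), call. = FALSE)
  }
  out <- tibble::tibble(
    value1 = g1$value, value2 = g2$value, script = g1$script,
    O = o, D = d, P = o / d
  )
  class(out) <- c("similarity_score", class(out))
  out
}

#' Welford numerical-distance term
#'
#' The Welford function `a + k * log(L / (L - S))`, with `L` the larger and
#' `S` the smaller of the two quantities, models both the numerical distance
#' effect (the term shrinks as the probe moves away from the standard) and the
#' size effect (for equal distance, comparisons among larger quantities give a
#' larger term, e.g. 6-vs-5 exceeds 4-vs-5).
#'
#' @param probe Integer vector of probe quantities (recycled against
#'   `standard`); must differ from the standard.
#' @param standard Integer standard quantity (5 in the canonical design).
#' @param spec A [welford_spec()].
#'
#' @return Numeric vector of Welford terms.
#' @export
#' @examples
#' welford_term(4, 5) # log(5/1) = 1.609...
#' welford_term(6, 5) > welford_term(4, 5) # the size effect
welford_term <- function(probe, standard = 5L, spec = welford_spec()) {
  stopifnot(inherits(spec, "welford_spec"))
  if (any(!is.finite(probe)) || any(probe <= 0) || any(probe != round(probe)) ||
    any(!is.finite(standard)) || any(standard <= 0) ||
    any(standard != round(standard))) {
    stop("`probe` and `standard` must be positive integers", call. = FALSE)
  }
  if (any(probe == standard)) {
    stop("`probe` must differ from `standard`: log(L/(L-S)) diverges at L = S",
      call. = FALSE
    )
  }
  L <- pmax(probe, standard)
  S <- pmin(probe, standard)
  logf <- if (spec$log_base == "base10") log10 else log
  spec$a + spec$k * logf(L / (L - S))
}

#' Constants of the Welford function
#'
#' Defaults `a = 0`, `k = 1` return the bare log-ratio term, which is what the
#' regression pipeline standardizes; `a` and `k` are then absorbed into the
#' fitted intercept and slope. The log base is a positive rescaling and is
#' likewise absorbed by standardization.
#'
#' @param a Additive constant (same units as the response it models).
#' @param k Multiplicative constant.
#' @param log_base `"natural"` or `"base10"`.
#' @return An object of class `welford_spec`.
#' @export
welford_spec <- function(a = 0, k = 1, log_base = c("natural", "base10")) {
  log_base <- match.arg(log_base)
  stopifnot(is.numeric(a), length(a) == 1L, is.numeric(k), length(k) == 1L)
  structure(list(a = a, k = k, log_base = log_base), class = "welford_spec")
}

#' Per-digit predictor table for the comparison-against-a-standard task
#'
#' For every probe digit (1--9 minus the standard) computes the three
#' predictors used by the regression pipeline: physical similarity of the
#' digit's Mandarin glyph to the Mandarin standard (PSM), physical similarity
#' of its Arabic seven-segment glyph to the Arabic standard (PSA), and the
#' Welford numerical-distance term (W). Each predictor is also standardized
#' (z-scored with the population, n-denominator variance) over the probe
#' digits, which is the scale the mixed model uses.
#'
#' @param standard The standard digit (default 5, the canonical design).
#' @param spec A [welford_spec()].
#' @param arabic_variant Display-variant choice for Arabic 6/7/9, see
#'   [arabic_variants()].
#'
#' @return A tibble of class `predictor_table` with columns `digit`,
#'   `psm_raw`, `psa_raw`, `w_raw`, `psm_z`, `psa_z`, `w_z` and attributes
#'   `standard`, `arabic_variant`, `log_base`.
#' @export
#' @examples
#' build_predictor_table()
build_predictor_table <- function(standard = 5L, spec = welford_spec(),
                                  arabic_variant = default_arabic_variant()) {
  stopifnot(
    length(standard) == 1L, standard %in% 1:9,
    inherits(spec, "welford_spec")
  )
  standard <- as.integer(standard)
  digits <- setdiff(1:9, standard)
  sim_to_standard <- function(script) {
    std <- encode_glyph(standard, script, arabic_variant = arabic_variant)
    vapply(digits, function(d) {
      physical_similarity(
        encode_glyph(d, script, arabic_variant = arabic_variant), std
      )$P
    }, numeric(1))
  }
  tab <- tibble::tibble(
    digit = digits,
    psm_raw = sim_to_standard("mandarin"),
    psa_raw = sim_to_standard("arabic_sevenseg"),
    w_raw = welford_term(digits, standard, spec)
  ) |>
    dplyr::mutate(
      psm_z = zscore_pop(.data$psm_raw),
      psa_z = zscore_pop(.data$psa_raw),
      w_z = zscore_pop(.data$w_raw)
    )
  attr(tab, "standard") <- standard
  attr(tab, "arabic_variant") <- arabic_variant
  attr(tab, "log_base") <- spec$log_base
  class(tab) <- c("predictor_table", class(tab))
  tab
}

# z-score with the population (n-denominator) variance: over a fixed set of
# digits the predictors are exhaustive measures, not a sample.
zscore_pop <- function(x) {
  s <- sqrt(mean((x - mean(x))^2))
  if (s == 0) {
    stop("cannot standardize a zero-variance column", call. = FALSE)
  }
  (x - mean(x)) / s
}

#' Pairwise correlations among the three predictors
#'
#' Pearson correlations of the raw PSA, PSM and Welford columns over the probe
#' digits, the structure that determines how separable the three effects are
#' in the regression.
#'
#' @param table A [build_predictor_table()] result (or any data frame with
#'   `psa_raw`, `psm_raw`, `w_raw`).
#' @return A symmetric 3 x 3 correlation matrix with dimnames
#'   `c("psa", "psm", "welford")` and unit diagonal.
#' @export
#' @examples
#' predictor_correlations(build_predictor_table())
predictor_correlations <- function(table) {
  cols <- c(psa = "psa_raw", psm = "psm_raw", welford = "w_raw")
  missing_cols <- setdiff(unname(cols), names(table))
  if (length(missing_cols)) {
    stop(
      "`table` lacks raw predictor column(s): ",
      paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  m <- as.matrix(table[unname(cols)])
  colnames(m) <- names(cols)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop(
      "zero-variance predictor column(s): ",
      paste(names(cols)[sds == 0], collapse = ", "),
      call. = FALSE
    )
  }
  r <- stats::cor(m)
  diag(r) <- 1
  r
}
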