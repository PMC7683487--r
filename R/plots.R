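#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Render a glyph's segment encoding
#'
#' Draws the stored line segments of one numeral on its coordinate grid --
#' the visual check that an encoding matches the printed glyph.
#'
#' @inheritParams encode_glyph
#' @return A ggplot object.
#' @export
#' @examples
#' plot_glyph(5, "mandarin")
plot_glyph <- function(value, script = c("arabic_sevenseg", "mandarin"),
                       arabic_variant = default_arabic_variant()) {
  g <- encode_glyph(value, script, arabic_variant = arabic_variant)
  inv <- segment_inventory(g$script)
  inv$on <- inv$segment_id %in% g$segment_ids
  ggplot2::ggplot(inv, ggplot2::aes(
    x = .data$x1, y = .data$y1, xend = .data$x2, yend = .data$y2,
    colour = .data$on, linewidth = .data$on
  )) +
    ggplot2::geom_segment(lineend = "round") +
    ggplot2::scale_colour_manual(values = c("TRUE" = "black", "FALSE" = "grey85"), guide = "none") +
    ggplot2::scale_linewidth_manual(values = c("TRUE" = 2, "FALSE" = 0.6), guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("%d (%s)", g$value, g$script))
}

#' Plot the per-digit predictors
#'
#' Raw PSM, PSA and Welford values against the probe digit; the competing
#' similarity gradients and the distance/size structure at a glance.
#'
#' @param object A [build_predictor_table()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot predictor_table
#' @export
autoplot.predictor_table <- function(object, ...) {
  long <- object |>
    dplyr::select("digit", "psm_raw", "psa_raw", "w_raw") |>
    tidyr::pivot_longer(-"digit", names_to = "predictor", values_to = "value") |>
    dplyr::mutate(predictor = dplyr::recode(.data$predictor,
      psm_raw = "PSM", psa_raw = "PSA", w_raw = "Welford"
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    .data$digit, .data$value,
    colour = .data$predictor
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$digit) +
    ggplot2::facet_wrap(~predictor, scales = "free_y") +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = "probe digit", y = "raw predictor value")
}

#' Boxplots of per-participant slopes
#'
#' The distribution, over participants, of the three predictor slopes from
#' one condition's mixed fit.
#'
#' @param object A [fit_condition()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot digitsim_fit
#' @export
autoplot.digitsim_fit <- function(object, ...) {
  long <- object$participant_slopes |>
    tidyr::pivot_longer(c("b_w", "b_psm", "b_psa"),
      names_to = "predictor", values_to = "slope"
    ) |>
    dplyr::mutate(predictor = factor(
      dplyr::recode(.data$predictor,
        b_w = "Welford", b_psm = "PSM", b_psa = "PSA"
      ),
      levels = c("Welford", "PSM", "PSA")
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$predictor, .data$slope)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_boxplot(width = 0.5) +
    ggplot2::labs(
      x = NULL, y = "per-participant slope (log-ms per SD)",
      title = sprintf("%s condition", object$condition)
    )
}

#' Scatter plots of the four slope correlations
#'
#' Per-participant PSM and PSA slopes plotted within and across conditions:
#' the individual-differences picture behind [correlate_slopes()].
#'
#' @param fit1,fit2 [fit_condition()] results for the two conditions.
#' @return A ggplot object (faceted over the four correlation panels).
#' @export
plot_slope_scatter <- function(fit1, fit2) {
  cors <- correlate_slopes(fit1, fit2)
  s1 <- fit1$participant_slopes
  s2 <- fit2$participant_slopes
  s2 <- s2[match(s1$participant_id, s2$participant_id), ]
  c1 <- fit1$condition
  c2 <- fit2$condition
  panel <- function(x, y, nm, xl, yl) {
    tibble::tibble(panel = nm, x = x, y = y, xlab = xl, ylab = yl)
  }
  dat <- dplyr::bind_rows(
    panel(
      s1$b_psm, s2$b_psm, sprintf("PSM: %s vs %s", c1, c2),
      sprintf("PSM slope (%s)", c1), sprintf("PSM slope (%s)", c2)
    ),
    panel(
      s1$b_psa, s2$b_psa, sprintf("PSA: %s vs %s", c1, c2),
      sprintf("PSA slope (%s)", c1), sprintf("PSA slope (%s)", c2)
    ),
    panel(
      s1$b_psm, s1$b_psa, sprintf("within %s: PSM vs PSA", c1),
      sprintf("PSM slope (%s)", c1), sprintf("PSA slope (%s)", c1)
    ),
    panel(
      s2$b_psm, s2$b_psa, sprintf("within %s: PSM vs PSA", c2),
      sprintf("PSM slope (%s)", c2), sprintf("PSA slope (%s)", c2)
    )
  )
  panel_r <- tibble::tibble(
    panel = unique(dat$panel), # creation order matches cors rows
    label = sprintf("r = %.2f", cors$r)
  )
  labels <- dat |>
    dplyr::group_by(.data$panel) |>
    dplyr::summarise(x = min(.data$x), y = max(.data$y), .groups = "drop") |>
    dplyr::left_join(panel_r, by = "panel")
  ggplot2::ggplot(dat, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "steelblue") +
    ggplot2::geom_text(
      data = labels, ggplot2::aes(label = .data$label),
      hjust = 0, vjust = 1, size = 3.2
    ) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "slope", y = "slope")
}
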