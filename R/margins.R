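#' Per-side, per-axis margin prescription
#'
#' A margin prescription holds four non-negative widths in mm, one per side
#' of each principal BEV axis: `x_plus`/`x_minus` along the leaf-travel axis
#' and `y_plus`/`y_minus` along the jaw axis, the sign naming the side of the
#' isocenter the margin is added on. Negative inputs are clamped to zero:
#' the margin generator only ever expands apertures, it never erodes them.
#'
#' @param x_plus,x_minus,y_plus,y_minus Margin widths in mm.
#' @return An object of class `margin_spec` (named numeric of length 4).
#' @examples
#' margin_spec(2, 4, 1, 1)
#' @export
margin_spec <- function(x_plus = 0, x_minus = 0, y_plus = 0, y_minus = 0) {
  m <- c(x_plus = as.numeric(x_plus), x_minus = as.numeric(x_minus),
         y_plus = as.numeric(y_plus), y_minus = as.numeric(y_minus))
  if (!all(is.finite(m))) abort("margins must be finite")
  m <- pmax(m, 0)
  structure(m, class = "margin_spec")
}

#' @export
print.margin_spec <- function(x, ...) {
  cat(sprintf(
    "<margin_spec> x: (+%.2f, -%.2f) mm, y: (+%.2f, -%.2f) mm\n",
    x[["x_plus"]], x[["x_minus"]], x[["y_plus"]], x[["y_minus"]]))
  invisible(x)
}

#' @export
tidy.margin_spec <- function(x, ...) {
  tibble(axis = c("x", "x", "y", "y"),
         side = c("plus", "minus", "plus", "minus"),
         margin_mm = as.numeric(x[c("x_plus", "x_minus", "y_plus", "y_minus")]))
}

as_margin_spec <- function(m) {
  if (inherits(m, "margin_spec")) return(m)
  if (is.numeric(m) && length(m) == 4L) {
    if (!is.null(names(m)) && all(c("x_plus", "x_minus", "y_plus", "y_minus") %in% names(m)))
      return(margin_spec(m[["x_plus"]], m[["x_minus"]], m[["y_plus"]], m[["y_minus"]]))
    return(margin_spec(m[1], m[2], m[3], m[4]))
  }
  abort("cannot interpret margins; use margin_spec()")
}
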