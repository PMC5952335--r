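#' MLC leaf-bank geometry
#'
#' Describes the static geometry of the leaf bank: `n_pairs` opposed leaf
#' pairs of width `leaf_width` mm stacked along y, tiling
#' `[y_center - n_pairs*leaf_width/2, y_center + n_pairs*leaf_width/2)`
#' contiguously. Leaves travel along x.
#'
#' @param n_pairs Number of leaf pairs.
#' @param leaf_width Leaf width in mm (5 mm by default, an Agility-class MLC).
#' @param y_center Center of the bank along y, mm.
#' @return A list of class `leaf_bank_geometry`.
#' @export
leaf_bank_geometry <- function(n_pairs = 24L, leaf_width = 5, y_center = 0) {
  stopifnot(n_pairs >= 1L, leaf_width > 0, is.finite(y_center))
  structure(list(n_pairs = as.integer(n_pairs), leaf_width = leaf_width,
                 y0 = y_center - n_pairs * leaf_width / 2),
            class = "leaf_bank_geometry")
}

# x-positions where the polygon boundary crosses the horizontal line y = yc
# (even-odd, half-open rule at vertices); sorted, even count.
row_crossings <- function(poly, yc) {
  x <- poly$x_mm; y <- poly$y_mm
  n <- length(x)
  j <- c(2:n, 1L)
  hit <- (y <= yc) != (y[j] <= yc)
  if (!any(hit)) return(numeric(0))
  t <- (yc - y[hit]) / (y[j][hit] - y[hit])
  sort(x[hit] + t * (x[j][hit] - x[hit]))
}

#' Fit MLC leaves to an aperture polygon by sub-leaf averaging
#'
#' Each leaf pair is subdivided into `n_subleaves` rows; the polygon's
#' intersection with each row's center line contributes its extreme x
#' positions (global min/max when a row is crossed more than twice, i.e.
#' the convex cover of that row), and the pair's left/right leaf positions
#' are the averages over the contributing rows. Pairs whose rows never meet
#' the polygon are closed at the aperture centroid's x with zero gap and
#' sit behind the jaws.
#'
#' @param poly An [aperture()].
#' @param bank A [leaf_bank_geometry()].
#' @param n_subleaves Rows per leaf pair (default 10, i.e. 0.5 mm effective
#'   discretization for 5 mm leaves).
#' @return A tibble of class `leaf_bank` with one row per pair
#'   (`pair`, `y_low_mm`, `y_high_mm`, `left_mm`, `right_mm`, `closed`,
#'   `n_rows` — the number of sub-leaf rows that met the polygon) and
#'   attributes `leaf_width`, `jaw_y_plus`, `jaw_y_minus` (initialized to
#'   the polygon's y extrema; see [set_jaws()]).
#' @export
fit_leaves <- function(poly, bank = leaf_bank_geometry(), n_subleaves = 10L) {
  poly <- as_aperture(poly)
  stopifnot(inherits(bank, "leaf_bank_geometry"), n_subleaves >= 1L)
  w <- bank$leaf_width
  cx <- aperture_centroid(poly)[1]
  multi <- FALSE
  fit_pair <- function(p) {
    y_low <- bank$y0 + (p - 1) * w
    ys <- y_low + (seq_len(n_subleaves) - 0.5) * w / n_subleaves
    lefts <- numeric(0); rights <- numeric(0)
    for (yc in ys) {
      xs <- row_crossings(poly, yc)
      if (length(xs) >= 2L) {
        if (length(xs) > 2L) multi <<- TRUE
        lefts <- c(lefts, xs[1])
        rights <- c(rights, xs[length(xs)])
      }
    }
    if (length(lefts) == 0L) {
      c(cx, cx, 1, 0)
    } else {
      c(mean(lefts), mean(rights), 0, length(lefts))
    }
  }
  res <- vapply(seq_len(bank$n_pairs), fit_pair, numeric(4))
  if (multi) {
    inform("sub-leaf row crossed more than twice; using global extents")
  }
  out <- tibble(
    pair = seq_len(bank$n_pairs),
    y_low_mm = bank$y0 + (seq_len(bank$n_pairs) - 1) * w,
    y_high_mm = bank$y0 + seq_len(bank$n_pairs) * w,
    left_mm = res[1, ],
    right_mm = res[2, ],
    closed = res[3, ] > 0,
    n_rows = as.integer(res[4, ])
  )
  if (all(out$closed)) warn("polygon entirely outside the leaf bank; all pairs closed")
  attr(out, "leaf_width") <- w
  attr(out, "jaw_y_plus") <- max(poly$y_mm)
  attr(out, "jaw_y_minus") <- min(poly$y_mm)
  class(out) <- c("leaf_bank", class(out))
  out
}

#' Set the jaws (diaphragms) from a polygon and y margins
#'
#' The jaws bound the field along y: the upper jaw sits at the polygon's
#' y maximum plus `y_plus` margin, the lower jaw at the y minimum minus
#' `y_minus`.
#'
#' @param bank A `leaf_bank` from [fit_leaves()].
#' @param margins A [margin_spec()] (only the y components are used).
#' @param poly The aperture the jaws should cover.
#' @return The `leaf_bank` with updated jaw attributes.
#' @export
set_jaws <- function(bank, margins, poly) {
  stopifnot(inherits(bank, "leaf_bank"))
  margins <- as_margin_spec(margins)
  poly <- as_aperture(poly)
  up <- max(poly$y_mm) + margins[["y_plus"]]
  lo <- min(poly$y_mm) - margins[["y_minus"]]
  if (lo > up) abort("jaws would cross")
  attr(bank, "jaw_y_plus") <- up
  attr(bank, "jaw_y_minus") <- lo
  bank
}

#' Rasterize a fitted leaf bank into the machine-deliverable aperture
#'
#' A cell is open iff its center lies between the leaf tips of its pair
#' (inclusive), inside the jaws, and the pair is not closed. This is the
#' fluence-defining aperture actually deliverable by the MLC.
#'
#' @param bank A `leaf_bank` from [fit_leaves()].
#' @param resolution Cell size in mm.
#' @param pad Padding in mm around the open region.
#' @return A [raster_mask()].
#' @export
rasterize_bank <- function(bank, resolution = 0.25, pad = 20) {
  stopifnot(inherits(bank, "leaf_bank"))
  open <- !bank$closed
  if (!any(open)) abort("all leaf pairs closed; nothing to rasterize")
  jp <- attr(bank, "jaw_y_plus"); jm <- attr(bank, "jaw_y_minus")
  xmin <- min(bank$left_mm[open]); xmax <- max(bank$right_mm[open])
  ymin <- max(min(bank$y_low_mm[open]), jm)
  ymax <- min(max(bank$y_high_mm[open]), jp)
  i0 <- floor((xmin - pad) / resolution); i1 <- ceiling((xmax + pad) / resolution)
  j0 <- floor((ymin - pad) / resolution); j1 <- ceiling((ymax + pad) / resolution)
  xs <- (i0:i1) * resolution
  ys <- (j0:j1) * resolution
  occ <- matrix(FALSE, length(xs), length(ys))
  w <- attr(bank, "leaf_width")
  for (j in seq_along(ys)) {
    yc <- ys[j]
    if (yc < jm || yc > jp) next
    p <- floor((yc - bank$y_low_mm[1]) / w) + 1L
    if (p < 1L || p > nrow(bank) || bank$closed[p]) next
    occ[, j] <- xs >= bank$left_mm[p] & xs <= bank$right_mm[p]
  }
  raster_mask(occ, resolution, origin = c(xs[1], ys[1]))
}
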