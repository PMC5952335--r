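#' Beam's-eye-view aperture polygons
#'
#' An aperture is a simple closed polygon in the beam's-eye view (BEV),
#' stored as a tibble of vertices in mm with the origin at the MLC isocenter.
#' `x_mm` runs along the leaf-travel axis, `y_mm` along the perpendicular
#' (jaw) axis. Vertices are kept as an open ring (the closing edge is
#' implicit) and orientation is normalized to counter-clockwise.
#'
#' @param vertices A data frame (or matrix) with columns `x_mm`, `y_mm`
#'   (or two unnamed columns taken in that order).
#' @param validate Check simplicity (non-self-intersection)? The check is
#'   quadratic in the vertex count; internal callers that construct outlines
#'   known to be simple skip it.
#' @return A tibble of class `aperture` with columns `x_mm`, `y_mm`.
#' @examples
#' sq <- aperture(data.frame(x_mm = c(-25, 25, 25, -25),
#'                           y_mm = c(-25, -25, 25, 25)))
#' aperture_area(sq)
#' @export
aperture <- function(vertices, validate = TRUE) {
  v <- as.data.frame(vertices)
  if (!all(c("x_mm", "y_mm") %in% names(v))) {
    if (ncol(v) < 2L) abort("aperture vertices need two coordinate columns")
    names(v)[1:2] <- c("x_mm", "y_mm")
  }
  x <- as.numeric(v$x_mm)
  y <- as.numeric(v$y_mm)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("aperture vertices must be finite")
  }
  # drop an explicit closing vertex
  n <- length(x)
  if (n >= 2L && x[1] == x[n] && y[1] == y[n]) {
    x <- x[-n]; y <- y[-n]; n <- n - 1L
  }
  # drop consecutive duplicates
  keep <- c(TRUE, x[-1] != x[-n] | y[-1] != y[-n])
  x <- x[keep]; y <- y[keep]; n <- length(x)
  if (n < 3L) abort("aperture needs at least 3 distinct vertices")
  if (validate && polygon_self_intersects(x, y)) {
    abort("aperture polygon is self-intersecting")
  }
  if (shoelace_area(x, y) < 0) {  # normalize to counter-clockwise
    x <- rev(x); y <- rev(y)
  }
  out <- tibble(x_mm = x, y_mm = y)
  class(out) <- c("aperture", class(out))
  out
}

#' @rdname aperture
#' @param radius,width,height,center Shape parameters in mm.
#' @param n_vertices Number of vertices used to approximate the circle.
#' @export
aperture_circle <- function(radius, center = c(0, 0), n_vertices = 128L) {
  stopifnot(is.finite(radius), radius > 0)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  aperture(tibble(x_mm = center[1] + radius * cos(th),
                  y_mm = center[2] + radius * sin(th)),
           validate = FALSE)
}

#' @rdname aperture
#' @export
aperture_rect <- function(width, height, center = c(0, 0)) {
  stopifnot(width > 0, height > 0)
  aperture(tibble(
    x_mm = center[1] + c(-1, 1, 1, -1) * width / 2,
    y_mm = center[2] + c(-1, -1, 1, 1) * height / 2
  ), validate = FALSE)
}

shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_self_intersects <- function(x, y) {
  n <- length(x)
  if (n <= 3L) return(FALSE)
  seg <- cbind(x, y, x[c(2:n, 1L)], y[c(2:n, 1L)])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    # the closing edge (n -> 1) is adjacent to edge 1
    if (i == 1L) js <- js[js != n]
    for (j in js) {
      if (segments_cross(seg[i, ], seg[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(a, b) {
  d1 <- cross2(b[3] - b[1], b[4] - b[2], a[1] - b[1], a[2] - b[2])
  d2 <- cross2(b[3] - b[1], b[4] - b[2], a[3] - b[1], a[4] - b[2])
  d3 <- cross2(a[3] - a[1], a[4] - a[2], b[1] - a[1], b[2] - a[2])
  d4 <- cross2(a[3] - a[1], a[4] - a[2], b[3] - a[1], b[4] - a[2])
  (d1 * d2 < 0) && (d3 * d4 < 0)
}

cross2 <- function(ux, uy, vx, vy) ux * vy - uy * vx

#' Shift an aperture rigidly in the BEV
#'
#' Translates every vertex by `displacement`; shape and area are preserved
#' exactly. This is how a planned segment follows the sensed target position.
#'
#' @param poly An [aperture()].
#' @param displacement Length-2 numeric, mm along (x, y).
#' @return The translated `aperture`.
#' @export
shift_aperture <- function(poly, displacement) {
  poly <- as_aperture(poly)
  displacement <- as.numeric(displacement)
  if (length(displacement) != 2L || !all(is.finite(displacement))) {
    abort("displacement must be two finite numbers (mm)")
  }
  out <- dplyr::mutate(poly,
                       x_mm = .data$x_mm + displacement[1],
                       y_mm = .data$y_mm + displacement[2])
  class(out) <- class(poly)
  out
}

#' Polygon area and centroid
#'
#' @param poly An [aperture()].
#' @return `aperture_area()`: signed shoelace area in mm^2 (positive,
#'   since orientation is normalized); `aperture_centroid()`: length-2
#'   numeric (mm).
#' @export
aperture_area <- function(poly) {
  poly <- as_aperture(poly)
  shoelace_area(poly$x_mm, poly$y_mm)
}

#' @rdname aperture_area
#' @export
aperture_centroid <- function(poly) {
  poly <- as_aperture(poly)
  x <- poly$x_mm; y <- poly$y_mm
  n <- length(x); j <- c(2:n, 1L)
  w <- x * y[j] - x[j] * y
  a <- sum(w) / 2
  if (abs(a) < .Machine$double.eps) return(c(mean(x), mean(y)))
  c(sum((x + x[j]) * w) / (6 * a), sum((y + y[j]) * w) / (6 * a))
}

as_aperture <- function(poly) {
  if (inherits(poly, "aperture")) return(poly)
  aperture(poly)
}

#' Even-odd point-in-polygon test
#'
#' Vectorized crossing-number test; points exactly on an edge follow the
#' half-open convention of the crossing rule.
#'
#' @param poly An [aperture()].
#' @param px,py Point coordinates (mm), equal length.
#' @return Logical vector.
#' @keywords internal
points_in_polygon <- function(poly, px, py) {
  x <- poly$x_mm; y <- poly$y_mm
  n <- length(x)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    yi <- y[i]; yj <- y[j]; xi <- x[i]; xj <- x[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xc <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      inside[crosses] <- xor(inside[crosses], px[crosses] < xc)
    }
    j <- i
  }
  inside
}
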