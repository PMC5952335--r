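#' Binary raster masks of apertures
#'
#' A `raster_mask` stores a binary occupancy grid on an isotropic cell
#' lattice. `occ[i, j]` covers the cell centered at
#' `origin + (i - 1, j - 1) * resolution`, with the first index running
#' along the leaf-travel axis x. Grids are aligned to integer multiples of
#' the resolution so masks from different calls share cell centers.
#'
#' @param occ Logical (or 0/1) matrix, x index first.
#' @param resolution Cell size in mm (> 0).
#' @param origin Length-2 numeric: BEV coordinates (mm) of the center of
#'   cell `[1, 1]`.
#' @return An object of class `raster_mask`.
#' @export
raster_mask <- function(occ, resolution, origin) {
  stopifnot(is.matrix(occ), length(resolution) == 1L, resolution > 0,
            length(origin) == 2L, all(is.finite(origin)))
  mode(occ) <- "logical"
  structure(list(occ = occ, resolution = as.numeric(resolution),
                 origin = as.numeric(origin)),
            class = "raster_mask")
}

#' @export
print.raster_mask <- function(x, ...) {
  cat(sprintf("<raster_mask> %d x %d cells @ %.3g mm, %d occupied\n",
              nrow(x$occ), ncol(x$occ), x$resolution, sum(x$occ)))
  invisible(x)
}

mask_axes <- function(mask) {
  list(x = mask$origin[1] + (seq_len(nrow(mask$occ)) - 1L) * mask$resolution,
       y = mask$origin[2] + (seq_len(ncol(mask$occ)) - 1L) * mask$resolution)
}

#' Area covered by a mask, in mm^2
#' @param mask A [raster_mask()].
#' @export
mask_area <- function(mask) sum(mask$occ) * mask$resolution^2

#' Rasterize an aperture polygon
#'
#' A cell is occupied iff its center lies inside the polygon under the
#' even-odd rule. The grid covers the polygon's bounding box padded by
#' `pad` (so later margin dilation normally stays on-grid), aligned to
#' integer multiples of the resolution.
#'
#' @param poly An [aperture()].
#' @param resolution Cell size in mm (default 0.25, the margin generator's
#'   working resolution).
#' @param pad Padding in mm around the bounding box; defaults to the
#'   maximum admissible margin of 20 mm.
#' @return A [raster_mask()].
#' @examples
#' m <- rasterize_aperture(aperture_rect(10, 10), resolution = 0.25)
#' sum(m$occ)  # 1600 cells
#' @export
rasterize_aperture <- function(poly, resolution = 0.25, pad = 20) {
  poly <- as_aperture(poly)
  stopifnot(resolution > 0, pad >= 0)
  if (abs(shoelace_area(poly$x_mm, poly$y_mm)) < .Machine$double.eps) {
    warn("zero-area polygon rasterizes to an empty mask")
  }
  i0 <- floor((min(poly$x_mm) - pad) / resolution)
  i1 <- ceiling((max(poly$x_mm) + pad) / resolution)
  j0 <- floor((min(poly$y_mm) - pad) / resolution)
  j1 <- ceiling((max(poly$y_mm) + pad) / resolution)
  xs <- (i0:i1) * resolution
  ys <- (j0:j1) * resolution
  pts <- expand.grid(x = xs, y = ys)
  occ <- matrix(points_in_polygon(poly, pts$x, pts$y),
                nrow = length(xs), ncol = length(ys))
  raster_mask(occ, resolution, origin = c(xs[1], ys[1]))
}

#' Asymmetric dilation-kernel extents
#'
#' Computes the one-dimensional structuring-element extents used to impose
#' a per-side margin on a rasterized segment: `n_minus` cells toward the
#' negative side, one center element, `n_plus` cells toward the positive
#' side. Cell counts are the margins divided by the grid resolution with
#' half-up rounding; e.g. margins of (4, 2) mm at 0.25 mm give extents
#' (16, 1, 8), a 25-element kernel.
#'
#' @param margins_axis Length-2 numeric `(m_minus, m_plus)` in mm, both >= 0.
#' @param resolution Grid resolution in mm.
#' @param max_margin Cap in mm; larger margins are capped with a warning.
#' @return A list with `n_minus`, `n_center` (always 1), `n_plus`, `total`.
#' @export
build_dilation_kernel <- function(margins_axis, resolution, max_margin = 20) {
  m <- as.numeric(margins_axis)
  stopifnot(length(m) == 2L, resolution > 0)
  if (any(!is.finite(m)) || any(m < 0)) abort("margins must be finite and >= 0")
  if (any(m > max_margin)) {
    warn(sprintf("margin capped at max_margin = %g mm", max_margin))
    m <- pmin(m, max_margin)
  }
  half_up <- function(v) floor(v / resolution + 0.5)
  n_minus <- as.integer(half_up(m[1]))
  n_plus <- as.integer(half_up(m[2]))
  list(n_minus = n_minus, n_center = 1L, n_plus = n_plus,
       total = n_minus + 1L + n_plus)
}

# Extend a mask grid by whole cells on each side (lo/hi are c(x, y) counts).
extend_mask <- function(mask, lo = c(0L, 0L), hi = c(0L, 0L)) {
  if (all(lo == 0L) && all(hi == 0L)) return(mask)
  occ <- mask$occ
  nx <- nrow(occ) + lo[1] + hi[1]
  ny <- ncol(occ) + lo[2] + hi[2]
  out <- matrix(FALSE, nx, ny)
  out[lo[1] + seq_len(nrow(occ)), lo[2] + seq_len(ncol(occ))] <- occ
  raster_mask(out, mask$resolution,
              mask$origin - c(lo[1], lo[2]) * mask$resolution)
}

# Separable 1-D binary dilation along the first margin axis via windowed
# prefix sums: out[i] = any(in[i - n_plus .. i + n_minus]).
dilate_axis <- function(occ, n_minus, n_plus, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (n_minus == 0L && n_plus == 0L) return(occ)
  if (axis == "y") return(t(dilate_axis(t(occ), n_minus, n_plus, "x")))
  n <- nrow(occ)
  cs <- apply(occ, 2L, cumsum)          # prefix sums down the x index
  if (!is.matrix(cs)) cs <- matrix(cs, nrow = n)
  cs <- rbind(0, cs)                    # cs[i + 1] = sum(occ[1:i])
  i <- seq_len(n)
  hi <- pmin(i + n_minus, n) + 1L
  lo <- pmax(i - n_plus - 1L, 0L) + 1L
  (cs[hi, , drop = FALSE] - cs[lo, , drop = FALSE]) > 0L
}

#' Dilate a mask by a margin prescription
#'
#' Minkowski dilation with the separable, asymmetric structuring element of
#' [build_dilation_kernel()], applied independently along x and y. The
#' output is always a superset of the input and grows monotonically with
#' each margin component. If the dilation would escape the grid, the grid
#' is extended automatically (with a message).
#'
#' @param mask A [raster_mask()].
#' @param margins A [margin_spec()].
#' @param max_margin Margin cap in mm, passed to [build_dilation_kernel()].
#' @return The dilated [raster_mask()].
#' @export
dilate_mask <- function(mask, margins, max_margin = 20) {
  stopifnot(inherits(mask, "raster_mask"))
  margins <- as_margin_spec(margins)
  kx <- build_dilation_kernel(c(margins[["x_minus"]], margins[["x_plus"]]),
                              mask$resolution, max_margin)
  ky <- build_dilation_kernel(c(margins[["y_minus"]], margins[["y_plus"]]),
                              mask$resolution, max_margin)
  occ <- mask$occ
  idx <- which(occ, arr.ind = TRUE)
  if (nrow(idx) > 0L) {
    need_lo <- c(max(0L, kx$n_minus - (min(idx[, 1]) - 1L)),
                 max(0L, ky$n_minus - (min(idx[, 2]) - 1L)))
    need_hi <- c(max(0L, kx$n_plus - (nrow(occ) - max(idx[, 1]))),
                 max(0L, ky$n_plus - (ncol(occ) - max(idx[, 2]))))
    if (any(need_lo > 0L) || any(need_hi > 0L)) {
      inform("dilation escapes the padded grid; grid extended")
      mask <- extend_mask(mask, need_lo, need_hi)
      occ <- mask$occ
    }
  }
  occ <- dilate_axis(occ, kx$n_minus, kx$n_plus, "x")
  occ <- dilate_axis(occ, ky$n_minus, ky$n_plus, "y")
  raster_mask(occ, mask$resolution, mask$origin)
}

#' Trace the outline of a mask back to a polygon
#'
#' Extracts the outer boundary of the occupied region as a polygon whose
#' vertices lie on the cell-corner lattice, so that
#' `rasterize_aperture(mask_to_polygon(m))` reproduces `m` exactly on the
#' same grid. If the mask contains several 4-connected components the
#' largest is kept (with a warning); interior holes are discarded.
#'
#' @param mask A non-empty [raster_mask()].
#' @param simplify Drop collinear vertices along straight runs?
#' @return An [aperture()].
#' @export
mask_to_polygon <- function(mask, simplify = TRUE) {
  stopifnot(inherits(mask, "raster_mask"))
  occ <- mask$occ
  if (!any(occ)) abort("aperture vanished: mask has no occupied cells")
  nx <- nrow(occ); ny <- ncol(occ)
  pocc <- matrix(FALSE, nx + 2L, ny + 2L)
  pocc[2:(nx + 1L), 2:(ny + 1L)] <- occ
  idx <- which(occ, arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  pi_ <- i + 1L; pj <- j + 1L
  south <- !pocc[cbind(pi_, pj - 1L)]
  north <- !pocc[cbind(pi_, pj + 1L)]
  west  <- !pocc[cbind(pi_ - 1L, pj)]
  east  <- !pocc[cbind(pi_ + 1L, pj)]
  # directed boundary edges on the corner lattice (interior on the left);
  # corner (a, b) sits at origin + (a - 1/2, b - 1/2) * resolution
  e_from_a <- c(i[south] - 1L, i[east],      i[north],      i[west] - 1L)
  e_from_b <- c(j[south] - 1L, j[east] - 1L, j[north],      j[west])
  e_to_a   <- c(i[south],      i[east],      i[north] - 1L, i[west] - 1L)
  e_to_b   <- c(j[south] - 1L, j[east],      j[north],      j[west] - 1L)
  ne <- length(e_from_a)
  key <- function(a, b) a * (ny + 2L) + b
  from_key <- key(e_from_a, e_from_b)
  to_key <- key(e_to_a, e_to_b)
  lookup <- split(seq_len(ne), from_key)
  used <- logical(ne)
  dirs_a <- e_to_a - e_from_a
  dirs_b <- e_to_b - e_from_b
  loops <- list()
  for (start in seq_len(ne)) {
    if (used[start]) next
    cur <- start
    va <- integer(0); vb <- integer(0)
    repeat {
      used[cur] <- TRUE
      va <- c(va, e_from_a[cur]); vb <- c(vb, e_from_b[cur])
      cand <- lookup[[as.character(to_key[cur])]]
      cand <- cand[!used[cand]]
      if (length(cand) == 0L) break
      if (length(cand) > 1L) {
        # at a touching corner prefer the sharpest left turn: keeps each
        # loop tight around its own 4-connected component
        turn <- dirs_a[cur] * dirs_b[cand] - dirs_b[cur] * dirs_a[cand]
        cand <- cand[which.max(turn)]
      } else cand <- cand[1L]
      cur <- cand
    }
    loops[[length(loops) + 1L]] <- list(a = va, b = vb)
  }
  areas <- vapply(loops, function(l) shoelace_area(l$a, l$b), numeric(1))
  outer <- which(areas > 0)
  if (length(outer) > 1L) {
    warn("mask has multiple connected components; largest kept")
  }
  best <- loops[[outer[which.max(areas[outer])]]]
  x <- mask$origin[1] + (best$a - 0.5) * mask$resolution
  y <- mask$origin[2] + (best$b - 0.5) * mask$resolution
  if (simplify) {
    n <- length(x)
    px <- c(x[n], x[-n]); py <- c(y[n], y[-n])
    nx_ <- c(x[-1], x[1]); ny_ <- c(y[-1], y[1])
    keep <- abs((x - px) * (ny_ - py) - (y - py) * (nx_ - px)) > 1e-12
    x <- x[keep]; y <- y[keep]
  }
  aperture(tibble(x_mm = x, y_mm = y), validate = FALSE)
}
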