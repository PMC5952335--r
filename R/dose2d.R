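#' 2-D accumulated dose maps in the target frame
#'
#' A `dose_map` wraps a matrix of relative dose on the same cell lattice
#' convention as [raster_mask()] (x index first, `origin` at cell `[1, 1]`,
#' isotropic `resolution`). Maps are accumulated in the target frame, so a
#' perfectly tracked delivery reproduces the static exposure.
#'
#' @param dose Numeric matrix (x index first).
#' @param resolution Cell size in mm.
#' @param origin Length-2 numeric, mm.
#' @param n_cycles Number of control cycles accumulated.
#' @return An object of class `dose_map`.
#' @export
dose_map <- function(dose, resolution, origin, n_cycles = NA_integer_) {
  stopifnot(is.matrix(dose), resolution > 0, length(origin) == 2L)
  if (any(dose < -1e-9)) abort("dose must be non-negative")
  structure(list(dose = dose, resolution = resolution,
                 origin = as.numeric(origin), n_cycles = n_cycles),
            class = "dose_map")
}

#' @export
print.dose_map <- function(x, ...) {
  cat(sprintf("<dose_map> %d x %d cells @ %.3g mm, max %.3f\n",
              nrow(x$dose), ncol(x$dose), x$resolution, max(x$dose)))
  invisible(x)
}

map_axes <- function(map) {
  list(x = map$origin[1] + (seq_len(nrow(map$dose)) - 1L) * map$resolution,
       y = map$origin[2] + (seq_len(ncol(map$dose)) - 1L) * map$resolution)
}

#' Rotate a 1-D penumbra kernel into its isotropic 2-D form
#'
#' `K2(x, y) = K1(sqrt(x^2 + y^2))` sampled on the map lattice and
#' renormalized to unit integral. For a Gaussian profile kernel this is
#' exactly the separable 2-D Gaussian with the same sigma.
#'
#' @param pgk A `pgk` tibble.
#' @param resolution Target lattice spacing in mm.
#' @return A numeric matrix with odd dimensions, center at offset 0.
#' @export
pgk_to_2d <- function(pgk, resolution = 0.25) {
  r_max <- max(abs(pgk$offset_mm))
  m <- ceiling(r_max / resolution)
  off <- (-m:m) * resolution
  r <- sqrt(outer(off^2, off^2, `+`))
  pos <- pgk$offset_mm >= 0
  w <- approx(pgk$offset_mm[pos], pgk$weight[pos], xout = as.vector(r),
              rule = 1)$y
  w[is.na(w)] <- 0
  k2 <- matrix(w, nrow = length(off))
  k2 / (sum(k2) * resolution^2)
}

# zero-padded linear 2-D convolution via FFT; kernel has odd dims with its
# center at offset zero, so the output stays aligned with `a`
conv2_fft <- function(a, k) {
  na <- dim(a); nk <- dim(k)
  n1 <- stats::nextn(na[1] + nk[1] - 1L, c(2, 3, 5))
  n2 <- stats::nextn(na[2] + nk[2] - 1L, c(2, 3, 5))
  pa <- matrix(0, n1, n2); pa[seq_len(na[1]), seq_len(na[2])] <- a
  pk <- matrix(0, n1, n2); pk[seq_len(nk[1]), seq_len(nk[2])] <- k
  full <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / (n1 * n2)
  c1 <- (nk[1] - 1L) %/% 2L
  c2 <- (nk[2] - 1L) %/% 2L
  full[c1 + seq_len(na[1]), c2 + seq_len(na[2])]
}

#' Accumulate delivered fluence in the target frame
#'
#' Deposits the open-aperture fluence once per control cycle, displaced by
#' the instantaneous tracking error `eps(t) = p_mlc(t) - p_target(t)` and
#' weighted by the cycle duration. Sub-cell displacements are split
#' bilinearly over the four neighboring lattice offsets. If a penumbra
#' kernel is supplied, the accumulated fluence is convolved with its
#' isotropic 2-D form once at the end (exact, by linearity of
#' convolution).
#'
#' @param target,mlc `motion_trace`s on identical time grids. For a static
#'   (or untracked) aperture pass an all-zero `mlc` trace.
#' @param apertures A single [raster_mask()] used for every cycle, or a
#'   list of masks together with `aperture_index` selecting one per cycle.
#' @param aperture_index Integer vector, one entry per cycle.
#' @param pgk Optional `pgk` kernel; `NULL` accumulates raw fluence.
#' @param resolution Map lattice spacing in mm.
#' @param pad Extra padding in mm beyond shapes, displacements and kernel.
#' @return A `dose_map` (unnormalized; see [normalize_map()]). The
#'   attribute `expected_integral` records `sum(cycle_dt * open_area)` for
#'   conservation checks.
#' @export
accumulate_dose <- function(target, mlc, apertures, aperture_index = NULL,
                            pgk = NULL, resolution = 0.25, pad = 2) {
  if (nrow(target) != nrow(mlc) || max(abs(target$t_s - mlc$t_s)) > 1e-9) {
    abort("target and MLC traces must share one time grid")
  }
  if (inherits(apertures, "raster_mask")) apertures <- list(apertures)
  stopifnot(all(vapply(apertures, inherits, logical(1), "raster_mask")))
  n_cyc <- nrow(target) - 1L  # dose deposited per completed cycle
  if (is.null(aperture_index)) aperture_index <- rep(1L, n_cyc)
  stopifnot(length(aperture_index) == n_cyc)
  dt <- diff(target$t_s)
  ex <- mlc$x_mm[-1] - target$x_mm[-1]
  ey <- mlc$y_mm[-1] - target$y_mm[-1]

  # shape bounding boxes in lattice units (origins are lattice-aligned)
  shp <- lapply(apertures, function(a) {
    stopifnot(abs(a$resolution - resolution) < 1e-9)
    idx <- which(a$occ, arr.ind = TRUE)
    if (nrow(idx) == 0L) abort("empty aperture mask in accumulation")
    i0 <- min(idx[, 1]); i1 <- max(idx[, 1])
    j0 <- min(idx[, 2]); j1 <- max(idx[, 2])
    list(m = a$occ[i0:i1, j0:j1, drop = FALSE] + 0,
         gi = round(a$origin[1] / resolution) + i0 - 1L,  # lattice coords
         gj = round(a$origin[2] / resolution) + j0 - 1L)
  })
  kr <- if (is.null(pgk)) 0 else ceiling(max(abs(pgk$offset_mm)) / resolution)
  gi_lo <- min(vapply(shp, `[[`, numeric(1), "gi")) +
    floor(min(ex, 0) / resolution) - kr - ceiling(pad / resolution)
  gi_hi <- max(vapply(shp, function(s) s$gi + nrow(s$m) - 1L, numeric(1))) +
    ceiling(max(ex, 0) / resolution) + kr + ceiling(pad / resolution)
  gj_lo <- min(vapply(shp, `[[`, numeric(1), "gj")) +
    floor(min(ey, 0) / resolution) - kr - ceiling(pad / resolution)
  gj_hi <- max(vapply(shp, function(s) s$gj + ncol(s$m) - 1L, numeric(1))) +
    ceiling(max(ey, 0) / resolution) + kr + ceiling(pad / resolution)
  nx <- gi_hi - gi_lo + 1L; ny <- gj_hi - gj_lo + 1L
  acc <- matrix(0, nx, ny)
  expected <- 0
  for (k in seq_len(n_cyc)) {
    s <- shp[[aperture_index[k]]]
    sx <- ex[k] / resolution; sy <- ey[k] / resolution
    ix <- floor(sx); fx <- sx - ix
    jy <- floor(sy); fy <- sy - jy
    r0 <- s$gi + ix - gi_lo + 1L
    c0 <- s$gj + jy - gj_lo + 1L
    nr <- nrow(s$m); nc <- ncol(s$m)
    wdt <- dt[k]
    for (q in 1:4) {
      dr <- (q - 1L) %%  2L
      dc <- (q - 1L) %/% 2L
      w <- (if (dr) fx else 1 - fx) * (if (dc) fy else 1 - fy)
      if (w == 0) next
      acc[(r0 + dr):(r0 + dr + nr - 1L), (c0 + dc):(c0 + dc + nc - 1L)] <-
        acc[(r0 + dr):(r0 + dr + nr - 1L), (c0 + dc):(c0 + dc + nc - 1L)] +
        (w * wdt) * s$m
    }
    expected <- expected + wdt * sum(s$m)
  }
  if (!is.null(pgk)) {
    # kernel is a continuous density (unit integral): include the cell area
    acc <- pmax(conv2_fft(acc, pgk_to_2d(pgk, resolution)) * resolution^2, 0)
  }
  out <- dose_map(acc, resolution,
                  origin = c(gi_lo, gj_lo) * resolution, n_cycles = n_cyc)
  attr(out, "expected_integral") <- expected * resolution^2
  out
}

#' Normalize a map to the central plateau of a reference exposure
#'
#' Doses are referenced to the mean over a square region (default
#' 15 x 15 mm^2) centered on the isocenter of the reference map (the
#' static exposure).
#'
#' @param map A `dose_map`.
#' @param reference The static reference `dose_map` (defaults to `map`).
#' @param region_mm Side length of the normalization square in mm.
#' @return The normalized `dose_map`; the divisor is stored in the
#'   `norm_value` attribute.
#' @export
normalize_map <- function(map, reference = map, region_mm = 15) {
  ax <- map_axes(reference)
  sel_x <- abs(ax$x) <= region_mm / 2
  sel_y <- abs(ax$y) <= region_mm / 2
  if (!any(sel_x) || !any(sel_y)) abort("normalization region off the map")
  norm <- mean(reference$dose[sel_x, sel_y])
  if (norm <= 0) abort("reference plateau has zero dose")
  out <- map
  out$dose <- map$dose / norm
  attr(out, "norm_value") <- norm
  out
}

#' Extract a 1-D profile through a dose map
#'
#' @param map A `dose_map`.
#' @param axis `"x"` (profile along x through `at` in y) or `"y"`.
#' @param at Perpendicular coordinate of the cut in mm (nearest lattice
#'   line is used).
#' @return A `dose_profile`.
#' @export
map_profile <- function(map, axis = c("x", "y"), at = 0) {
  axis <- match.arg(axis)
  ax <- map_axes(map)
  if (axis == "x") {
    j <- which.min(abs(ax$y - at))
    dose_profile(ax$x, map$dose[, j], kind = "static_real")
  } else {
    i <- which.min(abs(ax$x - at))
    dose_profile(ax$y, map$dose[i, ], kind = "static_real")
  }
}

#' Threshold region of a reference map
#'
#' Logical cell mask selecting `lower < dose < upper` on a reference map;
#' e.g. the shoulder band `0.9 < D < 0.97` or the plateau `D > 0.9`.
#'
#' @param reference A normalized `dose_map`.
#' @param lower,upper Relative dose bounds (strict).
#' @return Logical matrix.
#' @export
region_threshold <- function(reference, lower, upper = Inf) {
  reference$dose > lower & reference$dose < upper
}

#' Dose-area histogram over a region
#'
#' For each dose level, the fraction of the region's area receiving at
#' least that dose; `A90` is the fraction receiving more than 0.9 of the
#' reference dose.
#'
#' @param map A normalized `dose_map`.
#' @param region Logical matrix (same dimensions), e.g. from
#'   [region_threshold()].
#' @param levels Relative dose levels.
#' @return A tibble of class `dah_result` with columns `level`,
#'   `area_fraction` and attribute `a90`.
#' @export
dah <- function(map, region, levels = seq(0, 1.2, by = 0.01)) {
  stopifnot(is.logical(region), all(dim(region) == dim(map$dose)))
  if (!any(region)) abort("empty evaluation region")
  d <- map$dose[region]
  out <- tibble(level = levels,
                area_fraction = vapply(levels, function(l) mean(d >= l),
                                       numeric(1)))
  attr(out, "a90") <- mean(d > 0.9)
  class(out) <- c("dah_result", class(out))
  out
}

#' @rdname dah
#' @param x A `dah_result`.
#' @export
a90 <- function(x) {
  stopifnot(inherits(x, "dah_result"))
  attr(x, "a90")
}

#' Does one iso-dose region enclose another?
#'
#' Checks that every cell of the inner region lies in the outer region,
#' allowing a tolerance of `tol_cells` lattice cells (rasterized contours
#' are only defined to one cell).
#'
#' @param outer,inner Logical matrices of equal dimension.
#' @param tol_cells Dilation tolerance applied to `outer`, in cells.
#' @return `TRUE`/`FALSE`.
#' @export
encloses_region <- function(outer, inner, tol_cells = 1L) {
  stopifnot(all(dim(outer) == dim(inner)))
  if (tol_cells > 0L) {
    outer <- dilate_axis(outer, tol_cells, tol_cells, "x")
    outer <- dilate_axis(outer, tol_cells, tol_cells, "y")
  }
  !any(inner & !outer)
}
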