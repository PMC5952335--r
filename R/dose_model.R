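#' One-dimensional relative dose profiles
#'
#' A dose profile is a tibble with columns `x_mm` (uniform grid) and `dose`
#' (relative units, plateau approximately 1). The `kind` attribute records
#' what it represents: an exact `{0,1}` block (`"ideal"`), the penumbra-
#' blurred static model (`"static_real"`), a measurement (`"measured"`),
#' or an error-degraded profile (`"degraded"`).
#'
#' @param x_mm Uniformly spaced positions in mm.
#' @param dose Non-negative relative dose values.
#' @param kind Profile kind tag.
#' @return A tibble of class `dose_profile`.
#' @export
dose_profile <- function(x_mm, dose,
                         kind = c("ideal", "static_real", "measured", "degraded")) {
  kind <- match.arg(kind)
  x_mm <- as.numeric(x_mm); dose <- as.numeric(dose)
  stopifnot(length(x_mm) == length(dose), length(x_mm) >= 2L)
  dx <- diff(x_mm)
  if (any(abs(dx - dx[1]) > 1e-9 * abs(dx[1]))) abort("profile grid must be uniform")
  if (any(!is.finite(dose)) || any(dose < -1e-12)) abort("dose must be finite and >= 0")
  out <- tibble(x_mm = x_mm, dose = pmax(dose, 0))
  attr(out, "spacing") <- dx[1]
  attr(out, "kind") <- kind
  class(out) <- c("dose_profile", class(out))
  out
}

profile_spacing <- function(p) attr(p, "spacing") %||% diff(p$x_mm[1:2])

#' Ideal rectangular (block) dose profile
#'
#' Cell-center sampled indicator of the field `[-width/2, width/2]` on a
#' symmetric grid spanning `span`. The span must leave room for the
#' penumbra on both sides, otherwise edge wrap-around would corrupt the
#' Fourier deconvolution in [estimate_pgk()].
#'
#' @param field_width Field width in mm (e.g. 100 for the 10x10 cm
#'   calibration field).
#' @param grid Grid spacing in mm.
#' @param span Total profile span in mm; default leaves 8 expected
#'   penumbra sigmas per side.
#' @param expected_penumbra Penumbra scale used for the span check, mm.
#' @return A `dose_profile` of kind `"ideal"` with dose exactly in `{0, 1}`.
#' @export
ideal_block <- function(field_width, grid = 0.25,
                        span = field_width + 16 * expected_penumbra,
                        expected_penumbra = 5) {
  stopifnot(field_width > 0, grid > 0)
  if (span <= field_width + 8 * expected_penumbra) {
    abort("span too small: edge effects would corrupt the deconvolution")
  }
  n <- 2L * ceiling(span / (2 * grid))  # even count, half-offset centers
  x <- (seq_len(n) - 0.5 - n / 2) * grid
  dose_profile(x, as.numeric(abs(x) < field_width / 2), kind = "ideal")
}

#' Estimate the penumbra-generating kernel by regularized deconvolution
#'
#' Deconvolves a measured static profile with the ideal block profile in
#' the Fourier domain. The block's spectrum has near-zeros; those are
#' conditioned with a waterlevel: denominator bins with magnitude below
#' `waterlevel * max(|spectrum|)` are raised to that floor (phase
#' preserved), and — because the floored ratio is arbitrary there — the
#' kernel spectrum is repaired across the flagged bins by linear
#' interpolation from the reliable neighbors (the physical kernel is
#' compact, so its spectrum is smooth). A mild Gaussian apodization
#' (default 0.5 mm) suppresses noise amplification at high frequencies;
#' its variance contribution is recorded and removed again by [pgk_sd()].
#' The raw kernel is then centered, trimmed to its contiguous support
#' above `trim * max(weight)`, clipped to non-negative weights,
#' symmetrized by averaging with its mirror (the physical kernel is
#' radially symmetric), and renormalized to unit integral.
#'
#' @param measured A `dose_profile` (plateau normalized to 1).
#' @param ideal The matching ideal block profile (same grid).
#' @param waterlevel Regularization floor as a fraction of the peak
#'   denominator magnitude, in (0, 1). Default `1e-3`.
#' @param trim Support-trim threshold as a fraction of the peak weight.
#' @param apodization SD (mm) of the Gaussian low-pass applied to the
#'   estimate; 0 disables it.
#' @return A tibble of class `pgk` with columns `offset_mm`, `weight`
#'   (unit integral: `sum(weight) * spacing == 1`).
#' @export
estimate_pgk <- function(measured, ideal, waterlevel = 1e-3, trim = 1e-3,
                         apodization = 0.5) {
  if (!(waterlevel > 0 && waterlevel < 1)) abort("waterlevel must be in (0, 1)")
  if (nrow(measured) != nrow(ideal) ||
      max(abs(measured$x_mm - ideal$x_mm)) > 1e-9) {
    abort("measured and ideal profiles must share one grid")
  }
  dx <- profile_spacing(ideal)
  fm <- fft(measured$dose)
  fi <- fft(ideal$dose)
  n <- length(fm)
  mag <- Mod(fi)
  floor_mag <- waterlevel * max(mag)
  low <- mag < floor_mag
  fi[low] <- ifelse(mag[low] > 0,
                    fi[low] * (floor_mag / mag[low]),
                    complex(real = floor_mag))
  fk <- fm / fi
  if (any(low) && any(!low)) {
    idx <- seq_len(n)
    fk <- complex(
      real = approx(idx[!low], Re(fk[!low]), xout = idx, rule = 2)$y,
      imaginary = approx(idx[!low], Im(fk[!low]), xout = idx, rule = 2)$y)
  }
  if (apodization > 0) {
    f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * dx)
    fk <- fk * exp(-2 * pi^2 * apodization^2 * f^2)
  }
  k <- Re(fft(fk, inverse = TRUE)) / n
  # unwrap the cyclic kernel so offset 0 sits at the center
  half <- n %/% 2
  k <- c(k[(half + 1L):n], k[1:half])
  offsets <- (seq_len(n) - half - 1L) * dx
  # contiguous support around the peak
  peak <- which.max(k)
  thr <- trim * k[peak]
  lo <- peak
  while (lo > 1L && k[lo - 1L] > thr) lo <- lo - 1L
  hi <- peak
  while (hi < n && k[hi + 1L] > thr) hi <- hi + 1L
  r <- max(abs(offsets[lo]), abs(offsets[hi]))
  keep <- abs(offsets) <= r + dx / 2
  k <- pmax(k[keep], 0)
  offsets <- offsets[keep]
  k <- (k + rev(k)) / 2  # symmetric grid, symmetrize
  k <- k / (sum(k) * dx)
  out <- tibble(offset_mm = offsets, weight = k)
  attr(out, "spacing") <- dx
  attr(out, "waterlevel") <- waterlevel
  attr(out, "apodization") <- apodization
  class(out) <- c("pgk", class(out))
  out
}

#' Synthetic Gaussian penumbra kernel
#'
#' @param sigma Penumbra standard deviation in mm.
#' @param grid Grid spacing in mm.
#' @param radius Kernel half-width in mm (default 5 sigma).
#' @return A `pgk` tibble with unit integral.
#' @export
pgk_gaussian <- function(sigma, grid = 0.25, radius = 5 * sigma) {
  stopifnot(sigma > 0, grid > 0)
  m <- ceiling(radius / grid)
  offsets <- (-m:m) * grid
  w <- dnorm(offsets, 0, sigma)
  w <- w / (sum(w) * grid)
  out <- tibble(offset_mm = offsets, weight = w)
  attr(out, "spacing") <- grid
  class(out) <- c("pgk", class(out))
  out
}

#' Standard deviation of a penumbra kernel
#'
#' Second-moment SD of the kernel weights. For kernels estimated with a
#' Gaussian apodization the known apodization variance is subtracted, so
#' the value estimates the SD of the underlying physical kernel.
#'
#' @param pgk A `pgk` tibble.
#' @export
pgk_sd <- function(pgk) {
  w <- pgk$weight / sum(pgk$weight)
  mu <- sum(w * pgk$offset_mm)
  v <- sum(w * (pgk$offset_mm - mu)^2)
  apo <- attr(pgk, "apodization") %||% 0
  sqrt(max(v - apo^2, 0))
}

#' @export
glance.pgk <- function(x, ...) {
  tibble(n = nrow(x), spacing_mm = attr(x, "spacing"),
         sd_mm = pgk_sd(x),
         waterlevel = attr(x, "waterlevel") %||% NA_real_)
}

#' Convolve a profile with a kernel (profile-domain, zero-padded)
#'
#' Used both to build the blurred static reference from an ideal block and
#' to degrade a reference by an error density (Eq.-style
#' `D_dyn(x) = integral p(s) D_ref(x - s) ds`): a pure positive error
#' (aperture displaced toward +x in the target frame) moves dose toward +x.
#'
#' @param ref A `dose_profile`.
#' @param offsets,weights Kernel sample offsets (mm) and values (1/mm);
#'   offsets need not be aligned to the profile grid (they are resampled).
#' @param kind Kind tag for the result.
#' @return A `dose_profile` on the same grid as `ref`.
#' @keywords internal
convolve_profile <- function(ref, offsets, weights, kind = "degraded") {
  dx <- profile_spacing(ref)
  k0 <- floor(min(offsets) / dx)
  k1 <- ceiling(max(offsets) / dx)
  ks <- k0:k1
  w <- approx(offsets, weights, xout = ks * dx, rule = 1)$y
  w[is.na(w)] <- 0
  if (sum(w) <= 0) abort("kernel has no mass on the profile grid")
  w <- w / (sum(w) * dx)  # renormalize after resampling
  n <- nrow(ref)
  dose <- numeric(n)
  idx <- seq_len(n)
  for (m in seq_along(ks)) {
    src <- idx - ks[m]
    ok <- src >= 1L & src <= n
    dose[ok] <- dose[ok] + w[m] * dx * ref$dose[src[ok]]
  }
  dose_profile(ref$x_mm, dose, kind = kind)
}

#' Degrade a reference profile by a tracking-error density
#'
#' Convolves the static reference dose with the per-axis error density:
#' the expected dose under randomly displaced exposures. Integral dose is
#' conserved (the density is renormalized on the profile grid).
#'
#' @param ref A `dose_profile` (the static reference, penumbra included).
#' @param density An `error_density` from [estimate_density()], or any
#'   data frame with `x_mm` and `density` columns.
#' @return A `dose_profile` of kind `"degraded"`.
#' @export
degrade_profile <- function(ref, density) {
  if (!all(c("x_mm", "density") %in% names(density))) {
    abort("density needs columns x_mm and density")
  }
  if (profile_spacing(ref) > 1.01 * min(diff(density$x_mm))) {
    # finer density than profile: resampling in convolve_profile handles it
  } else if (profile_spacing(ref) < 0.99 * min(diff(density$x_mm))) {
    inform("density grid coarser than profile grid; resampling density")
  }
  convolve_profile(ref, density$x_mm, density$density, kind = "degraded")
}

# Outermost crossing of `level` on one side of the field: for the plus
# side, the largest x where dose passes downward through the level; for
# the minus side, the smallest x passing upward. Linear interpolation
# between grid points. Returns NA when the profile never reaches level.
crossing_position <- function(x, dose, level, side) {
  n <- length(dose)
  if (max(dose) < level) return(NA_real_)
  if (side == "plus") {
    i <- which(dose[-n] >= level & dose[-1] < level)
    if (length(i) == 0L) return(NA_real_)
    i <- max(i)
  } else {
    i <- which(dose[-n] < level & dose[-1] >= level)
    if (length(i) == 0L) return(NA_real_)
    i <- min(i)
  }
  x[i] + (level - dose[i]) / (dose[i + 1L] - dose[i]) * (x[i + 1L] - x[i])
}

#' Extract the per-side tracking margin at a confidence level
#'
#' Solves for the geometric distance between the confidence-level crossings
#' of the static reference and the degraded profile on one side of the
#' field. The margin is the inward retreat of the degraded shoulder: on the
#' plus side `max(0, x_ref - x_dyn)`, on the minus side
#' `max(0, x_dyn - x_ref)` (outermost crossings, linearly interpolated).
#' A shoulder pushed outward (local overdose) clamps to zero; a degraded
#' profile that never reaches the level at all saturates to `max_margin`
#' with attribute `saturated = TRUE`.
#'
#' @param ref,dyn Static reference and degraded `dose_profile`s.
#' @param level Confidence level in (0, 1), default 0.9: the fraction of
#'   reference dose the margin should restore at the field edge.
#' @param side `"plus"` or `"minus"`.
#' @param max_margin Saturation cap in mm.
#' @return Margin in mm (>= 0).
#' @export
extract_margin <- function(ref, dyn, level = 0.9, side = c("plus", "minus"),
                           max_margin = 20) {
  side <- match.arg(side)
  if (!(level > 0 && level < 1)) abort("confidence level must be in (0, 1)")
  if (max(ref$dose) < level) abort("reference profile has no plateau above the level")
  x_ref <- crossing_position(ref$x_mm, ref$dose, level, side)
  if (is.na(x_ref)) abort("reference profile does not cross the level on this side")
  x_dyn <- crossing_position(dyn$x_mm, dyn$dose, level, side)
  if (is.na(x_dyn)) {
    warn("degraded profile never reaches the confidence level; margin saturated")
    return(structure(max_margin, saturated = TRUE))
  }
  m <- if (side == "plus") x_ref - x_dyn else x_dyn - x_ref
  max(0, m)
}

#' Per-axis margins from the current error state
#'
#' Degrades each axis's static reference profile with that axis's error
#' density and solves both shoulders, yielding the four-component margin
#' prescription. When a density is unavailable (warm-up), margins stay at
#' zero and the result carries `warmup = TRUE`.
#'
#' @param density_x,density_y `error_density` objects (or `NULL` during
#'   warm-up).
#' @param ref_x,ref_y Static reference `dose_profile`s along x and y.
#' @param level Confidence level in (0, 1).
#' @param max_margin Cap in mm.
#' @return A [margin_spec()]; attribute `warmup` is `TRUE` when margins
#'   were suspended.
#' @export
margins_from_state <- function(density_x, density_y, ref_x, ref_y,
                               level = 0.9, max_margin = 20) {
  if (is.null(density_x) || is.null(density_y)) {
    m <- margin_spec()
    attr(m, "warmup") <- TRUE
    return(m)
  }
  dyn_x <- degrade_profile(ref_x, density_x)
  dyn_y <- degrade_profile(ref_y, density_y)
  m <- margin_spec(
    x_plus = min(extract_margin(ref_x, dyn_x, level, "plus", max_margin), max_margin),
    x_minus = min(extract_margin(ref_x, dyn_x, level, "minus", max_margin), max_margin),
    y_plus = min(extract_margin(ref_y, dyn_y, level, "plus", max_margin), max_margin),
    y_minus = min(extract_margin(ref_y, dyn_y, level, "minus", max_margin), max_margin)
  )
  attr(m, "warmup") <- FALSE
  m
}
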