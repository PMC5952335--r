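#' Timestamped 2-D motion traces
#'
#' A motion trace is a tibble with columns `t_s` (strictly increasing
#' timestamps, s), `x_mm` and `y_mm` (BEV displacements). The `role`
#' attribute tags what the positions are: the true target (`"target"`),
#' the delayed sensed feedback (`"sensed"`), or the aperture
#' center-of-gravity realized by the MLC (`"mlc"`). A `z_mm` column, if
#' present, is dropped with a warning: tracking is in the BEV only.
#'
#' @param samples Data frame with `t_s`, `x_mm`, `y_mm`.
#' @param role One of `"target"`, `"sensed"`, `"mlc"`.
#' @param delta_t_sense,delta_t_mlc Latency metadata in s (optional).
#' @return A tibble of class `motion_trace`.
#' @export
motion_trace <- function(samples, role = c("target", "sensed", "mlc"),
                         delta_t_sense = NA_real_, delta_t_mlc = NA_real_) {
  role <- match.arg(role)
  s <- as_tibble(as.data.frame(samples))
  if ("z_mm" %in% names(s)) {
    warn("z_mm ignored: tracking is restricted to the BEV plane")
    s$z_mm <- NULL
  }
  if (!all(c("t_s", "x_mm", "y_mm") %in% names(s))) {
    abort("motion trace needs columns t_s, x_mm, y_mm")
  }
  s <- s[c("t_s", "x_mm", "y_mm")]
  if (any(!is.finite(as.matrix(s)))) abort("motion trace values must be finite")
  if (any(diff(s$t_s) <= 0)) abort("timestamps must be strictly increasing")
  attr(s, "role") <- role
  attr(s, "delta_t_sense") <- delta_t_sense
  attr(s, "delta_t_mlc") <- delta_t_mlc
  class(s) <- c("motion_trace", class(s))
  s
}

# Linear interpolation of a trace at arbitrary times (rule = 2 clamps to
# the end values, used only for sub-sample look-backs at the trace edges).
interp_trace <- function(trace, t) {
  list(x = approx(trace$t_s, trace$x_mm, xout = t, rule = 2)$y,
       y = approx(trace$t_s, trace$y_mm, xout = t, rule = 2)$y)
}

#' Causal tracking-error estimate at one control cycle
#'
#' The sensing chain delivers target positions `delta_t_sense` seconds
#' late, so at wall-clock time `t_prime` the freshest sensed sample
#' describes the target at `t_prime - delta_t_sense`. The causal error
#' estimate therefore compares a looked-back MLC position with the current
#' sensed sample, per axis:
#' `eps(t_prime - delta_t_sense) = p_mlc(t_prime - delta_t_sense) - p_sense(t_prime)`.
#' The MLC trace is linearly interpolated at the look-back time.
#'
#' @param mlc A `motion_trace` of realized MLC COG positions.
#' @param sensed A `motion_trace` of sensed (delayed) target positions.
#' @param delta_t_sense Sensing latency in s (>= 0).
#' @param t_prime Current time in s.
#' @return Named numeric `c(x = , y = )` in mm, or `NULL` when either trace
#'   does not yet cover the look-back window (the caller skips the cycle).
#' @export
compute_tracking_error <- function(mlc, sensed, delta_t_sense, t_prime) {
  stopifnot(delta_t_sense >= 0)
  t_back <- t_prime - delta_t_sense
  if (t_back < min(mlc$t_s) || t_prime > max(mlc$t_s) + 1e-9 ||
      t_prime < min(sensed$t_s) || t_prime > max(sensed$t_s) + 1e-9) {
    return(NULL)
  }
  pm <- interp_trace(mlc, t_back)
  ps <- interp_trace(sensed, t_prime)
  c(x = pm$x - ps$x, y = pm$y - ps$y)
}

#' Cyclic FIFO buffer of tracking-error samples
#'
#' Holds the most recent `capacity` per-axis error samples; at the default
#' capacity of 500 and the 40 ms control cycle the buffer spans the past
#' 20 s of delivery. Eviction is strictly oldest-first.
#'
#' @param capacity Maximum number of retained samples (default 500).
#' @param cycle Control-system cycle period in s (default 0.040).
#' @return A list of class `error_buffer` with numeric vectors `t`, `x`, `y`.
#' @export
error_buffer <- function(capacity = 500L, cycle = 0.040) {
  stopifnot(capacity >= 1L, cycle > 0)
  structure(list(capacity = as.integer(capacity), cycle = cycle,
                 t = numeric(0), x = numeric(0), y = numeric(0)),
            class = "error_buffer")
}

#' @export
print.error_buffer <- function(x, ...) {
  cat(sprintf("<error_buffer> %d/%d samples, span %.1f s\n",
              length(x$t), x$capacity, x$capacity * x$cycle))
  invisible(x)
}

#' Push one error sample into the buffer
#'
#' @param buffer An [error_buffer()].
#' @param t Timestamp in s.
#' @param eps Named or positional numeric `c(x, y)` error in mm.
#' @return The updated buffer. Non-finite samples are rejected with a
#'   warning and leave the buffer unchanged.
#' @export
push_error <- function(buffer, t, eps) {
  stopifnot(inherits(buffer, "error_buffer"))
  eps <- as.numeric(eps)
  if (length(eps) != 2L || !all(is.finite(eps)) || !is.finite(t)) {
    warn("non-finite error sample rejected")
    return(buffer)
  }
  buffer$t <- c(buffer$t, t)
  buffer$x <- c(buffer$x, eps[1])
  buffer$y <- c(buffer$y, eps[2])
  if (length(buffer$t) > buffer$capacity) {
    keep <- seq.int(length(buffer$t) - buffer$capacity + 1L, length(buffer$t))
    buffer$t <- buffer$t[keep]; buffer$x <- buffer$x[keep]; buffer$y <- buffer$y[keep]
  }
  buffer
}

#' Rule-of-thumb Gaussian KDE bandwidth
#'
#' One-dimensional normal-reference rule
#' `sigma = s * (4 / (3 N))^(1/5)` with `s` the sample standard deviation.
#' With fewer than two distinct samples (zero variance) the bandwidth falls
#' back to the raster resolution of 0.25 mm, with a message.
#'
#' @param samples Numeric vector of error samples (mm).
#' @param fallback Bandwidth used for degenerate samples (mm).
#' @return Bandwidth sigma in mm.
#' @examples
#' kde_bandwidth(rnorm(500))  # about (4/1500)^0.2 for unit-SD samples
#' @export
kde_bandwidth <- function(samples, fallback = 0.25) {
  samples <- as.numeric(samples)
  n <- length(samples)
  s <- if (n >= 2L) sd(samples) else 0
  if (n < 2L || s == 0) {
    inform("degenerate samples; falling back to the raster resolution bandwidth")
    return(fallback)
  }
  s * (4 / (3 * n))^(1 / 5)
}

#' Gaussian kernel density of buffered tracking errors
#'
#' Evaluates the density as the mean of zero-mean Gaussian kernels centered
#' on each buffered sample, on a uniform grid spanning the samples plus
#' 4 bandwidths on either side at 0.05 mm spacing, and renormalizes it to
#' unit numerical integral (so that the downstream dose degradation
#' conserves integral dose).
#'
#' @param buffer An [error_buffer()] (or a bare numeric vector of samples).
#' @param axis `"x"` or `"y"`; which per-axis store to use.
#' @param warmup Minimum number of samples before a density is available;
#'   below it the margin generator stays suspended (an error is raised).
#' @param grid_step Evaluation-grid spacing in mm.
#' @return A tibble of class `error_density` with columns `x_mm`,
#'   `density`, and attributes `bandwidth`, `n`, `axis`.
#' @export
estimate_density <- function(buffer, axis = c("x", "y"), warmup = 50L,
                             grid_step = 0.05) {
  axis <- match.arg(axis)
  samples <- if (inherits(buffer, "error_buffer")) buffer[[axis]] else as.numeric(buffer)
  if (length(samples) < warmup) {
    abort(sprintf("only %d error samples buffered (warm-up needs %d)",
                  length(samples), warmup), class = "trackmargin_warmup")
  }
  sigma <- kde_bandwidth(samples)
  lo <- min(samples) - 4 * sigma
  hi <- max(samples) + 4 * sigma
  grid <- seq(floor(lo / grid_step) * grid_step,
              ceiling(hi / grid_step) * grid_step, by = grid_step)
  dens <- rowMeans(outer(grid, samples, function(g, s) dnorm(g, s, sigma)))
  integral <- trapz_integral(grid, dens)
  dens <- dens / integral
  out <- tibble(x_mm = grid, density = dens)
  attr(out, "bandwidth") <- sigma
  attr(out, "n") <- length(samples)
  attr(out, "axis") <- axis
  class(out) <- c("error_density", class(out))
  out
}

#' Empirical (binned) error density
#'
#' Linear-binned histogram of error samples on a uniform grid, normalized
#' to unit integral — the model-free counterpart of [estimate_density()],
#' used e.g. to check the dose model against a simulated delivery.
#'
#' @param samples Numeric error samples (mm).
#' @param spacing Bin/grid spacing in mm.
#' @return A tibble of class `error_density` (`x_mm`, `density`).
#' @export
error_histogram_density <- function(samples, spacing = 0.25) {
  samples <- samples[is.finite(samples)]
  stopifnot(length(samples) >= 1L, spacing > 0)
  k0 <- floor(min(samples) / spacing) - 1L
  k1 <- ceiling(max(samples) / spacing) + 1L
  w <- numeric(k1 - k0 + 1L)
  pos <- samples / spacing - k0
  i <- floor(pos); f <- pos - i
  for (m in seq_along(samples)) {   # linear-split binning
    w[i[m] + 1L] <- w[i[m] + 1L] + (1 - f[m])
    w[i[m] + 2L] <- w[i[m] + 2L] + f[m]
  }
  grid <- (k0:k1) * spacing
  dens <- w / (sum(w) * spacing)
  out <- tibble(x_mm = grid, density = dens)
  attr(out, "n") <- length(samples)
  attr(out, "axis") <- NA_character_
  class(out) <- c("error_density", class(out))
  out
}

trapz_integral <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' @export
glance.error_density <- function(x, ...) {
  tibble(axis = attr(x, "axis"), n = attr(x, "n"),
         bandwidth_mm = attr(x, "bandwidth"),
         mean_mm = trapz_integral(x$x_mm, x$x_mm * x$density),
         mode_mm = x$x_mm[which.max(x$density)])
}
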