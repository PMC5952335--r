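#' Breathing-motion generator parameters
#'
#' Parameterizes a liver-dome-like motion surrogate: a cyclic waveform with
#' a rest phase at end-exhale, per-cycle random variation of amplitude and
#' period, a slow baseline drift, and a small cardiac ripple. The scalar
#' surrogate is mapped onto the BEV axes by `axis_mix` (normalized to unit
#' length), mimicking the oblique principal axis of diaphragm motion.
#'
#' Two presets bracket the breathing classes seen in volunteer data:
#' `breathing_preset("v1")` is regular, sleep-like breathing (5% cycle
#' variability); `breathing_preset("v2")` is irregular in amplitude and
#' frequency (30% variability).
#'
#' @param amplitude Surrogate amplitude in mm (half peak-to-peak).
#' @param period Mean breathing period in s.
#' @param variability Fractional SD of per-cycle amplitude and period.
#' @param drift Baseline drift in mm/min.
#' @param cardiac_amplitude,cardiac_rate Cardiac ripple amplitude (mm) and
#'   rate (Hz).
#' @param axis_mix Length-2 vector mapping the surrogate onto (x, y).
#' @param seed Integer seed for reproducible traces.
#' @return A list of class `breathing_params`.
#' @export
breathing_params <- function(amplitude = 6.5, period = 4, variability = 0.05,
                             drift = 0.2, cardiac_amplitude = 0.4,
                             cardiac_rate = 1.1, axis_mix = c(0.96, 0.28),
                             seed = 1L) {
  stopifnot(amplitude >= 0, period > 0, variability >= 0, cardiac_rate > 0,
            length(axis_mix) == 2L, any(axis_mix != 0))
  structure(list(
    amplitude = amplitude, period = period, variability = variability,
    drift = drift, cardiac_amplitude = cardiac_amplitude,
    cardiac_rate = cardiac_rate,
    axis_mix = axis_mix / sqrt(sum(axis_mix^2)),
    seed = as.integer(seed)
  ), class = "breathing_params")
}

#' @rdname breathing_params
#' @param preset `"v1"` (regular) or `"v2"` (irregular).
#' @param ... Overrides passed on to [breathing_params()].
#' @export
breathing_preset <- function(preset = c("v1", "v2"), ...) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    v1 = list(amplitude = 6.5, period = 4.0, variability = 0.05),
    v2 = list(amplitude = 7.0, period = 3.3, variability = 0.30)
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(breathing_params, args)
}

#' Virtual machine and control-loop parameters
#'
#' @param cycle Control-system cycle in s (40 ms).
#' @param delta_t_sense Sensing-chain latency in s (default 0.300, the
#'   imposed imaging latency).
#' @param mlc_lag First-order electromechanical lag time constant in s.
#' @param rate_limit Maximum COG speed in mm/s.
#' @param quantization COG quantization step in mm (0 disables; aperture
#'   discretization normally enters through leaf fitting instead).
#' @return A list of class `machine_params`.
#' @export
machine_params <- function(cycle = 0.040, delta_t_sense = 0.300,
                           mlc_lag = 0.080, rate_limit = 25,
                           quantization = 0) {
  stopifnot(cycle > 0, delta_t_sense >= 0, mlc_lag >= 0, rate_limit > 0,
            quantization >= 0)
  structure(list(cycle = cycle, delta_t_sense = delta_t_sense,
                 mlc_lag = mlc_lag, rate_limit = rate_limit,
                 quantization = quantization),
            class = "machine_params")
}

#' Synthesize a target motion trace
#'
#' Generates the surrogate at the native sampling interval (default 0.1 s,
#' emulating a 10 Hz imaging chain), then linearly upsamples to the control
#' cycle. Each breathing cycle draws its own amplitude and period; the
#' waveform `A * (2 sin(pi phase)^4 - 1)` rests near end-exhale (-A) and
#' peaks at +A, giving a peak-to-peak excursion of `2 * amplitude`.
#'
#' @param params A [breathing_params()].
#' @param duration Trace length in s.
#' @param native_dt Native sampling interval in s.
#' @param cycle Output (control) sampling interval in s.
#' @return A `motion_trace` with role `"target"`, reproducible given
#'   `params$seed`.
#' @export
generate_trace <- function(params, duration, native_dt = 0.1, cycle = 0.040) {
  stopifnot(inherits(params, "breathing_params"), duration > 0,
            native_dt > 0, cycle > 0)
  withr::local_seed(params$seed)
  # per-cycle amplitudes/periods until the cumulative time covers duration
  n_guess <- ceiling(duration / params$period * (1 + 5 * params$variability)) + 5L
  repeat {
    periods <- params$period *
      pmax(1 + params$variability * stats::rnorm(n_guess), 0.3)
    if (sum(periods) > duration + params$period) break
    n_guess <- n_guess * 2L
  }
  amps <- params$amplitude *
    pmax(1 + params$variability * stats::rnorm(n_guess), 0)
  starts <- c(0, cumsum(periods))
  t_native <- seq(0, duration, by = native_dt)
  ci <- findInterval(t_native, starts)
  phase <- (t_native - starts[ci]) / periods[ci]
  breath <- amps[ci] * (2 * sin(pi * phase)^4 - 1)
  s <- breath + params$drift * t_native / 60 +
    params$cardiac_amplitude * sin(2 * pi * params$cardiac_rate * t_native)
  t_out <- seq(0, duration, by = cycle)
  s_out <- approx(t_native, s, xout = t_out, rule = 2)$y
  motion_trace(tibble(t_s = t_out,
                      x_mm = params$axis_mix[1] * s_out,
                      y_mm = params$axis_mix[2] * s_out),
               role = "target")
}

#' Delay a trace through the sensing chain
#'
#' Produces the sensed feedback signal: the target position transported by
#' a constant latency (`p_sense(t) = p_target(t - delay)`), sampled on the
#' same time grid. Times before the trace start clamp to the first sample.
#'
#' @param trace A `motion_trace`.
#' @param delay Latency in s.
#' @return A `motion_trace` with role `"sensed"`.
#' @export
sense_trace <- function(trace, delay) {
  stopifnot(delay >= 0)
  p <- interp_trace(trace, trace$t_s - delay)
  motion_trace(tibble(t_s = trace$t_s, x_mm = p$x, y_mm = p$y),
               role = "sensed", delta_t_sense = delay)
}

#' Virtual MLC response to a prescribed COG trajectory
#'
#' First-order lag (time constant `mlc_lag`) followed by a leaf-speed rate
#' limit and optional position quantization, applied independently per
#' axis. With zero lag, unlimited rate and no quantization the output
#' equals the input.
#'
#' @param prescribed A `motion_trace` sampled at the machine cycle
#'   (the per-cycle COG prescriptions, i.e. the sensed positions).
#' @param machine A [machine_params()].
#' @return A `motion_trace` with role `"mlc"`.
#' @export
respond <- function(prescribed, machine = machine_params()) {
  stopifnot(inherits(machine, "machine_params"))
  dt <- machine$cycle
  alpha <- if (machine$mlc_lag <= 0) 1 else 1 - exp(-dt / machine$mlc_lag)
  max_step <- machine$rate_limit * dt
  follow <- function(u) {
    y <- numeric(length(u))
    y[1] <- u[1]
    for (k in seq_along(u)[-1]) {
      step <- alpha * (u[k] - y[k - 1])
      step <- max(min(step, max_step), -max_step)
      y[k] <- y[k - 1] + step
    }
    if (machine$quantization > 0) {
      y <- round(y / machine$quantization) * machine$quantization
    }
    y
  }
  motion_trace(tibble(t_s = prescribed$t_s,
                      x_mm = follow(prescribed$x_mm),
                      y_mm = follow(prescribed$y_mm)),
               role = "mlc", delta_t_mlc = machine$mlc_lag)
}

#' First principal axis of 2-D motion
#'
#' PCA of the (x, y) samples of a trace (or any two-column matrix); the
#' sign is fixed to the positive-x half-plane. Degenerate input (fewer
#' than two samples or no variance) returns the x axis with a warning.
#'
#' @param obj A `motion_trace`, or a two-column matrix/data frame.
#' @return Unit length-2 numeric vector.
#' @export
principal_axis <- function(obj) {
  m <- if (inherits(obj, "motion_trace") || is.data.frame(obj)) {
    cbind(obj$x_mm %||% obj[[1]], obj$y_mm %||% obj[[2]])
  } else as.matrix(obj)
  if (nrow(m) < 2L || all(apply(m, 2, sd) < 1e-12)) {
    warn("degenerate motion: principal axis undefined, returning x axis")
    return(c(1, 0))
  }
  v <- prcomp(m, center = TRUE, scale. = FALSE)$rotation[, 1]
  if (v[1] < 0 || (v[1] == 0 && v[2] < 0)) v <- -v
  unname(v)
}
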