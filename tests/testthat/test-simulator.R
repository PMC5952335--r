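test_that("trace generation is reproducible and spans 2A peak-to-peak", {
  bp <- breathing_preset("v2", seed = 21)
  t1 <- generate_trace(bp, 60)
  t2 <- generate_trace(bp, 60)
  expect_identical(t1, t2)
  reg <- breathing_params(amplitude = 6.5, variability = 0, drift = 0,
                          cardiac_amplitude = 0, axis_mix = c(1, 0))
  tr <- generate_trace(reg, 60)
  expect_equal(diff(range(tr$x_mm)), 13, tolerance = 1e-6)
  expect_equal(tr$y_mm, rep(0, nrow(tr)))
  # strict periodicity: one period apart, same value
  n_per <- round(reg$period / 0.04)
  expect_equal(tr$x_mm[1:500], tr$x_mm[1:500 + n_per], tolerance = 1e-9)
})

test_that("irregular preset realizes the configured cycle variability", {
  bp <- breathing_preset("v2", seed = 8, drift = 0, cardiac_amplitude = 0)
  tr <- generate_trace(bp, 300)
  s <- tr$x_mm / bp$axis_mix[1]
  # per-cycle amplitudes from the cycle peaks (waveform max = +A_i)
  n <- length(s); w <- 25  # +/- 1 s window
  peaks <- vapply((w + 1):(n - w), function(i) {
    s[i] == max(s[(i - w):(i + w)]) && s[i] > 0
  }, logical(1))
  amp <- s[(w + 1):(n - w)][peaks]
  amp <- amp[!duplicated(round(which(peaks) / 10))]  # one per plateau
  expect_gt(length(amp), 50)
  cv <- sd(amp) / mean(amp)
  expect_lt(abs(cv - bp$variability) / bp$variability, 0.2)
})

test_that("machine response degenerates to identity and ramps under limits", {
  t <- seq(0, 30, by = 0.04)
  u <- motion_trace(tibble::tibble(t_s = t, x_mm = 5 * sin(t), y_mm = 2 * cos(t)),
                    role = "sensed")
  ident <- respond(u, machine_params(mlc_lag = 0, rate_limit = Inf))
  expect_equal(ident$x_mm, u$x_mm)
  expect_equal(ident$y_mm, u$y_mm)
  step <- motion_trace(tibble::tibble(t_s = t, x_mm = c(0, rep(10, length(t) - 1)),
                                      y_mm = 0), role = "sensed")
  ys <- respond(step, machine_params(mlc_lag = 0, rate_limit = 25))
  reached <- ys$t_s[min(which(ys$x_mm >= 10 - 1e-9))]
  expect_equal(reached, 0.4, tolerance = 0.05)  # 10 mm at 25 mm/s
  expect_true(all(diff(ys$x_mm) <= 25 * 0.04 + 1e-12))
  q <- respond(u, machine_params(mlc_lag = 0, rate_limit = Inf,
                                 quantization = 0.25))
  expect_true(all(abs(q$x_mm / 0.25 - round(q$x_mm / 0.25)) < 1e-9))
})

test_that("first-order lag shows the LTI gain and phase on a sinusoid", {
  t <- seq(0, 60, by = 0.04)
  f <- 0.25; tau <- 0.2; w <- 2 * pi * f
  u <- motion_trace(tibble::tibble(t_s = t, x_mm = 10 * sin(w * t), y_mm = 0),
                    role = "sensed")
  y <- respond(u, machine_params(mlc_lag = tau, rate_limit = Inf))
  sel <- 500:1500
  fit <- stats::lm(y$x_mm[sel] ~ sin(w * t[sel]) + cos(w * t[sel]) - 1)
  gain <- sqrt(sum(coef(fit)^2)) / 10
  phase <- atan2(-coef(fit)[2], coef(fit)[1])
  expect_equal(gain, 1 / sqrt(1 + (w * tau)^2), tolerance = 0.02)
  # discrete-time implementation: phase differs from the continuous
  # first-order system by about w * dt / 2
  expect_lt(abs(unname(phase) - atan(w * tau)), 0.05)
})

test_that("principal axis recovers the dominant motion direction", {
  t <- seq(0, 10, 0.04)
  along_x <- motion_trace(tibble::tibble(t_s = t, x_mm = sin(t), y_mm = 0),
                          role = "target")
  expect_equal(principal_axis(along_x), c(1, 0), tolerance = 1e-9)
  diag45 <- motion_trace(tibble::tibble(t_s = t, x_mm = sin(t) / sqrt(2),
                                        y_mm = sin(t) / sqrt(2)), role = "target")
  expect_equal(principal_axis(diag45), c(1, 1) / sqrt(2), tolerance = 1e-6)
  withr::with_seed(10, {
    cloud <- cbind(rnorm(2000, sd = 2), rnorm(2000, sd = 1))
    rot <- matrix(c(cos(0.5), sin(0.5), -sin(0.5), cos(0.5)), 2)
    v <- principal_axis(cloud %*% t(rot))
  })
  ang <- acos(sum(v * c(cos(0.5), sin(0.5)))) * 180 / pi
  expect_lt(ang, 5)
  expect_warning(principal_axis(matrix(1, 5, 2)), "degenerate")
})

test_that("accumulation reproduces the static exposure under perfect tracking", {
  shape <- rasterize_bank(fit_leaves(aperture_circle(15),
                                     leaf_bank_geometry(10, 5), 10), pad = 1)
  t <- seq(0, 20, by = 0.04)
  still <- motion_trace(tibble::tibble(t_s = t, x_mm = 0, y_mm = 0), role = "target")
  moving <- motion_trace(tibble::tibble(t_s = t, x_mm = 3 * sin(t),
                                        y_mm = 1.5 * cos(t)), role = "target")
  static <- accumulate_dose(still, still, shape, pgk = pgk_gaussian(3))
  # static target + static aperture: plateau equals total beam-on time
  expect_equal(max(static$dose), 20, tolerance = 1e-3)
  expect_equal(sum(static$dose) * 0.0625, attr(static, "expected_integral"),
               tolerance = 5e-3 * attr(static, "expected_integral"))
  # perfect tracking: MLC rides exactly on the target
  perfect <- accumulate_dose(moving, moving, shape, pgk = pgk_gaussian(3))
  st <- trackmargin:::crop_to(static, perfect)
  expect_lt(max(abs(perfect$dose - st$dose)), 1e-9 * max(static$dose))
  expect_error(accumulate_dose(still, motion_trace(
    tibble::tibble(t_s = t + 0.01, x_mm = 0, y_mm = 0), role = "mlc"), shape),
    "time grid")
})

test_that("accumulated dose is conserved during tracked motion", {
  run <- equivalence_run()
  raw <- accumulate_dose(run$target, run$mlc,
                         rasterize_bank(fit_leaves(aperture_circle(15),
                                                   leaf_bank_geometry(10, 5), 10),
                                        pad = 1))
  expect_lt(abs(sum(raw$dose) * raw$resolution^2 /
                  attr(raw, "expected_integral") - 1), 0.005)
})

test_that("simulated tracked profile equals the dose model prediction", {
  run <- equivalence_run()
  ref_x <- map_profile(run$static, "x")
  sim_x <- map_profile(trackmargin:::crop_to(run$tracked, run$static), "x")
  eps_x <- (run$mlc$x_mm - run$target$x_mm)[-1]
  model_x <- degrade_profile(ref_x, error_histogram_density(eps_x, 0.25))
  expect_lt(max(abs(sim_x$dose - model_x$dose)), 0.02)  # 2% of plateau
  # and along y
  ref_y <- map_profile(run$static, "y")
  sim_y <- map_profile(trackmargin:::crop_to(run$tracked, run$static), "y")
  eps_y <- (run$mlc$y_mm - run$target$y_mm)[-1]
  model_y <- degrade_profile(ref_y, error_histogram_density(eps_y, 0.25))
  expect_lt(max(abs(sim_y$dose - model_y$dose)), 0.02)
})

test_that("DAH matches direct counting and its endpoints", {
  withr::with_seed(11, d <- matrix(runif(400, 0, 1.1), 20, 20))
  m <- dose_map(d, 0.25, c(0, 0))
  region <- matrix(TRUE, 20, 20)
  h <- dah(m, region, levels = seq(0, 1.1, 0.05))
  for (i in seq_len(nrow(h))) {
    expect_identical(h$area_fraction[i], mean(d >= h$level[i]))
  }
  expect_identical(a90(h), mean(d > 0.9))
  expect_true(all(diff(h$area_fraction) <= 0))
  uni <- dose_map(matrix(1, 10, 10), 0.25, c(0, 0))
  expect_identical(a90(dah(uni, matrix(TRUE, 10, 10))), 1)
  half <- dose_map(matrix(c(rep(0.95, 50), rep(0.85, 50)), 10, 10), 0.25, c(0, 0))
  expect_identical(a90(dah(half, matrix(TRUE, 10, 10))), 0.5)
  expect_error(dah(uni, matrix(FALSE, 10, 10)), "empty")
})
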