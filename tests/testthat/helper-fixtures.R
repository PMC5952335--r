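# Shared fixtures and independent oracles, built in code at test time.

# erf-shouldered field profile: ideal block of `width` blurred by a
# Gaussian penumbra of SD `sigma` (closed form)
erf_profile <- function(x, width = 50, sigma = 3, kind = "static_real") {
  dose_profile(x, pnorm((x + width / 2) / sigma) - pnorm((x - width / 2) / sigma),
               kind = kind)
}

# Gaussian error density on the KDE evaluation grid
gaussian_density <- function(mean = 0, sd = 1, step = 0.05, span = 8 * sd) {
  g <- seq(mean - span, mean + span, by = step)
  out <- tibble::tibble(x_mm = g, density = dnorm(g, mean, sd))
  class(out) <- c("error_density", class(out))
  out
}

# random convex polygon (hull of a random star), for property tests;
# convexity keeps every sub-leaf row a single interval, so the dense-
# sampling oracle below sees the same geometry as the implementation
# everywhere except at top/bottom tangency rows (handled by row counts)
random_polygon <- function(n_vertices = 12, r_mean = 20, r_jitter = 8) {
  th <- sort(runif(n_vertices, 0, 2 * pi))
  r <- pmax(r_mean + runif(n_vertices, -r_jitter, r_jitter), 2)
  x <- r * cos(th); y <- r * sin(th)
  h <- grDevices::chull(x, y)
  aperture(tibble::tibble(x_mm = x[h], y_mm = y[h]))
}

# brute-force leaf-fitting oracle: dense row sampling at resolution/4.
# Returns per pair (left, right, n contributing rows). Rows whose chord is
# narrower than the sampling step are invisible to the oracle (tangency),
# so comparisons are restricted to pairs where both sides agree on the
# contributing-row count.
brute_force_leaves <- function(poly, bank, n_subleaves, fine = 0.0625) {
  w <- bank$leaf_width
  xs <- seq(min(poly$x_mm) - 1, max(poly$x_mm) + 1, by = fine)
  vapply(seq_len(bank$n_pairs), function(p) {
    y_low <- bank$y0 + (p - 1) * w
    ys <- y_low + (seq_len(n_subleaves) - 0.5) * w / n_subleaves
    lefts <- c(); rights <- c()
    for (yc in ys) {
      inside <- trackmargin:::points_in_polygon(poly, xs, rep(yc, length(xs)))
      if (any(inside)) {
        lefts <- c(lefts, min(xs[inside]))
        rights <- c(rights, max(xs[inside]))
      }
    }
    if (is.null(lefts)) c(NA_real_, NA_real_, 0)
    else c(mean(lefts), mean(rights), length(lefts))
  }, numeric(3))
}

# compare a fitted bank against the oracle; returns the number of pairs
# actually compared (generic-position pairs)
expect_leaves_match_oracle <- function(got, want, tol = 0.125) {
  compared <- 0L
  for (p in seq_len(nrow(got))) {
    if (want[3, p] == 0 || got$n_rows[p] != want[3, p]) next
    testthat::expect_lt(abs(got$left_mm[p] - want[1, p]), tol)
    testthat::expect_lt(abs(got$right_mm[p] - want[2, p]), tol)
    compared <- compared + 1L
  }
  compared
}

# heavyweight simulation results are computed once per test run
.tm_cache <- new.env(parent = emptyenv())

cache_get <- function(key, expr) {
  if (!exists(key, envir = .tm_cache)) {
    assign(key, force(expr), envir = .tm_cache)
  }
  get(key, envir = .tm_cache)
}

# closed-loop delivery on a breathing preset (static + tracked +/- margins)
preset_run <- function(preset, seed) {
  cache_get(paste0("run_", preset), {
    cfg <- run_config(breathing = breathing_preset(preset, seed = seed),
                      duration = 120)
    suppressMessages(run_tracking_loop(
      cfg, scenarios = c("static", "tracked", "tracked_margins")))
  })
}

# long tracked delivery with a fixed aperture, for the dose-model
# equivalence check (5000 cycles)
equivalence_run <- function(seed = 3) {
  cache_get("equivalence", {
    bank <- fit_leaves(aperture_circle(25), leaf_bank_geometry(), 10)
    shape <- rasterize_bank(bank, 0.25, pad = 1)
    target <- generate_trace(breathing_preset("v1", seed = seed), 200)
    sensed <- sense_trace(target, 0.3)
    mlc <- respond(sensed)
    zero <- motion_trace(tibble::tibble(t_s = target$t_s, x_mm = 0, y_mm = 0),
                         role = "mlc")
    pg <- pgk_gaussian(3)
    static <- normalize_map(accumulate_dose(zero, zero, shape, pgk = pg))
    tracked <- accumulate_dose(target, mlc, shape, pgk = pg)
    tracked$dose <- tracked$dose / attr(static, "norm_value")
    list(target = target, mlc = mlc, static = static, tracked = tracked)
  })
}

a90_of <- function(run, scenario, region) {
  run$a90$a90[run$a90$scenario == scenario & run$a90$region == region]
}
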