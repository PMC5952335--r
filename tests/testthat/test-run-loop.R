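test_that("zero motion leaves all exposures identical and margins inactive", {
  cfg <- run_config(breathing = breathing_params(amplitude = 0, variability = 0,
                                                 drift = 0, cardiac_amplitude = 0),
                    duration = 30)
  run <- suppressMessages(run_tracking_loop(cfg))
  expect_named(run$maps, c("static", "untracked", "tracked", "tracked_margins"))
  for (nm in c("untracked", "tracked", "tracked_margins")) {
    m <- trackmargin:::crop_to(run$maps[[nm]], run$maps$static)
    expect_lt(max(abs(m$dose - run$maps$static$dose)), 1e-9)
  }
  # margins stay below the raster quantum (so no dilation ever happens)
  expect_lt(max(abs(as.matrix(run$log[, c("m_x_plus", "m_x_minus",
                                          "m_y_plus", "m_y_minus")]))), 0.125)
})

test_that("reruns with the same config are bit-identical", {
  cfg <- run_config(breathing = breathing_preset("v1", seed = 5), duration = 30)
  r1 <- suppressMessages(run_tracking_loop(cfg, c("static", "tracked_margins")))
  r2 <- suppressMessages(run_tracking_loop(cfg, c("static", "tracked_margins")))
  expect_identical(r1$log, r2$log)
  expect_identical(r1$maps$tracked_margins$dose, r2$maps$tracked_margins$dose)
  expect_identical(r1$config$hash, r2$config$hash)
})

test_that("margins recover shoulder coverage on both breathing presets", {
  for (preset in c("v1", "v2")) {
    run <- preset_run(preset, seed = if (preset == "v1") 11 else 12)
    sh_c <- a90_of(run, "tracked", "shoulder")
    sh_m <- a90_of(run, "tracked_margins", "shoulder")
    pl_c <- a90_of(run, "tracked", "plateau")
    pl_m <- a90_of(run, "tracked_margins", "plateau")
    expect_gt(sh_m, sh_c)          # compensation strictly improves coverage
    expect_gte(sh_m, 0.8)          # and restores most of the shoulder
    expect_gt(pl_m, pl_c)
    # margins activate after warm-up and are finite
    expect_gt(max(run$log$m_x_plus), 0.25)
    expect_true(all(run$log$m_x_plus <= run$config$max_margin))
  }
})

test_that("run summaries expose the per-cycle log and A90 table", {
  run <- preset_run("v1", seed = 11)
  lg <- tidy(run)
  expect_true(all(c("t_s", "eps_x", "sigma_x", "m_x_plus") %in% names(lg)))
  expect_identical(nrow(lg), nrow(run$target) - 1L)
  gl <- glance(run)
  expect_identical(nrow(gl), 1L)
  expect_true("a90_tracked_margins_shoulder" %in% names(gl))
  expect_equal(gl$a90_tracked_margins_shoulder,
               a90_of(run, "tracked_margins", "shoulder"))
})

test_that("run artifacts round-trip through the output directory", {
  run <- preset_run("v1", seed = 11)
  dir <- withr::local_tempdir()
  write_run(run, dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"))
  expect_identical(cfg$hash, run$config$hash)
  expect_identical(cfg$seed, 11L)
  tr <- read_motion_trace(file.path(dir, "trace_target.csv"))
  expect_equal(tr$x_mm, run$target$x_mm, tolerance = 1e-9)
  mp <- read_dose_map(file.path(dir, "map_static.csv"))
  expect_equal(mp$dose, run$maps$static$dose, tolerance = 1e-9)
  expect_equal(mp$origin, run$maps$static$origin)
  lg <- readr::read_csv(file.path(dir, "cycle_log.csv"), show_col_types = FALSE)
  expect_identical(nrow(lg), nrow(run$log))
})

test_that("tabular artifacts survive file round trips", {
  dir <- withr::local_tempdir()
  ap <- aperture_circle(12, n_vertices = 16)
  write_aperture(ap, file.path(dir, "ap.json"))
  expect_equal(read_aperture(file.path(dir, "ap.json")), ap, tolerance = 1e-12)
  write_aperture(ap, file.path(dir, "ap.csv"))
  expect_equal(read_aperture(file.path(dir, "ap.csv"))$x_mm, ap$x_mm)
  pg <- pgk_gaussian(3)
  write_pgk(pg, file.path(dir, "pgk.csv"))
  pg2 <- read_pgk(file.path(dir, "pgk.csv"))
  expect_equal(pg2$weight, pg$weight, tolerance = 1e-12)
  expect_equal(pgk_sd(pg2), pgk_sd(pg), tolerance = 1e-9)
  prof <- erf_profile(seq(-40, 40, 0.25))
  write_dose_profile(prof, file.path(dir, "prof.csv"))
  expect_equal(read_dose_profile(file.path(dir, "prof.csv"))$dose, prof$dose,
               tolerance = 1e-12)
  m <- margin_spec(1.2, 3.4, 0, 0.5)
  write_margins(m, file.path(dir, "m.json"))
  expect_equal(read_margins(file.path(dir, "m.json")), m)
})

test_that("file-level commands drive the pipeline end to end", {
  dir <- withr::local_tempdir()
  # simulate writes a readable trace
  cmd_simulate("v1", 10, file.path(dir, "trace.csv"), seed = 2)
  tr <- read_motion_trace(file.path(dir, "trace.csv"))
  expect_identical(attr(tr, "role"), "target")
  expect_gt(nrow(tr), 200)
  # estimate-pgk on a synthetic 3 mm penumbra measurement
  ideal <- ideal_block(100, 0.25)
  meas <- erf_profile(ideal$x_mm, width = 100, sigma = 3, kind = "measured")
  write_dose_profile(meas, file.path(dir, "meas.csv"))
  cmd_estimate_pgk(file.path(dir, "meas.csv"), file.path(dir, "pgk.csv"))
  pg <- read_pgk(file.path(dir, "pgk.csv"))
  expect_lt(abs(pgk_sd(pg) / 3 - 1), 0.05)
  # compute-margin with zero errors yields the all-zero prescription
  readr::write_csv(tibble::tibble(eps_x_mm = rep(0, 100), eps_y_mm = 0),
                   file.path(dir, "errors.csv"))
  write_dose_profile(erf_profile(seq(-60, 60, 0.25)), file.path(dir, "ref.csv"))
  cmd_compute_margin(file.path(dir, "errors.csv"), file.path(dir, "ref.csv"),
                     file.path(dir, "margins.json"))
  mz <- read_margins(file.path(dir, "margins.json"))
  expect_equal(as.numeric(mz), rep(0, 4), ignore_attr = TRUE)
  # analyze a uniform map: full coverage
  write_dose_map(dose_map(matrix(1, 80, 80), 0.25, c(-10, -10)),
                 file.path(dir, "uni.csv"))
  cmd_analyze(file.path(dir, "uni.csv"), file.path(dir, "rep"))
  rep <- jsonlite::read_json(file.path(dir, "rep", "a90.json"),
                             simplifyVector = TRUE)
  expect_equal(rep$plateau, 1)
  expect_error(cmd_compute_margin(file.path(dir, "trace.csv"),
                                  file.path(dir, "ref.csv"),
                                  file.path(dir, "x.json")),
               "eps_x_mm")
})

test_that("autoplot methods return ggplot objects", {
  run <- preset_run("v1", seed = 11)
  expect_s3_class(autoplot(run$target), "ggplot")
  expect_s3_class(autoplot(run$maps$static), "ggplot")
  expect_s3_class(autoplot(run$dah[["tracked.shoulder"]]), "ggplot")
  expect_s3_class(autoplot(run), "ggplot")
  expect_s3_class(autoplot(pgk_gaussian(3)), "ggplot")
  expect_s3_class(autoplot(map_profile(run$maps$static, "x")), "ggplot")
  expect_s3_class(autoplot(estimate_density(rnorm(100), warmup = 10L)), "ggplot")
})
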