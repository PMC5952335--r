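#' Configuration for a closed-loop tracked delivery
#'
#' Collects every tunable of the virtual delivery: machine response,
#' breathing generator (or an externally supplied target trace), planned
#' aperture, penumbra kernel, confidence level, error-buffer depth,
#' warm-up, margin cap and grid resolutions. The resolved configuration is
#' stored (with its hash) in every run result.
#'
#' @param machine A [machine_params()].
#' @param breathing A [breathing_params()] (ignored when `trace` given).
#' @param trace Optional pre-made target `motion_trace`.
#' @param aperture Planned segment, an [aperture()]; default the 5 cm
#'   circular reference segment.
#' @param bank A [leaf_bank_geometry()].
#' @param pgk Penumbra kernel (`pgk` tibble); default Gaussian sigma 3 mm.
#' @param d_hat Confidence level in (0, 1).
#' @param buffer_n Error-FIFO capacity (500 spans 20 s at the 40 ms cycle).
#' @param warmup Samples required before margins activate.
#' @param max_margin Margin cap in mm.
#' @param resolution Raster/map resolution in mm.
#' @param n_subleaves Sub-leaf rows per leaf pair.
#' @param duration Delivery length in s.
#' @param margin_update Recompute margins every this many cycles.
#' @param normalization_mm Side of the plateau normalization square, mm.
#' @return A list of class `run_config`.
#' @export
run_config <- function(machine = machine_params(),
                       breathing = breathing_preset("v1"),
                       trace = NULL,
                       aperture = aperture_circle(25),
                       bank = leaf_bank_geometry(),
                       pgk = pgk_gaussian(3),
                       d_hat = 0.9,
                       buffer_n = 500L,
                       warmup = 50L,
                       max_margin = 20,
                       resolution = 0.25,
                       n_subleaves = 10L,
                       duration = 120,
                       margin_update = 10L,
                       normalization_mm = 15) {
  stopifnot(inherits(machine, "machine_params"),
            is.null(trace) || inherits(trace, "motion_trace"),
            inherits(pgk, "pgk"),
            d_hat > 0, d_hat < 1, buffer_n >= 1L, warmup >= 1L,
            max_margin > 0, resolution > 0, duration > 0, margin_update >= 1L)
  if (is.null(trace)) stopifnot(inherits(breathing, "breathing_params"))
  cfg <- list(machine = machine, breathing = breathing, trace = trace,
              aperture = as_aperture(aperture), bank = bank, pgk = pgk,
              d_hat = d_hat, buffer_n = as.integer(buffer_n),
              warmup = as.integer(warmup), max_margin = max_margin,
              resolution = resolution, n_subleaves = as.integer(n_subleaves),
              duration = duration, margin_update = as.integer(margin_update),
              normalization_mm = normalization_mm)
  cfg$hash <- rlang::hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Run the closed tracking loop on the virtual machine
#'
#' Simulates one delivery through the full chain: sense (delayed target)
#' -> machine response -> causal error estimation -> KDE -> margin
#' extraction -> raster dilation -> leaf fitting -> dose accumulation in
#' the target frame. Four exposures are produced, mirroring a film study:
#' `static`, `untracked`, `tracked` (no margins) and `tracked_margins`,
#' all normalized to the static central plateau, plus dose-area-histogram
#' coverage statistics over the plateau (`D > d_hat`) and shoulder
#' (`d_hat < D < 0.97`) regions of the static reference.
#'
#' @param config A [run_config()].
#' @param scenarios Subset of
#'   `c("static", "untracked", "tracked", "tracked_margins")`
#'   (static is always run: it defines normalization and regions).
#' @return A list of class `tracking_run` with elements `config`, traces
#'   (`target`, `sensed`, `mlc`), per-cycle `log` tibble, normalized
#'   `maps`, reference profiles `ref_x`/`ref_y`, `regions`, `dah` curves
#'   and the `a90` summary tibble.
#' @export
run_tracking_loop <- function(config,
                              scenarios = c("static", "untracked",
                                            "tracked", "tracked_margins")) {
  stopifnot(inherits(config, "run_config"))
  scenarios <- union("static", match.arg(scenarios, several.ok = TRUE))
  mach <- config$machine
  res <- config$resolution

  target <- config$trace %||%
    generate_trace(config$breathing, config$duration, cycle = mach$cycle)
  sensed <- sense_trace(target, mach$delta_t_sense)
  mlc <- respond(sensed, mach)
  zero <- motion_trace(tibble(t_s = target$t_s, x_mm = 0, y_mm = 0),
                       role = "mlc")
  n_cyc <- nrow(target) - 1L

  # machine-deliverable planned segment
  base_bank <- fit_leaves(config$aperture, config$bank, config$n_subleaves)
  base_shape <- rasterize_bank(base_bank, res, pad = 1)
  planned_mask <- rasterize_aperture(config$aperture, res,
                                     pad = config$max_margin + 1)

  maps <- list()
  maps$static <- accumulate_dose(zero, zero, base_shape, pgk = config$pgk,
                                 resolution = res)
  static_n <- normalize_map(maps$static, region_mm = config$normalization_mm)
  norm_value <- attr(static_n, "norm_value")
  maps$static <- static_n
  ref_x <- map_profile(static_n, "x")
  ref_y <- map_profile(static_n, "y")

  renorm <- function(map) {
    map$dose <- map$dose / norm_value
    map
  }
  if ("untracked" %in% scenarios) {
    maps$untracked <- renorm(accumulate_dose(target, zero, base_shape,
                                             pgk = config$pgk, resolution = res))
  }
  if ("tracked" %in% scenarios) {
    maps$tracked <- renorm(accumulate_dose(target, mlc, base_shape,
                                           pgk = config$pgk, resolution = res))
  }

  # causal per-cycle error estimate (vectorized look-back, Eq.-7 style):
  # eps_hat(t - dTs) = p_mlc(t - dTs) - p_sense(t), known at time t
  t_cyc <- target$t_s[-1]
  back_x <- approx(mlc$t_s, mlc$x_mm, xout = t_cyc - mach$delta_t_sense,
                   rule = 1)$y
  back_y <- approx(mlc$t_s, mlc$y_mm, xout = t_cyc - mach$delta_t_sense,
                   rule = 1)$y
  eps_x <- back_x - sensed$x_mm[-1]
  eps_y <- back_y - sensed$y_mm[-1]

  log <- tibble(
    t_s = t_cyc,
    target_x = target$x_mm[-1], target_y = target$y_mm[-1],
    sensed_x = sensed$x_mm[-1], sensed_y = sensed$y_mm[-1],
    mlc_x = mlc$x_mm[-1], mlc_y = mlc$y_mm[-1],
    eps_x = eps_x, eps_y = eps_y,
    sigma_x = NA_real_, sigma_y = NA_real_,
    m_x_plus = 0, m_x_minus = 0, m_y_plus = 0, m_y_minus = 0
  )

  if ("tracked_margins" %in% scenarios) {
    shapes <- list(base_shape)
    shape_idx <- integer(n_cyc)
    cur_idx <- 1L
    cur <- margin_spec()
    sig <- c(NA_real_, NA_real_)
    for (k in seq_len(n_cyc)) {
      due <- (k %% config$margin_update == 0L)
      if (due) {
        lo <- max(1L, k - config$buffer_n + 1L)
        sx <- eps_x[lo:k]; sx <- sx[is.finite(sx)]
        sy <- eps_y[lo:k]; sy <- sy[is.finite(sy)]
        if (length(sx) >= config$warmup && length(sy) >= config$warmup) {
          dens_x <- estimate_density(sx, warmup = config$warmup)
          dens_y <- estimate_density(sy, warmup = config$warmup)
          sig <- c(attr(dens_x, "bandwidth"), attr(dens_y, "bandwidth"))
          new <- margins_from_state(dens_x, dens_y, ref_x, ref_y,
                                    level = config$d_hat,
                                    max_margin = config$max_margin)
          if (any(abs(new - cur) > 1e-9)) {
            cur <- new
            kx <- build_dilation_kernel(c(cur[["x_minus"]], cur[["x_plus"]]),
                                        res, config$max_margin)
            ky <- build_dilation_kernel(c(cur[["y_minus"]], cur[["y_plus"]]),
                                        res, config$max_margin)
            if (kx$total + ky$total > 2L) {
              dm <- dilate_mask(planned_mask, cur, config$max_margin)
              poly_m <- mask_to_polygon(dm)
              bank_m <- fit_leaves(poly_m, config$bank, config$n_subleaves)
              shapes[[length(shapes) + 1L]] <- rasterize_bank(bank_m, res, pad = 1)
            } else {
              shapes[[length(shapes) + 1L]] <- base_shape
            }
            cur_idx <- length(shapes)
          }
        }
      }
      shape_idx[k] <- cur_idx
      log$sigma_x[k] <- sig[1]; log$sigma_y[k] <- sig[2]
      log$m_x_plus[k] <- cur[["x_plus"]]; log$m_x_minus[k] <- cur[["x_minus"]]
      log$m_y_plus[k] <- cur[["y_plus"]]; log$m_y_minus[k] <- cur[["y_minus"]]
    }
    maps$tracked_margins <- renorm(accumulate_dose(
      target, mlc, shapes, aperture_index = shape_idx,
      pgk = config$pgk, resolution = res))
  }

  regions <- list(
    shoulder = region_threshold(maps$static, config$d_hat, 0.97),
    plateau = region_threshold(maps$static, config$d_hat)
  )
  dahs <- list()
  a90_tbl <- tidyr::expand_grid(scenario = names(maps),
                                region = names(regions)) |>
    dplyr::mutate(a90 = NA_real_)
  for (sc in names(maps)) {
    for (rg in names(regions)) {
      # regions are defined on the static grid; maps share that lattice
      d <- crop_to(maps[[sc]], maps$static)
      h <- dah(d, regions[[rg]])
      dahs[[paste(sc, rg, sep = ".")]] <- h
      a90_tbl$a90[a90_tbl$scenario == sc & a90_tbl$region == rg] <- a90(h)
    }
  }

  structure(list(config = config, target = target, sensed = sensed,
                 mlc = mlc, log = log, maps = maps,
                 ref_x = ref_x, ref_y = ref_y,
                 regions = regions, dah = dahs, a90 = a90_tbl),
            class = "tracking_run")
}

# re-grid a map onto the lattice window of `template` (zero outside)
crop_to <- function(map, template) {
  if (identical(dim(map$dose), dim(template$dose)) &&
      max(abs(map$origin - template$origin)) < 1e-9) return(map)
  r <- template$resolution
  di <- round((template$origin[1] - map$origin[1]) / r)
  dj <- round((template$origin[2] - map$origin[2]) / r)
  nx <- nrow(template$dose); ny <- ncol(template$dose)
  out <- matrix(0, nx, ny)
  src_i <- seq_len(nx) + di; src_j <- seq_len(ny) + dj
  ok_i <- src_i >= 1L & src_i <= nrow(map$dose)
  ok_j <- src_j >= 1L & src_j <= ncol(map$dose)
  out[ok_i, ok_j] <- map$dose[src_i[ok_i], src_j[ok_j]]
  dose_map(out, r, template$origin, map$n_cycles)
}

#' @export
print.tracking_run <- function(x, ...) {
  cat(sprintf("<tracking_run> %d cycles, %d maps (%s)\n",
              nrow(x$log), length(x$maps), paste(names(x$maps), collapse = ", ")))
  print(x$a90)
  invisible(x)
}

#' @export
tidy.tracking_run <- function(x, ...) x$log

#' @export
glance.tracking_run <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$a90, names_from = c("scenario", "region"),
                             values_from = "a90", names_prefix = "a90_")
  dplyr::bind_cols(
    tibble(n_cycles = nrow(x$log),
           duration_s = max(x$log$t_s),
           d_hat = x$config$d_hat,
           config_hash = x$config$hash),
    wide
  )
}
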