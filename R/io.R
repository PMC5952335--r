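#' File interchange for traces, apertures, profiles, kernels and results
#'
#' All tabular artifacts are plain CSV with documented headers; structured
#' metadata (roles, latencies, jaws, grids, normalization) travels in JSON
#' sidecars. Every writer stamps provenance (`package_version`, and the
#' config hash where applicable).
#'
#' @name trackmargin-io
NULL

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

write_meta <- function(path, meta) {
  meta$package_version <- as.character(utils::packageVersion("trackmargin"))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_meta <- function(path) {
  sc <- sidecar_path(path)
  if (file.exists(sc)) jsonlite::read_json(sc, simplifyVector = TRUE) else list()
}

#' @rdname trackmargin-io
#' @param trace A `motion_trace`.
#' @param path Target file (`.csv`; a `.json` sidecar is written next to it).
#' @export
write_motion_trace <- function(trace, path) {
  stopifnot(inherits(trace, "motion_trace"))
  readr::write_csv(as_tibble(trace), path)
  write_meta(path, list(role = attr(trace, "role"),
                        delta_t_sense = attr(trace, "delta_t_sense"),
                        delta_t_mlc = attr(trace, "delta_t_mlc")))
  invisible(path)
}

#' @rdname trackmargin-io
#' @param role Role override when no sidecar exists.
#' @export
read_motion_trace <- function(path, role = NULL) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  meta <- read_meta(path)
  motion_trace(d, role = role %||% meta$role %||% "target",
               delta_t_sense = meta$delta_t_sense %||% NA_real_,
               delta_t_mlc = meta$delta_t_mlc %||% NA_real_)
}

#' @rdname trackmargin-io
#' @param poly An [aperture()].
#' @export
write_aperture <- function(poly, path) {
  poly <- as_aperture(poly)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unname(lapply(seq_len(nrow(poly)), function(i)
      c(poly$x_mm[i], poly$y_mm[i]))), path, digits = NA)
  } else {
    readr::write_csv(as_tibble(poly), path)
  }
  invisible(path)
}

#' @rdname trackmargin-io
#' @export
read_aperture <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    v <- jsonlite::read_json(path, simplifyVector = TRUE)
    aperture(tibble(x_mm = v[, 1], y_mm = v[, 2]))
  } else {
    aperture(readr::read_csv(path, show_col_types = FALSE))
  }
}

#' @rdname trackmargin-io
#' @param profile A `dose_profile`.
#' @export
write_dose_profile <- function(profile, path) {
  readr::write_csv(tibble(x_mm = profile$x_mm, dose_rel = profile$dose), path)
  write_meta(path, list(kind = attr(profile, "kind"),
                        spacing_mm = profile_spacing(profile)))
  invisible(path)
}

#' @rdname trackmargin-io
#' @export
read_dose_profile <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  meta <- read_meta(path)
  dose_profile(d$x_mm, d$dose_rel, kind = meta$kind %||% "measured")
}

#' @rdname trackmargin-io
#' @param pgk A `pgk` tibble.
#' @export
write_pgk <- function(pgk, path) {
  readr::write_csv(tibble(offset_mm = pgk$offset_mm, weight = pgk$weight), path)
  write_meta(path, list(spacing_mm = attr(pgk, "spacing"),
                        waterlevel = attr(pgk, "waterlevel"),
                        sd_mm = pgk_sd(pgk)))
  invisible(path)
}

#' @rdname trackmargin-io
#' @export
read_pgk <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  meta <- read_meta(path)
  out <- tibble(offset_mm = d$offset_mm, weight = d$weight)
  attr(out, "spacing") <- meta$spacing_mm %||% diff(d$offset_mm[1:2])
  attr(out, "waterlevel") <- meta$waterlevel
  class(out) <- c("pgk", class(out))
  out
}

#' @rdname trackmargin-io
#' @param bank A `leaf_bank`.
#' @export
write_leaf_bank <- function(bank, path) {
  stopifnot(inherits(bank, "leaf_bank"))
  readr::write_csv(tibble(pair_index = bank$pair, left_mm = bank$left_mm,
                          right_mm = bank$right_mm, closed = bank$closed), path)
  write_meta(path, list(leaf_width = attr(bank, "leaf_width"),
                        jaw_y_plus = attr(bank, "jaw_y_plus"),
                        jaw_y_minus = attr(bank, "jaw_y_minus")))
  invisible(path)
}

#' @rdname trackmargin-io
#' @param margins A [margin_spec()].
#' @export
write_margins <- function(margins, path) {
  margins <- as_margin_spec(margins)
  jsonlite::write_json(as.list(unclass(margins)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname trackmargin-io
#' @export
read_margins <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  margin_spec(v$x_plus, v$x_minus, v$y_plus, v$y_minus)
}

#' @rdname trackmargin-io
#' @param map A `dose_map`.
#' @export
write_dose_map <- function(map, path) {
  stopifnot(inherits(map, "dose_map"))
  utils::write.table(map$dose, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  write_meta(path, list(resolution_mm = map$resolution,
                        origin_mm = map$origin, n_cycles = map$n_cycles,
                        norm_value = attr(map, "norm_value")))
  invisible(path)
}

#' @rdname trackmargin-io
#' @export
read_dose_map <- function(path) {
  meta <- read_meta(path)
  d <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(d) <- NULL
  dose_map(d, meta$resolution_mm, meta$origin_mm,
           meta$n_cycles %||% NA_integer_)
}

#' @rdname trackmargin-io
#' @param dah_result A `dah_result`.
#' @export
write_dah <- function(dah_result, path) {
  readr::write_csv(tibble(level = dah_result$level,
                          area_fraction = dah_result$area_fraction), path)
  write_meta(path, list(a90 = attr(dah_result, "a90")))
  invisible(path)
}

#' Write all artifacts of a tracking run to a directory
#'
#' Emits the resolved configuration (with hash and seed), the three traces,
#' the per-cycle margin log, every normalized dose map and every DAH curve,
#' plus the A90 summary table.
#'
#' @param run A `tracking_run` from [run_tracking_loop()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "tracking_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- run$config
  jsonlite::write_json(list(
    hash = cfg$hash,
    seed = if (is.null(cfg$trace)) cfg$breathing$seed else NA,
    d_hat = cfg$d_hat, buffer_n = cfg$buffer_n, warmup = cfg$warmup,
    max_margin = cfg$max_margin, resolution = cfg$resolution,
    duration = cfg$duration, margin_update = cfg$margin_update,
    delta_t_sense = cfg$machine$delta_t_sense, cycle = cfg$machine$cycle,
    mlc_lag = cfg$machine$mlc_lag, rate_limit = cfg$machine$rate_limit,
    package_version = as.character(utils::packageVersion("trackmargin"))
  ), file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  write_motion_trace(run$target, file.path(dir, "trace_target.csv"))
  write_motion_trace(run$sensed, file.path(dir, "trace_sensed.csv"))
  write_motion_trace(run$mlc, file.path(dir, "trace_mlc.csv"))
  readr::write_csv(run$log, file.path(dir, "cycle_log.csv"))
  for (nm in names(run$maps)) {
    write_dose_map(run$maps[[nm]], file.path(dir, paste0("map_", nm, ".csv")))
  }
  for (nm in names(run$dah)) {
    write_dah(run$dah[[nm]], file.path(dir, paste0("dah_", nm, ".csv")))
  }
  readr::write_csv(run$a90, file.path(dir, "a90_summary.csv"))
  invisible(dir)
}
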