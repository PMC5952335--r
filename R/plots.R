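#' Plot methods
#'
#' `autoplot()` methods give quick ggplot2 views of every result type:
#' motion traces, error densities, dose profiles, penumbra kernels, dose
#' maps and DAH curves.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name trackmargin-plots
NULL

#' @rdname trackmargin-plots
#' @export
autoplot.motion_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object), c("x_mm", "y_mm"),
                              names_to = "axis", values_to = "position_mm")
  ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$position_mm,
                                     color = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "displacement [mm]",
                  title = sprintf("motion trace (%s)", attr(object, "role")))
}

#' @rdname trackmargin-plots
#' @export
autoplot.error_density <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x_mm, .data$density)) +
    ggplot2::geom_area(alpha = 0.4, fill = "goldenrod") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "tracking error [mm]", y = "density [1/mm]")
}

#' @rdname trackmargin-plots
#' @export
autoplot.dose_profile <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$x_mm, .data$dose)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position [mm]", y = "relative dose",
                  title = attr(object, "kind"))
}

#' @rdname trackmargin-plots
#' @export
autoplot.pgk <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object), ggplot2::aes(.data$offset_mm, .data$weight)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset [mm]", y = "weight [1/mm]",
                  title = sprintf("penumbra kernel (SD %.2f mm)", pgk_sd(object)))
}

#' @rdname trackmargin-plots
#' @export
autoplot.dose_map <- function(object, ...) {
  ax <- map_axes(object)
  df <- tidyr::expand_grid(x_mm = ax$x, y_mm = ax$y)
  df$dose <- as.vector(t(object$dose))  # expand_grid varies y fastest
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$dose)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]", fill = "rel. dose")
}

#' @rdname trackmargin-plots
#' @export
autoplot.dah_result <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(.data$level, .data$area_fraction)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = 0.9, linetype = "dashed") +
    ggplot2::labs(x = "relative dose level", y = "area fraction ≥ level",
                  title = sprintf("DAH (A90 = %.3f)", attr(object, "a90")))
}

#' @rdname trackmargin-plots
#' @export
autoplot.tracking_run <- function(object, ...) {
  curves <- purrr::imap(object$dah, function(d, nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    dplyr::mutate(as_tibble(d), scenario = parts[1], region = parts[2])
  }) |> purrr::list_rbind()
  ggplot2::ggplot(curves, ggplot2::aes(.data$level, .data$area_fraction,
                                       color = .data$scenario)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = object$config$d_hat, linetype = "dashed") +
    ggplot2::facet_wrap(~region) +
    ggplot2::labs(x = "relative dose level", y = "area fraction ≥ level")
}
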