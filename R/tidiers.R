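#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Tidiers for beat-frequency maps
#'
#' `tidy()` returns one row per analysis block; `glance()` a one-row
#' field-level summary.
#'
#' @param x a `cbf_map`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cbf_map <- function(x, ...) {
  dplyr::mutate(x$results, fov_id = x$fov_id, .before = 1)
}

#' @rdname tidy.cbf_map
#' @export
glance.cbf_map <- function(x, ...) {
  pam <- percent_area_moving(x)
  tibble::tibble(
    fov_id = x$fov_id,
    n_blocks = x$grid$n_blocks,
    n_moving = pam$n_blocks_moving,
    percent_moving = pam$percent_moving,
    mean_moving_freq_hz = pam$mean_moving_freq_hz,
    residual_pixels = x$grid$residual_pixels,
    fps = x$fps,
    block_size = x$grid$block_size
  )
}

#' Tidiers for coverage summaries
#'
#' @param x a `coverage_summary`.
#' @param ... unused.
#' @return A tibble: per-field rows (`tidy`) or the one-row insert-level
#'   aggregate (`glance`).
#' @export
tidy.coverage_summary <- function(x, ...) x$per_fov

#' @rdname tidy.coverage_summary
#' @export
glance.coverage_summary <- function(x, ...) {
  tibble::tibble(mean_percent = x$mean_percent, sd_percent = x$sd_percent,
                 n_fov = x$n_fov)
}

#' Tidiers for CBF summaries
#'
#' @param x a `cbf_summary`.
#' @param ... unused.
#' @return A tibble: per-ROI frequencies (`tidy`) or the one-row sample
#'   summary (`glance`).
#' @export
tidy.cbf_summary <- function(x, ...) {
  dplyr::mutate(x$per_roi, sample_id = x$sample_id, .before = 1)
}

#' @rdname tidy.cbf_summary
#' @export
glance.cbf_summary <- function(x, ...) {
  tibble::tibble(
    sample_id = x$sample_id, mean_cbf_hz = x$mean_cbf_hz, n_rois = x$n_rois,
    n_static = x$n_static, status = x$status, mixed_motility = x$mixed_motility,
    normal_low_hz = x$normal_range_hz[1], normal_high_hz = x$normal_range_hz[2]
  )
}

#' Tidiers for TEER batches
#'
#' @param x a `teer_batch`.
#' @param ... unused.
#' @return A tibble: per-insert values (`tidy`) or a one-row overall
#'   summary (`glance`); per-group means live in `x$by_group`.
#' @export
tidy.teer_batch <- function(x, ...) x$per_insert

#' @rdname tidy.teer_batch
#' @export
glance.teer_batch <- function(x, ...) {
  tibble::tibble(
    n_inserts = nrow(x$per_insert),
    n_groups = nrow(x$by_group),
    mean_ohm_cm2 = mean(x$per_insert$teer_ohm_cm2),
    sd_ohm_cm2 = if (nrow(x$per_insert) > 1) stats::sd(x$per_insert$teer_ohm_cm2) else NA_real_,
    n_negative = sum(x$per_insert$negative)
  )
}

.clamp_oob <- function(x, range) pmin(pmax(x, range[1]), range[2])

#' Plot a beat-frequency map in the standard monochrome ramp
#'
#' Blocks are drawn black (non-moving or 0 Hz) through white at
#' `ramp_max_hz` (default 25 Hz); faster in-band frequencies clip to white,
#' matching [write_cbf_map_image()].
#'
#' @param object a `cbf_map`.
#' @param ramp_max_hz frequency rendered white.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cbf_map <- function(object, ramp_max_hz = 25, ...) {
  df <- dplyr::mutate(object$results,
                      shade = ifelse(.data$is_moving, .data$freq_hz, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$shade)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(
      name = "CBF (Hz)", low = "black", high = "white",
      limits = c(0, ramp_max_hz), oob = .clamp_oob
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$fov_id, x = "block column", y = "block row") +
    ggplot2::theme_minimal()
}

#' Plot per-field cilia coverage with the insert mean
#'
#' @param object a `coverage_summary`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.coverage_summary <- function(object, ...) {
  df <- dplyr::mutate(object$per_fov, fov_id = factor(.data$fov_id,
                                                      levels = unique(.data$fov_id)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fov_id, y = .data$percent_moving,
                                   alpha = !.data$excluded)) +
    ggplot2::geom_col(fill = "grey30", show.legend = FALSE) +
    ggplot2::scale_alpha_manual(values = c(`TRUE` = 1, `FALSE` = 0.3)) +
    ggplot2::geom_hline(yintercept = object$mean_percent, linetype = 2, colour = "red") +
    ggplot2::labs(x = "field of view", y = "% area moving",
                  title = sprintf("mean cilia coverage %.1f%% (n = %d fields)",
                                  object$mean_percent, object$n_fov)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot per-ROI beat frequencies against the normal range
#'
#' @param object a `cbf_summary`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.cbf_summary <- function(object, ...) {
  df <- dplyr::mutate(object$per_roi,
                      plotted = ifelse(.data$is_moving, .data$freq_hz, 0))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi, y = .data$plotted,
                                   shape = .data$is_moving)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$normal_range_hz[1], ymax = object$normal_range_hz[2],
                      alpha = 0.15, fill = "steelblue") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4),
                                name = "moving") +
    ggplot2::geom_hline(yintercept = object$mean_cbf_hz, linetype = 2) +
    ggplot2::labs(x = "ROI", y = "CBF (Hz)",
                  title = sprintf("mean CBF %.1f Hz - %s", object$mean_cbf_hz,
                                  object$status)) +
    ggplot2::theme_minimal()
}

#' Plot a block power spectrum with the detection band
#'
#' @param object a `block_spectrum`.
#' @param params a [spectral_params()] supplying the band edges to shade.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.block_spectrum <- function(object, params = spectral_params(), ...) {
  df <- tibble::tibble(freq = object$frequencies, power = object$power)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq, y = .data$power)) +
    ggplot2::annotate("rect", xmin = params$f_min, xmax = params$f_max,
                      ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "steelblue") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$noise_floor, linetype = 3) +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = sprintf("block (%d, %d)", object$row, object$col)) +
    ggplot2::theme_minimal()
}
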