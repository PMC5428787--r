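#' Plot a rate time course
#'
#' Instantaneous sliding-window rate (or cumulative event count) against
#' time, with the stimulus marked when known.
#'
#' @param object A [rate_time_course()] result.
#' @param which `"rate"` or `"cumulative"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smti_rate_course <- function(object, which = c("rate", "cumulative"),
                                      ...) {
  which <- match.arg(which)
  stim <- attr(object, "stimulus_time_s")
  df <- tibble::as_tibble(object)
  p <- if (which == "rate") {
    ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$rate_per_s)) +
      ggplot2::geom_line(color = "#2166ac") +
      ggplot2::labs(x = "time (s)", y = "translation rate (events/s)")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$cumulative_count)) +
      ggplot2::geom_step(color = "#2166ac") +
      ggplot2::labs(x = "time (s)", y = "cumulative translation events")
  }
  if (!is.null(stim)) {
    p <- p + ggplot2::geom_vline(xintercept = stim, linetype = "dashed",
                                 color = "grey40")
  }
  p + ggplot2::theme_minimal()
}

#' Plot a translation density map
#'
#' Event-rate raster with the cell outline overlaid; bins outside the mask
#' are blanked, as density is only meaningful inside the cell.
#'
#' @param object A [density_map()] result.
#' @param mask_outside Blank bins outside the cell mask (default TRUE).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smti_density_map <- function(object, mask_outside = TRUE, ...) {
  g <- object$grid
  bin <- object$bin_size_nm
  df <- expand.grid(row = seq_len(nrow(g)), col = seq_len(ncol(g)))
  df$x_um <- (df$col - 0.5) * bin / 1000
  df$y_um <- (df$row - 0.5) * bin / 1000
  df$rate <- as.vector(g)
  if (mask_outside) {
    geom <- object$geometry
    inside <- point_in_mask((df$col - 0.5) * bin, (df$row - 0.5) * bin,
                            geom$mask, geom$pixel_size_nm, dilate = 1)
    df$rate[!inside] <- NA_real_
  }
  outline <- object$geometry$outline
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$rate)) +
    ggplot2::scale_fill_viridis_c(na.value = "grey95",
                                  name = "events/s") +
    ggplot2::coord_equal() +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
  if (nrow(outline) > 0) {
    p <- p + ggplot2::geom_path(
      data = dplyr::mutate(outline, x_um = .data$x_nm / 1000,
                           y_um = .data$y_nm / 1000),
      ggplot2::aes(.data$x_um, .data$y_um, group = .data$ring),
      color = "white", linewidth = 0.3
    )
  }
  p
}

#' Plot Sholl arc percentages
#'
#' @param object An [assign_events_to_arcs()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smti_sholl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$arc <- factor(df$arc, levels = df$arc)
  ggplot2::ggplot(df, ggplot2::aes(.data$arc, .data$percentage)) +
    ggplot2::geom_col(fill = "#2166ac") +
    ggplot2::labs(x = "arc (central → peripheral)",
                  y = "events (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
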