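#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a detection result into the particle table
#'
#' @param x An `hb_result` from [detect_particles()].
#' @param ... Unused.
#' @return The particle tibble (one row per detected particle).
#' @export
tidy.hb_result <- function(x, ...) x$particles

#' One-row summary of a detection run
#'
#' @param x An `hb_result`.
#' @param ... Unused.
#' @return One-row tibble: particle count, resolved strength threshold,
#'   audit counts, and scale range.
#' @export
glance.hb_result <- function(x, ...) {
  tibble::tibble(
    n_particles = nrow(x$particles),
    threshold = x$threshold,
    n_maxima = x$counts$n_maxima,
    n_after_overlap = x$counts$n_after_overlap,
    t_min_px2 = min(x$scales),
    t_max_px2 = max(x$scales),
    n_scales = length(x$scales)
  )
}

#' Plot a detection result
#'
#' Height map with detected boundaries and subpixel centres overlaid.
#' The y axis is reversed to match raster (scan) orientation.
#'
#' @param object An `hb_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hb_result <- function(object, ...) {
  imgdf <- as_tibble(object$image)
  p <- ggplot2::ggplot(imgdf, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$height)) +
    ggplot2::scale_fill_viridis_c(name = paste0("height (",
                                                object$image$unit, ")")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = paste0("x (", object$image$unit, ")"),
                  y = paste0("y (", object$image$unit, ")"))
  if (nrow(object$contours) > 0) {
    p <- p + ggplot2::geom_path(
      data = object$contours,
      ggplot2::aes(x = .data$x_phys, y = .data$y_phys,
                   group = interaction(.data$blob_id, .data$ring_id)),
      colour = "green", linewidth = 0.4)
  }
  if (nrow(object$particles) > 0) {
    p <- p + ggplot2::geom_point(
      data = object$particles,
      ggplot2::aes(x = .data$x, y = .data$y),
      colour = "red", shape = 3, size = 1)
  }
  p
}

#' Plot a scale-space signature
#'
#' Detector response at a fixed pixel against effective scale
#' `log2(1 + t)`, with local maxima (candidate natural scales) marked.
#'
#' @param object An `hb_signature` from [scale_space_signature()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hb_signature <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$effective_scale,
                                       y = .data$response)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(data = dplyr::filter(object, .data$is_max),
                        colour = "red") +
    ggplot2::labs(x = "effective scale log2(1 + t)",
                  y = "det H response")
}
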