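#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic ggplots of the main result
#' types: eye traces with detected-saccade markers, decoded-heading time
#' courses, compression curves, modulation time courses with their
#' bootstrap band, and gain kernels.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot.
#' @name periheading-plots
NULL

#' @rdname periheading-plots
#' @method autoplot eye_trace
#' @export
autoplot.eye_trace <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("x_deg", "y_deg"),
                           names_to = "axis", values_to = "position_deg")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_ms, .data$position_deg,
                                  colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "eye position (deg)") +
    ggplot2::theme_minimal()
}

#' @rdname periheading-plots
#' @method autoplot decoded_series
#' @export
autoplot.decoded_series <- function(object, ...) {
  sm <- running_mean2(object)
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$time_ms, .data$decoded_deg,
                               colour = factor(.data$heading_deg))) +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = sm) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from saccade onset (ms)",
                  y = "decoded heading (deg)", colour = "heading (deg)") +
    ggplot2::theme_minimal()
}

#' @rdname periheading-plots
#' @method autoplot compression_curve
#' @export
autoplot.compression_curve <- function(object, ...) {
  p <- ggplot2::ggplot(tibble::as_tibble(object),
                       ggplot2::aes(.data$time_ms, .data$normalized_sd)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from saccade onset (ms)",
                  y = "normalized SD of headings") +
    ggplot2::theme_minimal()
  t_min <- attr(object, "t_max_compression")
  if (!is.null(t_min) && !is.na(t_min)) {
    p <- p + ggplot2::geom_vline(xintercept = t_min, colour = "red",
                                 linetype = 2)
  }
  p
}

#' @rdname periheading-plots
#' @method autoplot modulation_timecourse
#' @export
autoplot.modulation_timecourse <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_ms, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from saccade onset (ms)",
                  y = "response modulation (spikes/s)") +
    ggplot2::theme_minimal()
}

#' @rdname periheading-plots
#' @method autoplot suppression_kernel
#' @export
autoplot.suppression_kernel <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(.data$time_ms, .data$gain)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 3) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "time from saccade onset (ms)",
                  y = "multiplicative gain",
                  title = unique(object$label)) +
    ggplot2::theme_minimal()
}
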