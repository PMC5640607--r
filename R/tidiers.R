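#' Tidy and summarize result objects
#'
#' Broom-style methods: `tidy()` returns the per-time-bin (or per-lag)
#' table of a result, `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name periheading-tidiers
NULL

#' @rdname periheading-tidiers
#' @method tidy compression_curve
#' @export
tidy.compression_curve <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "compression_curve")
  tibble::as_tibble(out)
}

#' @rdname periheading-tidiers
#' @method glance compression_curve
#' @export
glance.compression_curve <- function(x, ...) {
  tibble::tibble(
    min_normalized_sd = attr(x, "min_normalized_sd"),
    t_max_compression_ms = attr(x, "t_max_compression"),
    depth = 1 - attr(x, "min_normalized_sd"),
    flat = attr(x, "flat"),
    n_bins = nrow(x)
  )
}

#' @rdname periheading-tidiers
#' @method tidy suppression_model
#' @export
tidy.suppression_model <- function(x, ...) {
  tibble::as_tibble(x$decoded)
}

#' @rdname periheading-tidiers
#' @method glance suppression_model
#' @export
glance.suppression_model <- function(x, ...) {
  tibble::tibble(
    mode = x$mode,
    min_normalized_sd = attr(x$compression, "min_normalized_sd"),
    t_max_compression_ms = t_max_compression(x$compression),
    n_repetitions = x$n_repetitions
  )
}

#' @rdname periheading-tidiers
#' @method tidy latency_estimate
#' @export
tidy.latency_estimate <- function(x, ...) {
  attr(x, "correlations")
}

#' @rdname periheading-tidiers
#' @method glance latency_estimate
#' @export
glance.latency_estimate <- function(x, ...) {
  tibble::tibble(tau_ms = x$tau_ms, peak_correlation = x$peak_correlation)
}

#' @rdname periheading-tidiers
#' @method tidy reference_frame_result
#' @export
tidy.reference_frame_result <- function(x, ...) {
  x$conditions
}

#' @rdname periheading-tidiers
#' @method glance reference_frame_result
#' @export
glance.reference_frame_result <- function(x, ...) {
  tibble::tibble(conclusion = x$conclusion)
}
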