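#' Decode heading from one neuron's binned rates
#'
#' Inverts the linear tuning function: a rate `y` maps to the heading
#' estimate `x = (y - intercept_b) / slope_a`, bin by bin. Decoded values
#' are deliberately not clipped to the stimulus range, so centrifugal biases
#' remain visible.
#'
#' @param binned Binned rates for one neuron (`heading_deg`, `time_ms`,
#'   `rate_hz`).
#' @param fit One-row tuning fit with `slope_a`, `intercept_b`.
#' @param slope_eps Minimum `|slope_a|`; smaller slopes are an error (such
#'   neurons are excluded upstream).
#' @return `binned` with a `decoded_deg` column.
#' @examples
#' b <- data.frame(heading_deg = 30, time_ms = 0, rate_hz = 15.01)
#' f <- data.frame(slope_a = 0.108, intercept_b = 11.77)
#' decode_neuron(b, f)$decoded_deg  # 30
#' @export
decode_neuron <- function(binned, fit, slope_eps = 1e-6) {
  stopifnot(is.data.frame(fit), nrow(fit) == 1)
  if (abs(fit$slope_a) < slope_eps) {
    abort("Tuning slope too close to 0; neuron is not decodable.")
  }
  dplyr::mutate(binned,
                decoded_deg = (.data$rate_hz - fit$intercept_b) / fit$slope_a)
}

#' Decode heading for every decodable neuron in a population
#'
#' @param binned Binned rates with `neuron_id`, `heading_deg`, `time_ms`,
#'   `rate_hz`.
#' @param fits Per-neuron tuning fits (from [fit_population_tuning()]);
#'   only rows with `decodable` slopes (and `significant_tuning`, when the
#'   column is present) are used.
#' @param slope_eps Minimum usable `|slope_a|`.
#' @return Tibble with per-neuron decoded headings per bin.
#' @export
decode_neurons <- function(binned, fits, slope_eps = 1e-6) {
  use <- dplyr::filter(fits, abs(.data$slope_a) >= slope_eps)
  if ("significant_tuning" %in% names(use)) {
    use <- dplyr::filter(use, .data$significant_tuning)
  }
  if (!nrow(use)) abort("No decodable neurons in `fits`.")
  binned |>
    dplyr::inner_join(
      dplyr::select(use, "neuron_id", "slope_a", "intercept_b"),
      by = "neuron_id"
    ) |>
    dplyr::mutate(
      decoded_deg = (.data$rate_hz - .data$intercept_b) / .data$slope_a
    ) |>
    dplyr::select("neuron_id", "heading_deg", "time_ms", "decoded_deg")
}

#' Population heading readout
#'
#' The population's decoded heading in each bin is the median of the
#' per-neuron heading estimates (midpoint of the central order statistics
#' for even counts). A neuron missing from a bin is dropped from that bin's
#' median only.
#'
#' @param decoded Per-neuron decoded headings (`neuron_id`, `heading_deg`,
#'   `time_ms`, `decoded_deg`).
#' @return Tibble of class `decoded_series`: `heading_deg`, `time_ms`,
#'   `decoded_deg` (median), `n_neurons`.
#' @export
decode_population <- function(decoded) {
  out <- decoded |>
    dplyr::filter(is.finite(.data$decoded_deg)) |>
    dplyr::summarise(
      n_neurons = dplyr::n(),
      decoded_deg = median(.data$decoded_deg),
      .by = c("heading_deg", "time_ms")
    ) |>
    dplyr::arrange(.data$heading_deg, .data$time_ms) |>
    dplyr::select("heading_deg", "time_ms", "decoded_deg", "n_neurons")
  class(out) <- c("decoded_series", class(out))
  out
}

#' Bin-wise rank test for heading separation
#'
#' In each time bin, tests whether the per-neuron decoded headings differ
#' across stimulus headings (Kruskal-Wallis ANOVA on ranks), then adjusts
#' the per-bin p-values for multiple comparisons with the Benjamini-Hochberg
#' false-discovery-rate procedure across bins.
#'
#' @param decoded Per-neuron decoded headings (from [decode_neurons()]).
#' @param alpha Significance level on the adjusted p-values.
#' @return Tibble per bin: `time_ms`, `statistic`, `p_value`, `p_adjusted`,
#'   `significant`, `n_groups`. Bins with fewer than 2 heading groups are
#'   excluded from the adjustment and flagged with `NA`.
#' @export
binwise_separation_test <- function(decoded, alpha = 0.05) {
  per_bin <- decoded |>
    dplyr::filter(is.finite(.data$decoded_deg)) |>
    dplyr::group_by(.data$time_ms) |>
    dplyr::group_modify(function(d, key) {
      ng <- length(unique(d$heading_deg))
      if (ng < 2) {
        return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                              n_groups = ng))
      }
      k <- heading_significance(
        data.frame(heading_deg = d$heading_deg, rate_hz = d$decoded_deg)
      )
      tibble::tibble(statistic = k$statistic, p_value = k$p_value,
                     n_groups = ng)
    }) |>
    dplyr::ungroup()
  ok <- !is.na(per_bin$p_value)
  per_bin$p_adjusted <- NA_real_
  per_bin$p_adjusted[ok] <- p.adjust(per_bin$p_value[ok], method = "BH")
  per_bin$significant <- per_bin$p_adjusted < alpha
  per_bin
}

#' Two-bin running mean
#'
#' Averages consecutive pairs of bins and assigns the result to the
#' mid-point between the two bin timestamps (used for plotting decoded
#' heading; statistics operate on the raw bins).
#'
#' @param data Data frame with a time column and a value column.
#' @param value,time Column names (strings).
#' @param by Optional grouping column name (e.g. `"heading_deg"`).
#' @return Tibble with the same value column at mid-point timestamps
#'   (one fewer row per group).
#' @examples
#' running_mean2(data.frame(time_ms = c(0, 20), decoded_deg = c(10, 20)))
#' @export
running_mean2 <- function(data, value = "decoded_deg", time = "time_ms",
                          by = intersect("heading_deg", names(data))) {
  one <- function(d) {
    d <- d[order(d[[time]]), ]
    n <- nrow(d)
    if (n < 2) abort("Need at least 2 bins for a running mean.")
    out <- d[seq_len(n - 1), , drop = FALSE]
    out[[time]] <- (d[[time]][-n] + d[[time]][-1]) / 2
    out[[value]] <- (d[[value]][-n] + d[[value]][-1]) / 2
    out
  }
  if (length(by)) {
    data |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    tibble::as_tibble(one(as.data.frame(data)))
  }
}

#' Normalized-SD compression curve
#'
#' Quantifies compression as the standard deviation, across the stimulus
#' headings, of the decoded (or perceived) heading time courses, divided by
#' its mean value in two flanking normalization windows (default 200-100 ms
#' before and 200-300 ms after saccade onset). A value of 1 means the
#' headings are as separated as in the flanks; the time of maximum
#' compression is the argmin. Computed from the raw (un-smoothed) values.
#'
#' @param series Data frame with one value per heading and time bin.
#' @param value,group,time Column names (strings) of the decoded/perceived
#'   value, the heading label, and time.
#' @param norm_windows List of two `c(lo, hi)` windows (ms, half-open) whose
#'   mean SD defines the normalizer.
#' @param flat_tol If the curve's peak-to-trough depth is below this
#'   tolerance the curve is flagged flat and `t_max_compression` is `NA`.
#' @return Tibble of class `compression_curve`: `time_ms`, `sd_deg`,
#'   `normalized_sd`, with attributes `norm_windows`, `t_max_compression`,
#'   `min_normalized_sd` and `flat`. Use [glance()] for a one-row summary.
#' @export
compression_curve <- function(series, value = "decoded_deg",
                              group = "heading_deg", time = "time_ms",
                              norm_windows = list(c(-200, -100), c(200, 300)),
                              flat_tol = 1e-9) {
  stopifnot(all(c(value, group, time) %in% names(series)))
  if (length(unique(series[[group]])) < 2) {
    abort("Need at least 2 heading series to compute an SD across headings.")
  }
  sds <- series |>
    dplyr::summarise(
      sd_deg = sd(.data[[value]]),
      .by = dplyr::all_of(time)
    ) |>
    dplyr::arrange(.data[[time]]) |>
    dplyr::rename(time_ms = dplyr::all_of(time))

  in_norm <- Reduce(`|`, lapply(norm_windows, function(w) {
    sds$time_ms >= w[1] & sds$time_ms < w[2]
  }))
  if (!any(in_norm)) abort("No bins fall inside the normalization windows.")
  norm <- mean(sds$sd_deg[in_norm])
  if (!is.finite(norm) || norm <= flat_tol) {
    abort("Normalization mean is zero; heading series are degenerate.")
  }
  sds$normalized_sd <- sds$sd_deg / norm

  depth <- max(sds$normalized_sd) - min(sds$normalized_sd)
  flat <- depth < flat_tol
  t_min <- if (flat) NA_real_ else sds$time_ms[which.min(sds$normalized_sd)]

  class(sds) <- c("compression_curve", class(sds))
  attr(sds, "norm_windows") <- norm_windows
  attr(sds, "t_max_compression") <- t_min
  attr(sds, "min_normalized_sd") <- min(sds$normalized_sd)
  attr(sds, "flat") <- flat
  sds
}

#' Time of maximum compression
#'
#' @param curve A `compression_curve`.
#' @return Time (ms) at which the normalized SD is minimal; `NA` for flat
#'   curves.
#' @export
t_max_compression <- function(curve) {
  attr(curve, "t_max_compression")
}
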