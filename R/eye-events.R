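#' Detect saccades by a speed criterion
#'
#' Computes eye speed as the Euclidean norm of the centred finite-difference
#' velocity of the horizontal and vertical position and marks a saccade
#' wherever speed rises above the criterion (default 80 deg/s, the standard
#' offline criterion). Onset is the first sample at or above the criterion
#' whose predecessor is below it; offset is the first subsequent sample below.
#' Runs shorter than `min_duration_ms` are discarded as single-sample noise.
#'
#' @param trace Data frame with `time_ms`, `x_deg`, `y_deg`; uniformly
#'   sampled.
#' @param speed_threshold Speed criterion, deg/s.
#' @param min_duration_ms Minimum above-criterion duration, ms (default 6,
#'   i.e. 3 samples at 500 Hz).
#' @param two_dim Use 2-D speed (default); `FALSE` uses horizontal speed only.
#' @return Tibble with `onset_ms`, `offset_ms`, `amplitude_deg`,
#'   `peak_speed`, sorted by onset.
#' @examples
#' tr <- simulate_eye_trace(okn_params(), duration_s = 5, seed = 1)
#' detect_saccades(tr)
#' @export
detect_saccades <- function(trace, speed_threshold = 80,
                            min_duration_ms = 6, two_dim = TRUE) {
  stopifnot(is.data.frame(trace),
            all(c("time_ms", "x_deg", "y_deg") %in% names(trace)))
  if (nrow(trace) < 3) abort("`trace` must have at least 3 samples.")
  dt <- diff(trace$time_ms)
  if (any(abs(dt - dt[1]) > 1e-6 * dt[1])) {
    abort("`trace` must be uniformly sampled.")
  }
  dt <- dt[1]

  cdiff <- function(p) {
    n <- length(p)
    v <- c(p[2] - p[1], (p[3:n] - p[1:(n - 2)]) / 2, p[n] - p[n - 1])
    v / dt * 1000                       # deg/s
  }
  vx <- cdiff(trace$x_deg)
  speed <- if (two_dim) sqrt(vx^2 + cdiff(trace$y_deg)^2) else abs(vx)

  above <- speed >= speed_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= max(1, round(min_duration_ms / dt))
  starts <- starts[keep]; ends <- ends[keep]

  tibble::tibble(
    onset_ms = trace$time_ms[starts],
    offset_ms = trace$time_ms[pmin(ends + 1, nrow(trace))],
    amplitude_deg = sqrt(
      (trace$x_deg[pmin(ends + 1, nrow(trace))] - trace$x_deg[starts])^2 +
        (trace$y_deg[pmin(ends + 1, nrow(trace))] - trace$y_deg[starts])^2
    ),
    peak_speed = purrr::map2_dbl(starts, ends, ~ max(speed[.x:.y]))
  )
}

#' Select isolation-eligible perisaccadic snippets
#'
#' A saccade anchors an eligible snippet when (i) no other saccade onset
#' falls within the snippet window (default 200 ms before to 450 ms after
#' onset) and (ii) eye position stays within the central window of the
#' screen (default 20 deg wide, i.e. +/-10 deg on both axes) throughout the
#' snippet. Snippets are labelled with the stimulated heading from the
#' stimulus schedule.
#'
#' @param saccades Tibble from [detect_saccades()] (needs `onset_ms`).
#' @param trace The eye trace the saccades came from.
#' @param schedule Either a single heading (deg) for the whole trace, or a
#'   data frame with `start_ms`, `end_ms`, `heading_deg`; `NULL` leaves the
#'   label `NA`.
#' @param central_limit Width of the allowed central window, deg (the limit
#'   is `central_limit / 2` on each side of zero).
#' @param window Snippet window relative to onset, ms.
#' @param keep_ineligible Return ineligible snippets too (flagged), for
#'   diagnostics.
#' @return Tibble with `onset_ms`, `heading_deg`, `isolation_ok`,
#'   `central_ok`, `eligible`; only eligible rows unless `keep_ineligible`.
#' @export
select_snippets <- function(saccades, trace, schedule = NULL,
                            central_limit = 20, window = c(-200, 450),
                            keep_ineligible = FALSE) {
  stopifnot(is.data.frame(saccades), "onset_ms" %in% names(saccades))
  on <- saccades$onset_ms
  half <- central_limit / 2

  isolation <- vapply(seq_along(on), function(i) {
    others <- on[-i]
    !any(others >= on[i] + window[1] & others <= on[i] + window[2])
  }, logical(1))

  central <- vapply(on, function(o) {
    idx <- trace$time_ms >= o + window[1] & trace$time_ms <= o + window[2]
    all(abs(trace$x_deg[idx]) <= half & abs(trace$y_deg[idx]) <= half)
  }, logical(1))

  heading <- if (is.null(schedule)) {
    rep(NA_real_, length(on))
  } else if (is.data.frame(schedule)) {
    vapply(on, function(o) {
      hit <- schedule$start_ms <= o & o < schedule$end_ms
      if (any(hit)) schedule$heading_deg[which(hit)[1]] else NA_real_
    }, numeric(1))
  } else {
    rep(as.numeric(schedule), length(on))
  }

  out <- tibble::tibble(
    onset_ms = on, heading_deg = heading,
    isolation_ok = isolation, central_ok = central,
    eligible = isolation & central
  )
  if (keep_ineligible) out else dplyr::filter(out, .data$eligible)
}

#' Bin spikes into perisaccadic rates
#'
#' Aligns spike times to each snippet's saccade onset and averages spike
#' counts in half-open 20 ms bins across all snippets of the same heading,
#' yielding a mean firing rate per bin, heading and neuron.
#'
#' @param spikes Tibble with `neuron_id`, `time_ms` (one row per spike).
#' @param snippets Tibble with `onset_ms`, `heading_deg` (eligible snippets,
#'   from [select_snippets()] or constructed directly).
#' @param bin_ms Bin width, ms.
#' @param window Snippet window relative to onset, ms; binned on the
#'   [peri_bins()] grid.
#' @param neuron_ids Neurons to report (defaults to those present in
#'   `spikes`); neurons without spikes get all-zero rates.
#' @return Tibble with `neuron_id`, `heading_deg`, `time_ms` (bin left
#'   edge), `rate_hz`, `n_snippets`. Binned rates are invariant to snippet
#'   ordering.
#' @export
bin_perisaccadic_rates <- function(spikes, snippets, bin_ms = 20,
                                   window = c(-200, 450), neuron_ids = NULL) {
  stopifnot(is.data.frame(snippets),
            all(c("onset_ms", "heading_deg") %in% names(snippets)))
  if (!nrow(snippets)) abort("`snippets` is empty; nothing to align to.")
  neuron_ids <- neuron_ids %||% sort(unique(spikes$neuron_id))
  if (!length(neuron_ids)) {
    abort("No neurons: supply `neuron_ids` when `spikes` is empty.")
  }
  bins <- peri_bins(bin_ms, window)
  lo <- bins[1]; hi <- bins[length(bins)] + bin_ms

  n_snip <- dplyr::count(snippets, .data$heading_deg, name = "n_snippets")

  aligned <- purrr::map_dfr(seq_len(nrow(snippets)), function(i) {
    o <- snippets$onset_ms[i]
    rel <- spikes$time_ms - o
    keep <- rel >= lo & rel < hi
    tibble::tibble(
      neuron_id = spikes$neuron_id[keep],
      heading_deg = snippets$heading_deg[i],
      time_ms = bins[findInterval(rel[keep], c(bins, hi))]
    )
  })

  grid <- tidyr::expand_grid(
    neuron_id = neuron_ids,
    heading_deg = sort(unique(snippets$heading_deg)),
    time_ms = bins
  )
  counts <- dplyr::count(aligned, .data$neuron_id, .data$heading_deg,
                         .data$time_ms, name = "n_spikes")
  grid |>
    dplyr::left_join(counts, by = c("neuron_id", "heading_deg", "time_ms")) |>
    dplyr::left_join(n_snip, by = "heading_deg") |>
    dplyr::mutate(
      n_spikes = dplyr::coalesce(.data$n_spikes, 0L),
      rate_hz = .data$n_spikes / .data$n_snippets / (bin_ms / 1000)
    ) |>
    dplyr::select("neuron_id", "heading_deg", "time_ms", "rate_hz",
                  "n_snippets")
}
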