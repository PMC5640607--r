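#' Perisaccadic bin grid
#'
#' Left edges of the half-open 20 ms bins used throughout the perisaccadic
#' analyses. The default window runs from 200 ms before to 450 ms after
#' saccade onset; with 20 ms bins this yields 33 bins with left edges
#' -200, -180, ..., 440 ms (a bin's timestamp is its left edge, so the last
#' bin covers \[440, 460) ms). All binned-rate, decoding, modulation and
#' kernel functions share this grid.
#'
#' @param bin_ms Bin width in ms (default 20).
#' @param window Length-2 numeric, window relative to saccade onset in ms.
#' @return Numeric vector of bin left edges (ms).
#' @examples
#' peri_bins()         # 33 edges, -200 .. 440
#' @export
peri_bins <- function(bin_ms = 20, window = c(-200, 450)) {
  stopifnot(length(window) == 2, window[2] > window[1], bin_ms > 0)
  n <- ceiling((window[2] - window[1]) / bin_ms)
  window[1] + bin_ms * (seq_len(n) - 1)
}

# flank selector shared by kernel normalization: left edges strictly before
# -flank_ms or at/after +flank_ms
is_flank_bin <- function(bin_left, flank_ms = 100) {
  bin_left < -flank_ms | bin_left >= flank_ms
}

# mean over bins whose left edge falls in [lo, hi); NA-safe
window_mean <- function(bin_left, value, lo, hi) {
  keep <- bin_left >= lo & bin_left < hi
  if (!any(keep)) return(NA_real_)
  mean(value[keep], na.rm = TRUE)
}
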