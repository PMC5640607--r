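# minimum-jerk displacement profile, written out independently of the
# package internals so constructed traces serve as an external oracle
mj_profile <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

# hand-built 500 Hz trace with saccadic jumps at given launch times
make_jump_trace <- function(duration_ms, launches = numeric(0),
                            amplitudes = numeric(0), jump_dur_ms = 50,
                            slow_speed = 0, x0 = 0) {
  t <- seq(0, duration_ms - 2, by = 2)
  x <- x0 + slow_speed * t / 1000
  for (i in seq_along(launches)) {
    x <- x + amplitudes[i] * mj_profile((t - launches[i]) / jump_dur_ms)
  }
  tibble::tibble(time_ms = t, x_deg = x, y_deg = 0)
}

# homogeneous Poisson spike train on [0, duration_ms)
make_poisson_spikes <- function(rate_hz, duration_ms, neuron_id = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- rpois(1, rate_hz * duration_ms / 1000)
  tibble::tibble(neuron_id = neuron_id,
                 time_ms = sort(runif(n, 0, duration_ms)))
}

# snippet table aligned to arbitrary onsets
make_snippets <- function(onsets, headings) {
  tibble::tibble(onset_ms = onsets, heading_deg = headings)
}

# binned-rate table for one neuron with a constant rate, optionally scaled
# by a gain within a time window
make_flat_binned <- function(rate_hz = 10, neuron_id = 1, heading_deg = 0,
                             gain = 1, gain_window = c(Inf, Inf)) {
  bins <- peri_bins()
  g <- ifelse(bins >= gain_window[1] & bins < gain_window[2], gain, 1)
  tibble::tibble(neuron_id = neuron_id, heading_deg = heading_deg,
                 time_ms = bins, rate_hz = rate_hz * g, n_snippets = 100L)
}
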