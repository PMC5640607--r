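#' Build a linearly heading-tuned virtual population
#'
#' Draws a population of model neurons whose mean rate depends linearly on
#' heading, `rate = slope_a * heading + intercept_b`, with the population
#' split into a leftward-tuned subpopulation (negative slope) and a
#' rightward-tuned one (positive slope). Slope magnitudes are log-normal,
#' intercepts log-normal and therefore non-negative. The default split of
#' 38 leftward / 33 rightward neurons mirrors the MST/VIP sample the
#' analyses are designed for; the scale of the default slopes and intercepts
#' is anchored on a typical fit of 0.108 (spikes/s)/deg slope and
#' 11.77 spikes/s intercept.
#'
#' @param n_left,n_right Number of neurons with negative / positive slope.
#' @param slope_meanlog,slope_sdlog Log-normal parameters of `|slope_a|`.
#' @param intercept_meanlog,intercept_sdlog Log-normal parameters of
#'   `intercept_b` (spikes/s).
#' @param seed Optional seed.
#' @return Tibble with `neuron_id`, `slope_a` ((spikes/s)/deg) and
#'   `intercept_b` (spikes/s).
#' @examples
#' pop <- virtual_population(seed = 1)
#' table(sign(pop$slope_a))
#' @export
virtual_population <- function(n_left = 38, n_right = 33,
                               slope_meanlog = log(0.1), slope_sdlog = 0.5,
                               intercept_meanlog = log(12),
                               intercept_sdlog = 0.4,
                               seed = NULL) {
  stopifnot(n_left >= 0, n_right >= 0, n_left + n_right > 0)
  with_seed(seed, {
    n <- n_left + n_right
    mag <- stats::rlnorm(n, slope_meanlog, slope_sdlog)
    sgn <- rep(c(-1, 1), c(n_left, n_right))
    tibble::tibble(
      neuron_id = seq_len(n),
      slope_a = sgn * mag,
      intercept_b = stats::rlnorm(n, intercept_meanlog, intercept_sdlog)
    )
  })
}

#' Construct a perisaccadic gain kernel
#'
#' A kernel is a multiplicative gain as a function of time relative to
#' saccade onset, normalized so that its mean over the flank times (bins
#' more than 100 ms before or after onset) equals 1.
#'
#' @param time_ms Time axis (bin left edges), ms relative to saccade onset.
#' @param gain Unitless gain at each time point.
#' @param label Kernel label, e.g. `"global"`, `"congruent"`, `"incongruent"`.
#' @param flank_ms Flank half-width used for normalization (default 100 ms).
#' @return Tibble of class `suppression_kernel` with columns `time_ms`,
#'   `gain`, `label`; flank mean of `gain` is 1 by construction.
#' @export
suppression_kernel <- function(time_ms = peri_bins(), gain, label = "kernel",
                               flank_ms = 100) {
  stopifnot(length(time_ms) == length(gain))
  fm <- mean(gain[is_flank_bin(time_ms, flank_ms)])
  if (!is.finite(fm) || abs(fm) < 1e-12) {
    abort("Kernel flank mean is zero; cannot normalize.")
  }
  out <- tibble::tibble(time_ms = time_ms, gain = gain / fm, label = label)
  class(out) <- c("suppression_kernel", class(out))
  out
}

#' Identity (no-modulation) kernel
#' @inheritParams suppression_kernel
#' @return A `suppression_kernel` with gain identically 1.
#' @export
identity_kernel <- function(time_ms = peri_bins(), label = "identity") {
  suppression_kernel(time_ms, rep(1, length(time_ms)), label)
}

#' Gaussian-bump gain kernel
#'
#' Gain `1 - depth * exp(-(t - center)^2 / (2 width^2))`; negative `depth`
#' yields an enhancement bump. Normalized to flank mean 1.
#'
#' @param depth Peak deviation from 1 (positive = suppression dip).
#' @param center_ms Time of the peak deviation, ms after saccade onset.
#' @param width_ms Gaussian SD in ms.
#' @inheritParams suppression_kernel
#' @export
gaussian_kernel <- function(depth, center_ms, width_ms = 40,
                            time_ms = peri_bins(), label = "kernel") {
  g <- 1 - depth * exp(-(time_ms - center_ms)^2 / (2 * width_ms^2))
  suppression_kernel(time_ms, g, label)
}

#' Default kernel set for the suppression model
#'
#' Empirically shaped kernels for the virtual-neuron model: a congruent
#' suppression dip centred 80 ms after saccade onset, a mirrored
#' incongruent enhancement peaking 40 ms later (120 ms), and a global
#' kernel defined as the all-neuron average of the two condition profiles.
#' All are normalized to flank mean 1. The default depth of 0.25 matches
#' the scale of normalized perisaccadic modulation profiles in MST/VIP
#' populations, whose 40-160 ms modulation indices lie near 0.8
#' (suppression) and 1.2 (enhancement).
#'
#' @param suppression_depth,enhancement_depth Peak gain deviation of the
#'   congruent dip / incongruent bump.
#' @param t_suppression,t_enhancement Peak times in ms after saccade onset.
#' @param width_ms Gaussian SD of both profiles, ms.
#' @param time_ms Time axis (bin left edges).
#' @return Named list of three `suppression_kernel`s:
#'   `congruent`, `incongruent`, `global`.
#' @examples
#' k <- model_kernels()
#' sapply(k, function(x) min(x$gain))
#' @export
model_kernels <- function(suppression_depth = 0.25, enhancement_depth = 0.25,
                          t_suppression = 80, t_enhancement = 120,
                          width_ms = 40, time_ms = peri_bins()) {
  cong <- gaussian_kernel(suppression_depth, t_suppression, width_ms,
                          time_ms, "congruent")
  inc <- gaussian_kernel(-enhancement_depth, t_enhancement, width_ms,
                         time_ms, "incongruent")
  glob <- suppression_kernel(time_ms, (cong$gain + inc$gain) / 2, "global")
  list(congruent = cong, incongruent = inc, global = glob)
}

# gain of `kernel` at times `t_rel` (ms rel. to saccade onset); 1 outside axis
kernel_gain_at <- function(kernel, t_rel) {
  if (is.null(kernel)) return(rep(1, length(t_rel)))
  approx(kernel$time_ms, kernel$gain, xout = t_rel, rule = 2)$y
}

#' Simulate spike trains from a tuned population
#'
#' Draws Poisson spikes from the instantaneous rate
#' `max(0, gain(t) * (slope_a * heading + intercept_b) + noise)`, where the
#' perisaccadic gain is read from each neuron's assigned kernel in a window
#' around every saccade onset and is 1 elsewhere. Rates are clamped at zero:
#' model neurons cannot have negative firing rates.
#'
#' @param population Tibble from [virtual_population()] (columns `neuron_id`,
#'   `slope_a`, `intercept_b`).
#' @param heading_deg Stimulated heading, deg (rightward positive).
#' @param duration_s Duration of the simulated trial, s.
#' @param saccade_onsets Numeric vector of saccade-onset times, ms.
#' @param kernel_assignment Optional: a single `suppression_kernel` applied to
#'   all neurons, or a list of kernels indexed by neuron (same length as
#'   `nrow(population)`), or `NULL` for identity gain.
#' @param rate_noise_sd Additive Gaussian rate noise SD (spikes/s), redrawn
#'   every `noise_block_ms`; default 0 (pure Poisson).
#' @param noise_block_ms Correlation time of the additive rate noise, ms.
#' @param dt_ms Simulation step, ms.
#' @param seed Optional seed.
#' @return Tibble with `neuron_id`, `time_ms` (one row per spike), sorted.
#' @examples
#' pop <- tibble::tibble(neuron_id = 1, slope_a = 0.108, intercept_b = 11.77)
#' sp <- simulate_spike_trains(pop, heading_deg = 0, duration_s = 10, seed = 2)
#' nrow(sp) / 10  # close to 11.77 spikes/s
#' @export
simulate_spike_trains <- function(population, heading_deg, duration_s,
                                  saccade_onsets = numeric(0),
                                  kernel_assignment = NULL,
                                  rate_noise_sd = 0, noise_block_ms = 20,
                                  dt_ms = 1, seed = NULL) {
  stopifnot(is.data.frame(population),
            all(c("neuron_id", "slope_a", "intercept_b") %in% names(population)))
  if (duration_s <= 0) abort("`duration_s` must be positive.")
  with_seed(seed, {
    n_steps <- floor(duration_s * 1000 / dt_ms)
    t_grid <- (seq_len(n_steps) - 1) * dt_ms

    # time relative to the governing saccade (NA when outside every window)
    t_rel <- rep(NA_real_, n_steps)
    for (o in saccade_onsets) {
      idx <- which(t_grid >= o - 200 & t_grid < o + 460)
      t_rel[idx] <- t_grid[idx] - o
    }
    in_win <- !is.na(t_rel)

    per_neuron_kernels <- if (is.null(kernel_assignment)) {
      NULL
    } else if (inherits(kernel_assignment, "suppression_kernel")) {
      rep(list(kernel_assignment), nrow(population))
    } else {
      stopifnot(length(kernel_assignment) == nrow(population))
      kernel_assignment
    }

    spikes <- purrr::map_dfr(seq_len(nrow(population)), function(i) {
      base <- population$slope_a[i] * heading_deg + population$intercept_b[i]
      g <- rep(1, n_steps)
      if (!is.null(per_neuron_kernels) && any(in_win)) {
        g[in_win] <- kernel_gain_at(per_neuron_kernels[[i]], t_rel[in_win])
      }
      rate <- g * base
      if (rate_noise_sd > 0) {
        blocks <- floor(t_grid / noise_block_ms)
        noise <- rnorm(max(blocks) + 1, 0, rate_noise_sd)
        rate <- rate + noise[blocks + 1]
      }
      rate <- pmax(0, rate)
      counts <- rpois(n_steps, rate * dt_ms / 1000)
      hit <- which(counts > 0)
      if (!length(hit)) {
        return(tibble::tibble(neuron_id = integer(0), time_ms = numeric(0)))
      }
      times <- rep(t_grid[hit], counts[hit]) + runif(sum(counts[hit]), 0, dt_ms)
      tibble::tibble(neuron_id = population$neuron_id[i], time_ms = sort(times))
    })
    dplyr::arrange(spikes, .data$neuron_id, .data$time_ms)
  })
}
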