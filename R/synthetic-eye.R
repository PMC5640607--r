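# run code under a temporary RNG state when a seed is given
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("`seed` must be a single number or NULL.")
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# minimum-jerk position profile on u in [0,1]; 0 before, 1 after
min_jerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  10 * u^3 - 15 * u^4 + 6 * u^5
}

#' Parameters for the optokinetic-like eye-movement generator
#'
#' Describes the alternation of constant-velocity slow tracking phases and
#' brief resetting saccades that large-field self-motion stimuli evoke.
#' Saccades follow a minimum-jerk position profile whose peak speed is set
#' explicitly, so threshold-based detection can be validated against a
#' controllable speed maximum.
#'
#' @param slow_phase_speed Slow-phase drift speed, deg/s.
#' @param saccade_amplitude_mean Mean saccade amplitude, deg. `0` disables
#'   saccades entirely (pure slow phase).
#' @param saccade_peak_speed Peak saccade speed, deg/s; must exceed the
#'   `speed_criterion` so saccades are detectable.
#' @param intersaccadic_interval_mean Mean interval between saccade launches,
#'   ms. Intervals are exponential with a refractory floor, so intervals long
#'   enough for isolation-eligible snippets (> 650 ms) occur with substantial
#'   probability at the default mean.
#' @param sampling_rate Sampling rate of the trace, Hz.
#' @param speed_criterion Speed criterion (deg/s) used to annotate ground-truth
#'   saccade onsets, matching the detection criterion (default 80).
#' @return A list of class `okn_params`.
#' @export
okn_params <- function(slow_phase_speed = 10,
                       saccade_amplitude_mean = 10,
                       saccade_peak_speed = 300,
                       intersaccadic_interval_mean = 1000,
                       sampling_rate = 500,
                       speed_criterion = 80) {
  if (sampling_rate <= 0) abort("`sampling_rate` must be positive.")
  if (saccade_amplitude_mean > 0 && saccade_peak_speed <= speed_criterion) {
    abort("`saccade_peak_speed` must exceed `speed_criterion` (80 deg/s).")
  }
  if (intersaccadic_interval_mean <= 0) {
    abort("`intersaccadic_interval_mean` must be positive.")
  }
  structure(
    list(
      slow_phase_speed = slow_phase_speed,
      saccade_amplitude_mean = saccade_amplitude_mean,
      saccade_peak_speed = saccade_peak_speed,
      intersaccadic_interval_mean = intersaccadic_interval_mean,
      sampling_rate = sampling_rate,
      speed_criterion = speed_criterion
    ),
    class = "okn_params"
  )
}

#' Simulate an optokinetic-like eye trace
#'
#' Generates a uniformly sampled 2-D gaze trace alternating constant-velocity
#' slow phases with brief, high-speed resetting saccades, together with the
#' ground-truth saccade list used to validate the detector. Ground-truth
#' `onset_ms`/`offset_ms` are the times at which the analytic eye speed
#' crosses the speed criterion (the field's definition of saccade onset);
#' `launch_ms` is the kinematic start of the movement.
#'
#' @param params An [okn_params()] object.
#' @param duration_s Trace duration in seconds.
#' @param seed Optional integer seed for reproducibility.
#' @return A tibble of class `eye_trace` with columns `time_ms`, `x_deg`,
#'   `y_deg`; attributes `sampling_rate` and `saccades` (a tibble with
#'   `launch_ms`, `onset_ms`, `offset_ms`, `amplitude_deg`). Retrieve the
#'   ground truth with [true_saccades()].
#' @examples
#' tr <- simulate_eye_trace(okn_params(), duration_s = 5, seed = 1)
#' nrow(true_saccades(tr))
#' @export
simulate_eye_trace <- function(params = okn_params(), duration_s, seed = NULL) {
  stopifnot(inherits(params, "okn_params"))
  if (!is.numeric(duration_s) || duration_s <= 0) {
    abort("`duration_s` must be a positive number.")
  }
  with_seed(seed, {
    fs <- params$sampling_rate
    dt <- 1000 / fs
    duration_ms <- duration_s * 1000
    time_ms <- seq(0, duration_ms - dt, by = dt)
    v <- params$slow_phase_speed         # deg/s
    home <- -0.5 * v * params$intersaccadic_interval_mean / 1000

    launches <- numeric(0)
    amps <- numeric(0)
    if (params$saccade_amplitude_mean > 0) {
      floor_ms <- min(250, 0.5 * params$intersaccadic_interval_mean)
      # a resetting saccade is due once the slow phase has drifted about one
      # amplitude, which bounds gaze within the central screen region
      cap_ms <- if (v > 0) {
        1000 * 1.2 * params$saccade_amplitude_mean / v
      } else {
        Inf
      }
      t_cur <- 0
      x_cum <- 0                          # cumulated saccadic displacement
      repeat {
        gap <- max(floor_ms,
                   min(rexp(1, 1 / params$intersaccadic_interval_mean),
                       cap_ms))
        t_cur <- t_cur + gap
        if (t_cur >= duration_ms - 100) break
        x_pre <- home + v * t_cur / 1000 + x_cum
        # resetting saccade back toward the home position; skip if the gaze
        # has not drifted enough for a full-sized saccade yet
        step <- (home - x_pre) +
          rnorm(1, 0, 0.05 * params$saccade_amplitude_mean)
        if (abs(step) < 0.3 * params$saccade_amplitude_mean) next
        launches <- c(launches, t_cur)
        amps <- c(amps, step)
        x_cum <- x_cum + step
      }
    }

    durs <- if (length(amps)) 1.875 * abs(amps) / params$saccade_peak_speed * 1000 else numeric(0)

    x <- home + v * time_ms / 1000
    for (j in seq_along(launches)) {
      x <- x + amps[j] * min_jerk((time_ms - launches[j]) / durs[j])
    }
    y <- 0.3 * sin(2 * pi * time_ms / 7000)

    # analytic criterion crossing of the minimum-jerk speed profile:
    # speed(u) = peak * 30 u^2 (1-u)^2 / 1.875 >= criterion
    cc <- 1.875 * params$speed_criterion / params$saccade_peak_speed
    r <- sqrt(cc / 30)
    u_c <- (1 - sqrt(1 - 4 * r)) / 2
    sacc <- tibble::tibble(
      launch_ms = launches,
      onset_ms = launches + u_c * durs,
      offset_ms = launches + (1 - u_c) * durs,
      amplitude_deg = abs(amps)
    )

    out <- tibble::tibble(time_ms = time_ms, x_deg = x, y_deg = y)
    class(out) <- c("eye_trace", class(out))
    attr(out, "sampling_rate") <- fs
    attr(out, "saccades") <- sacc
    out
  })
}

#' Ground-truth saccades of a simulated eye trace
#'
#' @param trace An `eye_trace` from [simulate_eye_trace()].
#' @return Tibble with `launch_ms`, `onset_ms`, `offset_ms`, `amplitude_deg`.
#' @export
true_saccades <- function(trace) {
  s <- attr(trace, "saccades")
  if (is.null(s)) abort("`trace` carries no ground-truth saccade list.")
  s
}

#' Sampling rate of an eye trace
#'
#' Returns the stored sampling rate, or infers it from the time stamps.
#'
#' @param trace A data frame with a `time_ms` column.
#' @return Sampling rate in Hz.
#' @export
trace_sampling_rate <- function(trace) {
  fs <- attr(trace, "sampling_rate")
  if (!is.null(fs)) return(fs)
  dt <- diff(trace$time_ms)
  1000 / median(dt)
}
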