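# truncated running mean of k consecutive samples, assigned to the centre
running_mean_k <- function(x, k = 5) {
  n <- length(x)
  half <- (k - 1) %/% 2
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

#' Perceived-heading time course
#'
#' For each stimulus heading, orders the reports by stimulus-onset time
#' relative to saccade onset and smooths them with a running mean of five
#' consecutive trials assigned to the central sample (truncated at the
#' series edges). Headings with fewer than `k` trials keep their raw
#' reports and are flagged.
#'
#' @param trials Behavioral trials with `onset_ms`, `true_heading_deg`,
#'   `reported_heading_deg`.
#' @param k Running-mean width in trials (default 5).
#' @return Tibble with `true_heading_deg`, `onset_ms`,
#'   `reported_heading_deg` (raw), `smoothed_deg`, `enough_trials`.
#' @export
perceived_timecourse <- function(trials, k = 5) {
  stopifnot(all(c("onset_ms", "true_heading_deg", "reported_heading_deg")
                %in% names(trials)))
  trials |>
    dplyr::arrange(.data$true_heading_deg, .data$onset_ms) |>
    dplyr::group_by(.data$true_heading_deg) |>
    dplyr::group_modify(function(d, key) {
      enough <- nrow(d) >= k
      d$smoothed_deg <- if (enough) {
        running_mean_k(d$reported_heading_deg, k)
      } else {
        NA_real_
      }
      d$enough_trials <- enough
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::select("true_heading_deg", "onset_ms", "reported_heading_deg",
                  "smoothed_deg", "enough_trials")
}

#' Fixation reference percepts
#'
#' Mean reported heading per stimulus heading in fixation trials, the
#' reference against which perisaccadic percepts are compared.
#'
#' @param trials Fixation-condition trials.
#' @return Tibble with `true_heading_deg`, `mean_reported_deg`, `n`.
#' @export
fixation_reference <- function(trials) {
  trials |>
    dplyr::summarise(mean_reported_deg = mean(.data$reported_heading_deg),
                     n = dplyr::n(), .by = "true_heading_deg")
}

# interpolate each heading's smoothed series onto a regular onset grid
grid_timecourses <- function(tc, grid_step_ms, range_ms) {
  grid <- seq(range_ms[1], range_ms[2], by = grid_step_ms)
  tc |>
    dplyr::filter(.data$enough_trials) |>
    dplyr::group_by(.data$true_heading_deg) |>
    dplyr::group_modify(function(d, key) {
      tibble::tibble(
        time_ms = grid,
        value_deg = approx(d$onset_ms, d$smoothed_deg, xout = grid,
                           rule = 2)$y
      )
    }) |>
    dplyr::ungroup()
}

#' Behavioral compression curve
#'
#' Computes the normalized SD of the perceived-heading time courses across
#' the stimulus headings: reports are smoothed per heading
#' ([perceived_timecourse()]), interpolated onto a common onset-time grid
#' (default 2.5 ms, the typical trial spacing), and the per-time SD across
#' headings is divided by its mean at times at least 100 ms away from
#' saccade onset. The time of maximum compression is the argmin.
#'
#' @param trials Saccade-condition behavioral trials.
#' @param grid_step_ms Common time grid step, ms.
#' @param range_ms Onset-time range covered, ms.
#' @param norm_windows Normalization windows (ms, half-open); default all
#'   times <= -100 ms or >= +100 ms.
#' @param k Running-mean width in trials.
#' @param min_depth Curves whose depth (1 - minimum) is below this are not
#'   assigned a meaningful argmin (`t_max_compression` is `NA`).
#' @return A [compression_curve()] on the behavioral grid.
#' @export
behavioral_compression <- function(trials, grid_step_ms = 2.5,
                                   range_ms = c(-200, 200),
                                   norm_windows = list(c(-Inf, -100),
                                                       c(100, Inf)),
                                   k = 5, min_depth = 0.05) {
  tc <- perceived_timecourse(trials, k = k)
  gridded <- grid_timecourses(tc, grid_step_ms, range_ms)
  if (length(unique(gridded$true_heading_deg)) < 2) {
    abort("Need smoothed series for at least 2 headings.")
  }
  curve <- compression_curve(gridded, value = "value_deg",
                             group = "true_heading_deg",
                             norm_windows = norm_windows,
                             flat_tol = 1e-9)
  depth <- 1 - attr(curve, "min_normalized_sd")
  if (is.na(depth) || depth < min_depth) {
    attr(curve, "t_max_compression") <- NA_real_
    attr(curve, "flat") <- TRUE
  }
  curve
}

#' Pooled-SD effect size between two performance sets
#'
#' `d' = (mean_prepost - mean_peri) / combined SD`, with the combined SD the
#' usual pooled estimate
#' `sqrt(((n1-1) sd1^2 + (n2-1) sd2^2) / (n1 + n2 - 2))`.
#'
#' @param mean_prepost,mean_peri Mean performance outside / inside the
#'   perisaccadic window.
#' @param sd1,sd2 SDs of the two sets.
#' @param n1,n2 Sample counts of the two sets.
#' @return One-row tibble: `d_prime`, `combined_std`, plus the inputs.
#'   Zero pooled SD yields 0 for equal means and (flagged) `Inf` otherwise.
#' @examples
#' pooled_sd_dprime(0.97, 0.95, 0.1, 0.1, 50, 50)$d_prime  # 0.2
#' @export
pooled_sd_dprime <- function(mean_prepost, mean_peri, sd1, sd2, n1, n2) {
  if (n1 + n2 < 3) abort("Need at least 3 samples in total.")
  combined <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  diff <- mean_prepost - mean_peri
  d <- if (combined > 0) diff / combined else if (diff == 0) 0 else Inf * sign(diff)
  tibble::tibble(
    d_prime = d, combined_std = combined,
    mean_prepost = mean_prepost, mean_peri = mean_peri,
    std1 = sd1, std2 = sd2, n1 = n1, n2 = n2,
    degenerate = combined == 0 && diff != 0
  )
}

#' Perisaccadic discriminability of forward vs. backward self-motion
#'
#' Splits 2-AFC discrimination trials into a perisaccadic window (stimulus
#' onset within `peri_ms` of saccade onset) and the remaining, fixation-like
#' onsets, computes per-subject percent correct in each window, and the
#' pooled-SD effect size between the two (Eq. form in
#' [pooled_sd_dprime()]).
#'
#' @param trials Tibble with `subject`, `onset_ms`, `correct` (0/1).
#' @param peri_ms Perisaccadic half-window, ms (default 50).
#' @return One-row tibble with percent correct in each window (on the 0-100
#'   scale), the per-subject SDs, and `d_prime`.
#' @export
discrimination_dprime <- function(trials, peri_ms = 50) {
  stopifnot(all(c("subject", "onset_ms", "correct") %in% names(trials)))
  perf <- trials |>
    dplyr::mutate(window = ifelse(abs(.data$onset_ms) < peri_ms,
                                  "peri", "prepost")) |>
    dplyr::summarise(pct = mean(.data$correct),
                     .by = c("subject", "window"))
  pre <- dplyr::filter(perf, .data$window == "prepost")$pct
  peri <- dplyr::filter(perf, .data$window == "peri")$pct
  if (!length(pre) || !length(peri)) {
    abort("Both the perisaccadic and the pre/post window must contain trials.")
  }
  res <- pooled_sd_dprime(mean(pre), mean(peri),
                          sd(pre), sd(peri),
                          length(pre), length(peri))
  dplyr::mutate(res,
                pct_correct_prepost = 100 * .data$mean_prepost,
                pct_correct_peri = 100 * .data$mean_peri)
}

#' Latency between neural and behavioral compression
#'
#' Resamples two compression curves onto a common grid (the neural 20 ms
#' resolution by default; finer curves are block-averaged) and finds the
#' temporal shift maximizing their Pearson correlation. Positive `tau_ms`
#' means the neural curve lags the behavioral one, i.e.
#' `neural(t) ~ behavioral(t - tau)` - the neuronal processing latency.
#'
#' @param neural,behavioral Data frames with `time_ms` and `normalized_sd`
#'   (any [compression_curve()] works).
#' @param lag_range Searched lags, ms.
#' @param grid_ms Common grid step, ms.
#' @param min_overlap Minimum number of overlapping samples per lag.
#' @return Tibble of class `latency_estimate` with one row (`tau_ms`,
#'   `peak_correlation`) and the full correlation-by-lag table in the
#'   `correlations` attribute.
#' @export
cross_correlate_compression <- function(neural, behavioral,
                                        lag_range = c(-200, 200),
                                        grid_ms = 20, min_overlap = 5) {
  resample <- function(curve) {
    t0 <- floor(min(curve$time_ms) / grid_ms) * grid_ms
    t1 <- ceiling(max(curve$time_ms) / grid_ms) * grid_ms
    grid <- seq(t0, t1, by = grid_ms)
    bin <- grid[findInterval(curve$time_ms, c(grid, t1 + grid_ms))]
    out <- tapply(curve$normalized_sd, bin, mean)
    tibble::tibble(time_ms = as.numeric(names(out)), value = as.numeric(out))
  }
  a <- resample(neural); b <- resample(behavioral)
  if (sd(a$value) == 0 || sd(b$value) == 0) {
    abort("Flat compression curve: the cross-correlation lag is undefined.")
  }
  lags <- seq(ceiling(lag_range[1] / grid_ms) * grid_ms,
              floor(lag_range[2] / grid_ms) * grid_ms, by = grid_ms)
  cors <- vapply(lags, function(l) {
    m <- dplyr::inner_join(a, dplyr::mutate(b, time_ms = .data$time_ms + l),
                           by = "time_ms", suffix = c("_a", "_b"))
    if (nrow(m) < min_overlap || sd(m$value_a) == 0 || sd(m$value_b) == 0) {
      return(NA_real_)
    }
    cor(m$value_a, m$value_b)
  }, numeric(1))
  if (all(is.na(cors))) abort("No lag had enough overlapping samples.")
  best <- which.max(cors)
  out <- tibble::tibble(tau_ms = lags[best], peak_correlation = cors[best])
  class(out) <- c("latency_estimate", class(out))
  attr(out, "correlations") <- tibble::tibble(lag_ms = lags,
                                              correlation = cors)
  out
}

#' Reference frame of the compression centre
#'
#' Contrasts two offset conditions - head turned with gaze straight, and
#' gaze turned with head straight - to classify the centre toward which
#' percepts compress. For each condition the across-heading mean percept is
#' tracked over time, the compression curve locates the time of maximum
#' compression, and the mean percept at that time is compared with the two
#' predicted centres: the straight-ahead direction (0 deg: screen, body, and
#' whichever of head/gaze is not offset) and the offset direction. An
#' eye-centred compression follows the gaze offset but not the head offset.
#'
#' @param gaze_trials Saccade trials from the gaze-offset condition
#'   (`alpha_deg` nonzero, `head_deg` 0).
#' @param head_trials Saccade trials from the head-offset condition
#'   (`head_deg` nonzero, `alpha_deg` 0).
#' @param grid_step_ms,range_ms,k Passed to the behavioral gridding.
#' @return List of class `reference_frame_result`: `conditions` (per
#'   condition: offset, time of max compression, compression centre, nearest
#'   predicted centre) and `conclusion` (`"eye-centered"`,
#'   `"head-centered"`, `"screen/body-centered"`, `"indistinguishable"` or
#'   `"mixed"`).
#' @export
reference_frame_analysis <- function(gaze_trials, head_trials,
                                     grid_step_ms = 2.5,
                                     range_ms = c(-200, 200), k = 5) {
  one <- function(trials, condition, offset) {
    tc <- grid_timecourses(perceived_timecourse(trials, k = k),
                           grid_step_ms, range_ms)
    curve <- compression_curve(tc, value = "value_deg",
                               group = "true_heading_deg",
                               norm_windows = list(c(-Inf, -100),
                                                   c(100, Inf)))
    t_star <- t_max_compression(curve)
    mean_series <- tc |>
      dplyr::summarise(mean_deg = mean(.data$value_deg), .by = "time_ms")
    center <- if (is.na(t_star)) {
      NA_real_
    } else {
      mean_series$mean_deg[which.min(abs(mean_series$time_ms - t_star))]
    }
    nearest <- if (is.na(center) || offset == 0) {
      "indistinguishable"
    } else if (abs(center - offset) < abs(center - 0)) {
      "offset"
    } else {
      "straight"
    }
    tibble::tibble(condition = condition, offset_deg = offset,
                   t_max_compression_ms = t_star, center_deg = center,
                   nearest = nearest)
  }
  ga <- unique(gaze_trials$alpha_deg)
  ho <- unique(head_trials$head_deg)
  if (length(ga) != 1 || length(ho) != 1) {
    abort("Each condition must have a single constant offset.")
  }
  cond <- dplyr::bind_rows(
    one(gaze_trials, "gaze_offset", ga),
    one(head_trials, "head_offset", ho)
  )
  gaze_follows <- cond$nearest[cond$condition == "gaze_offset"]
  head_follows <- cond$nearest[cond$condition == "head_offset"]
  conclusion <- if (gaze_follows == "indistinguishable" &&
                    head_follows == "indistinguishable") {
    "indistinguishable"
  } else if (identical(gaze_follows, "offset") &&
             head_follows %in% c("straight", "indistinguishable")) {
    "eye-centered"
  } else if (identical(head_follows, "offset") &&
             gaze_follows %in% c("straight", "indistinguishable")) {
    "head-centered"
  } else if (identical(gaze_follows, "straight") &&
             identical(head_follows, "straight")) {
    "screen/body-centered"
  } else {
    "mixed"
  }
  structure(list(conditions = cond, conclusion = conclusion),
            class = "reference_frame_result")
}

#' @export
print.reference_frame_result <- function(x, ...) {
  cat("Reference-frame analysis of perisaccadic heading compression\n")
  print(x$conditions)
  cat("conclusion:", x$conclusion, "\n")
  invisible(x)
}
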