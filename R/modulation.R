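#' Mean-subtracted perisaccadic response modulation
#'
#' Subtracts each response's mean rate over the full perisaccadic window
#' from its time-resolved rate, leaving the modulation around the neuron's
#' own mean (which sums to zero across bins by construction).
#'
#' @param binned Data frame with `time_ms` and `rate_hz`.
#' @param by Grouping columns (defaults to whichever of `neuron_id`,
#'   `heading_deg`, `condition` are present).
#' @return Input with a `modulation_hz` column.
#' @export
response_modulation <- function(binned,
                                by = intersect(c("neuron_id", "heading_deg",
                                                 "condition"),
                                               names(binned))) {
  dplyr::mutate(binned,
                modulation_hz = .data$rate_hz - mean(.data$rate_hz),
                .by = dplyr::all_of(by))
}

#' Bootstrap confidence band for a population time course
#'
#' Per-bin mean across neurons with a percentile confidence interval from
#' resampling neurons with replacement (default 1000 resamples, 95% level).
#' The resampling unit is the neuron, matching population-level inference.
#'
#' @param timecourses Data frame with `neuron_id`, `time_ms`, and the value
#'   column.
#' @param value Name of the value column (default `"modulation_hz"`).
#' @param n_boot Number of bootstrap resamples.
#' @param level Confidence level.
#' @param seed Optional seed.
#' @return Tibble of class `modulation_timecourse`: `time_ms`, `mean`,
#'   `ci_low`, `ci_high`, `n_neurons`.
#' @export
bootstrap_ci <- function(timecourses, value = "modulation_hz",
                         n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(all(c("neuron_id", "time_ms", value) %in% names(timecourses)))
  ids <- unique(timecourses$neuron_id)
  if (length(ids) < 2) abort("Need at least 2 neurons to bootstrap.")
  if (n_boot < 100) warn("`n_boot` < 100: confidence intervals will be noisy.")
  wide <- timecourses |>
    dplyr::select("neuron_id", "time_ms", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "time_ms", values_from = dplyr::all_of(value))
  mat <- as.matrix(wide[, -1, drop = FALSE])
  times <- as.numeric(colnames(mat))
  n <- nrow(mat)
  with_seed(seed, {
    boots <- matrix(NA_real_, n_boot, ncol(mat))
    for (b in seq_len(n_boot)) {
      boots[b, ] <- colMeans(mat[sample.int(n, n, replace = TRUE), ,
                                 drop = FALSE], na.rm = TRUE)
    }
    a <- (1 - level) / 2
    out <- tibble::tibble(
      time_ms = times,
      mean = unname(colMeans(mat, na.rm = TRUE)),
      ci_low = apply(boots, 2, quantile, probs = a, na.rm = TRUE),
      ci_high = apply(boots, 2, quantile, probs = 1 - a, na.rm = TRUE),
      n_neurons = n
    ) |>
      dplyr::arrange(.data$time_ms)
    class(out) <- c("modulation_timecourse", class(out))
    out
  })
}

#' Assign responses to the congruent and incongruent conditions
#'
#' Each tuned neuron contributes its response to the heading it prefers
#' (slope sign) to the congruent condition and its response to the opposite
#' heading to the incongruent condition: a leftward-tuned neuron is
#' congruent during leftward self-motion and incongruent during rightward
#' self-motion, and vice versa. Straight-ahead responses are unused; zero
#' slopes are excluded. Every included neuron appears exactly once in each
#' condition.
#'
#' @param binned Binned rates with `neuron_id`, `heading_deg`, `time_ms`,
#'   `rate_hz`.
#' @param fits Per-neuron fits with `slope_a` (use the significantly tuned
#'   ones).
#' @param left_heading,right_heading Headings used as the leftward /
#'   rightward stimulus (default: most extreme negative / positive heading
#'   present).
#' @return `binned` rows for the two headings with a `condition` column
#'   (`"congruent"` / `"incongruent"`).
#' @export
assign_conditions <- function(binned, fits,
                              left_heading = NULL, right_heading = NULL) {
  hs <- sort(unique(binned$heading_deg))
  left_heading <- left_heading %||% min(hs)
  right_heading <- right_heading %||% max(hs)
  if (left_heading >= 0 || right_heading <= 0) {
    abort("Need one negative (leftward) and one positive (rightward) heading.")
  }
  use <- dplyr::filter(fits, .data$slope_a != 0)
  if ("significant_tuning" %in% names(use)) {
    use <- dplyr::filter(use, .data$significant_tuning)
  }
  binned |>
    dplyr::filter(.data$heading_deg %in% c(left_heading, right_heading)) |>
    dplyr::inner_join(dplyr::select(use, "neuron_id", "slope_a"),
                      by = "neuron_id") |>
    dplyr::mutate(
      preferred = ifelse(.data$slope_a < 0, left_heading, right_heading),
      condition = ifelse(.data$heading_deg == .data$preferred,
                         "congruent", "incongruent")
    ) |>
    dplyr::select(-"preferred", -"slope_a")
}

#' Perisaccadic modulation index
#'
#' Ratio of the mean rate in the perisaccadic window (default 40-160 ms
#' after saccade onset) to the mean rate long after the saccade
#' (300-450 ms). 1 means no modulation, below 1 suppression, above 1
#' enhancement. Responses with a zero late-window rate have no defined
#' index and are flagged.
#'
#' @param binned Data frame with `time_ms`, `rate_hz`.
#' @param index_window,late_window Windows in ms (half-open on bin left
#'   edges).
#' @param by Grouping columns (default: those of `neuron_id`, `heading_deg`,
#'   `condition` present).
#' @return Tibble per group: `rate_peri`, `rate_late`, `index`, `defined`.
#' @export
modulation_index <- function(binned, index_window = c(40, 160),
                             late_window = c(300, 450),
                             by = intersect(c("neuron_id", "heading_deg",
                                              "condition"), names(binned))) {
  binned |>
    dplyr::summarise(
      rate_peri = window_mean(.data$time_ms, .data$rate_hz,
                              index_window[1], index_window[2]),
      rate_late = window_mean(.data$time_ms, .data$rate_hz,
                              late_window[1], late_window[2]),
      .by = dplyr::all_of(by)
    ) |>
    dplyr::mutate(
      defined = is.finite(.data$rate_late) & .data$rate_late > 0,
      index = ifelse(.data$defined, .data$rate_peri / .data$rate_late,
                     NA_real_)
    )
}

#' Sign tests and bootstrap CIs for modulation indices
#'
#' Per condition: the median index, a percentile bootstrap CI on the
#' median, and a one-sided sign test against 1.0 - testing for suppression
#' (indices below 1) in the congruent condition and for enhancement (above
#' 1) in the incongruent condition. Ties at exactly 1 are dropped, as usual
#' for a sign test.
#'
#' @param indices Data frame with `condition` and `index` columns.
#' @param sides Named character vector mapping condition to `"below"` or
#'   `"above"` (the direction tested against 1.0).
#' @param n_boot,level Bootstrap settings for the CI on the median.
#' @param seed Optional seed.
#' @return Tibble per condition: `n`, `median`, `ci_low`, `ci_high`,
#'   `p_sign`.
#' @export
index_sign_tests <- function(indices,
                             sides = c(congruent = "below",
                                       incongruent = "above"),
                             n_boot = 1000, level = 0.95, seed = NULL) {
  stopifnot(all(c("condition", "index") %in% names(indices)))
  with_seed(seed, {
    indices |>
      dplyr::filter(is.finite(.data$index)) |>
      dplyr::group_by(.data$condition) |>
      dplyr::group_modify(function(d, key) {
        x <- d$index
        side <- sides[[as.character(key$condition)]] %||% "below"
        non_tie <- x[x != 1]
        hits <- if (side == "below") sum(non_tie < 1) else sum(non_tie > 1)
        p <- if (length(non_tie)) {
          binom.test(hits, length(non_tie), 0.5,
                     alternative = "greater")$p.value
        } else {
          1
        }
        med_boot <- vapply(seq_len(n_boot), function(i) {
          median(sample(x, length(x), replace = TRUE))
        }, numeric(1))
        a <- (1 - level) / 2
        tibble::tibble(
          n = length(x), median = median(x),
          ci_low = quantile(med_boot, a, names = FALSE),
          ci_high = quantile(med_boot, 1 - a, names = FALSE),
          p_sign = p
        )
      }) |>
      dplyr::ungroup()
  })
}

#' Extract normalized gain kernels from condition time courses
#'
#' Turns population rate time courses (in rate units, not mean-subtracted)
#' into multiplicative gain kernels by dividing each course by its flank
#' mean (bins more than 100 ms before or after saccade onset), so flank
#' gain is centred on 1. If a `neuron_id` column is present, rates are
#' first averaged across neurons within each condition.
#'
#' @param timecourses Data frame with `time_ms`, `rate_hz`, and optionally
#'   `condition` and `neuron_id` columns. Without a `condition` column the
#'   single resulting kernel is labelled `"global"`.
#' @param flank_ms Flank half-width, ms.
#' @return Named list of [suppression_kernel()]s, one per condition.
#' @export
extract_kernels <- function(timecourses, flank_ms = 100) {
  stopifnot(all(c("time_ms", "rate_hz") %in% names(timecourses)))
  if (!"condition" %in% names(timecourses)) {
    timecourses$condition <- "global"
  }
  avg <- timecourses |>
    dplyr::summarise(rate_hz = mean(.data$rate_hz),
                     .by = c("condition", "time_ms"))
  labs <- unique(avg$condition)
  setNames(lapply(labs, function(l) {
    d <- dplyr::arrange(dplyr::filter(avg, .data$condition == l),
                        .data$time_ms)
    suppression_kernel(d$time_ms, d$rate_hz, label = l, flank_ms = flank_ms)
  }), labs)
}
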