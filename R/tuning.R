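#' Per-slice firing rates of long trials
#'
#' Splits a trial of given duration into consecutive slices (default
#' 1000 ms) and computes each neuron's firing rate per slice; these slice
#' rates are the replicates for the rank-based tuning test.
#'
#' @param spikes Tibble with `neuron_id`, `time_ms`.
#' @param duration_s Trial duration, s.
#' @param heading_deg Heading stimulated in this trial, deg.
#' @param slice_ms Slice length, ms.
#' @param neuron_ids Neurons to report (defaults to those present).
#' @return Tibble with `neuron_id`, `heading_deg`, `slice`, `rate_hz`.
#' @export
slice_rates <- function(spikes, duration_s, heading_deg, slice_ms = 1000,
                        neuron_ids = NULL) {
  neuron_ids <- neuron_ids %||% sort(unique(spikes$neuron_id))
  n_slices <- floor(duration_s * 1000 / slice_ms)
  if (n_slices < 1) abort("Trial shorter than one slice.")
  grid <- tidyr::expand_grid(neuron_id = neuron_ids, slice = seq_len(n_slices))
  sl <- spikes |>
    dplyr::filter(.data$time_ms < n_slices * slice_ms) |>
    dplyr::mutate(slice = floor(.data$time_ms / slice_ms) + 1) |>
    dplyr::count(.data$neuron_id, .data$slice, name = "n_spikes")
  grid |>
    dplyr::left_join(sl, by = c("neuron_id", "slice")) |>
    dplyr::mutate(
      heading_deg = heading_deg,
      rate_hz = dplyr::coalesce(.data$n_spikes, 0L) / (slice_ms / 1000)
    ) |>
    dplyr::select("neuron_id", "heading_deg", "slice", "rate_hz")
}

#' Rank-based test for heading tuning
#'
#' Kruskal-Wallis ANOVA on ranks of per-slice firing rates across heading
#' groups (chi-square approximation; with three headings the test has
#' 2 degrees of freedom). Midranks resolve ties; when every rate is
#' identical the statistic is 0 and p = 1.
#'
#' @param slices Data frame with `heading_deg` and `rate_hz` (one row per
#'   slice).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n_slices`,
#'   `n_headings`.
#' @examples
#' d <- data.frame(heading_deg = rep(c(-30, 0, 30), each = 3),
#'                 rate_hz = c(1, 2, 3, 11, 12, 13, 21, 22, 23))
#' heading_significance(d)  # H = 7.2
#' @export
heading_significance <- function(slices) {
  stopifnot(is.data.frame(slices),
            all(c("heading_deg", "rate_hz") %in% names(slices)))
  g <- factor(slices$heading_deg)
  if (nlevels(g) < 2) abort("Need at least 2 heading groups.")
  df <- nlevels(g) - 1L
  if (stats::var(slices$rate_hz) == 0 || all(is.na(slices$rate_hz))) {
    # all ranks tied: no evidence against equal distributions
    return(tibble::tibble(statistic = 0, df = df, p_value = 1,
                          n_slices = nrow(slices), n_headings = nlevels(g)))
  }
  k <- kruskal.test(slices$rate_hz, g)
  tibble::tibble(
    statistic = unname(k$statistic), df = df, p_value = k$p.value,
    n_slices = nrow(slices), n_headings = nlevels(g)
  )
}

#' Linear heading-tuning fit
#'
#' Least-squares fit of `rate = slope_a * heading + intercept_b` to the mean
#' post-saccadic rate per heading (the forward model the decoder inverts).
#'
#' @param rates Data frame with `heading_deg` and `rate_hz`, one row per
#'   heading (>= 3 points).
#' @param slope_eps Slopes with `|slope_a| < slope_eps` are flagged as
#'   non-invertible for decoding.
#' @return One-row tibble: `slope_a`, `intercept_b`, `r_squared`, `p_fit`,
#'   `decodable`, `n_points`. On collinear inputs `r_squared` is exactly 1;
#'   with identical rates the slope is 0 and the fit is flagged
#'   non-decodable.
#' @examples
#' fit_linear_tuning(data.frame(heading_deg = c(-30, 0, 30),
#'                              rate_hz = c(8.53, 11.77, 15.01)))
#' @export
fit_linear_tuning <- function(rates, slope_eps = 1e-6) {
  stopifnot(is.data.frame(rates),
            all(c("heading_deg", "rate_hz") %in% names(rates)))
  if (nrow(rates) < 3) abort("Need at least 3 (heading, rate) points.")
  m <- lm(rate_hz ~ heading_deg, data = rates)
  cf <- coef(m)
  ss_tot <- sum((rates$rate_hz - mean(rates$rate_hz))^2)
  ss_res <- sum(m$residuals^2)
  r2 <- if (ss_tot <= 0) 0 else 1 - ss_res / ss_tot
  r2 <- min(max(r2, 0), 1)
  p_fit <- if (ss_tot <= 0) {
    1
  } else if (ss_res <= 1e-12 * ss_tot) {
    0
  } else {
    fstat <- summary(m)$fstatistic
    unname(stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }
  tibble::tibble(
    slope_a = unname(cf["heading_deg"]),
    intercept_b = unname(cf["(Intercept)"]),
    r_squared = r2, p_fit = p_fit,
    decodable = abs(unname(cf["heading_deg"])) >= slope_eps,
    n_points = nrow(rates)
  )
}

#' Tuning tests and fits for a whole population
#'
#' For each neuron, runs the rank test for heading tuning on per-slice rates
#' and fits the linear tuning function to the mean rate in a post-saccadic
#' window (default 300-450 ms) of the perisaccadically binned response.
#'
#' @param binned Perisaccadic rates from [bin_perisaccadic_rates()].
#' @param slices Per-slice rates from [slice_rates()] (rows for all
#'   headings).
#' @param fit_window Post-saccadic window (ms) whose mean rate per heading
#'   feeds the linear fit.
#' @param alpha Significance level for the tuning flag.
#' @param slope_eps Passed to [fit_linear_tuning()].
#' @return Tibble with one row per neuron: fit parameters plus `p_anova` and
#'   `significant_tuning`.
#' @export
fit_population_tuning <- function(binned, slices, fit_window = c(300, 450),
                                  alpha = 0.05, slope_eps = 1e-6) {
  fits <- binned |>
    dplyr::filter(.data$time_ms >= fit_window[1],
                  .data$time_ms < fit_window[2]) |>
    dplyr::summarise(rate_hz = mean(.data$rate_hz),
                     .by = c("neuron_id", "heading_deg")) |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(~ fit_linear_tuning(.x, slope_eps = slope_eps)) |>
    dplyr::ungroup()
  anov <- slices |>
    dplyr::group_by(.data$neuron_id) |>
    dplyr::group_modify(~ heading_significance(.x)) |>
    dplyr::ungroup() |>
    dplyr::select("neuron_id", p_anova = "p_value")
  fits |>
    dplyr::left_join(anov, by = "neuron_id") |>
    dplyr::mutate(significant_tuning = .data$p_anova < alpha)
}

#' Split tuned neurons into left- and rightward-preferring subpopulations
#'
#' Partitions tuning fits by slope sign: negative slopes respond most to
#' leftward headings (subpopulation 1), positive slopes to rightward
#' headings (subpopulation 2); zero slopes are counted separately.
#'
#' @param fits Data frame with a `slope_a` column (typically the
#'   significantly tuned neurons).
#' @return One-row tibble: `n_left`, `n_right`, `n_zero`.
#' @export
split_subpopulations <- function(fits) {
  stopifnot(is.data.frame(fits), "slope_a" %in% names(fits))
  tibble::tibble(
    n_left = sum(fits$slope_a < 0),
    n_right = sum(fits$slope_a > 0),
    n_zero = sum(fits$slope_a == 0)
  )
}
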