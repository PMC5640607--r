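#' Gaussian-in-time compression profile
#'
#' Returns a function `c(t)` giving the fraction of heading eccentricity (in
#' gaze coordinates) that is compressed away for a stimulus presented at
#' `t` ms relative to saccade onset. The profile is Gaussian, peaking just
#' before saccade onset as perceived-heading compression does.
#'
#' @param depth Peak compression fraction in \[0, 1\].
#' @param peak_ms Time of maximal compression, ms relative to saccade onset.
#' @param width_ms Gaussian SD, ms.
#' @return A function mapping time (ms) to a compression fraction in \[0, 1\].
#' @examples
#' cp <- compression_profile_gaussian()
#' cp(c(-200, -5, 200))
#' @export
compression_profile_gaussian <- function(depth = 0.8, peak_ms = -5,
                                         width_ms = 50) {
  if (depth < 0 || depth > 1) abort("`depth` must lie in [0, 1].")
  force(peak_ms); force(width_ms)
  function(t) depth * exp(-(t - peak_ms)^2 / (2 * width_ms^2))
}

#' Parameters of the behavioral trial generator
#'
#' @param headings Tested headings in deg (rightward positive).
#' @param trials_per_heading Trials per heading and condition.
#' @param compression_profile Function of onset time (ms) returning the
#'   compression fraction in \[0, 1\]; see [compression_profile_gaussian()].
#' @param central_bias Unitless shrink of perceived eccentricity toward the
#'   gaze centre present at all times (models the fixation bias toward gaze);
#'   in \[0, 1\], default 0.
#' @param report_noise_sd SD of the report noise, deg.
#' @param gaze_offset Eye-in-head offset `alpha`, deg; shifts the gaze centre
#'   (and hence the centre of compression).
#' @param head_offset Head-on-body offset, deg; does not shift the gaze
#'   centre.
#' @param onset_jitter_ms Half-range of stimulus-onset times, ms; onsets are
#'   uniform on `[-onset_jitter_ms, +onset_jitter_ms]` (default 200).
#' @return List of class `behavioral_params`.
#' @export
behavioral_params <- function(headings = c(-30, -15, 0, 15, 30),
                              trials_per_heading = 200,
                              compression_profile = compression_profile_gaussian(),
                              central_bias = 0,
                              report_noise_sd = 2,
                              gaze_offset = 0,
                              head_offset = 0,
                              onset_jitter_ms = 200) {
  if (!length(headings)) abort("`headings` must be non-empty.")
  if (central_bias < 0 || central_bias > 1) abort("`central_bias` must lie in [0, 1].")
  probe <- compression_profile(seq(-300, 300, by = 10))
  if (any(probe < -1e-9 | probe > 1 + 1e-9)) {
    abort("`compression_profile` must map times into [0, 1].")
  }
  structure(
    list(headings = headings, trials_per_heading = trials_per_heading,
         compression_profile = compression_profile,
         central_bias = central_bias, report_noise_sd = report_noise_sd,
         gaze_offset = gaze_offset, head_offset = head_offset,
         onset_jitter_ms = onset_jitter_ms),
    class = "behavioral_params"
  )
}

#' Simulate behavioral heading-report trials
#'
#' Generates per-trial heading reports under perisaccadic compression toward
#' the gaze centre. In gaze coordinates the reported heading is
#' `gaze + (1 - central_bias) * (1 - c(t_onset)) * (heading - gaze) + noise`,
#' where `c(t)` is the compression profile and the gaze centre equals the
#' eye-in-head offset `gaze_offset` (a head offset leaves it unchanged). In
#' fixation trials no saccade occurs, so `c` is 0 and only the static bias
#' applies.
#'
#' @param params A [behavioral_params()] object.
#' @param condition `"saccade"` or `"fixation"`.
#' @param subject Subject identifier.
#' @param seed Optional seed.
#' @return Tibble with `subject`, `condition`, `onset_ms`,
#'   `true_heading_deg`, `reported_heading_deg`, `alpha_deg`, `head_deg`.
#' @examples
#' p <- behavioral_params(trials_per_heading = 20)
#' tr <- simulate_behavioral_trials(p, seed = 3)
#' dplyr::count(tr, true_heading_deg)
#' @export
simulate_behavioral_trials <- function(params = behavioral_params(),
                                       condition = c("saccade", "fixation"),
                                       subject = "S1", seed = NULL) {
  stopifnot(inherits(params, "behavioral_params"))
  condition <- match.arg(condition)
  with_seed(seed, {
    n <- params$trials_per_heading
    trials <- tidyr::expand_grid(
      true_heading_deg = params$headings,
      rep = seq_len(n)
    )
    m <- nrow(trials)
    onset <- runif(m, -params$onset_jitter_ms, params$onset_jitter_ms)
    comp <- if (condition == "saccade") params$compression_profile(onset) else 0
    gaze <- params$gaze_offset
    ecc <- trials$true_heading_deg - gaze
    report <- gaze + (1 - params$central_bias) * (1 - comp) * ecc +
      rnorm(m, 0, params$report_noise_sd)
    tibble::tibble(
      subject = subject,
      condition = condition,
      onset_ms = onset,
      true_heading_deg = trials$true_heading_deg,
      reported_heading_deg = report,
      alpha_deg = gaze,
      head_deg = params$head_offset
    )
  })
}

#' Simulate forward/backward discrimination trials
#'
#' Two-alternative forced-choice control: each trial is correct with a
#' probability that depends on whether the stimulus fell within the
#' perisaccadic window (|onset| < `peri_ms`). Defaults reproduce near-ceiling
#' performance with a marginal perisaccadic deficit.
#'
#' @param n_trials Trials per subject.
#' @param subjects Subject identifiers.
#' @param p_fixation Probability correct for onsets outside the perisaccadic
#'   window.
#' @param p_peri Probability correct inside the window.
#' @param peri_ms Perisaccadic half-window, ms (default 50).
#' @param onset_jitter_ms Half-range of onsets, ms.
#' @param seed Optional seed.
#' @return Tibble with `subject`, `onset_ms`, `correct` (0/1).
#' @export
simulate_discrimination_trials <- function(n_trials = 400,
                                           subjects = paste0("S", 1:5),
                                           p_fixation = 0.971, p_peri = 0.961,
                                           peri_ms = 50,
                                           onset_jitter_ms = 200,
                                           seed = NULL) {
  with_seed(seed, {
    purrr::map_dfr(subjects, function(s) {
      onset <- runif(n_trials, -onset_jitter_ms, onset_jitter_ms)
      p <- ifelse(abs(onset) < peri_ms, p_peri, p_fixation)
      tibble::tibble(
        subject = s, onset_ms = onset,
        correct = as.integer(runif(n_trials) < p)
      )
    })
  })
}
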