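schema_cols <- list(
  eye_trace = c("time_ms", "x_deg", "y_deg"),
  spikes = c("neuron_id", "time_ms"),
  behavioral = c("subject", "condition", "onset_ms", "true_heading_deg",
                 "reported_heading_deg", "alpha_deg", "head_deg")
)

read_table_checked <- function(path, required) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(out))
  if (length(missing)) {
    abort(paste0("`", path, "` is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out
}

#' Read and write the package's tabular formats
#'
#' Plain CSV with a header row; times in ms, positions and headings in deg.
#' Columns are matched by name (order is irrelevant) and a missing required
#' column is a schema error naming the column. Numeric values round-trip to
#' better than 1e-12 relative precision.
#'
#' @param path File path.
#' @param x Table to write.
#' @return The table (readers) or `path`, invisibly (writers).
#' @name table_io
NULL

#' @rdname table_io
#' @export
read_eye_trace <- function(path) {
  out <- read_table_checked(path, schema_cols$eye_trace)
  class(out) <- c("eye_trace", class(out))
  out
}

#' @rdname table_io
#' @export
write_eye_trace <- function(x, path) {
  readr::write_csv(x[, schema_cols$eye_trace], path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_spike_trains <- function(path) {
  read_table_checked(path, schema_cols$spikes)
}

#' @rdname table_io
#' @export
write_spike_trains <- function(x, path) {
  readr::write_csv(x[, schema_cols$spikes], path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_behavioral_trials <- function(path) {
  read_table_checked(path, schema_cols$behavioral)
}

#' @rdname table_io
#' @export
write_behavioral_trials <- function(x, path) {
  readr::write_csv(x[, schema_cols$behavioral], path)
  invisible(path)
}

#' Write / read a run manifest
#'
#' A YAML manifest recording the seed and every parameter of an analysis
#' run, so the run can be reproduced exactly.
#'
#' @param config Named list of parameters (must include `seed`).
#' @param path Manifest path.
#' @return `path` invisibly; [read_run_manifest()] returns the list.
#' @export
write_run_manifest <- function(config, path) {
  stopifnot(is.list(config), "seed" %in% names(config))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_manifest
#' @export
read_run_manifest <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full synthetic analysis pipeline
#'
#' Chains every stage on synthetic data: simulate an optokinetic-like eye
#' trace and a tuned spiking population per heading (with selective
#' perisaccadic gain), detect saccades, select isolation-eligible snippets,
#' bin perisaccadic rates, test and fit heading tuning, decode the
#' population, compute the compression curve, extract modulation indices
#' and gain kernels, run the global/selective virtual-neuron model, and run
#' the behavioral analyses (compression, cross-correlation latency,
#' forward/backward discriminability). Fully deterministic under `seed`.
#'
#' @param seed Integer seed governing every random draw.
#' @param headings Neural stimulus headings, deg.
#' @param trial_duration_s Duration of each simulated long trial, s.
#' @param population_args Arguments for [virtual_population()].
#' @param kernels Kernel set from [model_kernels()] used both to modulate
#'   the synthetic spikes and in the virtual model.
#' @param n_repetitions Virtual-model repetitions.
#' @param behavioral_args Arguments for [behavioral_params()].
#' @param out_dir Optional directory: stage outputs are written as CSV plus
#'   a YAML manifest.
#' @return List of class `periheading_pipeline` with the stage outputs.
#' @export
run_pipeline <- function(seed,
                         headings = c(-30, 0, 30),
                         trial_duration_s = 60,
                         population_args = list(),
                         kernels = model_kernels(),
                         n_repetitions = 50,
                         behavioral_args = list(trials_per_heading = 200),
                         out_dir = NULL) {
  with_seed(seed, {
    pop <- do.call(virtual_population, population_args)

    neural <- purrr::map(headings, function(h) {
      trace <- simulate_eye_trace(okn_params(), trial_duration_s)
      assign <- lapply(pop$slope_a, function(a) {
        if (h == 0) {
          suppression_kernel(kernels$congruent$time_ms,
                             (kernels$congruent$gain +
                                kernels$incongruent$gain) / 2, "mixed")
        } else if (sign(a) == sign(h)) {
          kernels$congruent
        } else {
          kernels$incongruent
        }
      })
      spikes <- simulate_spike_trains(
        pop, h, trial_duration_s,
        saccade_onsets = true_saccades(trace)$onset_ms,
        kernel_assignment = assign
      )
      saccades <- detect_saccades(trace)
      snippets <- select_snippets(saccades, trace, schedule = h)
      list(heading = h, trace = trace, spikes = spikes, snippets = snippets)
    })

    binned <- purrr::map_dfr(neural, function(x) {
      if (!nrow(x$snippets)) return(NULL)
      bin_perisaccadic_rates(x$spikes, x$snippets,
                             neuron_ids = pop$neuron_id)
    })
    slices <- purrr::map_dfr(neural, function(x) {
      slice_rates(x$spikes, trial_duration_s, x$heading,
                  neuron_ids = pop$neuron_id)
    })

    fits <- fit_population_tuning(binned, slices)
    decoded <- decode_neurons(binned, fits)
    population_decoded <- decode_population(decoded)
    separation <- binwise_separation_test(decoded)
    neural_compression <- compression_curve(population_decoded)

    conditions <- assign_conditions(binned, fits)
    indices <- modulation_index(conditions, by = c("neuron_id", "condition"))
    sign_tests <- index_sign_tests(indices)
    kernel_estimates <- extract_kernels(
      dplyr::bind_rows(
        conditions,
        dplyr::mutate(conditions, condition = "global")
      )
    )

    model_global <- run_suppression_model("global", kernels,
                                          n_repetitions = n_repetitions,
                                          population_args = population_args)
    model_selective <- run_suppression_model("selective", kernels,
                                             n_repetitions = n_repetitions,
                                             population_args = population_args)

    bp <- do.call(behavioral_params, behavioral_args)
    trials_sacc <- simulate_behavioral_trials(bp, "saccade")
    trials_fix <- simulate_behavioral_trials(bp, "fixation")
    behav_compression <- behavioral_compression(trials_sacc)
    latency <- cross_correlate_compression(neural_compression,
                                           behav_compression)
    disc <- discrimination_dprime(simulate_discrimination_trials())

    results <- structure(
      list(
        population = pop, binned = binned, fits = fits,
        decoded = population_decoded, separation = separation,
        neural_compression = neural_compression,
        indices = indices, sign_tests = sign_tests,
        kernel_estimates = kernel_estimates,
        model = compare_modes(model_global, model_selective),
        behavioral_trials = dplyr::bind_rows(trials_sacc, trials_fix),
        behavioral_compression = behav_compression,
        latency = latency, discrimination = disc,
        config = list(seed = seed, headings = headings,
                      trial_duration_s = trial_duration_s,
                      n_repetitions = n_repetitions)
      ),
      class = "periheading_pipeline"
    )
    if (!is.null(out_dir)) write_pipeline_outputs(results, out_dir)
    results
  })
}

# write the tabular stage outputs plus a manifest
write_pipeline_outputs <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(out_dir, paste0(name, ".csv")))
  }
  w(results$fits, "tuning_fits")
  w(results$decoded, "decoded_heading")
  w(tibble::as_tibble(results$neural_compression), "neural_compression")
  w(results$indices, "modulation_indices")
  w(results$model, "model_summary")
  w(results$behavioral_trials[, schema_cols$behavioral], "behavioral_trials")
  w(tibble::as_tibble(results$behavioral_compression),
    "behavioral_compression")
  write_run_manifest(results$config, file.path(out_dir, "manifest.yml"))
  invisible(out_dir)
}

#' @export
print.periheading_pipeline <- function(x, ...) {
  cat("periheading pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  neurons:", nrow(x$population),
      " tuned:", sum(x$fits$significant_tuning), "\n")
  cat("  neural compression min:",
      signif(attr(x$neural_compression, "min_normalized_sd"), 3),
      "at", t_max_compression(x$neural_compression), "ms\n")
  cat("  behavioral compression min at",
      t_max_compression(x$behavioral_compression), "ms\n")
  cat("  cross-correlation latency:", x$latency$tau_ms, "ms\n")
  invisible(x)
}
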