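# Convenience glue between the raw trace table and the analysis stages:
# dataset-wide normalization, summed post-switch activities, and stacked
# trial averages.

#' Ground-state normalize every trace of a dataset
#'
#' Applies [detect_ground_state()] and F/F_G normalization per (neuron,
#' animal) trace, adding a `value` column.
#'
#' @param dataset A `wm_trace_dataset` or validated trace tibble.
#' @param kernel_frames Smoothing window for ground-state detection.
#' @return The trace tibble with a `value` column (F/F_G).
#' @export
normalize_dataset <- function(dataset, kernel_frames = 20) {
  traces <- if (inherits(dataset, "wm_trace_dataset")) dataset$traces
            else dataset
  traces |>
    dplyr::group_by(.data$neuron_id, .data$animal_id) |>
    dplyr::mutate(value = .data$intensity /
                    detect_ground_state(.data$intensity, kernel_frames)) |>
    dplyr::ungroup()
}

#' Summed post-switch activities per animal, neuron and switch
#'
#' The summary statistic feeding the comparison design: per trace, the
#' normalized activity summed over a window after each stimulus switch.
#'
#' @param dataset A `wm_trace_dataset`.
#' @param window_s Integration window in seconds (default 10).
#' @param switch_type Which switches to use (`"all"`, `"but_on"`,
#'   `"but_off"`).
#' @param normalized Optional pre-normalized trace tibble (with `value`)
#'   to avoid recomputing ground states.
#' @return Tibble `neuron_id`, `group`, `animal_id`, `switch_index`,
#'   `integrated`.
#' @export
summed_activities <- function(dataset, window_s = 10, switch_type = "all",
                              normalized = NULL) {
  traces <- normalized %||% normalize_dataset(dataset)
  sched <- dataset$schedule
  traces |>
    dplyr::group_by(.data$neuron_id, .data$group, .data$animal_id) |>
    dplyr::group_modify(function(df, key) {
      integrate_post_switch(df$value, df$time, sched, window_s,
                            switch_type)[, c("switch_index", "integrated")]
    }) |>
    dplyr::ungroup()
}

#' Trial-averaged activities for a set of neurons
#'
#' Stacks [trial_average()] over neurons on the ground-state-normalized
#' dataset.
#'
#' @param dataset A `wm_trace_dataset`.
#' @param neurons Neuron ids (default all).
#' @param window_s Post-switch window in seconds (default 15).
#' @param switch_type Switch type anchoring the windows.
#' @return Tibble as from [trial_average()], stacked over neurons.
#' @export
trial_average_all <- function(dataset, neurons = NULL, window_s = 15,
                              switch_type = "but_on") {
  traces <- normalize_dataset(dataset)
  neurons <- neurons %||% unique(traces$neuron_id)
  dplyr::bind_rows(lapply(neurons, function(nrn) {
    trial_average(traces, nrn, dataset$schedule, window_s, switch_type)
  }))
}
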