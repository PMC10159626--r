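# Trace normalization and feature extraction: ground-state detection,
# F/F_G and dF/F_max normalization, linear resampling, time derivative,
# post-switch integration, and bin + z-normalize feature vectors.

#' Detect the ground state of a fluorescence trace
#'
#' For long recordings the ground state F_G is the mean of the smoothed
#' intensity values lying strictly below the 10% quantile of the smoothed
#' trace, where smoothing is a centered 20-frame moving average (edge
#' truncated). If no smoothed value lies strictly below the quantile (e.g. a
#' constant trace), the quantile value itself is returned.
#'
#' @param intensity Numeric vector of raw fluorescence values.
#' @param kernel_frames Smoothing window in frames (default 20).
#' @param quantile Quantile level (default 0.10); linear-interpolation
#'   (type 7) quantile of the smoothed values.
#' @return The scalar ground state F_G.
#' @export
#' @examples
#' detect_ground_state(c(rep(1, 30), rep(5, 10)))
detect_ground_state <- function(intensity, kernel_frames = 20,
                                quantile = 0.10) {
  if (length(intensity) < kernel_frames) {
    wm_abort(paste0("trace must have at least ", kernel_frames,
                    " frames for ground-state detection"),
             "wm_validation_error")
  }
  if (!all(is.finite(intensity))) {
    wm_abort("intensity must be finite", "wm_validation_error")
  }
  sm <- moving_average(intensity, kernel_frames)
  q <- stats::quantile(sm, quantile, names = FALSE, type = 7)
  below <- sm[sm < q]
  if (length(below) == 0) return(q)
  mean(below)
}

#' Ground state from the trailing frames of a recording
#'
#' For short recordings where the neuron resumes its pre-exposure baseline
#' by the end, the ground state is the mean of the last `n_frames` values.
#'
#' @param intensity Numeric vector of raw fluorescence values.
#' @param n_frames Number of trailing frames (default 10).
#' @return The scalar ground state F_G.
#' @export
detect_ground_state_tail <- function(intensity, n_frames = 10) {
  n <- length(intensity)
  if (n < n_frames) {
    wm_abort(paste0("trace must have at least ", n_frames, " frames"),
             "wm_validation_error")
  }
  mean(intensity[(n - n_frames + 1):n])
}

#' Normalize a fluorescence trace
#'
#' Two conventions: `"ground_state"` divides by the ground state (F/F_G, so
#' the baseline maps to 1); `"max"` rescales to (F - F_G)/(F_max - F_G) so
#' the peak maps to 1.
#'
#' @param intensity Numeric vector of raw fluorescence values.
#' @param mode `"ground_state"` or `"max"`.
#' @param F_G Ground state (must be > 0 for ground-state mode); see
#'   [detect_ground_state()] / [detect_ground_state_tail()].
#' @param F_max Maximal fluorescence (required for `"max"`, must exceed F_G).
#' @param time Optional time vector carried through.
#' @return A list of class `normalized_trace` with `values`, `mode`, `F_G`,
#'   `F_max`, `time`.
#' @export
normalize_trace <- function(intensity, mode = c("ground_state", "max"),
                            F_G, F_max = NULL, time = NULL) {
  mode <- match.arg(mode)
  if (mode == "ground_state") {
    if (F_G <= 0) {
      wm_abort(paste0("F_G must be positive for ground-state normalization ",
                      "(got ", F_G, "); consider the tail detector or a ",
                      "manual override"), "wm_validation_error")
    }
    values <- intensity / F_G
  } else {
    if (is.null(F_max) || F_max <= F_G) {
      wm_abort("max mode requires F_max > F_G", "wm_validation_error")
    }
    values <- (intensity - F_G) / (F_max - F_G)
  }
  structure(list(values = values, mode = mode, F_G = F_G,
                 F_max = F_max, time = time),
            class = "normalized_trace")
}

#' Resample traces to a common frame rate by linear interpolation
#'
#' Datasets acquired at mixed rates (2-5 Hz) are brought to a common uniform
#' time base, by default the highest frame rate present. Values are linearly
#' interpolated; no extrapolation occurs beyond each trace's own endpoints.
#'
#' @param traces A validated trace tibble (see [validate_trace_table()]).
#' @param target_rate Target rate in Hz; default is the dataset maximum.
#' @return A trace tibble on the common rate with `frame_rate = target_rate`.
#' @export
resample_linear <- function(traces, target_rate = NULL) {
  target_rate <- target_rate %||% max(traces$frame_rate)
  key <- c("neuron_id", "animal_id", "paradigm", "treatment")
  resample_one <- function(df) {
    if (nrow(df) < 2) {
      wm_abort("cannot resample a trace with fewer than 2 samples",
               "wm_validation_error")
    }
    new_t <- seq(df$time[1], df$time[nrow(df)], by = 1 / target_rate)
    vals <- stats::approx(df$time, df$intensity, xout = new_t)$y
    out <- df[rep(1, length(new_t)), , drop = FALSE]
    out$time <- new_t
    out$intensity <- vals
    out$frame_rate <- target_rate
    out
  }
  traces |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::group_modify(~ resample_one(.x)) |>
    dplyr::ungroup()
}

#' Time derivative of a uniformly sampled trace
#'
#' Optionally smooths with a centered moving average, then takes central
#' finite differences (one-sided at the ends). Output length equals input
#' length. Used for neurons whose sensory-evoked component is best seen in
#' the derivative of the activity (e.g. RIA).
#'
#' @param values Numeric vector of normalized activity.
#' @param time Uniform time base in seconds.
#' @param smooth_frames Moving-average window before differencing (1 = none).
#' @return Numeric vector of derivatives (1/s).
#' @export
time_derivative <- function(values, time, smooth_frames = 1) {
  dt <- diff(time)
  if (length(dt) < 1 || any(abs(dt - dt[1]) > 1e-8 * max(abs(dt)))) {
    wm_abort("time base must be uniform; resample first",
             "wm_validation_error")
  }
  h <- dt[1]
  x <- if (smooth_frames > 1) moving_average(values, smooth_frames) else values
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * h)
  d[1] <- (x[2] - x[1]) / h
  d[n] <- (x[n] - x[n - 1]) / h
  d
}

#' Integrate activity after each stimulus switch
#'
#' Sums the samples of a normalized trace in `[switch, switch + window)` for
#' each switch of the schedule. The default 10 s window follows the standard
#' post-exchange integration; per-neuron overrides are supported because
#' integration times are neuron-specific.
#'
#' @param values Numeric activity vector.
#' @param time Time base in seconds.
#' @param schedule A [stim_schedule()].
#' @param window_s Integration window in seconds (default 10).
#' @param switch_type Which switches to integrate over (`"all"`, `"but_on"`,
#'   `"but_off"`).
#' @return Tibble with `switch_index`, `switch_time`, `switch_type`,
#'   `window_s`, `integrated` (sum of samples in the window).
#' @export
integrate_post_switch <- function(values, time, schedule, window_s = 10,
                                  switch_type = "all") {
  sw <- schedule$switches
  if (switch_type != "all") sw <- sw[sw$type == switch_type, , drop = FALSE]
  t_end <- time[length(time)]
  over <- sw$time + window_s > t_end + 1e-9
  if (any(over)) {
    wm_abort(paste0("integration window exceeds recording for switch at ",
                    paste(sw$time[over], collapse = ", "), " s"),
             "wm_validation_error")
  }
  integrated <- vapply(sw$time, function(s) {
    sum(values[time >= s - 1e-9 & time < s + window_s - 1e-9])
  }, numeric(1))
  tibble::tibble(
    switch_index = seq_len(nrow(sw)), switch_time = sw$time,
    switch_type = sw$type, window_s = window_s, integrated = integrated
  )
}

#' Bin a trace and z-normalize the bin means
#'
#' Averages non-overlapping `kernel_frames`-frame bins (a trailing partial
#' bin is dropped) and z-scores the resulting vector (population SD, i.e.
#' divisor n). A zero-variance bin vector maps to all zeros. This is the
#' feature transform used for condition classification.
#'
#' @param values Numeric activity vector.
#' @param kernel_frames Bin width in frames (default 20).
#' @return Numeric feature vector with mean 0 and SD 1 (or all zeros).
#' @export
bin_and_znorm <- function(values, kernel_frames = 20) {
  n_bins <- length(values) %/% kernel_frames
  if (n_bins < 1) {
    wm_abort(paste0("trace shorter than one bin of ", kernel_frames,
                    " frames"), "wm_validation_error")
  }
  idx <- rep(seq_len(n_bins), each = kernel_frames)
  means <- as.vector(tapply(values[seq_along(idx)], idx, mean))
  s <- sqrt(mean((means - mean(means))^2))
  if (s == 0) return(rep(0, n_bins))
  (means - mean(means)) / s
}
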