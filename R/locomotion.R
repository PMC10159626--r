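# Locomotion quantification from 2-D worm tracks: per-segment deviation
# angle, speed and distance to target; reversal detection; and profiles of
# the metrics against distance to the target.

#' Per-segment locomotion metrics of one track
#'
#' Splits a track into non-overlapping `segment_frames`-frame segments. Per
#' segment: the deviation angle is the unsigned angle (degrees, [0, 180])
#' between the segment displacement vector (end minus start position) and
#' the vector from the segment start to the target; 0 means motion directly
#' towards the target and 180 directly away. Speed is the polyline path
#' length divided by the segment duration (cm/min). Distance to target is
#' measured at the segment midpoint. Segments with zero net displacement
#' have no defined angle and are skipped (count reported as an attribute).
#'
#' @param track Tibble with `x`, `y` (cm) per frame, in frame order.
#' @param frame_rate Frames per second.
#' @param target 2-D target coordinates (cm).
#' @param segment_frames Frames per segment (default 24).
#' @param max_duration_s Only the first part of the track is analyzed
#'   (default 600 s, the first 10 min).
#' @return Tibble `segment_index`, `deviation_angle`, `speed_cm_min`,
#'   `distance_to_target`; attribute `n_skipped` counts skipped segments.
#' @export
segment_metrics <- function(track, frame_rate, target,
                            segment_frames = 24, max_duration_s = 600) {
  n_use <- min(nrow(track), floor(max_duration_s * frame_rate) + 1)
  x <- track$x[seq_len(n_use)]
  y <- track$y[seq_len(n_use)]
  if (length(x) < segment_frames) {
    wm_abort(paste0("track shorter than one segment of ", segment_frames,
                    " frames"), "wm_validation_error")
  }
  n_seg <- (length(x) - 1) %/% segment_frames
  rows <- list()
  skipped <- 0L
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1) * segment_frames + 1
    i1 <- i0 + segment_frames
    seg_x <- x[i0:i1]; seg_y <- y[i0:i1]
    v <- c(seg_x[length(seg_x)] - seg_x[1], seg_y[length(seg_y)] - seg_y[1])
    vn <- sqrt(sum(v^2))
    if (vn < 1e-12) {
      skipped <- skipped + 1L
      next
    }
    w <- c(target[1] - seg_x[1], target[2] - seg_y[1])
    wn <- sqrt(sum(w^2))
    ang <- acos(pmin(pmax(sum(v * w) / (vn * wn), -1), 1)) * 180 / pi
    path_len <- sum(sqrt(diff(seg_x)^2 + diff(seg_y)^2))
    dur_min <- segment_frames / frame_rate / 60
    mid <- c(seg_x[ceiling(length(seg_x) / 2)],
             seg_y[ceiling(length(seg_y) / 2)])
    rows[[length(rows) + 1L]] <- tibble::tibble(
      segment_index = s, deviation_angle = ang,
      speed_cm_min = path_len / dur_min,
      distance_to_target = sqrt(sum((mid - target)^2))
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_skipped") <- skipped
  out
}

#' Detect reversal events along a track
#'
#' A reversal starts when the instantaneous displacement vector's projection
#' on the recent heading (a moving average of displacements over the
#' preceding `heading_frames`) is negative beyond `displacement_threshold`,
#' and ends when forward motion resumes. The rate profile reports events
#' per centimeter of track path, binned by distance to the target.
#'
#' @param track Tibble with `x`, `y` (cm) per frame.
#' @param target 2-D target coordinates (cm).
#' @param frame_rate Frames per second.
#' @param heading_frames Window for the recent-heading average (default 24,
#'   one segment).
#' @param displacement_threshold Minimum backward displacement per frame in
#'   cm (default 0.01, i.e. 0.1 mm).
#' @param bin_width Distance-bin width in cm for the rate profile.
#' @param max_duration_s Analyze only the first part of the track.
#' @return A list with `events` (tibble `start_frame`, `end_frame`,
#'   `distance_to_target`), `n_events`, `rate_profile` (tibble
#'   `bin_mid`, `events`, `path_cm`, `rate_per_cm`), `total_rate_per_cm`.
#' @export
detect_reversals <- function(track, target, frame_rate,
                             heading_frames = 24,
                             displacement_threshold = 0.01,
                             bin_width = 0.25, max_duration_s = 600) {
  if (displacement_threshold <= 0 || bin_width <= 0) {
    wm_abort("thresholds must be positive", "wm_config_error")
  }
  n_use <- min(nrow(track), floor(max_duration_s * frame_rate) + 1)
  x <- track$x[seq_len(n_use)]
  y <- track$y[seq_len(n_use)]
  if (length(x) < 3) wm_abort("need at least 3 frames", "wm_validation_error")
  dx <- diff(x); dy <- diff(y)
  hx <- moving_average_trailing(dx, heading_frames)
  hy <- moving_average_trailing(dy, heading_frames)
  hn <- sqrt(hx^2 + hy^2)
  # projection of each displacement on the heading over the preceding window
  proj <- ifelse(hn > 1e-12, (dx * hx + dy * hy) / hn, 0)
  backward <- proj < -displacement_threshold
  # run-length encode backward episodes -> events
  r <- rle(backward)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev_idx <- which(r$values)
  events <- tibble::tibble(
    start_frame = starts[ev_idx], end_frame = ends[ev_idx],
    distance_to_target = sqrt((x[starts[ev_idx]] - target[1])^2 +
                                (y[starts[ev_idx]] - target[2])^2)
  )
  step_len <- sqrt(dx^2 + dy^2)
  d_mid <- sqrt(((x[-length(x)] + x[-1]) / 2 - target[1])^2 +
                  ((y[-length(y)] + y[-1]) / 2 - target[2])^2)
  max_d <- max(d_mid, events$distance_to_target, bin_width)
  edges <- seq(0, max_d + bin_width, by = bin_width)
  bin_of <- function(d) pmin(findInterval(d, edges), length(edges) - 1)
  path_by_bin <- tapply(step_len, bin_of(d_mid), sum)
  ev_by_bin <- if (nrow(events) > 0) {
    table(bin_of(events$distance_to_target))
  } else {
    table(integer(0))
  }
  bins <- sort(unique(c(as.integer(names(path_by_bin)),
                        as.integer(names(ev_by_bin)))))
  profile <- tibble::tibble(
    bin_mid = edges[bins] + bin_width / 2,
    events = as.numeric(ifelse(is.na(ev_by_bin[as.character(bins)]), 0,
                               ev_by_bin[as.character(bins)])),
    path_cm = as.numeric(ifelse(is.na(path_by_bin[as.character(bins)]), 0,
                                path_by_bin[as.character(bins)]))
  )
  profile$rate_per_cm <- ifelse(profile$path_cm > 0,
                                profile$events / profile$path_cm, NA_real_)
  total_path <- sum(step_len)
  list(events = events, n_events = nrow(events), rate_profile = profile,
       total_rate_per_cm = if (total_path > 0) nrow(events) / total_path
                           else NA_real_)
}

# Trailing moving average over the preceding k samples (including current).
moving_average_trailing <- function(x, k) {
  n <- length(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - k + 1L)
  (cs[i + 1L] - cs[lo]) / (i - lo + 1L)
}

#' Profile a segment metric against distance to the target
#'
#' Bins per-segment metrics by distance to the target and reports the
#' per-bin mean and SEM across animals (each animal contributes its own
#' per-bin mean), plus a summary over the proximal region (default
#' 1.2-3.5 cm from the target).
#'
#' @param metrics Tibble of segment metrics with `track_id`,
#'   `distance_to_target`, and the metric column.
#' @param metric Name of the metric column (e.g. `"deviation_angle"`).
#' @param bin_width Bin width in cm (default 0.25).
#' @param proximal Proximal-region interval in cm.
#' @return A list with `profile` (tibble `bin_mid`, `mean`, `sem`, `n`) and
#'   `proximal_mean` (mean over segments in the proximal interval;
#'   `NA` and flagged via `proximal_defined` when empty).
#' @export
distance_profile <- function(metrics, metric = "deviation_angle",
                             bin_width = 0.25, proximal = c(1.2, 3.5)) {
  d <- metrics$distance_to_target
  v <- metrics[[metric]]
  edges <- seq(0, max(d) + bin_width, by = bin_width)
  bin <- pmin(findInterval(d, edges), length(edges) - 1)
  per_animal <- tibble::tibble(track_id = metrics$track_id, bin = bin,
                               v = v) |>
    dplyr::group_by(.data$track_id, .data$bin) |>
    dplyr::summarise(v = mean(.data$v), .groups = "drop")
  profile <- per_animal |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      mean = mean(.data$v),
      sem = stats::sd(.data$v) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::mutate(bin_mid = edges[.data$bin] + bin_width / 2) |>
    dplyr::select("bin_mid", "mean", "sem", "n")
  in_prox <- d >= proximal[1] & d <= proximal[2]
  list(
    profile = profile,
    proximal_mean = if (any(in_prox)) mean(v[in_prox]) else NA_real_,
    proximal_defined = any(in_prox)
  )
}

#' Segment metrics for every track of a dataset
#'
#' Convenience wrapper applying [segment_metrics()] to each track of a
#' `wm_track_dataset`, towards the CS endpoint.
#'
#' @param dataset A `wm_track_dataset` from [gen_track_dataset()].
#' @param target Target coordinates (default: the arena's CS endpoint).
#' @return Tibble of segment metrics with `track_id` and `group` columns.
#' @export
dataset_segment_metrics <- function(dataset, target = NULL) {
  target <- target %||% dataset$arena$cs
  ids <- unique(dataset$tracks$track_id)
  rows <- lapply(ids, function(id) {
    tr <- dataset$tracks[dataset$tracks$track_id == id, ]
    if (nrow(tr) < 25) return(NULL)
    sm <- segment_metrics(tr, dataset$frame_rate, target)
    if (nrow(sm) == 0) return(NULL)
    sm$track_id <- id
    sm$group <- tr$group[1]
    sm
  })
  dplyr::bind_rows(rows)
}
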