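# Synthetic worm-track generator with planted per-group locomotion
# statistics (deviation angle, speed, reversal rate).

#' Arena geometry for the two-choice assay
#'
#' A rectangular arena with a conditioned-stimulus (CS) endpoint, an
#' alternative endpoint, and a start point. The default mirrors the assay
#' layout: worms start 3.5 cm from each target endpoint.
#'
#' @param xlim,ylim Arena extent in cm.
#' @param cs,alt,start 2-D coordinates (cm) of the CS endpoint, alternative
#'   endpoint, and start point.
#' @return A list of class `wm_arena`.
#' @export
arena_geometry <- function(xlim = c(0, 10), ylim = c(0, 6),
                           cs = c(1.5, 3), alt = c(8.5, 3),
                           start = c(5, 3)) {
  inside <- function(p) {
    p[1] >= xlim[1] && p[1] <= xlim[2] && p[2] >= ylim[1] && p[2] <= ylim[2]
  }
  if (!inside(cs) || !inside(alt)) {
    wm_abort("endpoint outside arena", "wm_config_error")
  }
  if (!inside(start)) wm_abort("start point outside arena", "wm_config_error")
  structure(list(xlim = xlim, ylim = ylim, cs = cs, alt = alt, start = start),
            class = "wm_arena")
}

#' Configuration for the synthetic track generator
#'
#' Group locomotion parameters are, per group: a deviation-angle
#' distribution (truncated normal on [0, 180] degrees), a speed distribution
#' (truncated normal, > 0, cm/min) and a mean reversal rate (events per cm
#' of track). Headings are redrawn once per 24-frame segment so the planted
#' distributions are exactly the per-segment quantities that
#' [segment_metrics()] measures.
#'
#' @param group_params Named list (one entry per group) of lists with
#'   elements `angle = c(mean, sd)` degrees, `speed = c(mean, sd)` cm/min,
#'   `reversal_rate` events/cm.
#' @param n_tracks Tracks per group.
#' @param arena An [arena_geometry()].
#' @param frame_rate Frames per second.
#' @param duration_s Maximum track duration in seconds (default 600 s,
#'   the analyzed first 10 min).
#' @param segment_frames Frames per heading segment (default 24).
#' @param reversal_frames Frames of backward motion per reversal event.
#' @param absorb_radius Absorbing radius around each endpoint in cm.
#' @param seed Integer seed.
#' @return A list of class `track_gen_config`.
#' @export
track_gen_config <- function(group_params,
                             n_tracks = 50,
                             arena = arena_geometry(),
                             frame_rate = 3,
                             duration_s = 600,
                             segment_frames = 24,
                             reversal_frames = 2,
                             absorb_radius = 0.3,
                             seed = 1L) {
  stopifnot(inherits(arena, "wm_arena"), length(group_params) >= 1)
  for (g in names(group_params)) {
    p <- group_params[[g]]
    stopifnot(all(c("angle", "speed", "reversal_rate") %in% names(p)))
    if (p$angle[1] < 0 || p$angle[1] > 180 || p$speed[1] <= 0 ||
        p$reversal_rate < 0) {
      wm_abort(paste0("invalid locomotion parameters for group ", g),
               "wm_config_error")
    }
  }
  structure(list(
    group_params = group_params, n_tracks = n_tracks, arena = arena,
    frame_rate = frame_rate, duration_s = duration_s,
    segment_frames = segment_frames, reversal_frames = reversal_frames,
    absorb_radius = absorb_radius, seed = as.integer(seed)
  ), class = "track_gen_config")
}

# Truncated-normal draw by rejection; degenerate when sd == 0.
rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x >= lo & x <= hi
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Generate synthetic worm tracks with planted locomotion statistics
#'
#' Each track starts at the arena start point. Per 24-frame segment the
#' heading is the direction to the CS endpoint rotated by a drawn deviation
#' angle (random sign); frames advance at the drawn speed, with
#' Poisson-drawn reversal events inserting short backward excursions.
#' Tracks are absorbed (stop) within `absorb_radius` of either endpoint and
#' are clamped to the arena.
#'
#' @param config A [track_gen_config()].
#' @return A list of class `wm_track_dataset` with elements `tracks` (tibble
#'   `track_id`, `group`, `frame`, `time`, `x`, `y`), `truth` (per-segment
#'   drawn angle, speed and reversal count), `arena`, `frame_rate`.
#' @export
gen_track_dataset <- function(config) {
  stopifnot(inherits(config, "track_gen_config"))
  set.seed(config$seed)
  ar <- config$arena
  fr <- config$frame_rate
  seg_n <- config$segment_frames
  n_seg_max <- ceiling(config$duration_s * fr / seg_n)

  tracks <- vector("list", 0)
  truth <- vector("list", 0)
  for (g in names(config$group_params)) {
    p <- config$group_params[[g]]
    for (k in seq_len(config$n_tracks)) {
      track_id <- sprintf("%s_t%03d", g, k)
      pos <- ar$start
      xs <- pos[1]; ys <- pos[2]
      absorbed <- FALSE
      for (s in seq_len(n_seg_max)) {
        theta_deg <- rtruncnorm1(1, p$angle[1], p$angle[2], 0, 180)
        speed <- rtruncnorm1(1, p$speed[1], p$speed[2], 1e-6, Inf)
        sgn <- sample(c(-1, 1), 1)
        to_cs <- ar$cs - pos
        base_dir <- to_cs / sqrt(sum(to_cs^2))
        u <- drop(rotate2d(matrix(base_dir, 1), sgn * theta_deg * pi / 180))
        step_len <- speed / 60 / fr
        dir_sign <- rep(1, seg_n)
        n_rev <- stats::rpois(1, p$reversal_rate * step_len * seg_n)
        n_rev <- min(n_rev, floor(seg_n / (2 * config$reversal_frames + 2)))
        if (n_rev > 0) {
          slots <- floor(seq(2, seg_n - config$reversal_frames,
                             length.out = max(n_rev, 2)))[seq_len(n_rev)]
          for (f0 in slots) {
            dir_sign[f0:(f0 + config$reversal_frames - 1)] <- -1
          }
        }
        dx <- cumsum(step_len * dir_sign * u[1])
        dy <- cumsum(step_len * dir_sign * u[2])
        px <- pmin(pmax(pos[1] + dx, ar$xlim[1]), ar$xlim[2])
        py <- pmin(pmax(pos[2] + dy, ar$ylim[1]), ar$ylim[2])
        d_cs <- sqrt((px - ar$cs[1])^2 + (py - ar$cs[2])^2)
        d_alt <- sqrt((px - ar$alt[1])^2 + (py - ar$alt[2])^2)
        hit <- which(d_cs < config$absorb_radius |
                       d_alt < config$absorb_radius)
        if (length(hit) > 0) {
          px <- px[1:hit[1]]; py <- py[1:hit[1]]
          absorbed <- TRUE
        }
        xs <- c(xs, px); ys <- c(ys, py)
        pos <- c(px[length(px)], py[length(py)])
        truth[[length(truth) + 1L]] <- tibble::tibble(
          track_id = track_id, group = g, segment = s,
          angle_deg = theta_deg, speed_cm_min = speed, n_reversals = n_rev
        )
        if (absorbed) break
      }
      nf <- length(xs)
      tracks[[length(tracks) + 1L]] <- tibble::tibble(
        track_id = track_id, group = g, frame = seq_len(nf) - 1L,
        time = (seq_len(nf) - 1L) / fr, x = xs, y = ys
      )
    }
  }
  structure(list(
    tracks = dplyr::bind_rows(tracks),
    truth = dplyr::bind_rows(truth),
    arena = ar, frame_rate = fr
  ), class = "wm_track_dataset")
}
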