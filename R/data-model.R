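# Shared data model: trace tables, stimulus schedules, endpoint counts,
# and delimited-file I/O. All downstream stages key on the closed sets of
# paradigm/treatment labels defined here.

#' Training paradigm and treatment label sets
#'
#' The experimental design crosses four training paradigms (short-/long-term,
#' appetitive/aversive) with trained and mock-trained treatments, plus an
#' untreated naive group. Labels form a closed set: unknown labels are a hard
#' error because every downstream stage (comparison design, decoding classes,
#' component contrasts) keys on them.
#'
#' @format Character vectors.
#' @name label-sets
NULL

#' @rdname label-sets
#' @export
PARADIGMS <- c("STAP", "STAV", "LTAP", "LTAV", "NONE")

#' @rdname label-sets
#' @export
TREATMENTS <- c("trained", "mock", "naive")

#' Compose a group label from paradigm and treatment
#'
#' Group labels are `"<paradigm>-T"` (trained), `"<paradigm>-M"` (mock), or
#' `"naive"`. The naive group has no paradigm (`"NONE"`).
#'
#' @param paradigm One of [PARADIGMS].
#' @param treatment One of [TREATMENTS].
#' @return Character vector of group labels.
#' @export
#' @examples
#' group_label("STAP", "trained")
#' group_label("NONE", "naive")
group_label <- function(paradigm, treatment) {
  if (!all(paradigm %in% PARADIGMS)) {
    wm_abort(paste0("unknown paradigm label: ",
                    paste(setdiff(paradigm, PARADIGMS), collapse = ", ")),
             "wm_label_error")
  }
  if (!all(treatment %in% TREATMENTS)) {
    wm_abort(paste0("unknown treatment label: ",
                    paste(setdiff(treatment, TREATMENTS), collapse = ", ")),
             "wm_label_error")
  }
  bad <- xor(paradigm == "NONE", treatment == "naive")
  if (any(bad)) {
    wm_abort("paradigm 'NONE' if and only if treatment 'naive'",
             "wm_label_error")
  }
  ifelse(treatment == "naive", "naive",
         paste0(paradigm, ifelse(treatment == "trained", "-T", "-M")))
}

# All group labels of the short-term exchange design.
ST_GROUPS <- c("STAP-T", "STAP-M", "STAV-T", "STAV-M", "naive")

#' Validate a tidy trace table
#'
#' A trace table is a long-format tibble with one row per (neuron, animal,
#' time point) and columns `neuron_id`, `animal_id`, `paradigm`, `treatment`,
#' `time` (seconds, strictly increasing within a trace), `intensity` (raw
#' fluorescence, finite and non-negative) and `frame_rate` (Hz, constant
#' within a trace).
#'
#' @param traces A data frame with the columns above.
#' @return The validated table as a tibble, sorted by trace and time, with a
#'   `group` column added.
#' @export
validate_trace_table <- function(traces) {
  required <- c("neuron_id", "animal_id", "paradigm", "treatment",
                "time", "intensity", "frame_rate")
  missing_cols <- setdiff(required, names(traces))
  if (length(missing_cols) > 0) {
    wm_abort(paste0("trace table is missing required column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "wm_schema_error")
  }
  traces <- tibble::as_tibble(traces)
  traces$group <- group_label(traces$paradigm, traces$treatment)
  if (!all(is.finite(traces$intensity)) || any(traces$intensity < 0)) {
    wm_abort("intensity values must be finite and non-negative",
             "wm_validation_error")
  }
  if (any(traces$frame_rate <= 0)) {
    wm_abort("frame_rate must be positive", "wm_validation_error")
  }
  traces <- dplyr::arrange(traces, .data$neuron_id, .data$animal_id,
                           .data$paradigm, .data$treatment, .data$time)
  bad <- traces |>
    dplyr::group_by(.data$neuron_id, .data$animal_id, .data$paradigm,
                    .data$treatment) |>
    dplyr::summarise(ok = all(diff(.data$time) > 0), .groups = "drop") |>
    dplyr::filter(!.data$ok)
  if (nrow(bad) > 0) {
    wm_abort(paste0("non-monotone time in trace ", bad$neuron_id[1], "/",
                    bad$animal_id[1]), "wm_validation_error")
  }
  traces
}

#' Load a tidy trace table from a delimited file
#'
#' Reads a comma-delimited, header-row, UTF-8 table of per-neuron
#' fluorescence time series and validates it against the trace-table schema.
#' An optional `schema` map renames source columns to the canonical names.
#'
#' @param path Path to a CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the file's column names, e.g. `c(intensity = "F_raw")`.
#' @return A validated trace tibble (see [validate_trace_table()]).
#' @export
load_trace_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    wm_abort(paste0("file not found: ", path), "wm_io_error")
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0) {
    wm_warn("empty trace table; returning zero records", "wm_empty_warning")
    return(tibble::tibble(
      neuron_id = character(), animal_id = character(),
      paradigm = character(), treatment = character(),
      time = numeric(), intensity = numeric(), frame_rate = numeric(),
      group = character()
    ))
  }
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      src <- schema[[canonical]]
      if (!src %in% names(raw)) {
        wm_abort(paste0("schema names missing source column: ", src),
                 "wm_schema_error")
      }
      names(raw)[names(raw) == src] <- canonical
    }
  }
  validate_trace_table(raw)
}

#' Save a stage result table and read it back
#'
#' Results (comparison tables, decoding summaries, simulation curves, ...)
#' are written as CSV at full numeric precision; `NA`/`NaN` entries (e.g.
#' q-values of untested comparisons) are preserved as empty fields or `NaN`
#' and round-trip through [load_results()].
#'
#' @param results A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_results <- function(results, path) {
  results <- as.data.frame(results)
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) wm_abort(paste0("unwritable path: ", path), "wm_io_error")
  utils::write.csv(format_full_precision(results), path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}

# Format numeric columns at full double precision for text round-trips.
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) {
      x <- df[[j]]
      out <- sprintf("%.17g", x)
      out[is.na(x) & !is.nan(x)] <- NA
      out[is.nan(x)] <- "NaN"
      df[[j]] <- out
    }
  }
  df
}

#' @rdname save_results
#' @export
load_results <- function(path) {
  if (!file.exists(path)) wm_abort(paste0("file not found: ", path), "wm_io_error")
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Stimulus schedule for a recording
#'
#' A schedule is an ordered set of contiguous, non-overlapping stimulus
#' epochs plus the switch times at the epoch boundaries. Switches are typed
#' `but_on` (diacetyl-to-butanone) or `but_off` (butanone-to-diacetyl); these
#' are the events that ON- and OFF-type neurons respond to.
#'
#' @param epochs Tibble with columns `start`, `end` (seconds) and `stimulus`
#'   (one of `"BUT"`, `"DA"`, `"buffer"`).
#' @return An object of class `stim_schedule` with elements `epochs` and
#'   `switches` (tibble of `time`, `type`).
#' @export
stim_schedule <- function(epochs) {
  epochs <- tibble::as_tibble(epochs)
  stopifnot(all(c("start", "end", "stimulus") %in% names(epochs)))
  if (!all(epochs$stimulus %in% c("BUT", "DA", "buffer"))) {
    wm_abort("unknown stimulus label", "wm_label_error")
  }
  if (nrow(epochs) > 1) {
    if (any(abs(epochs$start[-1] - epochs$end[-nrow(epochs)]) > 1e-9)) {
      wm_abort("epochs must be contiguous and non-overlapping",
               "wm_validation_error")
    }
  }
  if (any(epochs$end <= epochs$start)) {
    wm_abort("epoch end must exceed start", "wm_validation_error")
  }
  sw <- tibble::tibble(time = numeric(), type = character())
  if (nrow(epochs) > 1) {
    for (i in 2:nrow(epochs)) {
      type <- if (epochs$stimulus[i] == "BUT") {
        "but_on"
      } else if (epochs$stimulus[i - 1] == "BUT") {
        "but_off"
      } else {
        "other"
      }
      sw <- dplyr::bind_rows(sw, tibble::tibble(time = epochs$start[i], type = type))
    }
  }
  structure(list(epochs = epochs, switches = sw), class = "stim_schedule")
}

#' The butanone/diacetyl exchange protocol schedule
#'
#' The default recording protocol: one minute of diacetyl followed by six
#' exchange trials, each a 30 s butanone step then a 30 s diacetyl step
#' (420 s total, six `but_on` and six `but_off` switches). Each BUT/DA
#' exchange is one "trial".
#'
#' @param n_trials Number of exchange trials (default 6).
#' @param pre_s Duration of the initial diacetyl epoch in seconds.
#' @param step_s Duration of each exchange step in seconds.
#' @return A `stim_schedule`.
#' @export
#' @examples
#' sched <- exchange_schedule()
#' sched$switches
exchange_schedule <- function(n_trials = 6, pre_s = 60, step_s = 30) {
  starts <- c(0, pre_s + seq(0, by = step_s, length.out = 2 * n_trials))
  ends <- c(starts[-1], pre_s + 2 * n_trials * step_s)
  stim <- c("DA", rep(c("BUT", "DA"), n_trials))
  stim_schedule(tibble::tibble(start = starts, end = ends, stimulus = stim))
}

#' Switch times of a given type
#'
#' @param schedule A `stim_schedule`.
#' @param type `"but_on"`, `"but_off"`, or `"all"`.
#' @return Numeric vector of switch times in seconds.
#' @export
switch_times <- function(schedule, type = c("all", "but_on", "but_off")) {
  type <- match.arg(type)
  sw <- schedule$switches
  if (type != "all") sw <- sw[sw$type == type, , drop = FALSE]
  sw$time
}

#' Endpoint counts from a two-choice assay
#'
#' @param n_cs Worms scored at the conditioned-stimulus endpoint(s).
#' @param n_alt Worms scored at the alternative endpoint(s).
#' @return An `endpoint_counts` object.
#' @export
endpoint_counts <- function(n_cs, n_alt) {
  if (n_cs < 0 || n_alt < 0) {
    wm_abort("endpoint counts must be non-negative", "wm_validation_error")
  }
  structure(list(n_cs = n_cs, n_alt = n_alt), class = "endpoint_counts")
}

#' JSON results manifests and YAML configs
#'
#' Structured (non-tabular) results — variance reports, simulation
#' summaries, ground-truth records — are written as JSON manifests;
#' pipeline configuration (kernel sizes, per-neuron integration windows,
#' normalization modes, thresholds) round-trips through YAML.
#'
#' @param x A list.
#' @param path File path.
#' @return `path` (writers, invisibly) or the parsed list (readers).
#' @export
save_manifest <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' @rdname save_manifest
#' @export
save_config_yaml <- function(x, path) {
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_config_yaml <- function(path) {
  yaml::read_yaml(path)
}
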