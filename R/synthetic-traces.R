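# Synthetic calcium-trace generator with a planted neuron x experience-component
# effect matrix. Gives every downstream stage (statistics, decoding, regression,
# component PCA) a dataset with known ground truth.

# Experience-component columns of the effect matrix.
EFFECT_COMPONENTS <- c("USp", "USm", "CSap", "CSav", "VAL")

#' Construct a neuron x experience-component effect matrix
#'
#' Entries are signed, dimensionless amplitude multipliers planted on the
#' group structure: `USp`/`USm` act on the appetitive/aversive mock (and
#' trained) groups relative to naive, `CSap`/`CSav` act on the trained groups
#' relative to their mocks, and `VAL` shifts the two valence arms
#' symmetrically (+VAL/2 on appetitive, -VAL/2 on aversive). A zero entry
#' means the neuron's expected response is identical across the groups that
#' define that component. Five groups span four free contrasts against naive,
#' so the `VAL` column overlaps with the US contrasts; the generator's ground
#' truth therefore records the realized per-group multipliers, from which any
#' contrast's expected value can be derived exactly.
#'
#' @param neuron_ids Character vector of neuron names (rows).
#' @param entries Optional numeric matrix (neurons x 5) to initialize with.
#' @return A numeric matrix with rownames `neuron_ids` and colnames
#'   `c("USp", "USm", "CSap", "CSav", "VAL")`.
#' @export
effect_matrix <- function(neuron_ids, entries = NULL) {
  m <- matrix(0, nrow = length(neuron_ids), ncol = length(EFFECT_COMPONENTS),
              dimnames = list(neuron_ids, EFFECT_COMPONENTS))
  if (!is.null(entries)) {
    entries <- as.matrix(entries)
    if (!all(is.finite(entries))) {
      wm_abort("effect matrix entries must be finite", "wm_config_error")
    }
    m[seq_len(nrow(entries)), seq_len(ncol(entries))] <- entries
  }
  m
}

#' Realized per-group amplitude multipliers implied by an effect matrix
#'
#' @param effects An [effect_matrix()].
#' @return Matrix neurons x groups (`STAP-T`, `STAP-M`, `STAV-T`, `STAV-M`,
#'   `naive`) of additive amplitude multipliers (naive = 0).
#' @export
group_multipliers <- function(effects) {
  g <- cbind(
    `STAP-T` = effects[, "USp"] + effects[, "CSap"] + effects[, "VAL"] / 2,
    `STAP-M` = effects[, "USp"] + effects[, "VAL"] / 2,
    `STAV-T` = effects[, "USm"] + effects[, "CSav"] - effects[, "VAL"] / 2,
    `STAV-M` = effects[, "USm"] - effects[, "VAL"] / 2,
    naive    = rep(0, nrow(effects))
  )
  rownames(g) <- rownames(effects)
  g
}

#' Configuration for the synthetic trace generator
#'
#' Defaults emulate the butanone/diacetyl exchange recordings: 2 Hz soma
#' sampling, the 60 s + 6 x (30 s BUT / 30 s DA) schedule, GCaMP-like
#' transient kinetics (1 s rise, 8 s decay), additive Gaussian noise and a
#' slow sinusoidal baseline drift of at most 5% of the base amplitude.
#'
#' @param neurons Tibble with columns `neuron_id`, `responder_type` (`"ON"`
#'   responds to butanone onset, `"OFF"` to butanone removal),
#'   `base_amplitude` (peak fractional fluorescence change of a responder in
#'   the naive group) and optionally `responder_prob` (per-animal or
#'   per-trial probability of responding; default 1). Bimodal
#'   animal-to-animal responsiveness (e.g. ~50% responders) is planted by
#'   setting `responder_prob = 0.5`.
#' @param n_animals Animals per group (scalar or named vector over groups).
#' @param groups Group labels to generate (default: the five short-term
#'   exchange groups).
#' @param frame_rate Sampling rate in Hz.
#' @param noise_sd Additive Gaussian noise SD as a fraction of each neuron's
#'   base amplitude.
#' @param rise_s,decay_s Transient kernel time constants in seconds.
#' @param drift_frac Amplitude of the sinusoidal baseline drift as a
#'   fraction of base amplitude (phase randomized per trace).
#' @param drift_period_s Period of the baseline drift in seconds.
#' @param baseline Ground-state fluorescence level in arbitrary units.
#' @param responder_mode Draw responder status per `"animal"` (fixed across
#'   the six trials) or per `"trial"`.
#' @param schedule A [stim_schedule()] (default [exchange_schedule()]).
#' @param seed Integer seed; a fixed seed makes the dataset bit-identical.
#' @return A list of class `trace_gen_config`.
#' @export
trace_gen_config <- function(neurons,
                             n_animals = 10,
                             groups = ST_GROUPS,
                             frame_rate = 2,
                             noise_sd = 0.05,
                             rise_s = 1,
                             decay_s = 8,
                             drift_frac = 0.05,
                             drift_period_s = 120,
                             baseline = 100,
                             responder_mode = c("animal", "trial"),
                             schedule = exchange_schedule(),
                             seed = 1L) {
  neurons <- tibble::as_tibble(neurons)
  stopifnot(all(c("neuron_id", "responder_type", "base_amplitude") %in%
                  names(neurons)))
  if (!all(neurons$responder_type %in% c("ON", "OFF"))) {
    wm_abort("responder_type must be 'ON' or 'OFF'", "wm_config_error")
  }
  if (!"responder_prob" %in% names(neurons)) neurons$responder_prob <- 1
  if (any(neurons$responder_prob < 0 | neurons$responder_prob > 1)) {
    wm_abort("responder_prob must lie in [0, 1]", "wm_config_error")
  }
  if (rise_s <= 0 || decay_s <= 0 || rise_s >= decay_s) {
    wm_abort("need 0 < rise_s < decay_s", "wm_config_error")
  }
  if (is.null(names(n_animals))) {
    n_animals <- stats::setNames(rep(n_animals[1], length(groups)), groups)
  }
  structure(list(
    neurons = neurons, n_animals = n_animals, groups = groups,
    frame_rate = frame_rate, noise_sd = noise_sd, rise_s = rise_s,
    decay_s = decay_s, drift_frac = drift_frac,
    drift_period_s = drift_period_s, baseline = baseline,
    responder_mode = match.arg(responder_mode), schedule = schedule,
    seed = as.integer(seed)
  ), class = "trace_gen_config")
}

# Difference-of-exponentials transient kernel, normalized to unit peak.
transient_kernel <- function(tau, rise_s, decay_s) {
  k <- ifelse(tau >= 0, exp(-tau / decay_s) - exp(-tau / rise_s), 0)
  t_peak <- log(decay_s / rise_s) / (1 / rise_s - 1 / decay_s)
  k / (exp(-t_peak / decay_s) - exp(-t_peak / rise_s))
}

#' Generate a synthetic calcium-trace dataset with planted effects
#'
#' Builds, per animal and neuron, a raw fluorescence trace over the exchange
#' schedule: stimulus-locked transients from a difference-of-exponentials
#' kernel at butanone onsets (ON neurons) or removals (OFF neurons), peak
#' amplitude `base_amplitude * (1 + group multiplier)`, responder status
#' drawn per animal or per trial, plus additive Gaussian noise and a slow
#' sinusoidal baseline drift. Intensities are `baseline * (1 + signal)`,
#' floored at zero.
#'
#' @param config A [trace_gen_config()].
#' @param effects An [effect_matrix()] covering all configured neurons.
#' @return A list of class `wm_trace_dataset` with elements `traces` (tidy
#'   trace tibble), `schedule`, and `truth` (drawn latent values: per-trace
#'   responder status, amplitude multiplier and peak amplitude, the realized
#'   group-multiplier matrix, effect matrix and config).
#' @export
#' @examples
#' cfg <- trace_gen_config(
#'   tibble::tibble(neuron_id = c("AWA", "AWCON"),
#'                  responder_type = c("ON", "OFF"),
#'                  base_amplitude = c(1.5, 2)),
#'   n_animals = 2, seed = 42)
#' eff <- effect_matrix(c("AWA", "AWCON"))
#' ds <- gen_trace_dataset(cfg, eff)
#' head(ds$traces)
gen_trace_dataset <- function(config, effects) {
  stopifnot(inherits(config, "trace_gen_config"))
  missing_n <- setdiff(config$neurons$neuron_id, rownames(effects))
  if (length(missing_n) > 0) {
    wm_abort(paste0("effect matrix missing neuron(s): ",
                    paste(missing_n, collapse = ", ")), "wm_config_error")
  }
  set.seed(config$seed)
  sched <- config$schedule
  fr <- config$frame_rate
  t_end <- max(sched$epochs$end)
  time <- seq(0, t_end, by = 1 / fr)
  n_t <- length(time)

  on_times <- switch_times(sched, "but_on")
  off_times <- switch_times(sched, "but_off")
  n_trials <- length(on_times)

  # per-trial unit signal matrices (time x trial), one per responder type
  trial_signal <- function(events) {
    vapply(events, function(ev) {
      transient_kernel(time - ev, config$rise_s, config$decay_s)
    }, numeric(n_t))
  }
  sig <- list(ON = trial_signal(on_times), OFF = trial_signal(off_times))

  gmult <- group_multipliers(effects)
  groups <- intersect(colnames(gmult), config$groups)
  if (length(groups) != length(config$groups)) {
    wm_abort("unknown group label in config$groups", "wm_config_error")
  }

  traces <- vector("list", 0)
  truth_rows <- vector("list", 0)
  for (g in config$groups) {
    paradigm <- if (g == "naive") "NONE" else sub("-.*", "", g)
    treatment <- if (g == "naive") "naive" else
      if (endsWith(g, "-T")) "trained" else "mock"
    for (a in seq_len(config$n_animals[[g]])) {
      animal_id <- sprintf("%s_a%02d", g, a)
      for (i in seq_len(nrow(config$neurons))) {
        nrn <- config$neurons[i, ]
        m <- gmult[nrn$neuron_id, g]
        p_resp <- nrn$responder_prob
        if (config$responder_mode == "animal") {
          resp <- rep(stats::rbinom(1, 1, p_resp), n_trials)
        } else {
          resp <- stats::rbinom(n_trials, 1, p_resp)
        }
        amp <- nrn$base_amplitude * (1 + m)
        signal <- as.vector(sig[[nrn$responder_type]] %*% (amp * resp))
        phase <- stats::runif(1, 0, 2 * pi)
        drift <- config$drift_frac * nrn$base_amplitude *
          sin(2 * pi * time / config$drift_period_s + phase)
        noise <- stats::rnorm(n_t, 0, config$noise_sd * nrn$base_amplitude)
        intensity <- pmax(config$baseline * (1 + signal + drift + noise), 0)
        traces[[length(traces) + 1L]] <- tibble::tibble(
          neuron_id = nrn$neuron_id, animal_id = animal_id,
          paradigm = paradigm, treatment = treatment,
          time = time, intensity = intensity, frame_rate = fr
        )
        truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
          neuron_id = nrn$neuron_id, animal_id = animal_id, group = g,
          multiplier = m, amplitude = amp,
          responder_any = any(resp == 1),
          n_responding_trials = sum(resp)
        )
      }
    }
  }
  traces <- validate_trace_table(dplyr::bind_rows(traces))
  truth <- list(
    per_trace = dplyr::bind_rows(truth_rows),
    group_multipliers = gmult,
    effects = effects,
    config = config
  )
  structure(list(traces = traces, schedule = sched, truth = truth),
            class = "wm_trace_dataset")
}
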