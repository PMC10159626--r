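# Small dataset builders shared across test files. All fixtures are built in
# code under fixed seeds; sizes are kept small so the full suite stays fast.

# A compact exchange-protocol trace dataset with configurable effects.
make_trace_fixture <- function(n_animals = 4, noise_sd = 0.05,
                               drift_frac = 0.05, effects = NULL,
                               neurons = NULL, seed = 11,
                               responder_mode = "animal",
                               groups = c("STAP-T", "STAP-M", "STAV-T",
                                          "STAV-M", "naive")) {
  neurons <- neurons %||% tibble::tibble(
    neuron_id = c("AWA", "AWCON", "ASER"),
    responder_type = c("ON", "OFF", "ON"),
    base_amplitude = c(1.5, 2.0, 1.0)
  )
  cfg <- trace_gen_config(neurons, n_animals = n_animals, groups = groups,
                          noise_sd = noise_sd, drift_frac = drift_frac,
                          responder_mode = responder_mode, seed = seed)
  eff <- effects %||% effect_matrix(neurons$neuron_id)
  gen_trace_dataset(cfg, eff)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# An effect matrix separating all five short-term groups, scaled by `size`.
separating_effects <- function(neuron_ids, size = 1) {
  k <- length(neuron_ids)
  base <- matrix(0, k, 5, dimnames = list(neuron_ids,
    c("USp", "USm", "CSap", "CSav", "VAL")))
  patterns <- list(
    c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0), c(0, 0, 1, 0, 0),
    c(0, 0, 0, 1, 0), c(1, -1, 0, 0, 0), c(0, 0, 1, -1, 0),
    c(-1, 0, 0, 1, 0), c(0, 1, -1, 0, 0)
  )
  for (i in seq_len(k)) {
    base[i, ] <- size * patterns[[(i - 1) %% length(patterns) + 1]]
  }
  base
}

# A two-group track dataset with configurable planted statistics.
make_track_fixture <- function(n_tracks = 15, duration_s = 240,
                               naive = list(angle = c(60, 25),
                                            speed = c(6, 1.5),
                                            reversal_rate = 1),
                               trained = list(angle = c(25, 15),
                                              speed = c(6, 1.5),
                                              reversal_rate = 1),
                               seed = 21) {
  cfg <- track_gen_config(list(naive = naive, trained = trained),
                          n_tracks = n_tracks, duration_s = duration_s,
                          seed = seed)
  gen_track_dataset(cfg)
}

# Deterministic polyline track as a tibble.
polyline_track <- function(x, y) tibble::tibble(x = x, y = y)

# Orthogonal regressor set on the concatenated-trial time base: trial-avg
# tibbles built directly (six trials of `len` points each).
make_trial_avg <- function(values_by_trial, neuron_id = "X",
                           condition = "naive") {
  dplyr::bind_rows(lapply(seq_along(values_by_trial), function(tr) {
    v <- values_by_trial[[tr]]
    tibble::tibble(neuron_id = neuron_id, condition = condition, trial = tr,
                   rel_time = seq_along(v) - 1, value = v)
  }))
}

# Split a length-(6*len) observation vector into a trial-averaged tibble.
vec_as_trial_avg <- function(v, len, neuron_id = "X", condition = "naive") {
  make_trial_avg(split(v, rep(1:6, each = len)), neuron_id, condition)
}

# Effect matrix planting response-loss/gain barcodes: each group gets a
# distinct presence/absence pattern across neurons, mirroring the
# observed phenomenology (neurons losing their response in specific
# training groups). Amplitude-only gain effects are invisible to
# z-normalized features; presence/absence is not.
loss_effects <- function(neuron_ids) {
  k <- length(neuron_ids)
  stopifnot(k <= 8)
  m <- matrix(0, 8, 5, dimnames = list(NULL,
    c("USp", "USm", "CSap", "CSav", "VAL")))
  m[1, "USp"] <- -1
  m[2, "USm"] <- -1
  m[3, "CSap"] <- -1
  m[4, "CSav"] <- -1
  m[5, c("USp", "CSap")] <- c(-1, 1)
  m[6, c("USm", "CSav")] <- c(-1, 1)
  m[7, "VAL"] <- -2
  m[8, c("USp", "USm")] <- -1
  out <- m[seq_len(k), , drop = FALSE]
  rownames(out) <- neuron_ids
  out
}
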