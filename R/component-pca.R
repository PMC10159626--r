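# Experience-component delta matrix, PCA-based reconstruction filtering,
# per-neuron signed change maps, and k-means significance thresholding.

# The six component contrasts of the short-term design, defined as
# group-mean differences. Each is computed per trial.
DELTA_COMPONENTS <- list(
  "CS(AP)" = c("STAP-T", "STAP-M"),
  "CS(AV)" = c("STAV-T", "STAV-M"),
  "US+"    = c("STAP-M", "naive"),
  "US-"    = c("STAV-M", "naive"),
  "VAL(T)" = c("STAP-T", "STAV-T"),
  "VAL(M)" = c("STAP-M", "STAV-M")
)

#' Build the experience-component delta matrix
#'
#' Rows are (component, trial) pairs — the six component contrasts times
#' six trials, 36 rows; columns are the concatenated per-neuron time points
#' of trial-averaged activity differences. Component contrasts: CS(AP) =
#' STAP-T - STAP-M, CS(AV) = STAV-T - STAV-M, US+ = STAP-M - naive, US- =
#' STAV-M - naive, VAL(T) = STAP-T - STAV-T, VAL(M) = STAP-M - STAV-M.
#'
#' @param trial_averaged Tibble from [trial_average()] stacked over neurons:
#'   columns `neuron_id`, `condition`, `trial`, `rel_time`, `value`, with
#'   all five short-term groups and six trials present per neuron.
#' @return A list of class `delta_matrix`: `matrix` (36 x columns),
#'   `row_info` (`component`, `trial`), `col_info` (`neuron_id`,
#'   `rel_time`).
#' @export
build_delta_matrix <- function(trial_averaged) {
  ta <- tibble::as_tibble(trial_averaged)
  neurons <- unique(ta$neuron_id)
  trials <- sort(unique(ta$trial))
  need <- unique(unlist(DELTA_COMPONENTS))
  have <- unique(ta$condition)
  missing_g <- setdiff(need, have)
  if (length(missing_g) > 0) {
    wm_abort(paste0("missing condition(s): ",
                    paste(missing_g, collapse = ", ")), "wm_validation_error")
  }
  # wide lookup: value vector per (neuron, condition, trial), fixed time order
  get_vec <- function(nrn, cond, tr) {
    v <- ta[ta$neuron_id == nrn & ta$condition == cond & ta$trial == tr, ]
    v <- dplyr::arrange(v, .data$rel_time)
    v$value
  }
  col_info <- dplyr::bind_rows(lapply(neurons, function(nrn) {
    rt <- sort(unique(ta$rel_time[ta$neuron_id == nrn]))
    tibble::tibble(neuron_id = nrn, rel_time = rt)
  }))
  rows <- list(); row_info <- list()
  for (comp in names(DELTA_COMPONENTS)) {
    pair <- DELTA_COMPONENTS[[comp]]
    for (tr in trials) {
      delta <- unlist(lapply(neurons, function(nrn) {
        get_vec(nrn, pair[1], tr) - get_vec(nrn, pair[2], tr)
      }))
      rows[[length(rows) + 1L]] <- delta
      row_info[[length(row_info) + 1L]] <-
        tibble::tibble(component = comp, trial = tr)
    }
  }
  m <- do.call(rbind, rows)
  if (!all(is.finite(m))) {
    wm_abort("delta matrix entries must be finite", "wm_validation_error")
  }
  structure(list(matrix = m, row_info = dplyr::bind_rows(row_info),
                 col_info = col_info), class = "delta_matrix")
}

#' PCA-filter a delta matrix by selected principal components
#'
#' Column-mean-centered PCA over the 36 (component x trial) rows; the
#' reconstruction keeps only the selected components (1-based, by
#' descending eigenvalue) and adds the column means back. With 36 centered
#' rows at most 35 components have nonzero variance. The variance report
#' gives the retained and filtered variance fractions (eigenvalue ratios),
#' which sum to 1.
#'
#' @param dm A `delta_matrix`.
#' @param keep Integer set of component indices to retain (default
#'   `c(1, 2, 3, 5)`, the components found to best represent the experience
#'   components).
#' @return A list of class `pca_filter_result`: `reconstructed` (a
#'   `delta_matrix`), `variance` tibble (`component`, `variance_fraction`,
#'   `kept`), `retained_fraction`, `filtered_fraction`, `scores`,
#'   `loadings`.
#' @export
pca_filter <- function(dm, keep = c(1, 2, 3, 5)) {
  stopifnot(inherits(dm, "delta_matrix"))
  X <- dm$matrix
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  ev <- sv$d^2
  n_comp <- min(nrow(X) - 1, length(sv$d))
  if (max(keep) > n_comp) {
    wm_abort(paste0("keep index ", max(keep), " exceeds the ", n_comp,
                    " available components"), "wm_validation_error")
  }
  scores <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  loadings <- sv$v
  recon <- scores[, keep, drop = FALSE] %*% t(loadings[, keep, drop = FALSE])
  recon <- sweep(recon, 2, mu, "+")
  vf <- ev / sum(ev)
  retained <- sum(vf[keep])
  out_dm <- dm
  out_dm$matrix <- recon
  structure(list(
    reconstructed = out_dm,
    variance = tibble::tibble(component = seq_along(vf),
                              variance_fraction = vf,
                              kept = seq_along(vf) %in% keep),
    retained_fraction = retained,
    filtered_fraction = 1 - retained,
    scores = scores, loadings = loadings
  ), class = "pca_filter_result")
}

#' Per-neuron signed change map from filtered deltas
#'
#' For each neuron, component and trial, sums the (reconstructed) deltas
#' over the neuron's time points and normalizes by the neuron's mean
#' response amplitude (`weighting = "divide"`, the default) or multiplies
#' by it (`weighting = "multiply"`). The mean over the six trials gives the
#' signed change (arrow length/direction); the SD over trials estimates its
#' variance.
#'
#' @param dm A `delta_matrix` (typically the `reconstructed` element of
#'   [pca_filter()]).
#' @param mean_amplitudes Named numeric vector of per-neuron mean response
#'   amplitudes (> 0); neurons with zero amplitude are excluded with a
#'   warning.
#' @param weighting `"divide"` or `"multiply"`.
#' @return Tibble `neuron_id`, `component`, `mean_change`, `sd_change`
#'   (over the six trials).
#' @export
arrow_map <- function(dm, mean_amplitudes,
                      weighting = c("divide", "multiply")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(dm, "delta_matrix"))
  neurons <- unique(dm$col_info$neuron_id)
  zero_amp <- neurons[mean_amplitudes[neurons] <= 0]
  if (length(zero_amp) > 0) {
    wm_warn(paste0("excluding neuron(s) with zero mean amplitude: ",
                   paste(zero_amp, collapse = ", ")), "wm_degenerate_warning")
    neurons <- setdiff(neurons, zero_amp)
  }
  rows <- list()
  for (nrn in neurons) {
    cols <- which(dm$col_info$neuron_id == nrn)
    amp <- mean_amplitudes[[nrn]]
    for (comp in unique(dm$row_info$component)) {
      ridx <- which(dm$row_info$component == comp)
      per_trial <- rowSums(dm$matrix[ridx, cols, drop = FALSE])
      per_trial <- if (weighting == "divide") per_trial / amp
                   else per_trial * amp
      rows[[length(rows) + 1L]] <- tibble::tibble(
        neuron_id = nrn, component = comp,
        mean_change = mean(per_trial), sd_change = stats::sd(per_trial)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Separate significant from insignificant changes by 1-D k-means
#'
#' Clusters the absolute change magnitudes with k = 2; the cluster with the
#' larger centroid is labeled significant. The decision boundary is the
#' midpoint between the two centroids. If all magnitudes are equal no
#' separation exists and everything is insignificant (with a warning).
#'
#' @param magnitudes Numeric vector of (absolute) change magnitudes.
#' @return A list with `significant` (logical vector), `boundary`,
#'   `centers`.
#' @export
kmeans_threshold <- function(magnitudes) {
  if (length(magnitudes) < 2) {
    wm_abort("need at least 2 values", "wm_validation_error")
  }
  mag <- abs(magnitudes)
  if (length(unique(mag)) < 2) {
    wm_warn("all magnitudes equal; none significant", "wm_degenerate_warning")
    return(list(significant = rep(FALSE, length(mag)), boundary = NA_real_,
                centers = rep(mag[1], 2)))
  }
  km <- stats::kmeans(mag, centers = 2, nstart = 25)
  hi <- which.max(km$centers)
  boundary <- mean(km$centers)
  list(significant = km$cluster == hi, boundary = boundary,
       centers = as.vector(km$centers))
}
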