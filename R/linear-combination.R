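# Linear-combination model of interneuron activity: trial-averaged inputs,
# OLS fits with coefficient statistics, incremental regressor addition,
# 50/50 cross-validation, and within-animal simple-regression R^2.

#' Trial-averaged activity of one neuron per condition
#'
#' Averages normalized activity pointwise over animals, per trial, within
#' the 15 s window following each stimulus exchange (butanone onset). The
#' six averaged vectors per neuron and condition are the inputs to the
#' multivariate linear model.
#'
#' @param traces Trace tibble with a `value` column of normalized activity
#'   (plus `neuron_id`, `group`, `animal_id`, `time`) on a common time base.
#' @param neuron Neuron id to average.
#' @param schedule A [stim_schedule()].
#' @param window_s Window length after each switch in seconds (default 15).
#' @param switch_type Switch type anchoring the windows.
#' @return Tibble `neuron_id`, `condition`, `trial`, `rel_time`, `value`
#'   (mean over animals).
#' @export
trial_average <- function(traces, neuron, schedule, window_s = 15,
                          switch_type = "but_on") {
  sw <- switch_times(schedule, switch_type)
  sub <- traces[traces$neuron_id == neuron, ]
  if (nrow(sub) == 0) {
    wm_abort(paste0("no traces for neuron ", neuron), "wm_validation_error")
  }
  out <- vector("list", 0)
  for (g in unique(sub$group)) {
    gdat <- sub[sub$group == g, ]
    for (i in seq_along(sw)) {
      win <- gdat[gdat$time >= sw[i] - 1e-9 &
                    gdat$time < sw[i] + window_s - 1e-9, ]
      if (nrow(win) == 0) {
        wm_abort(paste0("empty condition x trial cell: ", g, " trial ", i),
                 "wm_validation_error")
      }
      avg <- win |>
        dplyr::group_by(.data$time) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop")
      out[[length(out) + 1L]] <- tibble::tibble(
        neuron_id = neuron, condition = g, trial = i,
        rel_time = avg$time - sw[i], value = avg$value
      )
    }
  }
  dplyr::bind_rows(out)
}

# Stack a trial-averaged tibble (one condition) into the observation vector:
# the six trial vectors concatenated in trial order.
stack_trials <- function(ta) {
  ta <- dplyr::arrange(ta, .data$trial, .data$rel_time)
  ta$value
}

#' Fit an interneuron as a linear combination of sensory activities
#'
#' Ordinary least squares of the response neuron's trial-averaged activity
#' on the regressor neurons' trial-averaged activities (intercept included),
#' observations being the six concatenated trial vectors of one condition.
#' Reports coefficients with t-statistics, p-values and confidence
#' intervals, plus R^2 and adjusted R^2.
#'
#' @param response Trial-averaged tibble of the response neuron (one
#'   condition).
#' @param regressors Named list of trial-averaged tibbles, one per regressor
#'   neuron (same condition, same time base).
#' @param conf_level Level for coefficient confidence intervals.
#' @return A list of class `wm_regression_fit`: `coefficients` tibble
#'   (`term`, `beta`, `p`, `ci_lo`, `ci_hi`), `r_squared`,
#'   `adj_r_squared`, `fit` (the underlying `lm`), `condition`.
#' @export
fit_linear_combo <- function(response, regressors, conf_level = 0.95) {
  y <- stack_trials(response)
  X <- vapply(regressors, stack_trials, numeric(length(y)))
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- setdiff(seq_len(ncol(X) + 1), keep) - 1L
    wm_abort(paste0("rank-deficient design; collinear regressor(s): ",
                    paste(names(regressors)[dropped], collapse = ", ")),
             "wm_validation_error")
  }
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- tibble::tibble(
    term = c("(Intercept)", names(regressors)),
    beta = unname(stats::coef(fit)),
    p = unname(sm$coefficients[, "Pr(>|t|)"]),
    ci_lo = unname(ci[, 1]), ci_hi = unname(ci[, 2])
  )
  structure(list(
    coefficients = coefs, r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared, fit = fit,
    condition = response$condition[1]
  ), class = "wm_regression_fit")
}

#' Variance explained as regressors are added one by one
#'
#' Fits the linear-combination model on regressor prefixes of length 1..K
#' (in the given order). R^2 is non-decreasing in prefix length by the
#' nesting property of OLS.
#'
#' @inheritParams fit_linear_combo
#' @return Tibble `n_regressors`, `last_added`, `r_squared`,
#'   `adj_r_squared`.
#' @export
incremental_fit <- function(response, regressors) {
  rows <- lapply(seq_along(regressors), function(k) {
    f <- fit_linear_combo(response, regressors[seq_len(k)])
    tibble::tibble(
      n_regressors = k, last_added = names(regressors)[k],
      r_squared = f$r_squared, adj_r_squared = f$adj_r_squared
    )
  })
  dplyr::bind_rows(rows)
}

#' Cross-validate a linear-combination fit with a 50/50 split
#'
#' Observations are randomly split in half; the model is fitted on one half
#' and scored on the held-out half (R^2 about the held-out mean, so a
#' useless model scores <= 0 on average).
#'
#' @inheritParams fit_linear_combo
#' @param seed Integer seed fixing the split.
#' @return A list with `train_r2`, `test_r2`, `train_idx`.
#' @export
crossval_fit <- function(response, regressors, seed = 1L) {
  y <- stack_trials(response)
  X <- vapply(regressors, stack_trials, numeric(length(y)))
  n <- length(y)
  if (n < 8) wm_abort("need at least 4 observations per half",
                      "wm_validation_error")
  set.seed(seed)
  tr <- sort(sample(n, floor(n / 2)))
  te <- setdiff(seq_len(n), tr)
  df <- data.frame(y = y, X)
  fit <- stats::lm(y ~ ., data = df[tr, , drop = FALSE])
  pr <- stats::predict(fit, newdata = df[te, , drop = FALSE])
  test_r2 <- 1 - sum((y[te] - pr)^2) / sum((y[te] - mean(y[te]))^2)
  list(train_r2 = summary(fit)$r.squared, test_r2 = test_r2, train_idx = tr)
}

#' Within-animal variance in one neuron explained by another
#'
#' For animals in which both neurons were recorded simultaneously, fits a
#' simple OLS of the downstream neuron on the upstream neuron over the
#' post-switch windows, per condition, and reports the R^2 range across
#' conditions.
#'
#' @param paired Tibble with columns `animal_id`, `condition`, and the two
#'   activity columns named by `x` and `y` (paired samples from the same
#'   animal and time point).
#' @param x,y Column names of the upstream (explanatory) and downstream
#'   (response) activities.
#' @return Tibble `condition`, `r_squared`, `n`; attribute `range` holds the
#'   min/max R^2 across conditions.
#' @export
within_animal_r2 <- function(paired, x = "awa", y = "aiy") {
  if (!all(c(x, y, "animal_id", "condition") %in% names(paired))) {
    wm_abort("paired table must have animal_id, condition, x and y columns",
             "wm_validation_error")
  }
  rows <- paired |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(function(df, key) {
      fit <- stats::lm(df[[y]] ~ df[[x]])
      tibble::tibble(r_squared = summary(fit)$r.squared, n = nrow(df))
    }) |>
    dplyr::ungroup()
  attr(rows, "range") <- range(rows$r_squared)
  rows
}
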