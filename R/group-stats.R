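# Group-comparison machinery: the pairwise comparison design, the 95% CI
# outlier filter, normality-gated test selection, pFDR adjustment, behavioral
# choice/learning indices, and responder classification.

#' The pairwise comparison design
#'
#' Returns the ordered list of pairwise group contrasts used to test for
#' training-induced activity differences. The butanone-exposure design has
#' all 18 comparisons (8 short-term + 10 long-term rows); the
#' butanone/diacetyl exchange design uses the first 8 (short-term block).
#' Each row carries the experience-component label the contrast isolates:
#' `CS` (trained vs mock), `US+`/`US-` (mock vs naive), `VAL` (appetitive vs
#' aversive arm), `TR` (trained vs naive), `SL` (short- vs long-term).
#'
#' @param dataset_kind `"but_exposure"` (18 comparisons) or
#'   `"but_da_exchange"` (first 8).
#' @return Tibble with columns `group_a`, `group_b`, `component`.
#' @export
#' @examples
#' comparison_table("but_da_exchange")
comparison_table <- function(dataset_kind = c("but_exposure",
                                              "but_da_exchange")) {
  dataset_kind <- match.arg(dataset_kind)
  short_term <- tibble::tribble(
    ~group_a, ~group_b, ~component,
    "STAP-T", "STAV-T", "VAL",
    "STAP-M", "STAV-M", "VAL",
    "STAP-T", "STAP-M", "CS",
    "STAV-T", "STAV-M", "CS",
    "STAP-M", "naive",  "US+",
    "STAV-M", "naive",  "US-",
    "STAP-T", "naive",  "TR",
    "STAV-T", "naive",  "TR"
  )
  long_term <- tibble::tribble(
    ~group_a, ~group_b, ~component,
    "STAP-T", "LTAP-T", "SL",
    "STAV-T", "LTAV-T", "SL",
    "LTAP-T", "LTAV-T", "VAL",
    "LTAP-M", "LTAV-M", "VAL",
    "LTAP-T", "LTAP-M", "CS",
    "LTAV-T", "LTAV-M", "CS",
    "LTAP-T", "naive",  "TR",
    "LTAV-T", "naive",  "TR",
    "LTAP-M", "naive",  "US+",
    "LTAV-M", "naive",  "US-"
  )
  if (dataset_kind == "but_da_exchange") short_term
  else dplyr::bind_rows(short_term, long_term)
}

#' Filter summed activities by a 95% confidence band
#'
#' Retains values within `mean +/- z(level) * SD` of the group (for the
#' default level 0.95, z = 1.959964). Applied per neuron x group to summed
#' post-switch activities before hypothesis testing. With fewer than 3
#' values no filtering is done (with a warning).
#'
#' @param values Numeric vector of summed activities.
#' @param level Confidence level (default 0.95).
#' @return A list with `kept` (values), `excluded_idx` (integer indices into
#'   the input), `bounds`.
#' @export
ci_filter <- function(values, level = 0.95) {
  if (length(values) < 3) {
    wm_warn("fewer than 3 values; CI filter not applied", "wm_small_n_warning")
    return(list(kept = values, excluded_idx = integer(0),
                bounds = c(-Inf, Inf)))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- mean(values)
  s <- stats::sd(values)
  lo <- m - z * s
  hi <- m + z * s
  out <- which(values < lo | values > hi)
  list(kept = values[setdiff(seq_along(values), out)],
       excluded_idx = out, bounds = c(lo, hi))
}

#' Pairwise test with normality-gated test selection
#'
#' Each group is tested for normality (Shapiro-Wilk for n below
#' `n_threshold`, otherwise Kolmogorov-Smirnov against a normal with the
#' sample mean and SD). If both groups look normal (p >= 0.05) a t-test is
#' used (paired if requested); otherwise a Wilcoxon rank-sum test (unpaired)
#' or signed-rank test (paired).
#'
#' @param a,b Numeric vectors of (filtered) summed activities.
#' @param paired Use a paired test.
#' @param n_threshold Sample size at which the normality test switches from
#'   Shapiro-Wilk to Kolmogorov-Smirnov (default 50).
#' @return Tibble with `test_used` (`"t"`, `"rank_sum"`, `"signed_rank"`),
#'   `statistic`, `p`.
#' @export
pairwise_test <- function(a, b, paired = FALSE, n_threshold = 50) {
  if (length(a) < 3 || length(b) < 3) {
    wm_abort("each group needs at least 3 values", "wm_validation_error")
  }
  if (paired && length(a) != length(b)) {
    wm_abort("paired test requires equal group sizes", "wm_validation_error")
  }
  is_normal <- function(x) {
    if (stats::sd(x) == 0) return(FALSE)
    p <- if (length(x) < n_threshold) {
      stats::shapiro.test(x)$p.value
    } else {
      suppressWarnings(
        stats::ks.test(x, "pnorm", mean(x), stats::sd(x))$p.value)
    }
    p >= 0.05
  }
  if (is_normal(a) && is_normal(b)) {
    ht <- stats::t.test(a, b, paired = paired)
    test_used <- "t"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = FALSE))
    test_used <- if (paired) "signed_rank" else "rank_sum"
  }
  tibble::tibble(test_used = test_used,
                 statistic = unname(ht$statistic),
                 p = ht$p.value)
}

#' Positive false discovery rate (pFDR) q-values
#'
#' Storey's q-values with the null proportion estimated at lambda = 0.5
#' (`pi0 = min(1, mean(p > 0.5) / 0.5)`), with the usual monotonicity
#' enforcement. Benjamini-Hochberg step-up is available as a cross-check;
#' BH is the Storey procedure with pi0 fixed at 1, so BH q-values always
#' upper-bound Storey q-values.
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @param method `"storey"` (default) or `"bh"`.
#' @param lambda Tuning parameter for the Storey pi0 estimate.
#' @return Numeric vector of q-values, same order as input.
#' @export
pfdr_adjust <- function(pvalues, method = c("storey", "bh"), lambda = 0.5) {
  method <- match.arg(method)
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    wm_abort("p-values must lie in [0, 1]", "wm_validation_error")
  }
  if (method == "bh") {
    return(stats::p.adjust(pvalues, method = "BH"))
  }
  m <- length(pvalues)
  pi0 <- min(1, mean(pvalues > lambda) / (1 - lambda))
  if (pi0 == 0) pi0 <- 1 / m  # degenerate: all p small; keep q > 0
  o <- order(pvalues, decreasing = TRUE)
  q <- numeric(m)
  q[o[1]] <- min(pi0 * pvalues[o[1]], 1)
  for (i in seq_len(m - 1)) {
    j <- o[i + 1]
    rank_j <- m - i
    q[j] <- min(pi0 * m * pvalues[j] / rank_j, q[o[i]])
  }
  q
}

#' Choice index from endpoint counts
#'
#' `CI = (n_cs - n_alt) / (n_cs + n_alt)`, ranging from -1 (complete
#' aversion to the conditioned stimulus) to +1 (full attraction).
#'
#' @param counts An [endpoint_counts()] object.
#' @return The scalar choice index.
#' @export
#' @examples
#' choice_index(endpoint_counts(75, 25))
choice_index <- function(counts) {
  stopifnot(inherits(counts, "endpoint_counts"))
  tot <- counts$n_cs + counts$n_alt
  if (tot <= 0) {
    wm_abort("total endpoint count must be positive", "wm_validation_error")
  }
  (counts$n_cs - counts$n_alt) / tot
}

#' Choice and learning indices for a training paradigm
#'
#' Computes the choice index (CI) for the trained, mock-trained and naive
#' groups and the three learning indices: stimulus-specific
#' `LI_stimulus = CI_trained - CI_mock`, training-specific
#' `LI_training = CI_trained - CI_naive`, and treatment-specific
#' `LI_treatment = CI_mock - CI_naive`.
#'
#' @param counts_trained,counts_mock,counts_naive [endpoint_counts()] for
#'   the three groups.
#' @return A list with `CI_trained`, `CI_mock`, `CI_naive`, `LI_stimulus`,
#'   `LI_training`, `LI_treatment`.
#' @export
behavior_indices <- function(counts_trained, counts_mock, counts_naive) {
  ci_t <- choice_index(counts_trained)
  ci_m <- choice_index(counts_mock)
  ci_n <- choice_index(counts_naive)
  list(
    CI_trained = ci_t, CI_mock = ci_m, CI_naive = ci_n,
    LI_stimulus = ci_t - ci_m,
    LI_training = ci_t - ci_n,
    LI_treatment = ci_m - ci_n
  )
}

#' One-sample t-test of learning-index replicates against zero
#'
#' @param values Numeric vector of LI replicates (n >= 3).
#' @return Tibble with `statistic`, `p`.
#' @export
one_sample_vs_zero <- function(values) {
  if (length(values) < 3) {
    wm_abort("need at least 3 replicates", "wm_validation_error")
  }
  if (stats::sd(values) == 0) {
    if (mean(values) == 0) {
      return(tibble::tibble(statistic = 0, p = 1))
    }
    wm_warn("zero variance with nonzero mean; p -> 0", "wm_degenerate_warning")
    return(tibble::tibble(statistic = Inf, p = 0))
  }
  ht <- stats::t.test(values, mu = 0)
  tibble::tibble(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Classify traces as responding or non-responding
#'
#' A trace "responds" when its activity crosses a neuron-specific threshold
#' upward. In `trial` mode a single crossing within the trial marks the
#' trial as responding; in `animal` mode the activity must cross the
#' threshold at least twice across the animal's six consecutive trials.
#'
#' @param trial_traces List of numeric activity vectors, one per trial.
#' @param threshold Neuron-specific activity threshold.
#' @param mode `"trial"` or `"animal"`.
#' @return `trial` mode: logical vector per trial. `animal` mode: single
#'   logical.
#' @export
classify_responders <- function(trial_traces, threshold,
                                mode = c("trial", "animal")) {
  mode <- match.arg(mode)
  crossings <- vapply(trial_traces, function(v) {
    above <- v >= threshold
    sum(diff(above) == 1)
  }, numeric(1))
  if (mode == "trial") return(crossings >= 1)
  if (length(trial_traces) != 6) {
    wm_abort("animal mode requires the six-trial structure",
             "wm_validation_error")
  }
  sum(crossings) >= 2
}

#' Run the full comparison design on summed post-switch activities
#'
#' For every neuron x switch x comparison: applies the 95% CI filter per
#' group, selects and runs the pairwise test, and adjusts the whole family
#' of p-values by pFDR.
#'
#' @param summed Tibble with columns `neuron_id`, `group`, `animal_id`,
#'   `switch_index`, `integrated` (one row per animal).
#' @param design A [comparison_table()] result (or subset).
#' @param ci_level Level for [ci_filter()].
#' @param method pFDR method passed to [pfdr_adjust()].
#' @return Tibble of comparison results with `q` added.
#' @export
run_comparisons <- function(summed, design = comparison_table("but_da_exchange"),
                            ci_level = 0.95, method = "storey") {
  cells <- summed |>
    dplyr::distinct(.data$neuron_id, .data$switch_index)
  res <- vector("list", 0)
  for (ci in seq_len(nrow(cells))) {
    nrn <- cells$neuron_id[ci]
    sw <- cells$switch_index[ci]
    sub <- summed[summed$neuron_id == nrn & summed$switch_index == sw, ]
    for (di in seq_len(nrow(design))) {
      ga <- design$group_a[di]; gb <- design$group_b[di]
      a <- sub$integrated[sub$group == ga]
      b <- sub$integrated[sub$group == gb]
      if (length(a) < 3 || length(b) < 3) next
      a <- suppressWarnings(ci_filter(a, ci_level)$kept)
      b <- suppressWarnings(ci_filter(b, ci_level)$kept)
      if (length(a) < 3 || length(b) < 3) next
      tst <- pairwise_test(a, b)
      res[[length(res) + 1L]] <- tibble::tibble(
        neuron_id = nrn, switch_index = sw,
        group_a = ga, group_b = gb, component = design$component[di],
        test_used = tst$test_used, statistic = tst$statistic, p = tst$p
      )
    }
  }
  out <- dplyr::bind_rows(res)
  if (nrow(out) > 0) out$q <- pfdr_adjust(out$p, method = method)
  out
}
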