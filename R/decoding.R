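# Population decoding of the training condition from multi-neuron activity
# features: feature assembly under three split schemes, classifier backends
# (distance-weighted kNN, random forest, a small MLP), cross-validated macro
# F1 evaluation with scrambled-label controls, and the neuron-scaling curve.

#' Decoding configuration
#'
#' @param classifier `"knn"` (k = 2 nearest neighbours, distance-weighted
#'   votes), `"random_forest"` (500 trees), or `"mlp"` (two hidden layers of
#'   50 and 100 units).
#' @param knn_k Number of neighbours for kNN.
#' @param rf_trees Number of trees for the random forest.
#' @param mlp_layers Hidden layer sizes for the MLP.
#' @param train_fraction Fraction of data used for training (default 0.6).
#' @param cv_rounds Number of cross-validation rounds (default 10).
#' @param seed Integer seed governing splits and classifier randomness.
#' @return A list of class `decoding_config`.
#' @export
decoding_config <- function(classifier = c("knn", "random_forest", "mlp"),
                            knn_k = 2, rf_trees = 500,
                            mlp_layers = c(50, 100),
                            train_fraction = 0.6, cv_rounds = 10,
                            seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    wm_abort("train_fraction must lie in (0, 1)", "wm_config_error")
  }
  structure(list(
    classifier = match.arg(classifier), knn_k = knn_k, rf_trees = rf_trees,
    mlp_layers = mlp_layers, train_fraction = train_fraction,
    cv_rounds = cv_rounds, seed = as.integer(seed)
  ), class = "decoding_config")
}

#' Assemble decoding features from a trace dataset
#'
#' Per (animal, trial, neuron), the trace segment of one exchange trial
#' (butanone onset to the next onset) is ground-state normalized, binned
#' into `kernel_frames`-frame bins and z-normalized; the per-neuron vectors
#' are concatenated into one feature row per (animal, trial). Units missing
#' any neuron of `neuron_set` are dropped with a warning.
#'
#' @param dataset A `wm_trace_dataset` (see [gen_trace_dataset()]) or a list
#'   with `traces` and `schedule`.
#' @param neuron_set Character vector of neurons to concatenate.
#' @param kernel_frames Bin width for [bin_and_znorm()].
#' @param trial_s Trial window length in seconds (default: one exchange
#'   cycle, 60 s).
#' @return A list of class `decoding_features`: `features` (matrix), `labels`
#'   (factor of group labels), `animal`, `trial`, `neuron_set`.
#' @export
assemble_features <- function(dataset, neuron_set = NULL,
                              kernel_frames = 20, trial_s = 60) {
  traces <- dataset$traces
  sched <- dataset$schedule
  neuron_set <- neuron_set %||% unique(traces$neuron_id)
  on_times <- switch_times(sched, "but_on")
  n_trials <- length(on_times)

  sub <- traces[traces$neuron_id %in% neuron_set, ]
  keys <- dplyr::distinct(sub, .data$animal_id, .data$group)
  rows <- vector("list", 0)
  labels <- character(0); animals <- character(0); trials <- integer(0)
  dropped <- 0L
  for (i in seq_len(nrow(keys))) {
    aid <- keys$animal_id[i]
    adat <- sub[sub$animal_id == aid, ]
    have <- unique(adat$neuron_id)
    if (!all(neuron_set %in% have)) {
      dropped <- dropped + 1L
      next
    }
    # normalize each neuron's full trace once
    norm <- lapply(neuron_set, function(nn) {
      tr <- adat[adat$neuron_id == nn, ]
      fg <- detect_ground_state(tr$intensity)
      list(time = tr$time, values = tr$intensity / fg)
    })
    names(norm) <- neuron_set
    for (tr_i in seq_len(n_trials)) {
      t0 <- on_times[tr_i]
      t1 <- t0 + trial_s
      feat <- unlist(lapply(neuron_set, function(nn) {
        v <- norm[[nn]]
        seg <- v$values[v$time >= t0 - 1e-9 & v$time < t1 - 1e-9]
        bin_and_znorm(seg, kernel_frames)
      }))
      rows[[length(rows) + 1L]] <- feat
      labels <- c(labels, keys$group[i])
      animals <- c(animals, aid)
      trials <- c(trials, tr_i)
    }
  }
  if (dropped > 0) {
    wm_warn(paste0(dropped, " animal(s) dropped: missing neurons"),
            "wm_dropped_units_warning")
  }
  if (length(rows) == 0) wm_abort("no usable units", "wm_validation_error")
  structure(list(
    features = do.call(rbind, rows), labels = factor(labels),
    animal = animals, trial = trials, neuron_set = neuron_set
  ), class = "decoding_features")
}

# ---- classifier backends ------------------------------------------------

# Distance-weighted k-nearest-neighbour prediction (votes weighted 1/d).
knn_predict <- function(train_x, train_y, test_x, k = 2) {
  lv <- levels(train_y)
  pred <- character(nrow(test_x))
  for (i in seq_len(nrow(test_x))) {
    d <- sqrt(colSums((t(train_x) - test_x[i, ])^2))
    nn <- order(d)[seq_len(min(k, length(d)))]
    if (d[nn[1]] < 1e-12) {
      pred[i] <- as.character(train_y[nn[1]])
    } else {
      w <- tapply(1 / d[nn], train_y[nn], sum)
      pred[i] <- names(which.max(w))
    }
  }
  factor(pred, levels = lv)
}

# Minimal two-hidden-layer ReLU/softmax network trained with Adam on the
# cross-entropy loss (full batch). Deterministic given the RNG state.
mlp_fit <- function(x, y, layers = c(50, 100), max_iter = 2000,
                    lr = 1e-3, l2 = 1e-4) {
  lv <- levels(y)
  n <- nrow(x); p <- ncol(x); k <- length(lv)
  yi <- as.integer(y)
  Y <- matrix(0, n, k); Y[cbind(seq_len(n), yi)] <- 1
  sizes <- c(p, layers, k)
  W <- list(); b <- list()
  for (l in seq_len(length(sizes) - 1)) {
    sd0 <- sqrt(2 / sizes[l])
    W[[l]] <- matrix(stats::rnorm(sizes[l] * sizes[l + 1], 0, sd0),
                     sizes[l], sizes[l + 1])
    b[[l]] <- rep(0, sizes[l + 1])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(bb) bb * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  nl <- length(W)
  for (it in seq_len(max_iter)) {
    a <- list(x)
    for (l in seq_len(nl)) {
      z <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < nl) pmax(z, 0) else z
    }
    z_out <- a[[nl + 1]]
    z_out <- z_out - apply(z_out, 1, max)
    ez <- exp(z_out)
    prob <- ez / rowSums(ez)
    delta <- (prob - Y) / n
    for (l in rev(seq_len(nl))) {
      gW <- crossprod(a[[l]], delta) + l2 * W[[l]]
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (a[[l]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mW_h <- mW[[l]] / (1 - beta1^it); vW_h <- vW[[l]] / (1 - beta2^it)
      mb_h <- mb[[l]] / (1 - beta1^it); vb_h <- vb[[l]] / (1 - beta2^it)
      W[[l]] <- W[[l]] - lr * mW_h / (sqrt(vW_h) + eps)
      b[[l]] <- b[[l]] - lr * mb_h / (sqrt(vb_h) + eps)
    }
  }
  structure(list(W = W, b = b, levels = lv), class = "wm_mlp")
}

mlp_predict <- function(model, x) {
  a <- x
  nl <- length(model$W)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% model$W[[l]], 2, model$b[[l]], "+")
    a <- if (l < nl) pmax(z, 0) else z
  }
  factor(model$levels[max.col(a, ties.method = "first")],
         levels = model$levels)
}

fit_predict <- function(train_x, train_y, test_x, config) {
  switch(config$classifier,
    knn = knn_predict(train_x, train_y, test_x, k = config$knn_k),
    random_forest = {
      fit <- randomForest::randomForest(x = train_x, y = train_y,
                                        ntree = config$rf_trees)
      stats::predict(fit, test_x)
    },
    mlp = {
      model <- mlp_fit(train_x, train_y, layers = config$mlp_layers)
      mlp_predict(model, test_x)
    }
  )
}

#' Macro F1 score
#'
#' Unweighted mean over classes of the per-class F1 score
#' (`2 * precision * recall / (precision + recall)`); a class with an
#' undefined precision, recall, or F1 contributes 0.
#'
#' @param true,pred Factors with identical level sets.
#' @return Scalar macro F1 in [0, 1].
#' @export
macro_f1 <- function(true, pred) {
  lv <- levels(true)
  pred <- factor(pred, levels = lv)
  cm <- table(true, pred)
  f1 <- vapply(seq_along(lv), function(i) {
    tp <- cm[i, i]
    fp <- sum(cm[, i]) - tp
    fn <- sum(cm[i, ]) - tp
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  mean(f1)
}

# Stratified train-index draw; re-drawn (bounded) if a class is missing.
stratified_split <- function(labels, train_fraction) {
  idx <- unlist(lapply(split(seq_along(labels), labels), function(ii) {
    n_tr <- max(1, round(length(ii) * train_fraction))
    if (length(ii) == 1) ii else sample(ii, n_tr)
  }))
  unname(idx)
}

#' Evaluate decoding performance by repeated cross-validation
#'
#' Runs `cv_rounds` repeats of a stratified 60/40 split under one of three
#' schemes: `"trial"` (rows are animal x trial vectors, split by row),
#' `"within_individual"` (each animal's trials are split into train/test
#' halves, each half averaged to one vector per animal), or
#' `"between_individual"` (rows are animal trial-averages, split by animal).
#' With `scrambled = TRUE` labels are permuted before splitting, giving the
#' chance-level control.
#'
#' @param fs A `decoding_features` object from [assemble_features()].
#' @param config A [decoding_config()].
#' @param scheme Split scheme.
#' @param scrambled Permute labels before splitting.
#' @return A list of class `decoding_result`: `macro_f1_mean`,
#'   `macro_f1_sd`, `per_round_f1`, `confusion` (row-normalized, rows = true
#'   class), `neuron_set`, `scheme`.
#' @export
evaluate_decoding <- function(fs, config = decoding_config(),
                              scheme = c("trial", "within_individual",
                                         "between_individual"),
                              scrambled = FALSE) {
  scheme <- match.arg(scheme)
  set.seed(config$seed)
  lv <- levels(fs$labels)
  if (length(lv) < 2) wm_abort("need at least 2 classes", "wm_validation_error")
  conf <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  f1s <- numeric(config$cv_rounds)

  animals <- unique(fs$animal)
  animal_label <- fs$labels[match(animals, fs$animal)]

  for (r in seq_len(config$cv_rounds)) {
    labels <- fs$labels
    a_label <- animal_label
    if (scrambled) {
      if (scheme == "trial") {
        labels <- sample(labels)
      } else {
        a_label <- sample(a_label)
        labels <- a_label[match(fs$animal, animals)]
      }
    }
    if (scheme == "trial") {
      tr <- stratified_split(labels, config$train_fraction)
      te <- setdiff(seq_along(labels), tr)
      pred <- fit_predict(fs$features[tr, , drop = FALSE], labels[tr],
                          fs$features[te, , drop = FALSE], config)
      truth <- labels[te]
    } else if (scheme == "within_individual") {
      tr_rows <- list(); te_rows <- list()
      tr_y <- character(0); te_y <- character(0)
      for (ai in seq_along(animals)) {
        ridx <- which(fs$animal == animals[ai])
        half <- sample(ridx, floor(length(ridx) / 2))
        other <- setdiff(ridx, half)
        tr_rows[[ai]] <- colMeans(fs$features[half, , drop = FALSE])
        te_rows[[ai]] <- colMeans(fs$features[other, , drop = FALSE])
        tr_y <- c(tr_y, as.character(a_label[ai]))
        te_y <- c(te_y, as.character(a_label[ai]))
      }
      pred <- fit_predict(do.call(rbind, tr_rows), factor(tr_y, levels = lv),
                          do.call(rbind, te_rows), config)
      truth <- factor(te_y, levels = lv)
    } else {
      avg <- t(vapply(animals, function(a) {
        colMeans(fs$features[fs$animal == a, , drop = FALSE])
      }, numeric(ncol(fs$features))))
      tr_a <- stratified_split(a_label, config$train_fraction)
      te_a <- setdiff(seq_along(animals), tr_a)
      pred <- fit_predict(avg[tr_a, , drop = FALSE], a_label[tr_a],
                          avg[te_a, , drop = FALSE], config)
      truth <- a_label[te_a]
    }
    f1s[r] <- macro_f1(truth, pred)
    conf <- conf + table(truth, factor(pred, levels = lv))
  }
  rs <- rowSums(conf)
  conf_norm <- sweep(conf, 1, ifelse(rs == 0, 1, rs), "/")
  structure(list(
    macro_f1_mean = mean(f1s), macro_f1_sd = stats::sd(f1s),
    per_round_f1 = f1s, confusion = conf_norm,
    neuron_set = fs$neuron_set, scheme = scheme
  ), class = "decoding_result")
}

#' Decoding performance vs number of neurons considered
#'
#' Evaluates decoding for a growing (ordered) family of neuron sets and the
#' matching scrambled-label controls.
#'
#' @param dataset A `wm_trace_dataset`.
#' @param orderings List of neuron-id vectors (e.g. nested prefixes).
#' @param config A [decoding_config()].
#' @param scheme Split scheme for [evaluate_decoding()].
#' @return Tibble with `set_size`, `neurons`, `f1_mean`, `f1_sd`,
#'   `f1_scrambled_mean`, `f1_scrambled_sd`.
#' @export
neuron_scaling_curve <- function(dataset, orderings,
                                 config = decoding_config(),
                                 scheme = "trial") {
  if (any(vapply(orderings, length, integer(1)) == 0)) {
    wm_abort("empty neuron set", "wm_validation_error")
  }
  rows <- lapply(orderings, function(ns) {
    fs <- assemble_features(dataset, ns)
    real <- evaluate_decoding(fs, config, scheme)
    scr <- evaluate_decoding(fs, config, scheme, scrambled = TRUE)
    tibble::tibble(
      set_size = length(ns), neurons = paste(ns, collapse = "+"),
      f1_mean = real$macro_f1_mean, f1_sd = real$macro_f1_sd,
      f1_scrambled_mean = scr$macro_f1_mean,
      f1_scrambled_sd = scr$macro_f1_sd
    )
  })
  dplyr::bind_rows(rows)
}
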