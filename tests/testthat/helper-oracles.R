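# Independent brute-force oracles. These deliberately use naive loops and
# explicit formulas, not the package's code paths, so that implementation
# and oracle can only agree by computing the same quantity.

# Explicit centered moving average with edge truncation.
oracle_moving_average <- function(x, k) {
  n <- length(x)
  half_lo <- (k - 1) %/% 2
  half_hi <- k %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1, i - half_lo)
    hi <- min(n, i + half_hi)
    acc <- 0
    for (j in lo:hi) acc <- acc + x[j]
    out[i] <- acc / (hi - lo + 1)
  }
  out
}

# Sort-based linear-interpolation (type 7) quantile.
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Ground state: smooth, take the quantile, average the values strictly below.
oracle_ground_state <- function(x, k = 20, p = 0.10) {
  sm <- oracle_moving_average(x, k)
  q <- oracle_quantile(sm, p)
  below <- sm[sm < q]
  if (length(below) == 0) return(q)
  acc <- 0
  for (v in below) acc <- acc + v
  acc / length(below)
}

# Post-switch integration by explicit loop over samples.
oracle_integrate <- function(values, time, sw, window) {
  acc <- 0
  for (i in seq_along(values)) {
    if (time[i] >= sw - 1e-9 && time[i] < sw + window - 1e-9) {
      acc <- acc + values[i]
    }
  }
  acc
}

# Macro F1 by explicit per-class loops over the label vectors.
oracle_macro_f1 <- function(true, pred, classes) {
  total <- 0
  for (cl in classes) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(true)) {
      if (pred[i] == cl && true[i] == cl) tp <- tp + 1
      if (pred[i] == cl && true[i] != cl) fp <- fp + 1
      if (pred[i] != cl && true[i] == cl) fn <- fn + 1
    }
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    total <- total + f1
  }
  total / length(classes)
}

# OLS by the normal equations.
oracle_ols <- function(X, y) {
  Xi <- cbind(1, X)
  beta <- solve(t(Xi) %*% Xi, t(Xi) %*% y)
  fitted <- Xi %*% beta
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(beta = as.vector(beta), r_squared = 1 - ss_res / ss_tot)
}

# Exhaustive optimal 1-D two-cluster partition (minimum within-cluster SS).
# In 1-D the optimal partition is a split of the sorted values, so all n-1
# splits are enumerated.
oracle_kmeans1d <- function(x) {
  o <- order(x)
  s <- x[o]
  n <- length(s)
  best_ss <- Inf
  best_split <- 1
  for (cut in 1:(n - 1)) {
    a <- s[1:cut]
    b <- s[(cut + 1):n]
    ss <- sum((a - mean(a))^2) + sum((b - mean(b))^2)
    if (ss < best_ss) {
      best_ss <- ss
      best_split <- cut
    }
  }
  hi_cluster <- logical(n)
  hi_cluster[o[(best_split + 1):n]] <- TRUE
  list(in_upper = hi_cluster, within_ss = best_ss)
}

# Two-sample pooled-variance t statistic in closed form.
oracle_t_statistic <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}

# One-sample t statistic in closed form.
oracle_t1_statistic <- function(x) {
  mean(x) / (sd(x) / sqrt(length(x)))
}

# Benjamini-Hochberg step-up by hand.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(p[o[i]] * m / i, prev)
    q[o[i]] <- val
    prev <- val
  }
  q
}
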