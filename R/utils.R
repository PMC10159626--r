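# Internal numeric helpers shared across modules.

#' Centered moving average with edge truncation
#'
#' Smooths a numeric vector with a centered window of `k` samples. Near the
#' edges the window is truncated to the available samples, so the output has
#' the same length as the input and no padding assumptions are made.
#'
#' @param x Numeric vector.
#' @param k Window size in samples (frames).
#' @return Numeric vector of the same length as `x`.
#' @keywords internal
#' @noRd
moving_average <- function(x, k) {
  n <- length(x)
  stopifnot(k >= 1, n >= 1)
  if (k == 1) return(x)
  half_lo <- (k - 1L) %/% 2L
  half_hi <- k %/% 2L
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_lo)
  hi <- pmin(n, i + half_hi)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Rotate 2-D row vectors by `theta` radians (counter-clockwise).
rotate2d <- function(xy, theta) {
  ct <- cos(theta)
  st <- sin(theta)
  cbind(ct * xy[, 1] - st * xy[, 2], st * xy[, 1] + ct * xy[, 2])
}

# Abort with a classed condition so callers/tests can match on class.
wm_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "wormmem_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

wm_warn <- function(msg, class) {
  warning(structure(
    class = c(class, "wormmem_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
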