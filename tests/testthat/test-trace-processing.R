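test_that("ground-state detection matches its definition and defaults", {
  # protocol defaults: 20-frame kernel, 10% quantile
  expect_equal(formals(detect_ground_state)$kernel_frames, 20)
  expect_equal(formals(detect_ground_state)$quantile, 0.10)

  # constant trace: nothing strictly below the quantile -> the quantile
  expect_equal(detect_ground_state(rep(3.5, 50)), 3.5)

  # ramp 1..100 against the explicit brute-force oracle
  x <- as.numeric(1:100)
  expect_equal(detect_ground_state(x), oracle_ground_state(x), tolerance = 0)

  expect_error(detect_ground_state(1:10), class = "wm_validation_error")
})

test_that("tail ground state is the mean of the trailing frames", {
  expect_equal(formals(detect_ground_state_tail)$n_frames, 10)
  expect_equal(detect_ground_state_tail(c(1:20, rep(2, 10))), 2)
  x <- rnorm(10, 5)
  expect_equal(detect_ground_state_tail(x), mean(x))
  expect_error(detect_ground_state_tail(1:5), class = "wm_validation_error")
})

test_that("normalization obeys its two conventions and invariances", {
  x <- c(2, 4, 6)
  # ground-state mode: F/F_G, gain invariant
  n1 <- normalize_trace(x, "ground_state", F_G = 2)
  expect_equal(n1$values, c(1, 2, 3))
  g <- 7.3
  n2 <- normalize_trace(g * x, "ground_state", F_G = g * 2)
  expect_equal(n2$values, n1$values)
  # trace equal to F_G everywhere -> all ones
  expect_equal(normalize_trace(rep(5, 4), "ground_state", F_G = 5)$values,
               rep(1, 4))
  # max mode maps ground state to 0 and peak to 1
  n3 <- normalize_trace(x, "max", F_G = 2, F_max = 6)
  expect_equal(n3$values, c(0, 0.5, 1))
  # max mode invariant under affine transforms of F
  a <- 3; b <- 10
  n4 <- normalize_trace(a * x + b, "max", F_G = a * 2 + b, F_max = a * 6 + b)
  expect_equal(n4$values, n3$values)
  expect_error(normalize_trace(x, "ground_state", F_G = 0),
               class = "wm_validation_error")
  expect_error(normalize_trace(x, "max", F_G = 2, F_max = 1),
               class = "wm_validation_error")
})

test_that("linear resampling interpolates to the dataset's highest rate", {
  tr <- tibble::tibble(
    neuron_id = "n", animal_id = "a", paradigm = "NONE",
    treatment = "naive", time = c(0, 1), intensity = c(0, 1), frame_rate = 1
  )
  tr <- validate_trace_table(tr)
  out <- resample_linear(tr, target_rate = 2)
  expect_equal(out$intensity[out$time == 0.5], 0.5)

  # native-rate resampling is the identity
  tr2 <- validate_trace_table(tibble::tibble(
    neuron_id = "n", animal_id = "a", paradigm = "NONE",
    treatment = "naive", time = seq(0, 2, by = 0.5),
    intensity = c(1, 4, 2, 8, 5), frame_rate = 2
  ))
  out2 <- resample_linear(tr2, target_rate = 2)
  expect_equal(out2$intensity, tr2$intensity)

  # mixed 2/3/5 Hz dataset ends up at 5 Hz throughout
  mixed <- validate_trace_table(dplyr::bind_rows(lapply(
    c(2, 3, 5), function(fr) tibble::tibble(
      neuron_id = paste0("n", fr), animal_id = "a", paradigm = "NONE",
      treatment = "naive", time = seq(0, 3, by = 1 / fr),
      intensity = seq(0, 3, by = 1 / fr), frame_rate = fr
    ))))
  out3 <- resample_linear(mixed)
  expect_equal(unique(out3$frame_rate), 5)
  expect_error(resample_linear(tr2[1, ]), class = "wm_validation_error")
})

test_that("the time derivative recovers analytic slopes", {
  t <- seq(0, 10, by = 0.1)
  expect_equal(time_derivative(rep(2, length(t)), t), rep(0, length(t)))
  m <- -1.7
  expect_equal(time_derivative(m * t + 3, t), rep(m, length(t)))
  d <- time_derivative(sin(t), t)
  inner <- 2:(length(t) - 1)
  expect_equal(d[inner], cos(t)[inner], tolerance = 0.01)
  expect_error(time_derivative(1:3, c(0, 1, 3)),
               class = "wm_validation_error")
})

test_that("post-switch integration sums the stated windows", {
  expect_equal(formals(integrate_post_switch)$window_s, 10)
  sched <- exchange_schedule()
  t <- seq(0, 420, by = 0.5)
  ones <- rep(1, length(t))
  out <- integrate_post_switch(ones, t, sched, window_s = 10)
  expect_equal(out$integrated, rep(20, 12))

  ramp <- t / 10
  out5 <- integrate_post_switch(ramp, t, sched, window_s = 5,
                                switch_type = "but_on")
  expected <- vapply(switch_times(sched, "but_on"),
                     function(s) oracle_integrate(ramp, t, s, 5), numeric(1))
  expect_equal(out5$integrated, expected)

  expect_error(
    integrate_post_switch(ones, t, sched, window_s = 100),
    class = "wm_validation_error"
  )
})

test_that("integration is additive over adjacent disjoint windows", {
  sched <- exchange_schedule()
  t <- seq(0, 420, by = 0.5)
  set.seed(5)
  v <- rnorm(length(t))
  whole <- integrate_post_switch(v, t, sched, window_s = 10)$integrated
  first <- integrate_post_switch(v, t, sched, window_s = 5)$integrated
  # second half-window = [switch+5, switch+10): shift the switch times
  second <- vapply(switch_times(sched), function(s) {
    sum(v[t >= s + 5 - 1e-9 & t < s + 10 - 1e-9])
  }, numeric(1))
  expect_equal(first + second, whole)
})

test_that("bin-and-z-normalize yields standardized bin means", {
  expect_equal(formals(bin_and_znorm)$kernel_frames, 20)
  set.seed(2)
  v <- rnorm(130)
  z <- bin_and_znorm(v)
  expect_equal(length(z), 6)  # trailing partial bin dropped
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-12)

  # bin means against direct averaging, 40-frame trace -> 2 bins
  v2 <- rnorm(40)
  m1 <- mean(v2[1:20]); m2 <- mean(v2[21:40])
  mu <- (m1 + m2) / 2
  s <- sqrt(((m1 - mu)^2 + (m2 - mu)^2) / 2)
  expect_equal(bin_and_znorm(v2), c(m1 - mu, m2 - mu) / s)

  expect_equal(bin_and_znorm(rep(4, 40)), c(0, 0))  # zero variance
  expect_error(bin_and_znorm(rnorm(10)), class = "wm_validation_error")
})
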