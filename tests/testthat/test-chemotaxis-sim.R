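# Point-mass parameter set: every draw returns the same value.
point_params <- function(angle = 0, speed = 6, rate = 0, group = "g") {
  structure(list(angle = angle, speed = speed, reversal_rate = rate,
                 source = c(angle = group, speed = group, reversal = group)),
            class = "agent_params")
}

test_that("parameter estimation produces sampling distributions", {
  ds <- make_track_fixture(n_tracks = 15, duration_s = 240, seed = 55)
  sm <- dataset_segment_metrics(ds)
  naive_m <- sm[sm$group == "naive", ]
  prm <- estimate_params(naive_m, reversal_rates = c(0.8, 1.1),
                         source_group = "naive", bin_width = NULL)
  # pooled: plain sample vectors; planted angle mean recovered within 3 SE
  drawn <- ds$truth$angle_deg[ds$truth$group == "naive"]
  se <- sd(prm$angle) / sqrt(length(prm$angle))
  expect_lt(abs(mean(prm$angle) - mean(drawn)), 3 * se + 0.5)
  expect_equal(unname(prm$source["angle"]), "naive")

  # single segment -> point-mass distributions
  p1 <- estimate_params(naive_m[1, ], reversal_rates = 1,
                        source_group = "naive", bin_width = NULL)
  expect_length(p1$angle, 1)

  # distance-conditioned variant carries bin edges and borrows when sparse
  p2 <- estimate_params(naive_m, reversal_rates = 1, source_group = "naive",
                        bin_width = 0.5, min_per_bin = 10)
  expect_true(is.list(p2$angle))
  expect_true(all(lengths(p2$angle$samples) >= 10))
  expect_error(estimate_params(naive_m[0, ], 1, "naive"),
               class = "wm_validation_error")
})

test_that("hybrid construction swaps exactly one parameter source", {
  n <- point_params(60, 5, 1, "naive")
  t <- point_params(20, 8, 2, "trained")
  h <- hybrid_params(n, t, "angle")
  expect_equal(h$angle, t$angle)
  expect_equal(h$speed, n$speed)
  expect_equal(h$reversal_rate, n$reversal_rate)
  expect_equal(unname(h$source), c("trained", "naive", "naive"))
})

test_that("deterministic kinematics arrive at distance over speed", {
  ar <- arena_geometry()
  v <- 6  # cm/min
  prm <- point_params(angle = 0, speed = v)
  step_s <- 8
  sim <- simulate_cohort(prm, ar, n_agents = 10, duration_s = 3600,
                         step_s = step_s, absorb_radius = 0.3, seed = 2)
  # event-driven closed form: absorbed when distance falls below the
  # radius, i.e. after ceil((3.5 - 0.3) / (v/60 * step)) steps
  expected_t <- ceiling((3.5 - 0.3) / (v / 60 * step_s)) * step_s
  expect_true(all(sim$arrival_endpoint == "cs"))
  expect_true(all(abs(sim$arrival_time - expected_t) <= step_s))

  # angle 180: agents walk away and never reach the CS endpoint
  sim180 <- simulate_cohort(point_params(angle = 180, speed = v), ar,
                            n_agents = 20, duration_s = 1200,
                            step_s = step_s, seed = 3)
  expect_equal(max(sim180$arrival$frac_cs), 0)
})

test_that("simulation is reproducible and arrival curves are monotone", {
  ds <- make_track_fixture(n_tracks = 12, duration_s = 240, seed = 61)
  sm <- dataset_segment_metrics(ds)
  prm <- estimate_params(sm[sm$group == "trained", ], c(0.5, 1),
                         "trained", bin_width = 0.5)
  s1 <- simulate_cohort(prm, ds$arena, n_agents = 150, duration_s = 1800,
                        seed = 7)
  s2 <- simulate_cohort(prm, ds$arena, n_agents = 150, duration_s = 1800,
                        seed = 7)
  expect_identical(s1$arrival, s2$arrival)
  expect_identical(s1$final_positions, s2$final_positions)
  expect_true(all(diff(s1$arrival$frac_cs) >= 0))
  expect_true(all(diff(s1$arrival$frac_alt) >= 0))
  expect_lte(max(s1$arrival$frac_cs + s1$arrival$frac_alt), 1)
})

test_that("radial drift matches the closed form on an open arena", {
  # huge arena, far endpoints: no absorption, no wall contact
  ar <- arena_geometry(xlim = c(0, 2000), ylim = c(0, 2000),
                       cs = c(10, 1000), alt = c(1990, 1000),
                       start = c(1000, 1000))
  set.seed(31)
  angles <- runif(4000, 0, 90)
  speeds <- rexp(4000, 1 / 6) + 1
  prm <- structure(list(angle = angles, speed = speeds, reversal_rate = 0,
                        source = c(angle = "g", speed = "g", reversal = "g")),
                   class = "agent_params")
  step_s <- 8
  n_steps <- 40
  sim <- simulate_cohort(prm, ar, n_agents = 2000,
                         duration_s = n_steps * step_s, step_s = step_s,
                         absorb_radius = 0.01, seed = 13)
  d0 <- sqrt(sum((ar$start - ar$cs)^2))
  d_end <- sqrt((sim$final_positions[, "x"] - ar$cs[1])^2 +
                  (sim$final_positions[, "y"] - ar$cs[2])^2)
  drift_per_step <- (d0 - mean(d_end)) / n_steps
  expected <- mean(speeds) / 60 * step_s * mean(cos(angles * pi / 180))
  expect_lt(abs(drift_per_step - expected) / expected, 0.05)
})

test_that("gap attribution isolates a single differing parameter", {
  ar <- arena_geometry()
  set.seed(8)
  naive <- structure(list(
    angle = pmin(pmax(rnorm(400, 75, 20), 0), 180),
    speed = pmax(rnorm(400, 6, 1), 0.5), reversal_rate = rep(1, 50),
    source = c(angle = "naive", speed = "naive", reversal = "naive")),
    class = "agent_params")
  trained <- naive
  trained$angle <- pmin(pmax(rnorm(400, 25, 15), 0), 180)
  trained$source[] <- "trained"
  ga <- gap_attribution(naive, trained, ar, n_agents = 400,
                        duration_s = 1800, n_reps = 3, seed = 5)
  fr <- ga$fractions
  expect_true(ga$gap_defined)
  expect_gt(fr$gap_fraction[fr$parameter == "angle"], 0.7)
  expect_lt(abs(fr$gap_fraction[fr$parameter == "speed"]), 0.3)
  expect_lt(abs(fr$gap_fraction[fr$parameter == "reversal"]), 0.3)

  # identical groups: gap undefined, flagged
  expect_warning(
    ga0 <- gap_attribution(naive, naive, ar, n_agents = 50,
                           duration_s = 400, n_reps = 2, seed = 6),
    class = "wm_degenerate_warning")
  expect_false(ga0$gap_defined)
})
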