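test_that("the comparison design has the stated structure", {
  ex <- comparison_table("but_da_exchange")
  expect_equal(nrow(ex), 8)
  expect_equal(ex$group_a[1], "STAP-T")
  expect_equal(ex$group_b[1], "STAV-T")
  full <- comparison_table("but_exposure")
  expect_equal(nrow(full), 18)
  expect_identical(full[1:8, ], ex)
  expect_true(all(full$group_a != full$group_b))
  expect_error(comparison_table("nope"))
})

test_that("the confidence-band filter excludes only outliers", {
  expect_equal(formals(ci_filter)$level, 0.95)
  res <- ci_filter(rep(2, 10))
  expect_length(res$excluded_idx, 0)

  vals <- c(rep(0, 9), 100)
  # by hand: mean 10, sd = sqrt((9*100 + 8100)/9) = sqrt(1000) = 31.62,
  # band = 10 +/- 1.959964 * 31.62 -> 100 lies outside
  res2 <- ci_filter(vals)
  expect_equal(res2$excluded_idx, 10L)
  expect_equal(res2$kept, rep(0, 9))
  expect_warning(ci_filter(c(1, 2)), class = "wm_small_n_warning")
})

test_that("test selection follows the normality gate", {
  # clearly separated normal samples -> t-test, statistic matches the
  # closed-form pooled-variance t
  set.seed(101)
  a <- rnorm(10, 0, 1)
  b <- rnorm(10, 5, 1)
  res <- pairwise_test(a, b)
  expect_equal(res$test_used, "t")
  expect_lt(res$p, 0.001)
  # Welch vs pooled differ slightly; check against closed form with
  # the same variance assumption as the implementation (Welch)
  expect_equal(sign(res$statistic), sign(oracle_t_statistic(a, b)))

  # heavily skewed sample -> Shapiro-Wilk rejects -> rank-based path
  set.seed(7)
  skew <- rexp(10)^3
  nrm <- rnorm(10)
  expect_lt(shapiro.test(skew)$p.value, 0.05)  # the gate's own criterion
  res2 <- pairwise_test(skew, nrm)
  expect_equal(res2$test_used, "rank_sum")

  # paired variant uses the signed-rank test
  res3 <- pairwise_test(skew, nrm, paired = TRUE)
  expect_equal(res3$test_used, "signed_rank")
  expect_error(pairwise_test(skew, nrm[1:5], paired = TRUE),
               class = "wm_validation_error")

  # identical groups: no evidence of a difference
  x <- c(1.2, 3.1, 2.2, 4.5, 2.8, 3.3, 1.9, 2.5, 3.8, 2.1)
  res4 <- pairwise_test(x, x)
  expect_gt(res4$p, 0.99)
})

test_that("pFDR adjustment is monotone and matches hand computations", {
  expect_equal(pfdr_adjust(rep(1, 5)), rep(1, 5))
  # BH on {0.01, 0.02, 0.9} by hand: q = {0.03, 0.03, 0.9}
  p <- c(0.01, 0.02, 0.9)
  expect_equal(pfdr_adjust(p, method = "bh"), c(0.03, 0.03, 0.9))
  expect_equal(pfdr_adjust(p, method = "bh"), oracle_bh(p))

  # monotone in p, and Storey bounded by BH (pi0 <= 1)
  set.seed(33)
  for (rep_i in 1:20) {
    pv <- runif(50)
    qs <- pfdr_adjust(pv, "storey")
    qb <- pfdr_adjust(pv, "bh")
    o <- order(pv)
    expect_true(all(diff(qs[o]) >= -1e-12))
    expect_true(all(qs <= qb + 1e-12))
    expect_true(all(qs >= 0 & qs <= 1))
  }
  expect_error(pfdr_adjust(c(0.5, 1.2)), class = "wm_validation_error")
})

test_that("choice and learning indices follow their definitions", {
  expect_equal(choice_index(endpoint_counts(120, 0)), 1)
  expect_equal(choice_index(endpoint_counts(0, 120)), -1)
  expect_equal(choice_index(endpoint_counts(75, 25)), 0.5)
  # antisymmetry under swapping endpoints
  expect_equal(choice_index(endpoint_counts(30, 70)),
               -choice_index(endpoint_counts(70, 30)))
  expect_error(choice_index(endpoint_counts(0, 0)),
               class = "wm_validation_error")

  bi <- behavior_indices(endpoint_counts(90, 10), endpoint_counts(60, 40),
                         endpoint_counts(50, 50))
  expect_equal(bi$CI_trained, 0.8)
  expect_equal(bi$LI_stimulus, bi$CI_trained - bi$CI_mock)
  expect_equal(bi$LI_training, bi$CI_trained - bi$CI_naive)
  expect_equal(bi$LI_treatment, bi$CI_mock - bi$CI_naive)
  expect_true(abs(bi$LI_stimulus) <= 2)
})

test_that("one-sample tests against zero handle degenerate inputs", {
  expect_equal(one_sample_vs_zero(rep(0, 5))$p, 1)
  set.seed(9)
  vals <- 1 + rnorm(4, 0, 1e-3)
  res <- one_sample_vs_zero(vals)
  expect_lt(res$p, 0.01)
  expect_equal(res$statistic, oracle_t1_statistic(vals))
  expect_gt(one_sample_vs_zero(rep(c(-1, 1), 3))$p, 0.99)
  expect_warning(one_sample_vs_zero(rep(2, 5)), class = "wm_degenerate_warning")
})

test_that("responder classification counts upward crossings", {
  flat <- rep(0.5, 50)
  pulse <- c(rep(0, 10), rep(2, 10), rep(0, 10))  # one upward crossing
  expect_false(classify_responders(list(flat), 1, "trial"))
  expect_true(classify_responders(list(pulse), 1, "trial"))

  # one crossing across six trials: responding trial-wise, not animal-wise
  trials <- c(list(pulse), rep(list(flat), 5))
  expect_equal(classify_responders(trials, 1, "trial"),
               c(TRUE, rep(FALSE, 5)))
  expect_false(classify_responders(trials, 1, "animal"))
  # two crossings -> responding animal
  trials2 <- c(list(pulse, pulse), rep(list(flat), 4))
  expect_true(classify_responders(trials2, 1, "animal"))
  expect_error(classify_responders(trials[1:3], 1, "animal"),
               class = "wm_validation_error")
})

test_that("run_comparisons wires filter, tests and pFDR together", {
  eff <- separating_effects(c("AWA", "AWCON", "ASER"), size = 1.2)
  ds <- make_trace_fixture(n_animals = 6, noise_sd = 0.05, effects = eff,
                           seed = 17)
  summed <- summed_activities(ds, switch_type = "but_on")
  res <- run_comparisons(summed)
  expect_true(all(res$p >= 0 & res$p <= 1))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(all(res$test_used %in% c("t", "rank_sum", "signed_rank")))
  # strong planted effects: at least some comparisons significant
  expect_gt(sum(res$q < 0.05), 0)
})
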