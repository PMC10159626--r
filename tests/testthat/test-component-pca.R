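# Build a trial-averaged tibble for all five groups from explicit per-group
# value generators, so expected deltas are known by construction.
make_group_ta <- function(neurons, len = 10, gen) {
  groups <- c("STAP-T", "STAP-M", "STAV-T", "STAV-M", "naive")
  dplyr::bind_rows(lapply(neurons, function(nrn) {
    dplyr::bind_rows(lapply(groups, function(g) {
      dplyr::bind_rows(lapply(1:6, function(tr) {
        tibble::tibble(neuron_id = nrn, condition = g, trial = tr,
                       rel_time = seq_len(len) - 1,
                       value = gen(nrn, g, tr, len))
      }))
    }))
  }))
}

test_that("the delta matrix has the stated contrast structure", {
  # identical groups everywhere -> zero matrix with 36 rows
  ta0 <- make_group_ta(c("AWA", "ASER"), 10,
                       function(nrn, g, tr, len) rep(1, len))
  dm0 <- build_delta_matrix(ta0)
  expect_equal(nrow(dm0$matrix), 36)
  expect_equal(ncol(dm0$matrix), 20)
  expect_equal(max(abs(dm0$matrix)), 0)
  expect_equal(sort(unique(dm0$row_info$component)),
               sort(c("CS(AP)", "CS(AV)", "US+", "US-", "VAL(T)", "VAL(M)")))

  # planted +delta on CS(AP) only: STAP-T differs from STAP-M by +0.5
  gen <- function(nrn, g, tr, len) {
    base <- rep(0, len)
    if (nrn == "AWA" && g == "STAP-T") base <- base + 0.5
    base
  }
  dm <- build_delta_matrix(make_group_ta(c("AWA", "ASER"), 10, gen))
  awa_cols <- dm$col_info$neuron_id == "AWA"
  csap <- dm$row_info$component == "CS(AP)"
  valt <- dm$row_info$component == "VAL(T)"
  expect_equal(unique(as.vector(dm$matrix[csap, awa_cols])), 0.5)
  expect_equal(unique(as.vector(dm$matrix[valt, awa_cols])), 0.5)
  other <- !(dm$row_info$component %in% c("CS(AP)", "VAL(T)"))
  expect_equal(max(abs(dm$matrix[other, ])), 0)
  expect_equal(max(abs(dm$matrix[, !awa_cols])), 0)

  # a missing condition is a hard error naming it
  ta_miss <- ta0[ta0$condition != "naive", ]
  expect_error(build_delta_matrix(ta_miss), "naive")
})

test_that("PCA filtering reconstructs exactly with all components", {
  set.seed(12)
  ta <- make_group_ta(c("A", "B", "C", "D"), 12,
                      function(nrn, g, tr, len) rnorm(len))
  dm <- build_delta_matrix(ta)
  full <- pca_filter(dm, keep = seq_len(35))  # all available components
  expect_lt(max(abs(full$reconstructed$matrix - dm$matrix)), 1e-9)
  # 36 centered rows with >= 36 columns: at most 35 nonzero components
  nz <- sum(full$variance$variance_fraction > 1e-12)
  expect_lte(nz, 35)
  # retained + filtered variance fractions sum to exactly 1
  pf <- pca_filter(dm, keep = c(1, 2, 3, 5))
  expect_identical(pf$retained_fraction + pf$filtered_fraction, 1)
  expect_equal(sum(pf$variance$variance_fraction), 1, tolerance = 1e-12)
  expect_error(pca_filter(dm, keep = 40), class = "wm_validation_error")
})

test_that("a planted low-rank subspace is reconstructed exactly", {
  set.seed(3)
  len <- 12; n_col <- 4 * len
  b1 <- rnorm(n_col); b2 <- rnorm(n_col)
  coefs <- matrix(rnorm(72), 36, 2)
  X <- coefs %*% rbind(b1, b2)
  ta <- make_group_ta(c("A", "B", "C", "D"), len,
                      function(nrn, g, tr, len) rep(0, len))
  dm <- build_delta_matrix(ta)
  dm$matrix <- X
  pf <- pca_filter(dm, keep = c(1, 2))
  expect_lt(max(abs(pf$reconstructed$matrix - X)), 1e-8)
  expect_lt(pf$filtered_fraction, 1e-12)
})

test_that("reconstruction error equals the discarded eigenvalue mass", {
  set.seed(9)
  ta <- make_group_ta(c("A", "B", "C"), 15,
                      function(nrn, g, tr, len) rnorm(len))
  dm <- build_delta_matrix(ta)
  keep <- c(1, 2, 3, 5)
  pf <- pca_filter(dm, keep = keep)
  Xc <- sweep(dm$matrix, 2, colMeans(dm$matrix))
  ev <- svd(Xc)$d^2
  frob2 <- sum((pf$reconstructed$matrix - dm$matrix)^2)
  expect_equal(frob2, sum(ev[-keep]), tolerance = 1e-8)
})

test_that("arrow maps normalize summed deltas by neuron amplitude", {
  len <- 10
  gen <- function(nrn, g, tr, len) {
    if (nrn == "AWA" && g == "STAP-T") rep(0.3, len) else rep(0, len)
  }
  dm <- build_delta_matrix(make_group_ta(c("AWA", "ASER"), len, gen))
  amps <- c(AWA = 1.5, ASER = 2)
  am <- arrow_map(dm, amps)
  # hand arithmetic: summed delta per trial = 0.3 * 10 = 3; / 1.5 = 2
  awa_csap <- am[am$neuron_id == "AWA" & am$component == "CS(AP)", ]
  expect_equal(awa_csap$mean_change, 2)
  expect_equal(awa_csap$sd_change, 0)  # identical across the six trials
  # all-zero deltas -> zero arrows
  aser <- am[am$neuron_id == "ASER", ]
  expect_equal(max(abs(aser$mean_change)), 0)
  # multiply weighting inverts the amplitude role
  am2 <- arrow_map(dm, amps, weighting = "multiply")
  expect_equal(am2$mean_change[am2$neuron_id == "AWA" &
                                 am2$component == "CS(AP)"], 3 * 1.5)
  # zero-amplitude neurons are excluded with a warning
  expect_warning(arrow_map(dm, c(AWA = 1.5, ASER = 0)),
                 class = "wm_degenerate_warning")
})

test_that("k-means thresholding separates magnitude clusters", {
  mags <- c(0, 0.01, 0.02, 1.0, 1.1)
  km <- kmeans_threshold(mags)
  expect_equal(km$significant, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  orc <- oracle_kmeans1d(abs(mags))
  expect_equal(km$significant, orc$in_upper)
  # labels invariant under positive rescaling
  km2 <- kmeans_threshold(mags * 37.5)
  expect_equal(km2$significant, km$significant)
  # degenerate all-equal input: nothing significant
  expect_warning(km3 <- kmeans_threshold(rep(0, 5)),
                 class = "wm_degenerate_warning")
  expect_false(any(km3$significant))
  expect_error(kmeans_threshold(1), class = "wm_validation_error")
})
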