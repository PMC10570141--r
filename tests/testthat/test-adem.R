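test_that("neighbor comparisons cover every adjacent pair", {
  sim <- simulate_bulk_series(bulk_sim_spec(n_genes = 40, seed = 6, n_up_gradual = 4, n_down_gradual = 4))
  scan <- neighbor_comparisons(sim$series)
  expect_length(scan$comparisons, 6)             # 7 timepoints
  expect_identical(scan$timepoints, c(3, 6, 9, 12, 14, 16, 24))
  expect_identical(dim(scan$means), c(40L, 7L))
  expect_s3_class(scan$multigroup, "tbl_df")
})

test_that("a strong gradual gene moves up in every adjacent comparison", {
  sim <- simulate_bulk_series(bulk_sim_spec(
    n_genes = 30, reps_per_timepoint = 6, n_up_gradual = 3,
    n_down_gradual = 0, per_step_log2_effect = 1, seed = 9
  ))
  scan <- neighbor_comparisons(sim$series)
  up <- which(sim$truth$genes$label == "up_gradual")
  for (cmp in scan$comparisons) {
    expect_true(all(cmp$log2fc[up] > 0))
  }
})

test_that("trend classification matches hand-checkable mean profiles", {
  # perfectly monotone rise with every step significant
  sc <- make_scan(means = 2^(1:7), sig = matrix(TRUE, 1, 6))
  calls <- classify_adem(sc, epsilon_se = 0, require_deg = "any_step_in_run",
                         require_age_cor = FALSE)
  expect_identical(calls$direction, "P-ADEM")
  expect_identical(calls$run_length, 7L)
  expect_identical(calls$n_significant_steps, 6L)

  # constant means: nothing to call
  sc0 <- make_scan(means = rep(5, 7))
  calls0 <- classify_adem(sc0, epsilon_se = 0, require_deg = "none",
                          require_age_cor = FALSE)
  expect_identical(calls0$direction, "none")

  # decline over the first five timepoints, then rebound; steps 1-4 are
  # the significant ones
  sig <- matrix(c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE), 1)
  scv <- make_scan(means = c(5, 4, 3, 2, 1, 2, 3), sig = sig)
  callsv <- classify_adem(scv, min_run = 5, epsilon_se = 0,
                          require_deg = "any_step_in_run",
                          require_age_cor = FALSE)
  expect_identical(callsv$direction, "N-ADEM")
  expect_identical(c(callsv$run_start, callsv$run_end), c(1L, 5L))
  expect_identical(callsv$run_length, 5L)

  # strict mode: a single non-significant step inside the run blocks the call
  sig2 <- matrix(c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE), 1)
  scv2 <- make_scan(means = c(5, 4, 3, 2, 1, 2, 3), sig = sig2)
  expect_identical(
    classify_adem(scv2, min_run = 5, epsilon_se = 0,
                  require_deg = "all_steps_in_run",
                  require_age_cor = FALSE)$direction,
    "none"
  )
  expect_identical(
    classify_adem(scv2, min_run = 5, epsilon_se = 0,
                  require_deg = "any_step_in_run",
                  require_age_cor = FALSE)$direction,
    "N-ADEM"
  )

  expect_error(classify_adem(scv, min_run = 9), "min_run")
})

test_that("the DEG gate applies the fold-change and p thresholds jointly", {
  # one significant step with log2fc 0.7 > log2(1.5) and p = 0.04
  sc <- make_scan(means = c(1, 2, 4, 8, 16), sig = matrix(FALSE, 1, 4))
  sc$comparisons[[2]]$p <- 0.04
  sc$comparisons[[2]]$log2fc <- 0.7
  calls <- classify_adem(sc, min_run = 5, epsilon_se = 0,
                         require_deg = "any_step_in_run",
                         require_age_cor = FALSE)
  expect_identical(calls$direction, "P-ADEM")

  # the same step fails the gate when the fold change sits below log2(1.5)
  sc$comparisons[[2]]$log2fc <- 0.5
  calls2 <- classify_adem(sc, min_run = 5, epsilon_se = 0,
                          require_deg = "any_step_in_run",
                          require_age_cor = FALSE)
  expect_identical(calls2$direction, "none")
})

test_that("strict classification agrees with brute-force window enumeration", {
  set.seed(10)
  for (i in 1:60) {
    m <- round(2^runif(7, 2, 6), 3)
    ref <- brute_monotone(m, min_run = 5)
    sc <- make_scan(means = m)
    calls <- classify_adem(sc, min_run = 5, epsilon_se = 0,
                           require_deg = "none", require_age_cor = FALSE)
    want <- switch(ref$dir, P = "P-ADEM", N = "N-ADEM", "none")
    expect_identical(calls$direction, want)
    if (ref$dir != "none") {
      expect_identical(calls$run_length, as.integer(ref$len))
      expect_identical(calls$run_start, as.integer(ref$start))
    }
  }
})

test_that("appending a continuing timepoint never shortens the run", {
  set.seed(11)
  for (i in 1:30) {
    m <- round(2^(2 + cumsum(runif(6, 0.1, 0.8))), 3)  # strictly increasing
    sc6 <- make_scan(means = m)
    sc7 <- make_scan(means = c(m, m[6] * 2))
    r6 <- classify_adem(sc6, min_run = 5, epsilon_se = 0,
                        require_deg = "none", require_age_cor = FALSE)
    r7 <- classify_adem(sc7, min_run = 5, epsilon_se = 0,
                        require_deg = "none", require_age_cor = FALSE)
    expect_gte(r7$run_length, r6$run_length)
  }
})

test_that("no gene is called in both directions", {
  sim <- simulate_bulk_series(bulk_sim_spec(n_genes = 400, seed = 13,
                                            n_up_gradual = 40,
                                            n_down_gradual = 40))
  calls <- classify_adem(neighbor_comparisons(sim$series))
  expect_true(all(calls$direction %in% c("P-ADEM", "N-ADEM", "none")))
  # directions carry matching correlation signs
  expect_true(all(calls$pearson_r[calls$direction == "P-ADEM"] > 0))
  expect_true(all(calls$pearson_r[calls$direction == "N-ADEM"] < 0))
})

test_that("age regression is exact on constructed profiles", {
  # log2(CPM + 1) equal to age: counts 2^age - 1 against a filler gene
  ages <- c(3, 6, 9, 12)
  main <- 2^ages - 1
  cnt <- rbind(sig = main, filler = 1e6 - main)
  colnames(cnt) <- paste0("s", 1:4)
  es <- make_series(cnt, ages = ages)
  ac <- age_correlation(es, "sig")
  expect_equal(ac$pearson_r, 1)
  expect_equal(ac$slope, 1, tolerance = 1e-10)

  # reversed profile: perfect negative correlation
  cnt2 <- rbind(sig = rev(main), filler = 1e6 - rev(main))
  colnames(cnt2) <- paste0("s", 1:4)
  es2 <- make_series(cnt2, ages = ages)
  expect_equal(age_correlation(es2, "sig")$pearson_r, -1)

  # zero-variance expression is flagged degenerate, not NaN
  cnt3 <- rbind(sig = rep(100, 4), filler = rep(1e6 - 100, 4))
  colnames(cnt3) <- paste0("s", 1:4)
  es3 <- make_series(cnt3, ages = ages)
  ac3 <- age_correlation(es3, "sig")
  expect_true(ac3$degenerate)
  expect_identical(ac3$pearson_r, 0)
})

test_that("age regression matches the covariance-formula oracle", {
  set.seed(14)
  ages <- runif(20, 3, 24)
  counts <- matrix(rpois(40, 500), 2, 20,
                   dimnames = list(c("g1", "g2"), paste0("s", 1:20)))
  es <- make_series(counts, ages = ages)
  ac <- age_correlation(es, "g1")
  y <- log2(normalize_counts(es, "cpm")["g1", ] + 1)
  r_oracle <- sum((ages - mean(ages)) * (y - mean(y))) /
    sqrt(sum((ages - mean(ages))^2) * sum((y - mean(y))^2))
  expect_equal(ac$pearson_r, r_oracle, tolerance = 1e-12)
  slope_oracle <- sum((ages - mean(ages)) * (y - mean(y))) /
    sum((ages - mean(ages))^2)
  expect_equal(ac$slope, slope_oracle, tolerance = 1e-12)
})
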