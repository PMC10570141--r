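test_that("CPM and FPKM follow their defining identities", {
  cnt <- matrix(c(1, 1, 2), 3, 1,
                dimnames = list(c("a", "b", "c"), "s1"))
  es <- make_series(cnt, ages = 3)
  expect_equal(unname(normalize_counts(es, "cpm")[, 1]),
               c(250000, 250000, 500000))

  # scaling one sample's counts leaves its CPM column unchanged
  cnt2 <- cbind(s1 = c(5, 10, 5), s2 = c(50, 100, 50))
  rownames(cnt2) <- c("a", "b", "c")
  es2 <- make_series(cnt2, ages = c(3, 3))
  cpm2 <- normalize_counts(es2, "cpm")
  expect_equal(cpm2[, 1], cpm2[, 2], ignore_attr = TRUE)

  # FPKM of a 2 kb gene is half its CPM
  lens <- c(a = 1, b = 2, c = 1)
  es3 <- make_series(cnt2, ages = c(3, 3), gene_lengths = lens)
  expect_equal(normalize_counts(es3, "fpkm")["b", ],
               normalize_counts(es3, "cpm")["b", ] / 2)
  expect_error(normalize_counts(es2, "fpkm"), "gene_lengths")
})

test_that("zero-total samples are rejected by name", {
  cnt <- cbind(s1 = c(1, 2), s2 = c(0, 0))
  rownames(cnt) <- c("a", "b")
  es <- make_series(cnt, ages = c(3, 6))
  expect_error(normalize_counts(es, "cpm"), "s2")
})

test_that("expression filter keeps the boundary gene and preserves order", {
  # library total 1e6, lengths 10 kb: FPKM = count / 10
  cnt <- rbind(low = 99, edge = 100, high = 5000, filler = 1e6 - 5199)
  colnames(cnt) <- "s1"
  lens <- c(low = 10, edge = 10, high = 10, filler = 10)
  es <- make_series(cnt, ages = 3, gene_lengths = lens)
  fl <- filter_low_expression(es, threshold_fpkm = 10)
  expect_identical(fl$removed, "low")
  expect_identical(rownames(fl$series$counts), c("edge", "high", "filler"))

  # threshold 0 is the identity; filtering is idempotent
  fl0 <- filter_low_expression(es, threshold_fpkm = 0)
  expect_identical(rownames(fl0$series$counts), rownames(es$counts))
  fl2 <- filter_low_expression(fl$series, threshold_fpkm = 10)
  expect_identical(fl2$series$counts, fl$series$counts)
  expect_length(fl2$removed, 0)

  # removal set matches directly computed means on a hand-built table
  cnt5 <- cbind(s1 = c(20, 300, 8, 1e4, 999672 - 1e4),
                s2 = c(40, 100, 6, 2e4, 999854 - 2e4))
  rownames(cnt5) <- paste0("g", 1:5)
  lens5 <- setNames(c(2, 20, 1, 10, 100), paste0("g", 1:5))
  es5 <- make_series(cnt5, ages = c(3, 6), gene_lengths = lens5)
  fpkm <- normalize_counts(es5, "fpkm")
  expected_removed <- rownames(cnt5)[rowMeans(fpkm) < 10]
  expect_identical(filter_low_expression(es5)$removed, expected_removed)
  expect_error(filter_low_expression(es5, threshold_fpkm = 1e9), "All genes")
})

test_that("BH adjustment matches the step-up formula and its bounds", {
  expect_equal(adjust_pvalues(0.5), 0.5)
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  p <- c(0.001, 0.3, 0.02, 0.9, 0.04, 0.5)
  q <- adjust_pvalues(p)
  expect_true(all(q >= p))
  expect_true(all(q <= 1))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "0, 1")
})

test_that("pairwise DE is exactly null on identical groups and symmetric", {
  set.seed(1)
  cnt <- matrix(rnbinom(40 * 8, mu = 200, size = 10), 40, 8)
  cnt[, 5:8] <- cnt[, 1:4]   # group B duplicates group A
  rownames(cnt) <- paste0("g", 1:40)
  colnames(cnt) <- paste0("s", 1:8)
  es <- make_series(cnt, ages = rep(c(3, 24), each = 4))
  de <- nb_de_pairwise(es, paste0("s", 1:4), paste0("s", 5:8))
  expect_equal(de$log2fc, rep(0, 40))
  expect_true(all(de$p > 0 & de$p <= 1))

  set.seed(2)
  cnt2 <- matrix(rnbinom(60 * 6, mu = 150, size = 10), 60, 6,
                 dimnames = list(paste0("g", 1:60), paste0("s", 1:6)))
  es2 <- make_series(cnt2, ages = rep(c(3, 24), each = 3))
  ab <- nb_de_pairwise(es2, paste0("s", 1:3), paste0("s", 4:6))
  ba <- nb_de_pairwise(es2, paste0("s", 4:6), paste0("s", 1:3))
  expect_equal(ab$log2fc, -ba$log2fc)
  expect_equal(ab$p, ba$p)

  expect_error(nb_de_pairwise(es2, paste0("s", 1:3), paste0("s", 3:5)),
               "disjoint")
  expect_error(nb_de_pairwise(es2, "s1", paste0("s", 4:6)), "two samples")
})

test_that("pairwise DE detects a strong true fold change", {
  set.seed(3)
  # 50 flat genes plus 10 up and 10 down 4-fold genes; the up/down pairs
  # balance the library totals so CPM fold changes stay uncontaminated
  cnt <- t(sapply(1:70, function(g) {
    m <- if (g > 60) c(rep(400, 4), rep(100, 4))
         else if (g > 50) c(rep(100, 4), rep(400, 4))
         else rep(200, 8)
    rnbinom(8, mu = m, size = 20)
  }))
  dimnames(cnt) <- list(paste0("g", 1:70), paste0("s", 1:8))
  es <- make_series(cnt, ages = rep(c(3, 24), each = 4))
  de <- nb_de_pairwise(es, paste0("s", 1:4), paste0("s", 5:8))
  hits <- de$gene_id[de$p < 0.05 & abs(de$log2fc) > log2(1.5)]
  expect_true(all(paste0("g", 51:70) %in% hits))
  expect_lt(mean(paste0("g", 1:50) %in% hits), 0.2)
  # fold-change estimates centred on the true +/- 2 log2 units
  expect_lt(abs(mean(de$log2fc[51:60]) - 2), 0.3)
  expect_lt(abs(mean(de$log2fc[61:70]) + 2), 0.3)
  expect_lt(max(abs(abs(de$log2fc[51:70]) - 2)), 1)
})

test_that("type-I error of the pairwise test is near nominal", {
  sim <- simulate_bulk_series(bulk_sim_spec(
    n_genes = 1200, timepoints = c(3, 24), reps_per_timepoint = 3,
    n_up_gradual = 0, n_down_gradual = 0, seed = 31
  ))
  s <- sim$series
  de <- nb_de_pairwise(s, s$meta$sample_id[s$meta$age_months == 3],
                       s$meta$sample_id[s$meta$age_months == 24])
  expect_gt(mean(de$p < 0.05), 0.02)
  expect_lt(mean(de$p < 0.05), 0.09)
})

test_that("multigroup DE handles null, strong and degenerate cases", {
  set.seed(4)
  cnt <- matrix(rnbinom(80 * 9, mu = 300, size = 10), 80, 9,
                dimnames = list(paste0("g", 1:80), paste0("s", 1:9)))
  # one gene with a quadrupled middle group
  cnt[1, 4:6] <- rnbinom(3, mu = 1200, size = 50)
  es <- make_series(cnt, ages = rep(c(3, 12, 24), each = 3))
  gl <- list(a = paste0("s", 1:3), b = paste0("s", 4:6), c = paste0("s", 7:9))
  de <- nb_de_multigroup(es, gl)
  expect_lt(de$p_adj[1], 0.05)
  expect_gt(de$max_abs_log2fc[1], 1.4)
  expect_true(all(de$p_adj >= de$p))

  # three identical groups of identical vectors: zero fold change
  cnt3 <- matrix(rep(c(10, 200, 3000, 40), 6), 4, 6,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  es3 <- make_series(cnt3, ages = rep(c(3, 12, 24), each = 2))
  de3 <- nb_de_multigroup(es3, list(a = paste0("s", 1:2),
                                    b = paste0("s", 3:4),
                                    c = paste0("s", 5:6)))
  expect_equal(de3$max_abs_log2fc, rep(0, 4))

  expect_error(nb_de_multigroup(es3, list(a = paste0("s", 1:2),
                                          b = paste0("s", 3:4))),
               "pairwise")
})

test_that("multigroup null keeps the BH-significant fraction in check", {
  sim <- simulate_bulk_series(bulk_sim_spec(
    n_genes = 1000, timepoints = c(3, 12, 24), reps_per_timepoint = 3,
    n_up_gradual = 0, n_down_gradual = 0, seed = 77
  ))
  s <- sim$series
  gl <- split(s$meta$sample_id, s$meta$age_months)
  de <- nb_de_multigroup(s, gl)
  expect_lt(mean(de$p_adj < 0.05), 0.02)
})

test_that("pairwise p-values agree in rank with an edgeR cross-check", {
  skip_if_not_installed("edgeR")
  sim <- simulate_bulk_series(bulk_sim_spec(
    n_genes = 400, timepoints = c(3, 24), reps_per_timepoint = 4,
    n_up_gradual = 40, n_down_gradual = 0, per_step_log2_effect = 1,
    seed = 5
  ))
  s <- sim$series
  de <- nb_de_pairwise(s, s$meta$sample_id[s$meta$age_months == 3],
                       s$meta$sample_id[s$meta$age_months == 24])
  grp <- factor(s$meta$age_months)
  y <- edgeR::DGEList(counts = s$counts, group = grp)
  y <- edgeR::calcNormFactors(y, method = "none")
  design <- stats::model.matrix(~grp)
  y <- edgeR::estimateDisp(y, design)
  fit <- edgeR::glmQLFit(y, design)
  qlf <- edgeR::glmQLFTest(fit, coef = 2)
  expect_gt(cor(-log10(de$p), -log10(qlf$table$PValue),
                method = "spearman"), 0.9)
  expect_gt(cor(de$log2fc, qlf$table$logFC), 0.98)
})
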