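# Small builders used across test files.

# A series from an explicit counts matrix, ages recycled over columns.
make_series <- function(counts, ages, gene_lengths = NULL) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  meta <- data.frame(
    sample_id = colnames(counts),
    age_months = ages,
    replicate = stats::ave(seq_along(ages), ages, FUN = seq_along)
  )
  expression_series(counts, meta, gene_lengths = gene_lengths)
}

# A hand-built neighbor scan for deterministic trend-classifier tests:
# `means` is a gene x timepoint matrix of group means; `sig` a logical
# gene x (T-1) matrix marking which adjacent steps count as DEG steps.
make_scan <- function(means, sig = NULL, timepoints = NULL) {
  means <- rbind(means)
  G <- nrow(means)
  Tn <- ncol(means)
  if (is.null(timepoints)) timepoints <- seq_len(Tn)
  if (is.null(sig)) sig <- matrix(FALSE, G, Tn - 1)
  gene_ids <- paste0("g", seq_len(G))
  lm2 <- log2(means + 0.5)
  comparisons <- lapply(seq_len(Tn - 1), function(k) {
    tibble::tibble(
      gene_id = gene_ids,
      log2fc = ifelse(sig[, k], sign(lm2[, k + 1] - lm2[, k] + 1e-12) * 1,
                      lm2[, k + 1] - lm2[, k]),
      p = ifelse(sig[, k], 0.01, 0.9),
      p_adj = ifelse(sig[, k], 0.04, 0.95),
      mean_a = means[, k], mean_b = means[, k + 1],
      comparison = paste0(k + 1, "_vs_", k)
    )
  })
  structure(list(
    timepoints = timepoints,
    gene_ids = gene_ids,
    means = means,
    se_log2 = matrix(0, G, Tn - 1),
    comparisons = comparisons,
    multigroup = NULL,
    dispersion = rep(0.1, G),
    series = NULL
  ), class = "neighbor_scan")
}

# Brute-force reference: longest strictly monotone window (>= min_run
# timepoints) in a mean vector; returns "P", "N" or "none" plus window.
brute_monotone <- function(m, min_run) {
  Tn <- length(m)
  best <- list(dir = "none", len = 0, start = NA, end = NA)
  for (start in 1:(Tn - min_run + 1)) {
    for (end in (start + min_run - 1):Tn) {
      w <- m[start:end]
      d <- diff(w)
      for (dir in c("P", "N")) {
        ok <- if (dir == "P") all(d > 0) else all(d < 0)
        len <- end - start + 1
        if (ok && len > best$len) {
          best <- list(dir = dir, len = len, start = start, end = end)
        }
      }
    }
  }
  best
}
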