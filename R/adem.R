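# Age-dependent trend calling over an ordered timepoint series.
#
# The caller combines three lines of evidence per gene:
#   1. a monotone run of group means over >= min_run consecutive
#      timepoints, tolerant to counter-steps smaller than a noise-scaled
#      epsilon;
#   2. differential expression over the series (by default membership in
#      the multigroup DEG set: BH-adjusted p < 0.05 and at least one
#      pairwise |log2FC| > log2 1.5);
#   3. a significant Pearson correlation with age whose sign matches the
#      run direction.
# Genes passing all three are P-ADEM (up) or N-ADEM (down).

#' Neighbor-timepoint comparisons across an age series
#'
#' Runs the pairwise NB test between every pair of adjacent timepoints
#' (T - 1 comparisons for T timepoints). Dispersion is estimated once from
#' the full multi-timepoint design and reused by every comparison, so the
#' per-step tests are mutually consistent.
#'
#' @param series An [expression_series()]; every timepoint needs >= 2
#'   replicates.
#' @inheritParams nb_de_pairwise
#' @return A `neighbor_scan` object: list with `timepoints` (ages),
#'   `means` (gene x timepoint CPM-scale matrix), `se_log2` (standard
#'   errors of each step's log2 fold change, gene x (T-1)),
#'   `comparisons` (list of T-1 [nb_de_pairwise()] tibbles), `multigroup`
#'   (the [nb_de_multigroup()] table when T >= 3, else `NULL`), and
#'   `dispersion`.
#' @export
#'
#' @examples
#' sim <- simulate_bulk_series(bulk_sim_spec(n_genes = 60, seed = 2))
#' scan <- neighbor_comparisons(sim$series)
#' scan$timepoints
neighbor_comparisons <- function(series, pseudocount = 0.5, shrink = 0.5,
                                 prior_df = 4) {
  stopifnot(inherits(series, "expr_series"))
  ages <- series_timepoints(series)
  if (length(ages) < 2) abort("Need at least two timepoints.")
  reps <- table(series$meta$age_months)
  if (any(reps < 2)) {
    abort(paste0("Timepoint(s) with < 2 replicates: ",
                 paste(names(reps)[reps < 2], collapse = ", ")))
  }
  Tn <- length(ages)
  sf <- .nb_size_factors(series$counts)
  grp <- match(series$meta$age_months, ages)

  alpha <- .estimate_dispersion(series$counts, sf, grp, shrink)
  ord <- order(grp)
  fit <- .nb_fit_groups(series$counts[, ord, drop = FALSE], sf[ord],
                        grp[ord], alpha)

  comparisons <- vector("list", Tn - 1)
  for (k in seq_len(Tn - 1)) {
    ga <- series$meta$sample_id[grp == k]
    gb <- series$meta$sample_id[grp == k + 1]
    comparisons[[k]] <- nb_de_pairwise(
      series, ga, gb, pseudocount = pseudocount, shrink = shrink,
      prior_df = prior_df, dispersion = alpha,
      label = paste0(ages[k + 1], "mo_vs_", ages[k], "mo")
    )
  }

  multigroup <- NULL
  if (Tn >= 3) {
    gl <- lapply(seq_len(Tn),
                 function(k) series$meta$sample_id[grp == k])
    names(gl) <- paste0("t", ages)
    multigroup <- nb_de_multigroup(series, gl, pseudocount = pseudocount,
                                   dispersion = alpha)
  }

  se_log2 <- sqrt(fit$se_log[, -Tn, drop = FALSE]^2 +
                    fit$se_log[, -1, drop = FALSE]^2) / log(2)
  means <- fit$means
  colnames(means) <- paste0("age_", ages)

  structure(list(
    timepoints = ages,
    gene_ids = rownames(series$counts),
    means = means,
    se_log2 = se_log2,
    comparisons = comparisons,
    multigroup = multigroup,
    dispersion = alpha,
    series = series
  ), class = "neighbor_scan")
}

#' @export
print.neighbor_scan <- function(x, ...) {
  cat("<neighbor_scan> ", length(x$gene_ids), " genes, ",
      length(x$timepoints), " timepoints (",
      paste(x$timepoints, collapse = ", "), " months), ",
      length(x$comparisons), " adjacent comparisons\n", sep = "")
  invisible(x)
}

# Longest qualifying monotone window for one direction.
# d: per-step log2 changes; tol: per-step run-breaking tolerance (>= 0);
# dir: +1 (up) or -1 (down). Returns NULL or c(start_tp, end_tp) of the
# longest (earliest on ties) window with >= min_steps tolerated steps.
.best_run <- function(d, tol, dir, min_steps) {
  ok <- if (dir > 0) d > -tol else d < tol
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  cand <- which(r$values & r$lengths >= min_steps)
  if (!length(cand)) return(NULL)
  best <- cand[which.max(r$lengths[cand])]   # which.max takes earliest tie
  c(starts[best], ends[best] + 1)            # step window -> timepoint window
}

#' Classify age-dependent trend (ADEM) genes
#'
#' Labels each gene P-ADEM (persistently up with age), N-ADEM
#' (persistently down) or none, from a [neighbor_comparisons()] scan.
#' A direction qualifies when the group means run monotonically over at
#' least `min_run` consecutive timepoints -- a counter-step only breaks
#' the run if it exceeds `epsilon + epsilon_se * SE(step log2FC)` -- and
#' the gene passes the configured differential-expression gate, and (by
#' default) its expression correlates significantly with age in the same
#' direction. If both directions qualify, the one with the larger
#' absolute net change over its window wins.
#'
#' @param scan A `neighbor_scan` from [neighbor_comparisons()].
#' @param min_run Minimum number of consecutive timepoints in the
#'   monotone window (default 5).
#' @param epsilon Absolute run-breaking tolerance in log2 units
#'   (default 0).
#' @param epsilon_se Multiplier on the per-step log2FC standard error
#'   added to `epsilon` (default 1; set 0 for strict monotonicity).
#' @param require_deg Differential-expression gate: `"multigroup"`
#'   (default; BH-adjusted multigroup p < `deg_alpha` and max pairwise
#'   |log2FC| > `deg_lfc`), `"any_step_in_run"` (>= 1 adjacent comparison
#'   inside the window with raw p < `deg_alpha` and |log2FC| >
#'   `deg_lfc`), `"all_steps_in_run"` (every step significant), or
#'   `"none"`.
#' @param require_age_cor Require a Pearson age correlation (computed on
#'   log2(CPM + 1) across individual samples) significant at
#'   `cor_alpha` with sign matching the run direction (default `TRUE`).
#' @param deg_alpha,deg_lfc Thresholds of the DEG gate: p (or adjusted p)
#'   cutoff and log2 fold-change cutoff (defaults 0.05 and log2(1.5)).
#' @param cor_alpha Significance level of the age-correlation condition.
#' @return A tibble with class `adem_calls`: `gene_id`, `direction`
#'   (`"P-ADEM"`, `"N-ADEM"`, `"none"`), `run_start`, `run_end`
#'   (timepoint indices), `run_start_age`, `run_end_age`, `run_length`,
#'   `n_significant_steps`, `pearson_r`, `pearson_p`.
#' @export
classify_adem <- function(scan, min_run = 5, epsilon = 0, epsilon_se = 1,
                          require_deg = c("multigroup", "any_step_in_run",
                                          "all_steps_in_run", "none"),
                          require_age_cor = TRUE,
                          deg_alpha = 0.05, deg_lfc = log2(1.5),
                          cor_alpha = 0.05) {
  stopifnot(inherits(scan, "neighbor_scan"))
  require_deg <- match.arg(require_deg)
  Tn <- length(scan$timepoints)
  if (min_run > Tn) abort("`min_run` exceeds the number of timepoints.")
  if (min_run < 2) abort("`min_run` must be >= 2.")
  min_steps <- min_run - 1
  G <- length(scan$gene_ids)

  if (require_deg == "multigroup" && is.null(scan$multigroup)) {
    abort("Multigroup DEG gate needs >= 3 timepoints in the scan.")
  }

  # per-step significance from the neighbor comparisons
  step_p <- vapply(scan$comparisons, function(x) x$p, numeric(G))
  step_fc <- vapply(scan$comparisons, function(x) x$log2fc, numeric(G))
  if (G == 1) {
    step_p <- matrix(step_p, nrow = 1)
    step_fc <- matrix(step_fc, nrow = 1)
  }
  step_sig <- step_p < deg_alpha & abs(step_fc) > deg_lfc

  deg_multi <- if (!is.null(scan$multigroup)) {
    scan$multigroup$p_adj < deg_alpha &
      scan$multigroup$max_abs_log2fc > deg_lfc
  } else {
    rep(TRUE, G)
  }

  # Pearson age correlation on log2(CPM + 1) across individual samples.
  # A scan assembled by hand (without the underlying series) can only be
  # classified with `require_age_cor = FALSE`; correlations are NA then.
  if (!is.null(scan$series)) {
    lcpm <- log2(normalize_counts(scan$series, "cpm") + 1)
    ages <- scan$series$meta$age_months
    n <- length(ages)
    sds <- apply(lcpm, 1, sd)
    r <- vapply(seq_len(G), function(g) {
      if (sds[g] == 0) 0 else cor(lcpm[g, ], ages)
    }, numeric(1))
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
    pr <- 2 * pt(-abs(tstat), n - 2)
    pr[sds == 0] <- 1
  } else {
    if (require_age_cor) {
      abort(paste0("Age-correlation condition needs the series inside the ",
                   "scan; use `require_age_cor = FALSE` for a hand-built scan."))
    }
    r <- rep(NA_real_, G)
    pr <- rep(NA_real_, G)
  }

  lmeans <- log2(scan$means + 0.5)
  d <- lmeans[, -1, drop = FALSE] - lmeans[, -Tn, drop = FALSE]

  direction <- rep("none", G)
  run_start <- run_end <- rep(NA_integer_, G)
  n_sig <- integer(G)

  for (g in seq_len(G)) {
    tol <- epsilon + epsilon_se * scan$se_log2[g, ]
    cand <- list()
    for (dir in c(1, -1)) {
      w <- .best_run(d[g, ], tol, dir, min_steps)
      if (is.null(w)) next
      steps <- w[1]:(w[2] - 1)
      gate <- switch(require_deg,
        multigroup = deg_multi[g],
        any_step_in_run = any(step_sig[g, steps]),
        all_steps_in_run = all(step_sig[g, steps]),
        none = TRUE
      )
      if (!gate) next
      if (require_age_cor && !(pr[g] < cor_alpha && sign(r[g]) == dir)) next
      cand[[length(cand) + 1]] <-
        list(dir = dir, w = w, net = sum(d[g, steps]))
    }
    if (!length(cand)) next
    if (length(cand) == 2) {
      nets <- abs(vapply(cand, `[[`, numeric(1), "net"))
      if (nets[1] == nets[2]) next   # irresolvable tie: leave unclassified
      cand <- cand[which.max(nets)]
    }
    ch <- cand[[1]]
    direction[g] <- if (ch$dir > 0) "P-ADEM" else "N-ADEM"
    run_start[g] <- as.integer(ch$w[1])
    run_end[g] <- as.integer(ch$w[2])
    n_sig[g] <- sum(step_sig[g, ch$w[1]:(ch$w[2] - 1)])
  }

  out <- tibble(
    gene_id = scan$gene_ids,
    direction = direction,
    run_start = run_start,
    run_end = run_end,
    run_start_age = scan$timepoints[run_start],
    run_end_age = scan$timepoints[run_end],
    run_length = run_end - run_start + 1L,
    n_significant_steps = n_sig,
    pearson_r = unname(r),
    pearson_p = unname(pr)
  )
  class(out) <- c("adem_calls", class(out))
  out
}

#' Linear age regression for a single gene
#'
#' Ordinary least squares of log2(CPM + 1) expression on age across
#' individual samples, with the Pearson correlation and a 95% confidence
#' band for the fitted line.
#'
#' @param series An [expression_series()].
#' @param gene_id Gene to test.
#' @return A one-row tibble: `gene_id`, `pearson_r`, `pearson_p`, `slope`,
#'   `intercept`, `slope_se`, `ci95_lo`, `ci95_hi` (slope band), `n`, and
#'   `degenerate` (`TRUE` when expression has zero variance, in which case
#'   `pearson_r` is 0 by convention rather than `NaN`).
#' @export
age_correlation <- function(series, gene_id) {
  stopifnot(inherits(series, "expr_series"))
  if (!gene_id %in% rownames(series$counts)) {
    abort(paste0("Unknown gene: ", gene_id))
  }
  x <- series$meta$age_months
  if (length(x) < 3 || length(unique(x)) < 2) {
    abort("Need >= 3 samples over >= 2 distinct ages.")
  }
  y <- log2(normalize_counts(series, "cpm")[gene_id, ] + 1)
  n <- length(x)
  if (sd(y) == 0) {
    return(tibble(gene_id = gene_id, pearson_r = 0, pearson_p = 1,
                  slope = 0, intercept = mean(y), slope_se = NA_real_,
                  ci95_lo = NA_real_, ci95_hi = NA_real_, n = n,
                  degenerate = TRUE))
  }
  fit <- stats::lm(y ~ x)
  # summary.lm warns on exact fits (r = +/-1); those are valid inputs here
  sm <- suppressWarnings(summary(fit))
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), n - 2)
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tcrit <- qt(0.975, n - 2)
  tibble(gene_id = gene_id, pearson_r = r, pearson_p = p,
         slope = slope, intercept = unname(coef(fit)[1]), slope_se = se,
         ci95_lo = slope - tcrit * se, ci95_hi = slope + tcrit * se,
         n = n, degenerate = FALSE)
}

#' @export
#' @rdname classify_adem
#' @param x An `adem_calls` tibble.
#' @param ... Unused.
tidy.adem_calls <- function(x, ...) {
  dplyr::filter(as_tibble(x), .data$direction != "none")
}

#' @export
#' @rdname classify_adem
glance.adem_calls <- function(x, ...) {
  tibble(
    n_genes = nrow(x),
    n_p_adem = sum(x$direction == "P-ADEM"),
    n_n_adem = sum(x$direction == "N-ADEM")
  )
}
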