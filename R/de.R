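# Negative-binomial differential-expression engine.
#
# Counts y_gj ~ NB(mu_g * s_j, alpha_g) with size factors s_j = lib_j / 1e6,
# so fitted group means live on the counts-per-million scale. Group means
# are maximum-likelihood (1-D optimization per gene and group, library-size
# offsets); the quasi-MLE weighted mean is only the starting point. Using
# the true MLE matters: with unequal library sizes the weighted mean can fit
# worse than the pooled null, truncating the likelihood ratio at zero for a
# few percent of null genes and breaking p-value uniformity.

.nb_size_factors <- function(counts) {
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero)) {
    abort(paste0("Sample(s) with zero total counts: ",
                 paste(zero, collapse = ", ")))
  }
  totals / 1e6
}

.nb_mle_mu <- function(y, sf, alpha) {
  q <- sum(y) / sum(sf)
  if (q <= 0) return(0)
  nll <- function(lm) -sum(dnbinom(y, mu = exp(lm) * sf, size = 1 / alpha,
                                   log = TRUE))
  exp(optimize(nll, c(log(q) - 3, log(q) + 3))$minimum)
}

.nb_ll <- function(y, sf, alpha, mu) {
  sum(dnbinom(y, mu = pmax(mu * sf, 1e-12), size = 1 / alpha, log = TRUE))
}

# Method-of-moments dispersion per gene (residuals around per-group fitted
# means, df-corrected), shrunk toward a lowess mean-dispersion trend.
.estimate_dispersion <- function(counts, sf, grp, shrink = 0.5) {
  n <- ncol(counts)
  k <- length(unique(grp))
  raw <- apply(counts, 1, function(y) {
    mu <- numeric(n)
    for (g in unique(grp)) {
      idx <- grp == g
      mu[idx] <- sum(y[idx]) / sum(sf[idx]) * sf[idx]
    }
    max((sum((y - mu)^2) * n / (n - k) - sum(mu)) / sum(mu^2), 1e-8)
  })
  mn <- log(rowMeans(sweep(counts, 2, sf, "/")) + 0.5)
  if (nrow(counts) >= 10) {
    lo <- lowess(mn, raw, f = 0.5)
    trend <- pmax(approx(lo$x, lo$y, xout = mn, rule = 2)$y, 1e-8)
  } else {
    trend <- rep(max(median(raw), 1e-8), nrow(counts))
  }
  pmax(shrink * trend + (1 - shrink) * raw, 1e-8)
}

# Fit per-group NB means for every gene. Returns CPM-scale means, standard
# errors of the log-mean (observed Fisher information), the free-model
# log-likelihood and its residual deviance.
.nb_fit_groups <- function(counts, sf, grp, alpha) {
  glev <- unique(grp)
  G <- nrow(counts)
  n <- ncol(counts)
  means <- se_log <- matrix(0, G, length(glev))
  ll_free <- dev <- numeric(G)
  for (g in seq_len(G)) {
    y <- counts[g, ]
    a <- alpha[g]
    mu_fit <- numeric(n)
    ll <- 0
    for (j in seq_along(glev)) {
      idx <- grp == glev[j]
      m <- .nb_mle_mu(y[idx], sf[idx], a)
      means[g, j] <- m
      info <- sum((m * sf[idx]) / (1 + a * m * sf[idx]))
      se_log[g, j] <- 1 / sqrt(max(info, 1e-12))
      ll <- ll + .nb_ll(y[idx], sf[idx], a, m)
      mu_fit[idx] <- m * sf[idx]
    }
    ll_free[g] <- ll
    dev[g] <- 2 * sum(y * log(pmax(y, 1e-8) / pmax(mu_fit, 1e-12)) -
                        (y + 1 / a) * log((y + 1 / a) / (mu_fit + 1 / a)))
  }
  colnames(means) <- colnames(se_log) <- as.character(glev)
  list(means = means, se_log = se_log, ll_free = ll_free, dev = dev)
}

.nb_ll_pooled <- function(counts, sf, alpha) {
  vapply(seq_len(nrow(counts)), function(g) {
    m <- .nb_mle_mu(counts[g, ], sf, alpha[g])
    .nb_ll(counts[g, ], sf, alpha[g], m)
  }, numeric(1))
}

.resolve_groups <- function(series, group, what) {
  ids <- colnames(series$counts)
  if (is.character(group)) {
    bad <- setdiff(group, ids)
    if (length(bad)) {
      abort(paste0(what, ": unknown sample id(s): ",
                   paste(bad, collapse = ", ")))
    }
    return(match(group, ids))
  }
  if (is.logical(group)) return(which(group))
  as.integer(group)
}

#' Pairwise negative-binomial differential expression
#'
#' Tests each gene for a mean difference between two disjoint sample
#' groups. Per-gene dispersion is estimated by method of moments and
#' shrunk toward a fitted mean-dispersion trend; group means are NB
#' maximum likelihood with library-size offsets; significance comes from
#' a quasi-likelihood F statistic (the likelihood ratio scaled by a
#' moderated deviance dispersion), which stays calibrated down to three
#' replicates per group.
#'
#' The reported `log2fc` is `log2((mean_b + c) / (mean_a + c))` on the
#' counts-per-million scale with pseudocount `c` (default 0.5), so a
#' positive value means higher expression in `group_b`.
#'
#' @param series An [expression_series()] object.
#' @param group_a,group_b Disjoint sample subsets (sample ids, logical
#'   mask, or column indices), each with at least two samples.
#' @param pseudocount Added to both group means inside the log ratio.
#' @param shrink Weight of the mean-dispersion trend in the shrunk
#'   dispersion estimate (0 = raw per-gene, 1 = pure trend).
#' @param prior_df Prior degrees of freedom for the moderated quasi-
#'   likelihood dispersion.
#' @param dispersion Optional per-gene dispersion vector (or scalar) to
#'   use instead of estimating from these two groups.
#' @param label Comparison label recorded in the `comparison` column.
#' @return A tibble (one row per gene): `gene_id`, `log2fc`, `p`, `p_adj`
#'   (Benjamini-Hochberg), `mean_a`, `mean_b`, `comparison`.
#' @export
#'
#' @examples
#' sim <- simulate_bulk_series(bulk_sim_spec(n_genes = 100, seed = 1))
#' s <- sim$series
#' young <- s$meta$sample_id[s$meta$age_months == 3]
#' old <- s$meta$sample_id[s$meta$age_months == 24]
#' de <- nb_de_pairwise(s, young, old)
#' head(de)
nb_de_pairwise <- function(series, group_a, group_b, pseudocount = 0.5,
                           shrink = 0.5, prior_df = 4, dispersion = NULL,
                           label = "B_vs_A") {
  stopifnot(inherits(series, "expr_series"))
  ia <- .resolve_groups(series, group_a, "group_a")
  ib <- .resolve_groups(series, group_b, "group_b")
  if (length(intersect(ia, ib))) abort("Groups must be disjoint.")
  if (length(ia) < 2 || length(ib) < 2) {
    abort("Each group needs at least two samples.")
  }
  sf_all <- .nb_size_factors(series$counts)
  idx <- c(ia, ib)
  counts <- series$counts[, idx, drop = FALSE]
  sf <- sf_all[idx]
  grp <- rep(c("a", "b"), c(length(ia), length(ib)))

  alpha <- if (is.null(dispersion)) {
    .estimate_dispersion(counts, sf, grp, shrink)
  } else {
    rep_len(dispersion, nrow(counts))
  }

  fit <- .nb_fit_groups(counts, sf, grp, alpha)
  ll0 <- .nb_ll_pooled(counts, sf, alpha)
  lr <- pmax(2 * (fit$ll_free - ll0), 0)

  df_resid <- ncol(counts) - 2
  phi <- fit$dev / df_resid
  phi0 <- max(median(phi), 1e-3)
  phi_mod <- pmax((prior_df * phi0 + df_resid * phi) / (prior_df + df_resid),
                  1e-3)
  p <- pf(lr / phi_mod, 1, prior_df + df_resid, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  mean_a <- fit$means[, "a"]
  mean_b <- fit$means[, "b"]
  tibble(
    gene_id = rownames(series$counts),
    log2fc = log2((mean_b + pseudocount) / (mean_a + pseudocount)),
    p = p,
    p_adj = p.adjust(p, "BH"),
    mean_a = mean_a,
    mean_b = mean_b,
    comparison = label
  )
}

#' Multigroup negative-binomial differential expression
#'
#' One-way NB test across three or more disjoint groups: the likelihood
#' ratio of free group means against a common mean, referred to a
#' chi-squared distribution after a genomic-control style calibration
#' (the statistic is rescaled so its ensemble median matches the
#' chi-squared median; the factor is floored at 1). The per-gene effect
#' size is the largest absolute log2 fold change over all pairwise
#' contrasts of fitted group means (with pseudocount).
#'
#' @param series An [expression_series()] object.
#' @param groups Named list of at least three disjoint sample subsets,
#'   each with >= 2 samples.
#' @inheritParams nb_de_pairwise
#' @return A tibble: `gene_id`, `p`, `p_adj` (Benjamini-Hochberg),
#'   `max_abs_log2fc`, plus one `mean_<name>` column per group. The
#'   calibration factor is stored in `attr(, "lambda")`.
#' @export
nb_de_multigroup <- function(series, groups, pseudocount = 0.5,
                             shrink = 0.5, dispersion = NULL) {
  stopifnot(inherits(series, "expr_series"))
  if (!is.list(groups) || length(groups) < 3) {
    abort("Need >= 3 groups; use `nb_de_pairwise()` for two.")
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  idx_list <- lapply(groups, .resolve_groups, series = series, what = "groups")
  if (any(lengths(idx_list) < 2)) {
    abort("Each group needs at least two samples.")
  }
  all_idx <- unlist(idx_list)
  if (anyDuplicated(all_idx)) abort("Groups must be disjoint.")

  sf_all <- .nb_size_factors(series$counts)
  counts <- series$counts[, all_idx, drop = FALSE]
  sf <- sf_all[all_idx]
  grp <- rep(names(groups), lengths(idx_list))

  alpha <- if (is.null(dispersion)) {
    .estimate_dispersion(counts, sf, grp, shrink)
  } else {
    rep_len(dispersion, nrow(counts))
  }

  fit <- .nb_fit_groups(counts, sf, grp, alpha)
  ll0 <- .nb_ll_pooled(counts, sf, alpha)
  lr <- pmax(2 * (fit$ll_free - ll0), 0)

  df <- length(groups) - 1
  lambda <- max(1, median(lr) / qchisq(0.5, df))
  p <- pchisq(lr / lambda, df, lower.tail = FALSE)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)

  lmeans <- log2(fit$means + pseudocount)
  max_abs <- apply(lmeans, 1, function(x) max(x) - min(x))

  out <- tibble(
    gene_id = rownames(series$counts),
    p = p,
    p_adj = p.adjust(p, "BH"),
    max_abs_log2fc = max_abs
  )
  for (nm in names(groups)) out[[paste0("mean_", nm)]] <- fit$means[, nm]
  attr(out, "lambda") <- lambda
  out
}
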