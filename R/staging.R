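# PCA embedding, contiguity-constrained stage segmentation and
# gradual-vs-switch trajectory classification.

#' PCA embedding of samples in an age series
#'
#' Principal components of samples on log2(CPM + 1) expression (genes
#' centred). Component signs follow a fixed convention -- the loading with
#' the largest magnitude is made positive -- so coordinates are stable
#' across runs and platforms.
#'
#' @param series An [expression_series()].
#' @param n_components Number of components to return; at most
#'   `min(genes, samples)`.
#' @return A list with `coords` (tibble: `sample_id`, `age_months`,
#'   `PC1`..), `explained_variance` (proportions, non-increasing) and
#'   `loadings` (gene x component matrix).
#' @export
pca_embed <- function(series, n_components = 2) {
  stopifnot(inherits(series, "expr_series"))
  x <- t(log2(normalize_counts(series, "cpm") + 1))  # samples x genes
  if (n_components > min(dim(x))) {
    abort("`n_components` exceeds min(#genes, #samples).")
  }
  if (all(apply(x, 2, var) == 0)) {
    abort("Expression matrix has zero variance; nothing to embed.")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- n_components
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- dplyr::bind_cols(
    tibble(sample_id = series$meta$sample_id,
           age_months = series$meta$age_months),
    as_tibble(scores)
  )
  list(coords = coords,
       explained_variance = ev[seq_len(k)],
       loadings = rot)
}

# Minimum within-block SSE over all contiguous partitions of `x`
# (rows = ordered timepoints) into `S` blocks, by dynamic programming.
# Returns the boundaries (last row index of each block) and the SSE.
.best_partition <- function(x, S) {
  Tn <- nrow(x)
  # cost[i, j]: SSE of the block spanning rows i..j
  cost <- matrix(0, Tn, Tn)
  for (i in seq_len(Tn)) {
    for (j in i:Tn) {
      block <- x[i:j, , drop = FALSE]
      m <- colMeans(block)
      cost[i, j] <- sum(sweep(block, 2, m)^2)
    }
  }
  # dp[s, j]: best SSE for rows 1..j in s blocks
  dp <- matrix(Inf, S, Tn)
  cut <- matrix(NA_integer_, S, Tn)
  dp[1, ] <- cost[1, ]
  if (S > 1) {
    for (s in 2:S) {
      for (j in s:Tn) {
        prev <- (s - 1):(j - 1)
        v <- dp[s - 1, prev] + cost[prev + 1, j]
        b <- which.min(v)
        dp[s, j] <- v[b]
        cut[s, j] <- prev[b]
      }
    }
  }
  bounds <- integer(S)
  bounds[S] <- Tn
  if (S > 1) {
    for (s in S:2) bounds[s - 1] <- cut[s, bounds[s]]
  }
  list(bounds = bounds, sse = dp[S, Tn])
}

#' Segment ordered timepoints into contiguous stages
#'
#' Partitions timepoint summaries (for example replicate-averaged PC
#' coordinates, one row per age) into contiguous blocks. For each number
#' of stages `S` up to `max_stages` the partition minimizing within-stage
#' sum of squares is found exactly (dynamic programming is equivalent to
#' exhaustive enumeration here); `S` is then chosen by the penalized
#' criterion `SSE / noise_var + penalty * S * dim * log(T)`. Ties go to
#' fewer stages.
#'
#' `noise_var` is the sampling variance of one timepoint summary. When
#' summaries are replicate averages (the [timepoint_summaries()] helper
#' attaches this automatically) it is the within-timepoint replicate
#' variance over the replicate count; without it, the residual variance
#' under the richest candidate model (`max_stages` blocks) is used.
#' The default `penalty = 4` reflects that an unwarranted extra stage
#' gets to pick the best of roughly `T - S` candidate splits, so the
#' acceptance threshold must beat the maximum of that many chi-squared
#' variates -- substantially more than the usual `log T` per parameter at
#' the short series lengths (T of about 7) this is designed for.
#'
#' @param timepoint_summaries Data frame or matrix of summaries, one row
#'   per timepoint in age order. An `age_months` column, if present, is
#'   used for labelling and excluded from the distance computation.
#' @param max_stages Maximum number of stages considered (default 4).
#' @param penalty Multiplier on the complexity term (default 4).
#' @param noise_var Sampling variance of a timepoint summary (scalar).
#'   Defaults to the `noise_var` attribute of `timepoint_summaries` when
#'   present, else to the richest-model residual variance.
#' @return A `stage_assignment` list: `stages` (tibble: `age_months` if
#'   known, `timepoint`, `stage`), `n_stages`, `sse`, `criterion` (tibble
#'   of candidate `S`, `sse`, `bic`).
#' @export
#'
#' @examples
#' pc1 <- c(0, 0.1, 1.0, 1.1, 1.05, 2.0, 2.1)
#' segment_stages(data.frame(pc1 = pc1), max_stages = 3)
segment_stages <- function(timepoint_summaries, max_stages = 4, penalty = 4,
                           noise_var = NULL) {
  noise_var <- noise_var %||% attr(timepoint_summaries, "noise_var")
  df <- as.data.frame(timepoint_summaries)
  ages <- if ("age_months" %in% names(df)) df$age_months else NULL
  df <- df[, setdiff(names(df), "age_months"), drop = FALSE]
  x <- as.matrix(df)
  storage.mode(x) <- "double"
  Tn <- nrow(x)
  if (Tn < 2) abort("Need >= 2 timepoints.")
  if (max_stages > Tn) abort("`max_stages` exceeds the number of timepoints.")
  d <- ncol(x)
  n <- Tn * d

  fits <- lapply(seq_len(max_stages), function(S) .best_partition(x, S))
  sse <- vapply(fits, `[[`, numeric(1), "sse")
  if (is.null(noise_var)) {
    df_resid <- n - max_stages * d
    if (df_resid < 1) {
      abort(paste0("Cannot estimate summary noise with max_stages = ", max_stages,
                   "; supply `noise_var` or lower `max_stages`."))
    }
    noise_var <- sse[max_stages] / df_resid
  }
  bic <- sse / max(noise_var, 1e-12) +
    penalty * seq_len(max_stages) * d * log(Tn)
  S <- which.min(bic)   # earliest minimum = fewest stages on ties

  bounds <- fits[[S]]$bounds
  stage <- rep(seq_len(S), times = diff(c(0, bounds)))
  stages <- tibble(timepoint = seq_len(Tn), stage = stage)
  if (!is.null(ages)) stages <- dplyr::mutate(stages, age_months = ages,
                                              .before = 1)
  structure(list(
    stages = stages,
    n_stages = S,
    sse = sse[S],
    criterion = tibble(S = seq_len(max_stages), sse = sse, bic = bic)
  ), class = "stage_assignment")
}

#' @export
print.stage_assignment <- function(x, ...) {
  cat("<stage_assignment> ", x$n_stages, " stages over ",
      nrow(x$stages), " timepoints (SSE ", signif(x$sse, 4), ")\n", sep = "")
  print(x$stages)
  invisible(x)
}

#' @export
tidy.stage_assignment <- function(x, ...) x$stages

#' @export
glance.stage_assignment <- function(x, ...) {
  tibble(n_stages = x$n_stages, sse = x$sse,
         n_timepoints = nrow(x$stages))
}

#' Classify an aging trajectory as gradual, switch-like or flat
#'
#' Fits three nested descriptions of a per-timepoint summary value over
#' age -- a constant, a straight line in age, and a single step (every
#' interior timepoint tried as the first post-switch point; the best
#' kept) -- and picks the winner by Gaussian BIC (parameter counts 1, 2
#' and 3 plus the shared variance). A step profile wins only when its fit
#' justifies the extra changepoint parameter; ties prefer the simpler
#' shape.
#'
#' @param timepoint_summaries Data frame with columns `age_months` and
#'   `value` (one row per timepoint, age-ordered), or a numeric vector of
#'   values with ages supplied via `ages`.
#' @param ages Ages in months when `timepoint_summaries` is a bare vector.
#' @return A `trajectory_shape` list: `shape` (`"gradual"`, `"switch"` or
#'   `"flat"`), `changepoint_age` (first post-switch age; `NA` unless
#'   switch), `delta_bic` (BIC of the best non-selected shape minus the
#'   selected one; positive margins mean a clearer call), `bic` (all
#'   three), and `fits` (fitted parameters of each model).
#' @export
#'
#' @examples
#' classify_trajectory_shape(data.frame(age_months = c(3, 6, 9, 12, 16, 19, 24),
#'                                      value = c(0, 0, 0, 1, 1, 1, 1)))
classify_trajectory_shape <- function(timepoint_summaries, ages = NULL) {
  if (is.numeric(timepoint_summaries) && is.null(dim(timepoint_summaries))) {
    if (is.null(ages)) abort("Supply `ages` alongside a bare value vector.")
    df <- tibble(age_months = ages, value = timepoint_summaries)
  } else {
    df <- as_tibble(timepoint_summaries)
    if (!all(c("age_months", "value") %in% names(df))) {
      abort("`timepoint_summaries` needs columns `age_months` and `value`.")
    }
  }
  df <- dplyr::arrange(df, .data$age_months)
  y <- df$value
  a <- df$age_months
  Tn <- length(y)
  if (Tn < 4) abort("Need >= 4 timepoints to classify a trajectory shape.")

  rss_flat <- sum((y - mean(y))^2)
  fit_lin <- stats::lm(y ~ a)
  rss_lin <- sum(stats::resid(fit_lin)^2)

  best_step <- NULL
  rss_step <- Inf
  for (cp in 2:Tn) {   # cp = first timepoint at the post-switch level
    lo <- mean(y[seq_len(cp - 1)])
    hi <- mean(y[cp:Tn])
    rss <- sum((y[seq_len(cp - 1)] - lo)^2) + sum((y[cp:Tn] - hi)^2)
    if (rss < rss_step) {
      rss_step <- rss
      best_step <- list(cp = cp, level_pre = lo, level_post = hi)
    }
  }

  bic_of <- function(rss, k) Tn * log(max(rss, 1e-12) / Tn) + (k + 1) * log(Tn)
  bic <- c(flat = bic_of(rss_flat, 1),
           gradual = bic_of(rss_lin, 2),
           switch = bic_of(rss_step, 3))
  # ties prefer the simpler shape (flat < gradual < switch in that order)
  shape <- names(bic)[which.min(bic)]
  delta <- sort(bic)[2] - min(bic)

  structure(list(
    shape = shape,
    changepoint_age = if (shape == "switch") a[best_step$cp] else NA_real_,
    delta_bic = unname(delta),
    bic = bic,
    fits = list(
      flat = list(level = mean(y), rss = rss_flat),
      gradual = list(intercept = unname(coef(fit_lin)[1]),
                     slope = unname(coef(fit_lin)[2]), rss = rss_lin),
      switch = c(best_step, list(rss = rss_step,
                                 changepoint_age = a[best_step$cp]))
    )
  ), class = "trajectory_shape")
}

#' @export
print.trajectory_shape <- function(x, ...) {
  cat("<trajectory_shape> ", x$shape, sep = "")
  if (x$shape == "switch") cat(" (changepoint at ", x$changepoint_age,
                               " months)", sep = "")
  cat(", delta BIC ", signif(x$delta_bic, 3), "\n", sep = "")
  invisible(x)
}

#' @export
glance.trajectory_shape <- function(x, ...) {
  tibble(shape = x$shape, changepoint_age = x$changepoint_age,
         delta_bic = x$delta_bic)
}

#' Replicate-averaged PC summaries per timepoint
#'
#' Convenience bridge from [pca_embed()] to [segment_stages()] /
#' [classify_trajectory_shape()]: averages sample coordinates within each
#' age.
#'
#' @param embedding Result of [pca_embed()].
#' @return Tibble with one row per age: `age_months` plus the averaged
#'   component columns. The `noise_var` attribute holds the estimated
#'   sampling variance of one summary value (within-age replicate
#'   variance over replicate count, pooled over ages and components),
#'   which [segment_stages()] picks up automatically.
#' @export
timepoint_summaries <- function(embedding) {
  out <- embedding$coords |>
    dplyr::group_by(.data$age_months) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("PC"), mean),
                     .groups = "drop") |>
    dplyr::arrange(.data$age_months)
  nv <- embedding$coords |>
    dplyr::group_by(.data$age_months) |>
    dplyr::summarise(dplyr::across(dplyr::starts_with("PC"),
                                   ~ var(.x) / length(.x)),
                     .groups = "drop") |>
    dplyr::select(dplyr::starts_with("PC"))
  nv <- mean(as.matrix(nv), na.rm = TRUE)
  if (is.finite(nv)) attr(out, "noise_var") <- nv
  out
}
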