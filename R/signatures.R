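# Gene-set signature scoring with expression-matched controls, set
# overlap statistics and fold-change concordance.

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB
#' member...`. Members are de-duplicated; empty sets and malformed lines
#' are rejected with the offending line number.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (set members).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(paste0("Malformed GMT line ", i,
                   ": need name, description and >= 1 member."))
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) {
      abort(paste0("Empty gene set on GMT line ", i, "."))
    }
    sets[[parts[1]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return Invisibly, `path`.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    abort("`sets` must be a named list.")
  }
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Expression-matched module score
#'
#' Scores each cell (or sample) for a gene set against controls matched on
#' dataset-average expression: genes are cut into `n_bins` equal-frequency
#' bins by their average log expression, `n_ctrl` control genes are drawn
#' from the bin of each set gene (without replacement within a bin, with
#' replacement once a bin is exhausted), and the score is the per-cell
#' mean over set genes minus the mean over the pooled controls. Adding a
#' constant to the whole matrix leaves scores unchanged.
#'
#' @param expr Cell-by-gene matrix of normalized log expression (cells in
#'   rows).
#' @param set Character vector of set gene ids; must all be columns of
#'   `expr`.
#' @param n_bins Number of average-expression bins (default 25, reduced
#'   automatically if there are fewer genes than bins).
#' @param n_ctrl Control genes sampled per set gene (default 100).
#' @param seed Integer seed for the control draw.
#' @return A tibble: `cell_id`, `score`, with the parameters in
#'   attributes `n_bins`, `n_ctrl`, `seed`.
#' @export
#'
#' @examples
#' sim <- simulate_cell_counts(c(50, 50), 200,
#'                             sprintf("gene%04d", 1:10), 1, seed = 1)
#' expr <- log1p(sim$counts)
#' sc <- module_score(expr, sprintf("gene%04d", 1:10), seed = 1)
#' head(sc)
module_score <- function(expr, set, n_bins = 25, n_ctrl = 100, seed = 1) {
  expr <- as.matrix(expr)
  if (is.null(colnames(expr))) abort("`expr` needs gene ids as column names.")
  missing_genes <- setdiff(set, colnames(expr))
  if (length(missing_genes)) {
    abort(paste0("Set gene(s) absent from `expr`: ",
                 paste(head(missing_genes, 5), collapse = ", ")))
  }
  if (length(set) > ncol(expr) / 2) {
    warn("Gene set covers more than half the universe; control matching is weak.")
  }
  if (n_bins < 2) abort("`n_bins` must be >= 2.")
  n_bins <- min(n_bins, ncol(expr))

  avg <- colMeans(expr)
  # equal-frequency bins on average expression (rank-based)
  bin <- dplyr::ntile(rank(avg, ties.method = "first"), n_bins)
  names(bin) <- colnames(expr)

  ctrl <- withr::with_seed(seed, {
    picks <- character(0)
    for (g in set) {
      pool <- setdiff(names(bin)[bin == bin[[g]]], g)
      if (length(pool) >= n_ctrl) {
        picks <- c(picks, sample(pool, n_ctrl))
      } else if (length(pool)) {
        picks <- c(picks, sample(pool, n_ctrl, replace = TRUE))
      }
    }
    picks
  })
  if (!length(ctrl)) abort("No control genes available for this set.")

  score <- rowMeans(expr[, set, drop = FALSE]) -
    rowMeans(expr[, ctrl, drop = FALSE])
  out <- tibble(
    cell_id = rownames(expr) %||% paste0("cell", seq_len(nrow(expr))),
    score = unname(score)
  )
  attr(out, "n_bins") <- n_bins
  attr(out, "n_ctrl") <- n_ctrl
  attr(out, "seed") <- seed
  out
}

#' Overlap between two gene sets with hypergeometric enrichment
#'
#' @param a,b Character vectors of gene ids; both must be subsets of
#'   `universe`.
#' @param universe Character vector of all eligible gene ids (for a
#'   filtered bulk series, the genes surviving [filter_low_expression()]).
#' @return A list: `intersection`, `n_a`, `n_b`, `n_overlap`,
#'   `n_universe`, and one-sided hypergeometric `p` for an overlap at
#'   least this large.
#' @export
set_overlap <- function(a, b, universe) {
  a <- unique(a); b <- unique(b); universe <- unique(universe)
  out_a <- setdiff(a, universe)
  out_b <- setdiff(b, universe)
  if (length(out_a) || length(out_b)) {
    abort(paste0("Set member(s) outside the universe: ",
                 paste(head(c(out_a, out_b), 5), collapse = ", ")))
  }
  inter <- intersect(a, b)
  k <- length(inter)
  p <- phyper(k - 1, length(a), length(universe) - length(a), length(b),
              lower.tail = FALSE)
  list(intersection = inter, n_a = length(a), n_b = length(b),
       n_overlap = k, n_universe = length(universe), p = p)
}

#' Fold-change concordance between two comparisons
#'
#' Pearson correlation and OLS fit of log2 fold changes over the genes
#' shared by two named fold-change vectors -- the standard check that two
#' signatures (for example an aging set against a disease-associated set)
#' move the same genes the same way.
#'
#' @param fc_a,fc_b Named numeric vectors of log2 fold changes.
#' @return A one-row tibble: `pearson_r`, `p`, `slope`, `intercept`,
#'   `n_shared`.
#' @export
fc_concordance <- function(fc_a, fc_b) {
  if (is.null(names(fc_a)) || is.null(names(fc_b))) {
    abort("Both fold-change vectors must be named by gene.")
  }
  shared <- intersect(names(fc_a), names(fc_b))
  if (length(shared) < 3) abort("Need >= 3 shared genes.")
  x <- fc_a[shared]; y <- fc_b[shared]
  n <- length(shared)
  r <- cor(x, y)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tstat), n - 2)
  if (abs(r) >= 1) p <- 0
  fit <- stats::lm(y ~ x)
  tibble(pearson_r = unname(r), p = unname(p),
         slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         n_shared = n)
}
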