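#' Library-size normalization of a count series
#'
#' CPM rescales each sample so its column total is exactly one million;
#' FPKM additionally divides each gene's CPM by its transcript length in
#' kilobases (so a 2 kb gene's FPKM is half its CPM).
#'
#' @param series An [expression_series()] object.
#' @param method `"cpm"` or `"fpkm"`. FPKM requires `gene_lengths` on the
#'   series.
#' @return A numeric matrix with the same dimensions as `series$counts`.
#' @export
normalize_counts <- function(series, method = c("cpm", "fpkm")) {
  stopifnot(inherits(series, "expr_series"))
  method <- match.arg(method)
  totals <- colSums(series$counts)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    abort(paste0("Sample(s) with zero total counts: ",
                 paste(zero, collapse = ", ")))
  }
  cpm <- sweep(series$counts, 2, totals, "/") * 1e6
  if (method == "cpm") return(cpm)
  if (is.null(series$gene_lengths)) {
    abort("FPKM requires `gene_lengths` (kb) on the series.")
  }
  cpm / series$gene_lengths
}

#' Filter genes below an average-FPKM threshold
#'
#' Mirrors the common bulk RNA-seq practice of excluding genes whose mean
#' expression over all samples falls below 10 FPKM. The boundary is
#' inclusive: genes with mean FPKM exactly at the threshold are kept
#' ("fewer than" the threshold is excluded). Gene order is preserved.
#'
#' @param series An [expression_series()] with `gene_lengths`.
#' @param threshold_fpkm Minimum mean FPKM to retain a gene (default 10).
#' @return List: `series` (filtered [expression_series()]) and `removed`
#'   (character vector of dropped gene ids).
#' @export
filter_low_expression <- function(series, threshold_fpkm = 10) {
  stopifnot(inherits(series, "expr_series"))
  fpkm <- normalize_counts(series, "fpkm")
  keep <- rowMeans(fpkm) >= threshold_fpkm
  if (!any(keep)) abort("All genes fall below the expression threshold.")
  filtered <- expression_series(
    series$counts[keep, , drop = FALSE],
    series$meta,
    gene_lengths = series$gene_lengths[keep]
  )
  list(series = filtered, removed = rownames(series$counts)[!keep])
}

#' Benjamini-Hochberg adjustment
#'
#' Thin, validated wrapper over the standard step-up procedure.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method Only `"bh"` is supported.
#' @return Adjusted p-values, elementwise >= `p` and <= 1.
#' @export
adjust_pvalues <- function(p, method = "bh") {
  method <- match.arg(tolower(method), "bh")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}
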