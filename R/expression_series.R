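#' Construct a longitudinal expression series
#'
#' Bundles a gene-by-sample matrix of raw counts with per-sample metadata
#' describing an ordered age design. This is the substrate consumed by the
#' differential-expression engine, the trend classifier and the staging
#' module.
#'
#' @param counts Integer matrix, genes in rows and samples in columns.
#'   Row names are gene identifiers, column names are sample identifiers.
#' @param meta Data frame with one row per sample; must contain columns
#'   `sample_id`, `age_months` (positive numeric) and `replicate`
#'   (positive integer). An optional `sex` column (`"F"`/`"M"`) is carried
#'   along. Rows must match the columns of `counts` one to one.
#' @param gene_lengths Optional named numeric vector of transcript lengths
#'   in kilobases, one per gene. Required for FPKM normalization.
#'
#' @return An object of class `expr_series`: a list with elements `counts`,
#'   `meta` (tibble ordered as the count columns) and `gene_lengths`.
#' @export
#'
#' @examples
#' counts <- matrix(rpois(12, 50), 3, 4,
#'                  dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' meta <- data.frame(sample_id = paste0("s", 1:4),
#'                    age_months = c(3, 3, 24, 24), replicate = c(1, 2, 1, 2))
#' es <- expression_series(counts, meta)
#' es
expression_series <- function(counts, meta, gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    abort("`counts` must have gene identifiers as row names.")
  }
  if (is.null(colnames(counts))) {
    abort("`counts` must have sample identifiers as column names.")
  }
  if (anyDuplicated(rownames(counts))) {
    dups <- unique(rownames(counts)[duplicated(rownames(counts))])
    abort(paste0("Duplicate gene ids: ", paste(head(dups, 5), collapse = ", ")))
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    abort("`counts` must be finite and non-negative.")
  }
  if (any(counts != round(counts))) {
    abort("`counts` must be whole numbers (raw counts, not normalized values).")
  }
  storage.mode(counts) <- "double"

  meta <- as_tibble(meta)
  needed <- c("sample_id", "age_months", "replicate")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols)) {
    abort(paste0("`meta` is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  extra <- setdiff(meta$sample_id, colnames(counts))
  absent <- setdiff(colnames(counts), meta$sample_id)
  if (length(extra)) {
    abort(paste0("Metadata sample(s) not in counts: ",
                 paste(head(extra, 5), collapse = ", ")))
  }
  if (length(absent)) {
    abort(paste0("Count column(s) without metadata: ",
                 paste(head(absent, 5), collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("`meta$sample_id` must be unique.")
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  if (!is.numeric(meta$age_months) || any(!is.finite(meta$age_months)) ||
      any(meta$age_months <= 0)) {
    abort("`meta$age_months` must be positive and finite.")
  }

  if (!is.null(gene_lengths)) {
    if (is.null(names(gene_lengths)) ||
        !all(rownames(counts) %in% names(gene_lengths))) {
      abort("`gene_lengths` must be named and cover every gene in `counts`.")
    }
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(gene_lengths <= 0)) abort("`gene_lengths` must be positive (kb).")
  }

  structure(
    list(counts = counts, meta = meta, gene_lengths = gene_lengths),
    class = "expr_series"
  )
}

#' @export
print.expr_series <- function(x, ...) {
  ages <- sort(unique(x$meta$age_months))
  cat("<expr_series> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("  ages (months): ", paste(ages, collapse = ", "), "\n", sep = "")
  if (!is.null(x$gene_lengths)) cat("  gene lengths: present (kb)\n")
  invisible(x)
}

#' @export
dim.expr_series <- function(x) dim(x$counts)

#' Ages of the distinct timepoints in an expression series
#'
#' @param series An [expression_series()] object.
#' @return Sorted numeric vector of distinct `age_months` values.
#' @export
series_timepoints <- function(series) {
  stopifnot(inherits(series, "expr_series"))
  sort(unique(series$meta$age_months))
}

#' Write an expression series to TSV files
#'
#' Counts are written genes-by-samples with a leading `gene_id` column;
#' metadata is written one row per sample.
#'
#' @param series An [expression_series()] object.
#' @param counts_path,meta_path Output file paths.
#' @return Invisibly, the input `series`.
#' @export
write_expression_series <- function(series, counts_path, meta_path) {
  stopifnot(inherits(series, "expr_series"))
  tab <- dplyr::bind_cols(
    tibble(gene_id = rownames(series$counts)),
    as_tibble(series$counts)
  )
  readr::write_tsv(tab, counts_path)
  readr::write_tsv(series$meta, meta_path)
  invisible(series)
}

#' Read an expression series from disk
#'
#' Accepts either a dense counts TSV (first column `gene_id`, one column
#' per sample) or a Matrix Market triplet file accompanied by `features`
#' and `barcodes` TSVs (one identifier per line). Counts must be whole
#' numbers; normalized or fractional matrices are rejected rather than
#' silently coerced.
#'
#' @param counts_path Path to the counts TSV, or to a `.mtx` file.
#' @param meta_path Path to the sample metadata TSV (columns `sample_id`,
#'   `age_months`, `replicate`, optionally `sex`).
#' @param features_path,barcodes_path Row/column identifier files, required
#'   when `counts_path` is an MTX triplet.
#' @param gene_lengths Optional named vector of lengths in kb, passed on to
#'   [expression_series()].
#' @return An [expression_series()] object.
#' @export
read_expression_series <- function(counts_path, meta_path,
                                   features_path = NULL, barcodes_path = NULL,
                                   gene_lengths = NULL) {
  if (!file.exists(counts_path)) abort(paste0("No such file: ", counts_path))
  if (!file.exists(meta_path)) abort(paste0("No such file: ", meta_path))

  if (grepl("\\.mtx$", counts_path)) {
    if (is.null(features_path) || is.null(barcodes_path)) {
      abort("MTX input needs `features_path` and `barcodes_path`.")
    }
    m <- as.matrix(Matrix::readMM(counts_path))
    feats <- readr::read_tsv(features_path, col_names = "gene_id",
                             show_col_types = FALSE)$gene_id
    cells <- readr::read_tsv(barcodes_path, col_names = "sample_id",
                             show_col_types = FALSE)$sample_id
    if (length(feats) != nrow(m)) {
      abort("features file length does not match MTX row count.")
    }
    if (length(cells) != ncol(m)) {
      abort("barcodes file length does not match MTX column count.")
    }
    dimnames(m) <- list(feats, cells)
    counts <- m
  } else {
    tab <- readr::read_tsv(counts_path, show_col_types = FALSE)
    if (names(tab)[1] != "gene_id") {
      abort("Counts table must have `gene_id` as its first column.")
    }
    counts <- as.matrix(tab[, -1, drop = FALSE])
    rownames(counts) <- tab$gene_id
  }

  meta <- readr::read_tsv(meta_path, show_col_types = FALSE)
  expression_series(counts, meta, gene_lengths = gene_lengths)
}

#' Write a sparse count matrix as a Matrix Market triplet
#'
#' @param counts Matrix (genes x cells/samples) with dimnames.
#' @param dir Output directory; files `matrix.mtx`, `features.tsv` and
#'   `barcodes.tsv` are created inside it.
#' @return Invisibly, the directory path.
#' @export
write_counts_mtx <- function(counts, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}
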