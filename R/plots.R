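# ggplot2 displays for the main result types.

#' Plot a gene's expression trajectory over age
#'
#' Points are individual samples (log2 CPM + 1); the line and ribbon show
#' the OLS age regression with its 95% confidence band, annotated with the
#' Pearson correlation.
#'
#' @param series An [expression_series()].
#' @param gene_id Gene to display.
#' @return A ggplot object.
#' @export
plot_age_trend <- function(series, gene_id) {
  stopifnot(inherits(series, "expr_series"))
  ac <- age_correlation(series, gene_id)
  df <- tibble(
    age_months = series$meta$age_months,
    expr = log2(normalize_counts(series, "cpm")[gene_id, ] + 1)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$age_months, .data$expr)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "steelblue", fill = "grey80") +
    ggplot2::geom_point() +
    ggplot2::labs(
      title = gene_id,
      subtitle = sprintf("r = %.2f, p = %.2g", ac$pearson_r, ac$pearson_p),
      x = "Age (months)", y = "log2(CPM + 1)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.adem_calls <- function(object, ...) {
  counts <- dplyr::count(dplyr::filter(as_tibble(object),
                                       .data$direction != "none"),
                         .data$direction)
  ggplot2::ggplot(counts, ggplot2::aes(.data$direction, .data$n,
                                       fill = .data$direction)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = NULL, y = "Genes",
                  title = "Age-dependent trend calls") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.stage_assignment <- function(object, ...) {
  df <- object$stages
  xvar <- if ("age_months" %in% names(df)) "age_months" else "timepoint"
  ggplot2::ggplot(df, ggplot2::aes(.data[[xvar]], .data$stage)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_continuous(breaks = seq_len(object$n_stages)) +
    ggplot2::labs(x = if (xvar == "age_months") "Age (months)" else "Timepoint",
                  y = "Stage", title = "Stage segmentation") +
    ggplot2::theme_minimal()
}

#' Plot a PCA embedding coloured by age
#'
#' @param embedding Result of [pca_embed()].
#' @return A ggplot object.
#' @export
plot_embedding <- function(embedding) {
  ev <- embedding$explained_variance
  ggplot2::ggplot(embedding$coords,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = .data$age_months)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_viridis_c(name = "Age (months)") +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * ev[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ev[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot Sholl profiles
#'
#' @param profiles A list of [sholl_profile()] objects.
#' @return A ggplot object (mean curve with per-cell traces).
#' @export
plot_sholl <- function(profiles) {
  df <- purrr::imap_dfr(profiles, function(p, i) {
    tibble(cell = i, radius = p$radii, intersections = p$intersections)
  })
  mean_df <- df |>
    dplyr::group_by(.data$radius) |>
    dplyr::summarise(intersections = mean(.data$intersections),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$radius, .data$intersections)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$cell),
                       alpha = 0.2, colour = "grey50") +
    ggplot2::geom_line(data = mean_df, linewidth = 1.1,
                       colour = "firebrick") +
    ggplot2::labs(x = "Radius (µm)", y = "Intersections") +
    ggplot2::theme_minimal()
}

#' Write a differential-expression table to TSV
#'
#' @param de A tibble from [nb_de_pairwise()] or [nb_de_multigroup()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_de_table <- function(de, path) {
  readr::write_tsv(as_tibble(de), path)
  invisible(path)
}
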