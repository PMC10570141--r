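# Forced-turnover quantification: cumulative divisions from
# depletion-repopulation densities, relative telomere length from qPCR,
# Sholl morphology, the senescence index, and the Y-maze alternation rate.

#' Depletion-repopulation density record
#'
#' @param residual_density,recovered_density Positive densities in
#'   cells/mm^2, one pair per round: the density left after depletion and
#'   the density after the population regrew.
#' @return A `turnover_record` tibble with columns `round`,
#'   `residual_density`, `recovered_density`.
#' @export
turnover_record <- function(residual_density, recovered_density) {
  if (length(residual_density) != length(recovered_density) ||
      !length(residual_density)) {
    abort("Need equal-length, non-empty density vectors.")
  }
  if (any(residual_density <= 0) || any(recovered_density <= 0)) {
    abort("Densities must be strictly positive.")
  }
  out <- tibble(round = seq_along(residual_density),
                residual_density = as.numeric(residual_density),
                recovered_density = as.numeric(recovered_density))
  class(out) <- c("turnover_record", class(out))
  out
}

#' Cumulative cell divisions across depletion-repopulation rounds
#'
#' Each round's residual population must double log2(recovered/residual)
#' times to regrow, so the minimal cumulative division count is the sum of
#' those per-round log2 ratios. For the three-round experiment with
#' residual/recovered densities 0.1304/190.2, 1.821/221.2 and 3.211/247.9
#' cells/mm^2 this gives 23.71 divisions.
#'
#' @param record A [turnover_record()] (or data frame with
#'   `residual_density` and `recovered_density` columns).
#' @return Total divisions (log2 units), a single number.
#' @export
#'
#' @examples
#' rec <- turnover_record(c(0.1304, 1.821, 3.211), c(190.2, 221.2, 247.9))
#' cumulative_divisions(rec)  # 23.71
cumulative_divisions <- function(record) {
  df <- as.data.frame(record)
  if (!all(c("residual_density", "recovered_density") %in% names(df))) {
    abort("`record` needs `residual_density` and `recovered_density`.")
  }
  if (any(df$residual_density <= 0) || any(df$recovered_density <= 0)) {
    abort("Densities must be strictly positive.")
  }
  sum(log2(df$recovered_density / df$residual_density))
}

#' Relative telomere length assay
#'
#' Holds the quantification cycles of a telomere qPCR: target and
#' reference samples, each assayed for the telomere amplicon and for a
#' single-copy reference locus, plus the reference telomere length.
#'
#' @param cq_target_tel,cq_ref_tel Telomere-amplicon Cq of the target and
#'   reference samples.
#' @param cq_target_scr,cq_ref_scr Single-copy-reference Cq of the target
#'   and reference samples.
#' @param ref_length_kb Reference telomere length in kb (> 0).
#' @return A `telomere_assay` list.
#' @export
telomere_assay <- function(cq_target_tel, cq_ref_tel, cq_target_scr,
                           cq_ref_scr, ref_length_kb) {
  vals <- c(cq_target_tel, cq_ref_tel, cq_target_scr, cq_ref_scr)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort("All Cq values must be finite and positive.")
  }
  if (ref_length_kb <= 0) abort("`ref_length_kb` must be > 0.")
  structure(list(cq_target_tel = cq_target_tel, cq_ref_tel = cq_ref_tel,
                 cq_target_scr = cq_target_scr, cq_ref_scr = cq_ref_scr,
                 ref_length_kb = ref_length_kb),
            class = "telomere_assay")
}

#' Telomere length from relative qPCR quantification
#'
#' Computes `ref_length_kb * 2^((Cq_target,tel - Cq_ref,tel) -
#' (Cq_target,scr - Cq_ref,scr))`. The default `"as_printed"` convention
#' applies that formula literally; note its exponent carries the opposite
#' sign to the conventional relative-quantification rule 2^(-ddCq) (a
#' *lower* telomere Cq means *more* telomeric template), so
#' `convention = "standard"` negates the exponent for users who want the
#' textbook behaviour.
#'
#' @param assay A [telomere_assay()].
#' @param convention `"as_printed"` (default) or `"standard"`.
#' @return Estimated telomere length in kb.
#' @export
#'
#' @examples
#' a <- telomere_assay(21, 20, 22, 22, ref_length_kb = 100)
#' telomere_length(a)  # 200
telomere_length <- function(assay, convention = c("as_printed", "standard")) {
  stopifnot(inherits(assay, "telomere_assay"))
  convention <- match.arg(convention)
  ddcq <- (assay$cq_target_tel - assay$cq_ref_tel) -
    (assay$cq_target_scr - assay$cq_ref_scr)
  expo <- if (convention == "as_printed") ddcq else -ddcq
  assay$ref_length_kb * 2^expo
}

#' Sholl intersection profile
#'
#' @param radii Strictly increasing, uniformly spaced radii in
#'   micrometres (the standard protocol starts at 5 um and advances in
#'   5 um rings).
#' @param intersections Non-negative integer intersection counts, one per
#'   radius.
#' @return A `sholl_profile` list.
#' @export
sholl_profile <- function(radii, intersections) {
  if (length(radii) != length(intersections)) {
    abort("`radii` and `intersections` must have equal length.")
  }
  if (length(radii) >= 2) {
    steps <- diff(radii)
    if (any(steps <= 0) || length(unique(round(steps, 9))) != 1) {
      abort("`radii` must be strictly increasing with a uniform step.")
    }
  }
  if (any(intersections < 0) || any(intersections != round(intersections))) {
    abort("`intersections` must be non-negative integers.")
  }
  structure(list(radii = as.numeric(radii),
                 intersections = as.numeric(intersections)),
            class = "sholl_profile")
}

#' Area under a Sholl curve
#'
#' Trapezoidal integral of intersection counts over radius, the standard
#' scalar summary of morphological complexity. No extrapolation below the
#' first radius.
#'
#' @param profile A [sholl_profile()] with >= 2 radii.
#' @return AUC in intersections x micrometres.
#' @export
#'
#' @examples
#' sholl_auc(sholl_profile(c(5, 10, 15), c(0, 4, 0)))  # 20
sholl_auc <- function(profile) {
  stopifnot(inherits(profile, "sholl_profile"))
  r <- profile$radii
  y <- profile$intersections
  if (length(r) < 2) abort("Need >= 2 radii for an AUC.")
  sum(diff(r) * (y[-1] + y[-length(y)]) / 2)
}

#' Microglial senescence index
#'
#' Density divided by morphological complexity (Sholl AUC): aged-like
#' populations are denser and less ramified, so larger values indicate a
#' more senescent state.
#'
#' @param density Microglial density in cells/mm^2.
#' @param auc Sholl AUC (> 0), e.g. from [sholl_auc()].
#' @return The index (density / AUC).
#' @export
#'
#' @examples
#' senescence_index(330, 110)  # 3
senescence_index <- function(density, auc) {
  if (any(auc <= 0)) abort("`auc` must be > 0.")
  if (any(density < 0)) abort("`density` must be non-negative.")
  density / auc
}

#' Y-maze correct alternation rate
#'
#' A correct alternation is a window of three consecutive arm entries
#' visiting three distinct arms; windows slide by one entry. The rate is
#' `alternations / (total entries - 2) * 100`.
#'
#' @param entries Character vector of arm labels, each one of
#'   `"A"`, `"B"`, `"C"`, in entry order.
#' @return Percentage in \[0, 100\].
#' @export
#'
#' @examples
#' alternation_rate(c("A", "B", "C", "A", "B", "C", "A", "B", "C", "A"))  # 100
#' alternation_rate(c("A", "A", "B", "C", "B"))  # 33.33
alternation_rate <- function(entries) {
  entries <- as.character(entries)
  if (length(entries) < 3) abort("Need at least 3 arm entries.")
  bad <- setdiff(unique(entries), c("A", "B", "C"))
  if (length(bad)) {
    abort(paste0("Unknown arm label(s): ", paste(bad, collapse = ", ")))
  }
  n <- length(entries)
  wins <- vapply(seq_len(n - 2), function(i) {
    length(unique(entries[i:(i + 2)])) == 3
  }, logical(1))
  sum(wins) / (n - 2) * 100
}
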