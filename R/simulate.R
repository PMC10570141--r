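#' Specification for a synthetic bulk aging series
#'
#' Describes a negative-binomial count simulation over an ordered set of
#' age timepoints, mirroring a cross-sectional bulk RNA-seq aging design:
#' seven ages spanning young to aged animals with a few biological
#' replicates each. Trend genes either drift gradually (a fixed log2
#' increment per adjacent timepoint) or switch once and stay at the new
#' level; the remainder are flat nulls.
#'
#' Counts for gene g in sample j are drawn NB with
#' mean = exp(baseline_g + trend_g(age_j)) * lib_size_j / 1e6 and variance
#' mu + dispersion * mu^2 (dispersion shared across genes). Baselines are
#' therefore interpreted on the counts-per-million scale of a 1e6-read
#' library; library sizes are drawn log-uniformly within `lib_size_range`.
#'
#' @param n_genes Total number of genes.
#' @param timepoints Strictly increasing ages in months.
#' @param reps_per_timepoint Replicates per timepoint; a single value is
#'   recycled. All must be >= 2.
#' @param n_up_gradual,n_down_gradual Number of gradually increasing /
#'   decreasing trend genes.
#' @param n_up_switch,n_down_switch Number of step-change genes.
#' @param per_step_log2_effect Log2 change per adjacent timepoint for
#'   gradual genes (>= 0).
#' @param switch_log2_effect Log2 jump applied from `switch_timepoint`
#'   onward for switch genes (>= 0).
#' @param switch_timepoint Index (1-based) of the first timepoint at the
#'   post-switch level; must be an interior index.
#' @param dispersion NB dispersion alpha (> 0), Var = mu + alpha mu^2.
#' @param baseline_log_mean_range Range (natural-log scale) for per-gene
#'   baseline means at a 1e6-read library.
#' @param lib_size_range Range of library sizes (total reads).
#' @param seed Integer seed; the simulation is a pure function of the spec.
#'
#' @return A `bulk_sim_spec` list, validated.
#' @export
bulk_sim_spec <- function(n_genes = 2000,
                          timepoints = c(3, 6, 9, 12, 14, 16, 24),
                          reps_per_timepoint = 3,
                          n_up_gradual = 100, n_down_gradual = 100,
                          n_up_switch = 0, n_down_switch = 0,
                          per_step_log2_effect = 0.3,
                          switch_log2_effect = 1,
                          switch_timepoint = 5,
                          dispersion = 0.1,
                          baseline_log_mean_range = log(c(50, 2000)),
                          lib_size_range = c(0.8e6, 1.2e6),
                          seed = 1) {
  Tn <- length(timepoints)
  if (Tn < 2 || any(diff(timepoints) <= 0)) {
    abort("`timepoints` must be strictly increasing with length >= 2.")
  }
  if (length(reps_per_timepoint) == 1) {
    reps_per_timepoint <- rep(reps_per_timepoint, Tn)
  }
  if (length(reps_per_timepoint) != Tn) {
    abort("`reps_per_timepoint` must have one entry per timepoint.")
  }
  if (any(reps_per_timepoint < 2)) {
    abort("`reps_per_timepoint`: all replicate counts must be >= 2.")
  }
  n_trend <- n_up_gradual + n_down_gradual + n_up_switch + n_down_switch
  if (n_trend > n_genes) {
    abort("Trend-gene counts exceed `n_genes`.")
  }
  if (per_step_log2_effect < 0) abort("`per_step_log2_effect` must be >= 0.")
  if (switch_log2_effect < 0) abort("`switch_log2_effect` must be >= 0.")
  if ((n_up_switch + n_down_switch) > 0 &&
      (switch_timepoint < 2 || switch_timepoint > Tn)) {
    abort("`switch_timepoint` must be an interior timepoint index (2..T).")
  }
  if (dispersion <= 0) abort("`dispersion` must be > 0.")
  if (length(baseline_log_mean_range) != 2 ||
      diff(baseline_log_mean_range) < 0) {
    abort("`baseline_log_mean_range` must be (lo, hi) with lo <= hi.")
  }
  if (length(lib_size_range) != 2 || any(lib_size_range <= 0) ||
      diff(lib_size_range) < 0) {
    abort("`lib_size_range` must be positive (lo, hi) with lo <= hi.")
  }
  if (length(seed) != 1 || !is.finite(seed)) abort("`seed` must be an integer.")

  structure(list(
    n_genes = n_genes, timepoints = timepoints,
    reps_per_timepoint = reps_per_timepoint,
    n_up_gradual = n_up_gradual, n_down_gradual = n_down_gradual,
    n_up_switch = n_up_switch, n_down_switch = n_down_switch,
    per_step_log2_effect = per_step_log2_effect,
    switch_log2_effect = switch_log2_effect,
    switch_timepoint = switch_timepoint,
    dispersion = dispersion,
    baseline_log_mean_range = baseline_log_mean_range,
    lib_size_range = lib_size_range,
    seed = as.integer(seed)
  ), class = "bulk_sim_spec")
}

#' Simulate a bulk RNA-seq aging series with known truth
#'
#' Draws NB counts according to a [bulk_sim_spec()]. Gene labels, true
#' mean trajectories (counts-per-million scale) and library sizes are
#' returned alongside the series so downstream calls can be scored
#' against ground truth.
#'
#' @param spec A [bulk_sim_spec()].
#' @return A list with elements `series` (an [expression_series()]) and
#'   `truth` (list: `genes` tibble with `gene_id` and `label`;
#'   `true_means` gene x timepoint matrix; `lib_sizes`; `seed`).
#' @export
#'
#' @examples
#' sim <- simulate_bulk_series(bulk_sim_spec(n_genes = 50, seed = 7,
#'                                           n_up_gradual = 5,
#'                                           n_down_gradual = 5))
#' table(sim$truth$genes$label)
simulate_bulk_series <- function(spec) {
  stopifnot(inherits(spec, "bulk_sim_spec"))
  Tn <- length(spec$timepoints)
  n <- sum(spec$reps_per_timepoint)
  grp <- rep(seq_len(Tn), spec$reps_per_timepoint)

  labels <- rep("null", spec$n_genes)
  i <- 0
  for (lab in c("up_gradual", "down_gradual", "up_switch", "down_switch")) {
    k <- spec[[paste0("n_", lab)]]
    if (k > 0) labels[i + seq_len(k)] <- lab
    i <- i + k
  }

  step_profile <- function(lab) {
    idx <- 0:(Tn - 1)
    switch(lab,
      up_gradual   = spec$per_step_log2_effect * idx,
      down_gradual = -spec$per_step_log2_effect * idx,
      up_switch    = ifelse(seq_len(Tn) >= spec$switch_timepoint,
                            spec$switch_log2_effect, 0),
      down_switch  = ifelse(seq_len(Tn) >= spec$switch_timepoint,
                            -spec$switch_log2_effect, 0),
      rep(0, Tn)
    )
  }

  withr::with_seed(spec$seed, {
    lib_sizes <- exp(runif(n, log(spec$lib_size_range[1]),
                           log(spec$lib_size_range[2])))
    sf <- lib_sizes / 1e6
    base <- runif(spec$n_genes, spec$baseline_log_mean_range[1],
                  spec$baseline_log_mean_range[2])
    true_means <- matrix(0, spec$n_genes, Tn)
    counts <- matrix(0, spec$n_genes, n)
    for (g in seq_len(spec$n_genes)) {
      true_means[g, ] <- exp(base[g]) * 2^step_profile(labels[g])
      mu <- true_means[g, grp] * sf
      counts[g, ] <- rnbinom(n, mu = mu, size = 1 / spec$dispersion)
    }
  })

  gene_ids <- sprintf("gene%04d", seq_len(spec$n_genes))
  sample_ids <- sprintf("t%02d_r%d", grp,
                        unlist(lapply(spec$reps_per_timepoint, seq_len)))
  dimnames(counts) <- list(gene_ids, sample_ids)
  rownames(true_means) <- gene_ids
  colnames(true_means) <- paste0("age_", spec$timepoints)

  meta <- tibble(
    sample_id = sample_ids,
    age_months = spec$timepoints[grp],
    sex = "F",
    replicate = unlist(lapply(spec$reps_per_timepoint, seq_len))
  )
  list(
    series = expression_series(counts, meta),
    truth = list(
      genes = tibble(gene_id = gene_ids, label = labels),
      true_means = true_means,
      lib_sizes = lib_sizes,
      seed = spec$seed
    )
  )
}

#' Simulate single-cell counts with a group-specific signature shift
#'
#' Two cell groups share per-gene baseline means; in the second
#' ("shifted") group, the listed signature genes have their means scaled
#' by `2^shift_log2`. Counts are NB with mild overdispersion and per-cell
#' depth variation, giving sparse matrices typical of droplet data.
#'
#' @param n_cells_per_group Length-2 integer vector: cells in the control
#'   and shifted groups.
#' @param n_genes Number of genes; identifiers are `gene0001`, ...
#' @param signature_genes Character vector of gene ids to shift; must be a
#'   subset of the gene universe.
#' @param shift_log2 Log2 fold applied to signature genes in group 2.
#' @param seed Integer seed.
#' @param dispersion NB dispersion for cell counts.
#' @return List: `counts` (cell x gene matrix), `groups` (factor,
#'   `"control"`/`"shifted"`), `seed`.
#' @export
simulate_cell_counts <- function(n_cells_per_group, n_genes, signature_genes,
                                 shift_log2, seed, dispersion = 0.5) {
  if (length(n_cells_per_group) != 2 || any(n_cells_per_group < 1)) {
    abort("`n_cells_per_group` must be two positive cell counts.")
  }
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  unknown <- setdiff(signature_genes, gene_ids)
  if (length(unknown)) {
    abort(paste0("Signature gene(s) outside the universe: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  n_cells <- sum(n_cells_per_group)
  groups <- factor(rep(c("control", "shifted"), n_cells_per_group),
                   levels = c("control", "shifted"))

  withr::with_seed(seed, {
    base <- exp(runif(n_genes, log(0.05), log(5)))   # per-cell expected counts
    depth <- exp(rnorm(n_cells, 0, 0.25))            # cell-to-cell depth
    mu <- outer(depth, base)
    shift_cols <- match(signature_genes, gene_ids)
    mu[groups == "shifted", shift_cols] <-
      mu[groups == "shifted", shift_cols] * 2^shift_log2
    counts <- matrix(
      rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
      nrow = n_cells
    )
  })
  dimnames(counts) <- list(sprintf("cell%04d", seq_len(n_cells)), gene_ids)
  list(counts = counts, groups = groups, seed = seed)
}

#' Simulate Sholl intersection profiles
#'
#' Each cell gets Poisson intersection counts around a shared unimodal
#' (Gaussian-bump) template peaking at `peak_radius`, truncated at zero.
#' The radius grid follows the standard protocol: first ring at 5 um,
#' advancing 5 um per ring.
#'
#' @param n_cells Number of profiles.
#' @param radii Radius grid in micrometres; must be uniform.
#' @param peak_height Expected intersections at the peak.
#' @param peak_radius Radius (um) of the template mode.
#' @param noise_sd Spread control: template width is held at a third of
#'   the radius span; `noise_sd` scales extra Gaussian jitter added to the
#'   Poisson mean before truncation (0 = pure template).
#' @param seed Integer seed.
#' @return List of `sholl_profile` objects (each a list with `radii` and
#'   integer `intersections`).
#' @export
simulate_sholl_profiles <- function(n_cells, radii = seq(5, 60, by = 5),
                                    peak_height = 12, peak_radius = 20,
                                    noise_sd = 1, seed = 1) {
  if (length(radii) < 2 || length(unique(round(diff(radii), 9))) != 1) {
    abort("`radii` must be a uniform grid.")
  }
  width <- (max(radii) - min(radii)) / 3
  template <- peak_height * exp(-((radii - peak_radius)^2) / (2 * width^2))
  withr::with_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      lambda <- pmax(template + rnorm(length(radii), 0, noise_sd), 0)
      sholl_profile(radii, rpois(length(radii), lambda))
    })
  })
}

#' Simulate a relative-telomere qPCR plate
#'
#' Builds quantification-cycle (Cq) values such that, with no noise, the
#' relative telomere-length formula recovers `true_length_ratio` exactly:
#' the target/reference telomere Cq difference is set to
#' `log2(true_length_ratio)` and the single-copy-reference difference to
#' zero, then Gaussian noise of `cq_noise_sd` cycles is added to each well.
#'
#' @param true_length_ratio Target:reference telomere-length ratio (> 0).
#' @param ref_length_kb Reference telomere length in kb (> 0).
#' @param cq_noise_sd Per-well Cq noise (cycles).
#' @param seed Integer seed.
#' @return A `telomere_assay` list (see [telomere_length()]).
#' @export
simulate_qpcr_plate <- function(true_length_ratio, ref_length_kb = 100,
                                cq_noise_sd = 0, seed = 1) {
  if (true_length_ratio <= 0) abort("`true_length_ratio` must be > 0.")
  if (ref_length_kb <= 0) abort("`ref_length_kb` must be > 0.")
  withr::with_seed(seed, {
    noise <- rnorm(4, 0, cq_noise_sd)
  })
  telomere_assay(
    cq_target_tel = 20 + log2(true_length_ratio) + noise[1],
    cq_ref_tel = 20 + noise[2],
    cq_target_scr = 22 + noise[3],
    cq_ref_scr = 22 + noise[4],
    ref_length_kb = ref_length_kb
  )
}

#' Simulate depletion-repopulation density rounds
#'
#' Each round leaves a residual microglial density equal to
#' `residual_fraction` of that round's recovered density; recovered
#' densities themselves vary around `recovered_density` on the log scale.
#' The true cumulative division count is the exact sum of per-round log2
#' recovery ratios, `n_rounds * log2(1 / residual_fraction)`.
#'
#' @param n_rounds Number of depletion-repopulation rounds.
#' @param residual_fraction Fraction of density surviving depletion, in
#'   (0, 1).
#' @param recovered_density Post-repopulation density (cells/mm^2).
#' @param seed Integer seed.
#' @param jitter_sd Log-scale jitter applied to each density.
#' @return List: `record` (a [turnover_record()]) and `true_divisions`.
#' @export
simulate_turnover_densities <- function(n_rounds, residual_fraction,
                                        recovered_density = 200, seed = 1,
                                        jitter_sd = 0.1) {
  if (residual_fraction <= 0 || residual_fraction >= 1) {
    abort("`residual_fraction` must lie strictly inside (0, 1).")
  }
  withr::with_seed(seed, {
    recovered <- recovered_density * exp(rnorm(n_rounds, 0, jitter_sd))
    residual <- recovered * residual_fraction
  })
  record <- turnover_record(residual, recovered)
  list(record = record,
       true_divisions = sum(log2(recovered / residual)))
}
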