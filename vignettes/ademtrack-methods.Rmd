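---
title: "Methods: trend calling, staging and turnover quantification in ademtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trend calling, staging and turnover quantification in ademtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ademtrack)
```

ademtrack analyses longitudinal microglial transcriptomes: bulk RNA-seq
count series over an ordered set of ages, single-cell matrices scored
against gene signatures, and the auxiliary measurements used to quantify
forced microglial turnover (depletion-repopulation densities, telomere
qPCR, Sholl morphology, Y-maze behaviour). This vignette explains the
models behind each stage, the defaults and why they are set where they
are, and what the synthetic-data module does and does not emulate.

## The count model and the differential-expression engine

Counts for gene $g$ in sample $j$ are modelled negative binomial,

$$y_{gj} \sim \mathrm{NB}\!\left(\mu_{gj},\,\alpha_g\right), \qquad
\mu_{gj} = m_{g,\mathrm{group}(j)} \cdot s_j, \qquad
\mathrm{Var} = \mu + \alpha \mu^2,$$

with size factors $s_j$ equal to library size over $10^6$, so fitted
group means $m$ live on the counts-per-million scale. Library-size
normalization is total-count (CPM); a robust trimmed scheme such as TMM
is deliberately out of scope, which matters only when a large fraction
of the transcriptome moves in one direction (see Limitations).

Dispersion is estimated per gene by method of moments around the fitted
group means (degrees-of-freedom corrected, floored at $10^{-8}$) and
shrunk half-way toward a lowess mean-dispersion trend
(`shrink = 0.5`). Group means are *maximum-likelihood* estimates found
by one-dimensional optimization with library-size offsets. The weighted
mean $\sum y / \sum s$ is only the starting point: under unequal library
sizes it is not the NB MLE, and using it makes the free model fit worse
than the pooled null for a few percent of null genes, piling their
likelihood-ratio statistics at exactly zero and visibly breaking
p-value uniformity.

Two tests are exposed:

* **Pairwise** (`nb_de_pairwise()`): a quasi-likelihood F statistic.
  The likelihood ratio of free-vs-pooled means is divided by a
  moderated deviance dispersion — the per-gene residual deviance over
  its degrees of freedom, squeezed toward the ensemble median with
  `prior_df = 4` — and referred to $F(1,\ \mathrm{prior\_df} + n - 2)$.
  At three replicates per group this keeps the observed type-I fraction
  at $p < 0.05$ close to nominal and the null p-value distribution
  uniform, which a plain $\chi^2$ reference does not (it runs ~60%
  liberal at this depth).
* **Multigroup** (`nb_de_multigroup()`): the free-vs-common-mean
  likelihood ratio referred to $\chi^2_{K-1}$ after a genomic-control
  style calibration: the statistic is divided by
  $\lambda = \mathrm{median}(LR) / \mathrm{median}(\chi^2_{K-1})$,
  floored at 1. The median over genes is robust to a minority of true
  signal. The F-type correction used pairwise is unnecessarily
  conservative at $K - 1 \geq 6$ numerator degrees of freedom and costs
  substantial power there, while the calibrated $\chi^2$ keeps the
  Benjamini-Hochberg-significant fraction of null genes in check.

Fold changes are $\log_2\!\big((m_B + c)/(m_A + c)\big)$ with
pseudocount $c = 0.5$ CPM, so they are finite even for all-zero groups.
Expression filtering mirrors standard practice: genes averaging fewer
than 10 FPKM over all samples are removed, with the boundary inclusive
(exactly 10 is kept).

## Age-dependent trend (ADEM) calling

`neighbor_comparisons()` runs the pairwise test between every pair of
adjacent ages (6 comparisons for 7 timepoints), using one dispersion
estimate from the full design so the per-step results are mutually
consistent, and attaches the multigroup test across all ages.

`classify_adem()` then labels a gene P-ADEM (persistently up with age)
or N-ADEM (persistently down) when three conditions hold:

1. **A monotone run**: the per-age mean moves in one direction over at
   least `min_run = 5` consecutive timepoints. A counter-step breaks
   the run only if it exceeds
   `epsilon + epsilon_se * SE(step log2FC)`, with `epsilon = 0` and
   `epsilon_se = 1` by default; the standard error comes from the
   observed Fisher information of the fitted NB means. Strict
   monotonicity (`epsilon_se = 0`) is available, but with three
   replicates and dispersion around 0.1 the group-mean noise is ~0.26
   natural-log units, and a truly gradual gene moving 0.3 log2 per step
   shows four consecutive upward sample means less than half the time —
   strictness costs most of the classifier's sensitivity while the
   noise-scaled tolerance keeps the false-call rate negligible because
   of the two gates below.
2. **Differential expression**: by default membership in the multigroup
   DEG set (BH-adjusted $p < 0.05$ and at least one pairwise
   $|\log_2 FC| > \log_2 1.5$ across ages). Alternatives:
   `any_step_in_run` / `all_steps_in_run` demand the adjacent-step
   comparisons themselves pass the raw-p DEG gate, and `none` disables
   the gate. The per-step reading is strict to the point of futility
   for gradual genes — a true 0.3-log2 step rarely clears a 0.585-log2
   threshold at 3-vs-3 — so the series-level DEG set is the default.
3. **Age correlation**: Pearson correlation of $\log_2(\mathrm{CPM}+1)$
   with age across individual samples, significant at 0.05 with sign
   matching the run direction. This is what makes the call genuinely
   *longitudinal*: shuffling the order of the timepoints leaves strong
   genes differentially expressed and (with a tolerant run rule)
   frequently "monotone-ish", but destroys their age correlation, and
   call rates collapse to below 1% of genes.

If both directions qualify (possible only with a nonzero tolerance),
the direction with the larger absolute net change over its window wins;
exact ties stay unclassified. The reported window is the longest
qualifying one, the earliest on ties.

Under the recovery conditions the suite simulates (2,000 genes, seven
ages, three replicates, 100 up- and 100 down-gradual genes at 0.3 log2
per step, dispersion 0.1) these defaults give mean sensitivity around
0.83-0.86 with an empirical FDR near 0.01.

## Staging and trajectory shape

`pca_embed()` embeds samples by PCA of $\log_2(\mathrm{CPM}+1)$ with a
fixed sign convention (the dominant loading of each component is made
positive) so coordinates are reproducible. `timepoint_summaries()`
averages replicate coordinates within each age — a stage is a property
of a timepoint, not of a sample — and records the sampling variance of
those averages.

`segment_stages()` partitions the ordered ages into contiguous blocks.
For each candidate stage count $S$ the within-stage SSE is minimized
exactly (dynamic programming, equivalent to exhaustive enumeration),
and $S$ is selected by

$$\mathrm{SSE}_S / \hat\sigma^2 + \text{penalty} \cdot S \cdot d \cdot \log T ,$$

where $\hat\sigma^2$ is the summary noise variance (from the replicate
scatter when available, else the residual variance of the richest
candidate model). Two numerical choices deserve comment. First, the
criterion is variance-normalized rather than the profiled-variance form
$n\log(\mathrm{SSE}/n)$, because an additive SSE penalty is
scale-dependent and the profiled form is dominated at $T \approx 7$ by
the chance fluctuations of tiny SSEs. Second, `penalty = 4`: an
unwarranted extra stage gets to choose the best of roughly $T - S$
candidate splits, so its null improvement behaves like the *maximum* of
that many $\chi^2_1$ variates (typically 5-8 at $T = 7$), well above
the $\log T \approx 1.95$ a textbook BIC charges per parameter. With
penalty 4 the three-stage young/middle/aged structure is recovered in
about 94% of replicate-averaged simulations at a stage gap of three
per-sample noise SDs, and the failure modes split between an extra
spurious stage and a one-step boundary shift; penalty 1 overfits to
four stages nearly always.

`classify_trajectory_shape()` distinguishes a gradual drift from a
single switch: it fits a constant, a line in age, and a step at every
interior age (keeping the best), and compares them by Gaussian BIC with
1, 2 and 3 mean parameters plus the shared variance. Ties prefer the
simpler shape, so a flat series is "flat", not a zero-slope "gradual".
The split between "gradual" and "switch" has no quantitative criterion
in the visual-inspection practice this replaces; the BIC contest is an
explicit operationalization and should be read as such.

## Signature scores and set comparisons

`module_score()` reimplements expression-matched signature scoring:
genes are cut into `n_bins = 25` equal-frequency bins of dataset-average
expression, `n_ctrl = 100` control genes are drawn from the bin of each
set gene (without replacement inside a bin, with replacement once a bin
is exhausted), and each cell's score is its mean over the set minus its
mean over the pooled controls. Scores are exactly invariant to adding a
constant to the whole matrix, and reproducible given a seed. The bin
and control counts are the cited algorithm's common settings; the
reference implementation does not document the values used in any
particular study, so both are configurable.

`set_overlap()` reports exact intersection counts and a one-sided
hypergeometric enrichment p-value. The universe matters: for bulk work
it should be the genes surviving the expression filter, and it is a
required argument rather than a default precisely so reports must state
it. `fc_concordance()` is ordinary least squares plus Pearson
correlation on the log2 fold changes of shared genes.

## Turnover and senescence quantification

These are closed-form and exact:

* **Cumulative divisions**: $\sum_i \log_2(\mathrm{recovered}_i /
  \mathrm{residual}_i)$ over depletion-repopulation rounds — the
  minimal number of doublings the residual pool needs to regrow.
* **Telomere length**: reference length $\times\ 2^{(\Delta
  Cq_{\mathrm{tel}} - \Delta Cq_{\mathrm{scr}})}$. The default
  `as_printed` convention applies the formula exactly as stated in the
  assay protocol it follows, whose exponent sign is opposite the
  conventional $2^{-\Delta\Delta Cq}$ (a lower telomere Cq means more
  telomeric template); `convention = "standard"` negates the exponent.
  The discrepancy is surfaced in the documentation rather than silently
  "fixed".
* **Sholl AUC**: trapezoidal integration of intersection counts over
  radius, no extrapolation below the first ring (5 um start, 5 um step
  by default). The protocol names no integration rule; the trapezoid is
  the least-assumption choice on a uniform grid.
* **Senescence index**: density / Sholl AUC.
* **Alternation rate**: sliding windows of three consecutive arm
  entries, counted correct when all three arms differ, divided by
  (total entries − 2) — consistent with that denominator, windows
  overlap.

## What the synthetic module emulates — and what it does not

`simulate_bulk_series()` emulates a cross-sectional bulk design over
seven ages (3, 6, 9, 12, 14, 16, 24 months) with 3 replicates, NB
counts with a shared dispersion (0.1), per-gene baselines log-uniform
between 50 and 2,000 CPM (the scale of a filtered, well-expressed
transcriptome), and library sizes log-uniform in 0.8-1.2 million.
Trend genes drift 0.3 log2 per adjacent age or switch once and stay.
Ground truth (labels, mean trajectories, library sizes) is returned
with the data.

It deliberately does **not** emulate: batch structure (the pipeline
assumes batch-homogeneous series; batch correction is out of scope),
gene-gene correlation, gene-specific dispersion trends beyond the
shared $\alpha$, compositional feedback (though CPM itself introduces
some — see below), sex-specific designs, or read-level artefacts.
Passing tests on these simulations therefore demonstrates the
*statistical contracts* of the methods — calibration, recovery,
invariances — not fidelity to any particular real dataset.

The companion generators follow the same pattern: single-cell matrices
with a known signature shift in one group, Poisson-noise Sholl profiles
around a unimodal template, qPCR plates that round-trip a known length
ratio exactly when noiseless, and density series whose true division
count is exact arithmetic.

## Problem sizes in the shipped checks

The test-suite and the acceptance script run, as the package's own
choice of demonstration scale: trend recovery on 2,000 genes x 21
samples over 10 seeds; DE calibration on 5,000 null genes; staging
recovery over 50 replicate-averaged series and shape classification
over 100 series per shape; signature separation over 50 independent
single-cell draws of 400 cells x 1,000 genes. All quantities are
recomputed from scratch at run time.

## Known limitations

* **Compositional bias.** CPM normalization couples genes through the
  library total: when a visible fraction of the transcriptome trends one
  way, the apparent trends of other genes shift oppositely. With ~10%
  trend genes the effect is minor; at 20% it measurably deflates
  sensitivity on the side of the dominant trend. TMM-style robust
  scaling would mitigate this and is intentionally not implemented.
* **Small-T selection.** Stage-count selection at $T = 7$ is
  intrinsically marginal; about half the residual error is a one-step
  boundary shift at a three-noise-SD gap, which no selector fixes.
* **Dispersion sharing.** The moment/trend-shrunk dispersion assumes a
  smooth mean-dispersion relationship; genes with idiosyncratically
  high dispersion are tested slightly liberally.
* **The trend classifier is windowed, not model-based.** Genes with
  genuinely non-monotone but age-locked profiles (for example a
  mid-life pulse) are invisible to it by design.
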