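---
title: "Models and methods behind epiturn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiturn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`epiturn` re-implements, as a tested pipeline, an analysis workflow for
gradual differentiation in the epidermal stem cell layer: intravital
basal-layer tracking, a neighbour fate-imbalance statistic, a single-cell
differentiation trajectory with an explicit delamination point, TF-module
(regulon) scoring, and a nested cubic-model ANOVA for recovery curves.
Every stage can be driven by a synthetic generator with known ground truth.
This vignette explains the models, the tunable parameters and why their
defaults are what they are, and what a green test does and does not
establish.

## 1. The basal-layer event model

Basal keratinocytes leave the proliferative layer by delamination and are
replaced by divisions of neighbours. `simulate_basal_dynamics()` is an
event-driven, continuous-time model on a 2D field:

* **Delamination** is a Poisson process over eligible cells at
  `delam_rate` (events·cell⁻¹·day⁻¹). The default **0.3/day** is
  calibrated so that ~90% of daughter cells resolve their next fate
  within a 5-day follow-up, the resolved fraction reported for tracked
  daughter populations in mouse ear epidermis; it corresponds to a mean
  inter-event time of ~1.7 days per cell at homeostasis.
* **Coupling**: with probability `coupling_prob` a delamination picks one
  uniform neighbour within `trigger_radius` (10 µm, one cell distance)
  and schedules its division after a uniform `trigger_delay` of 12–48 h
  (the lag is not directly measured; day-scale is what the imbalance
  plateaus suggest, so it is exposed as a parameter).
* **Commitment**: a cell scheduled to divide is protected from other
  fates until its division fires. Without this, roughly a third of
  triggers would fizzle (the target dies during the delay) and the
  coupled model would not balance gains and losses.
* **Homeostatic mode** forces `coupling_prob = 1` and prepends a
  stationary warm-up (`burn_in_h`, default twice the maximum delay,
  simulated before time zero). The warm-up matters: a run started with an
  empty compensation pipeline carries a transient population dip equal to
  the lagged-division stock (~15–20% at the default rates) before
  reaching steady state.
* **Geometry**: initial positions are hard-core (sequential inhibition at
  one cell radius, 5 µm) — epithelial nuclei exclude each other, and
  uniform Poisson seeding would put almost half the cells within the
  detector's minimum separation. Cells are quasi-static with sub-µm
  per-frame jitter; daughters are placed at ± half a cell radius along a
  random in-plane axis (divisions are parallel to the basement membrane).
* **Reporter**: every delaminating cell switches a differentiation
  reporter on `reporter_lead` hours before exit (normal, mean 84 h, sd
  12 h — onset typically precedes delamination by 3–4 days).

Under homeostasis the branching process forces mean offspring one, so the
*eventual* next fate of a daughter is delaminate/divide with probability
½ each. Inside a finite 5-day window the split tilts slightly toward
delamination (~52/48): a delamination resolves in one exponential step,
while a division requires commitment plus the 12–48 h delay. The same
truncation operates in revisit-based live imaging, which reports 51/49.

**What a green test establishes**: exact event bookkeeping, causal audit
of triggers, homeostatic balance and the daughter-fate split in *this*
model. It does not establish anything about mechanics (no vertex model,
no active migration) or about absolute rates beyond the calibration
argument above.

## 2. Synthetic timelapse and the image pipeline

`synthesize_timelapse()` renders nuclei as 3D Gaussian blobs riding on a
curved interface `h*(x, y)` (sinusoid, default amplitude 1.5 µm, period
80 µm), a membrane channel with ridges between neighbours, a nuclear
reporter channel scaled by reporter state, and an ECM slab directly below
the interface. The ECM is rendered with per-slice partial-volume
coverage, so the interface has a defined sub-slice position — as it does
in real data, where the axial PSF spreads the edge. Frame-to-frame drift
is a pure 2D translation (random walk, or injected).

The extraction pipeline mirrors standard height-correction practice:

1. `compute_height_map()` blurs the ECM (or nuclei) channel slice-wise in
   xy with σ = 6 µm (the stated width is interpreted as the Gaussian σ),
   thresholds with Otsu (no rule is stated for the mask), takes the first
   masked z per column and refines it to the local half-rise of the
   blurred edge. The half-rise refinement is what brings recovery from
   the ±0.5-slice quantization of a binary mask down to ~0.1 slice.
   Empty columns are filled by nearest neighbour.
2. `flatten_stack()` shifts each column by −h (linear interpolation), so
   the interface is level at the first slice.
3. `project_basal()` averages three consecutive slices into a 2D plane.
4. `detect_cells()` finds strict local extrema after light smoothing,
   discards peaks below 30% of the smoothed dynamic range (noise floor),
   prunes to a minimum separation keeping the more prominent peak, and
   refines positions by parabolic subpixel interpolation.
5. `register_frames()` does the stated coarse 1-µm grid search over the
   mean nearest-neighbour squared distance, then refines with a trimmed
   iterative-closest-point loop. The trimming matters: cells detected in
   only one frame otherwise drag the optimum by up to ~1 µm; with it,
   injected drift is recovered to well under 0.5 µm.
6. `quantify_reporter()` (disc mean at 3 µm, or segment sum over a label
   mask), `normalize_by_dividing()` (fold of the dividing-cell mean) and
   `classify_high()` (strict threshold, user-supplied — the original
   thresholds were set manually per experiment and are data-specific).

Limitations: detection recall is quoted for cells ≥ 3 µm from the image
border (border peaks are not strict extrema of the finite image), and the
height map degrades when the surface varies faster than the 6-µm blur —
both shared by any implementation of this procedure.

## 3. The neighbour fate-imbalance statistic

For each focal division, `imbalance_track()` scores every neighbour event
within 10 µm (inclusive) in the open window `(t_focal − τ, t_focal)`:
+1 per division, −1 per delamination (the figure convention; the mirror
"methods" convention is a flag). Grids are multiples of the frame
interval up to 120 h. `mean_imbalance()` averages tracks over focal
events; the quoted fluctuation is the s.d. across events.

Two subtleties:

* The focal cell's **own birth division** is excluded along with the
  focal event. A cell's appearance replaces its parent with itself plus
  one sibling — net zero for its neighbourhood — and in a quasi-static
  simulation the birth lies within 2.5 µm of the focal position, so
  counting it adds a spurious +P(age < τ) to the plateau.
* At high event densities a **lineage-clustering size bias** (focal
  divisions preferentially sit in locally grown clusters of static cells)
  adds a drift that grows with rate × lookback. The acceptance run uses
  a low background rate (0.03/day) where this bias is negligible; the
  coupled plateau then sits at −1 ± MC error and the independent-events
  control at 0.

## 4. The expression generator

`simulate_expression()` draws a latent differentiation position
`s ~ U(0, 1)` per cell and builds gene-wise negative-binomial counts
(default dispersion 0.1) around a log-normal library depth. Gene
programs are logistic in `s` (width 0.1, amplitude 2 on the natural-log
scale): `diff-up` genes switch on at staggered onsets spanning 0.15–0.8
(the earliest differentiation marker rises first), `basal-down` genes
switch off over 0.1–0.8, `cycle` genes are elevated only in the cycling
fraction (default 20%), and planted TF modules shift their targets' log
rates by `effect × (activity − ½)` with per-cell TF activity noise.
Unspliced counts follow the program at `s`, spliced counts at
`s − splicing_lag` — nascent transcription leads mature mRNA. The
sorted-basal gate flags all cells with `s < s₀` (default 0.6) plus a 5%
suprabasal contamination, which is exactly the situation the
95th-percentile delamination-point rule is designed to tolerate.

The onset staggering spans nearly the whole axis by design: a generator
whose programs all start mid-axis leaves the early half transcriptionally
flat and no ordering method — not this one, not any — could recover ranks
there. A green recovery test therefore establishes that the pipeline
orders cells correctly *when the data carry ordering information*, not
that pseudotime is trustworthy on arbitrary data.

## 5. The trajectory pipeline

* `normalize_log()`: size factor = library size / median library size
  (simple, monotone, testable), then `ln(x+1)`.
* `downsample_counts()`: exact multivariate hypergeometric per cell to
  2,000 counts (sequential `rhyper`), equalizing depth across platforms;
  cells at or below target are untouched and zeros are never created.
* `regress_covariates()`: gene-wise OLS on centred covariates, returning
  residual + intercept so gene means survive; cell cycle is regressed as
  the two phase scores.
* `select_hvg()`: dispersion (variance/mean of the de-logged matrix)
  z-scored within mean bins, top n per dataset, intersected across
  datasets. Bins are capped at one per ten genes so small synthetic
  panels do not produce singleton bins.
* `magic_impute()`: adaptive-bandwidth Gaussian kNN affinities in PC
  space (σᵢ = distance to the k-th neighbour), symmetrized,
  row-normalized, and applied as `Mᵗ·X` with k = 10, t = 2. t = 0 is the
  identity by construction.
* `diffusion_pseudotime()`: diffusion map of the α = 1
  (density-normalized) operator; pseudotime is the diffusion distance
  from the root with components weighted by λ/(1−λ), min-max scaled.
  `k` scales with cell count (`max(30, 0.12 n)`, cap 100): on a 1D
  continuum a too-sparse graph lets sampling clumps dominate the leading
  eigenvectors and the ordering collapses. The root is the cell with
  minimal anchor (differentiation marker) expression at the anchor-low
  extreme of the first diffusion component; orientation is flipped if
  pseudotime anticorrelates with the anchor. Imputed matrices are *not*
  used for pseudotime (imputation collapses local geometry); imputation
  serves label transfer and visualization.
* `assign_delamination_point()`: boundary = order rank of the
  ⌈0.95·n⌉-th sorted-basal cell; `bin_cells()` then makes six basal and
  four suprabasal equal-count bins (remainders to the earliest bins of a
  side).
* `classify_positive()`: strict threshold at the mean expression over all
  cells by default (for Krt10 in the source data this mean is 1.84
  log-normalized counts); computed on the downsampled log-normalized
  matrix, before any smoothing.
* `fit_trend()`: centred rolling mean over the ordered cells (window
  `max(31, 0.05 n)`, odd, truncated at edges) minus the bin-1 baseline.
  The fitting method behind the published smooth curves is unstated; a
  rolling mean is the assumption-light stand-in, with the window exposed.
* `score_gene_set()` / `assign_cycle_phase()`: expression-bin-matched
  control genes, score = mean(set) − mean(controls); a cell is cycling
  when max(S, G2M) exceeds 0.05, phase = the larger score, ties to S.
* `splicing_coexpression()`: log layers per gene; a cell co-expresses a
  basal/differentiation gene pair when all four species (spliced and
  unspliced of both) are strictly positive.

## 6. Regulon construction and scoring

Downstream of any adjacency list (externally supplied, or the built-in
surrogate), the module logic is: (1) genes correlated with the anchor
(Pearson r > 0.3, strictly positive) over the early-differentiation bins
2–4; (2) every TF with at least one edge into that set contributes a
module consisting of *all* its targets; (3) modules are scored per cell
with the bin-matched gene-set score after removing genes differentially
upregulated in bin 1 (rank-sum test vs all other cells, BH-adjusted
p < 0.05 and natural-log fold change > 0.5) so scores reflect
differentiation rather than basal identity. The log-fold-change base is
natural, matching the ln(x+1) normalization.

The built-in `infer_adjacency()` is a desk-scale surrogate for
tree-ensemble network inference: each target is regressed on all TFs by
OLS and |t| statistics rank the edges (no gradient-boosting
implementation is available in this stack, and with tens of TFs against
hundreds of cells the linear model is well-posed). It recovers planted
modules cleanly but will miss strongly non-linear regulation; the
external-adjacency path is the fidelity route.

## 7. Nested cubic-model comparison

Recovery of a cell proportion Y over days X after a perturbation is
compared between genotypes G by OLS of the nested models
H₀: `Y ~ X + X² + X³` (4 parameters) and
H₁: `Y ~ (X + X² + X³) × G` (8 parameters, G coded 0/1), with
`F = ((SSR₀ − SSR₁)/(df₀ − df₁)) / (SSR₁/df₁)` on (df₀ − df₁, df₁)
degrees of freedom. Observations (two regions per animal) enter as
independent rows and proportions are untransformed, as in the original
formulation; no random effects, beta regression or joinpoint models. The
type-I rate of the whole construction is verified at 0.03–0.07 over
1,000 null simulations of the trend generator, whose control curve is
the fixed cubic `1 − 0.9X + 0.45X² − 0.06X³` (depletion at day 1,
recovery by day 3–4) with Gaussian noise (default sd 0.1) and a constant
mutant offset.

## 8. Numerical choices and degenerate inputs

Zero-count cells error in normalization (no size factor exists);
rank-deficient covariate designs fall back to the pseudoinverse;
`register_frames` breaks coarse-grid ties toward the smaller shift;
`knn_transfer` resolves zero distances by copying that cell's label and
vote ties by the single nearest neighbour; disconnected pseudotime
graphs error with component sizes rather than silently ordering one
component; modules emptied by the bin-1 exclusion are skipped with a
warning; boundary contracts are strict (`>` for positivity and reporter
thresholds, `≤` radius inclusion, open lookback windows).

## 9. Known limitations

The tissue model has no mechanics and no cell motion; its spatial
statistics at high event density show the lineage-clustering bias
described above. The imaging model has no optical PSF beyond Gaussian
blobs and no photobleaching. The expression model is a single smooth
trajectory — no branching, no batch effects beyond per-dataset depth.
Stack IO uses plain-text JSON volumes with the YAML sidecar (no TIFF
reader exists in this R stack); the sidecar schema is preserved so a
TIFF-backed reader could be dropped in without touching consumers.
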