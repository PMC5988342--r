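---
title: "Attentional modulation of neural population representation spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentional modulation of neural population representation spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnspace)
library(dplyr)
```

## The question and the method

Single-neuron studies of attention report multiplicative gain changes and
tuning-curve shifts, but those observations do not say what happens to the
*population-level* representation of a stimulus set: does attending to shape
make shapes more discriminable as a population code, and does attention
rearrange the relative positions of stimuli in representation space (warping)
beyond uniformly magnifying it?

`attnspace` implements a complete analysis pipeline for that question, built
around a delayed match-to-sample design with two attention tasks (attend to
shape vs. attend to location), two passive fixation tasks, and two recorded
populations: a ventral-stream, shape-selective one ("AIT-like") and a
dorsal-stream, spatially tuned one ("LIP-like"). The pipeline is:

1. **Gain factors.** Each cell is recorded with 8 shapes and 8 iso-eccentric
   locations in the passive tasks but only 3 shapes x 3 locations in the
   attention tasks. For each cell, task and decode space, the attention
   responses to the 3 overlapping stimuli are regressed through the origin on
   the matched passive responses; the slope `b = sum(xy) / sum(x^2)` is the
   attentional gain factor. Four factors exist per cell (2 tasks x 2 passive
   baselines).
2. **Interpolation.** The active-task locations do not fall exactly on the
   passive 8-location grid, so passive responses at the active polar angles
   are estimated by cubic spline interpolation with periodic boundary
   conditions along the iso-eccentric circle.
3. **Population matrices and distances.** Attention-condition responses to
   the full stimulus set are estimated by multiplying each cell's passive
   tuning by its gain factor. For each condition this gives a cells x 8
   matrix; distances between stimuli are correlation distances `d = 1 - r`
   between the 8 column vectors, giving 28 unique pairwise distances whose
   mean measures the overall discriminability of the stimulus set.
4. **Embedding and alignment.** Classical (Torgerson) MDS embeds each
   distance matrix in 2 dimensions. Configurations from two conditions are
   compared by Procrustes alignment (translation, rotation/reflection, and
   optionally uniform scale) followed by the normalized stress
   `sum((d1 - d2)^2) / sum((d1 - mean(d1))^2)` over unique point pairs.
   With scaling enabled, stress isolates warping beyond magnification.
5. **Inference.** Significance of a stress value comes from a shuffle-split
   bootstrap: trials of the two conditions are pooled within each
   (cell, stimulus), shuffled, split into two pseudo-conditions with the
   original trial counts, and the entire pipeline (gain re-estimation
   included) is re-run on each split; the p-value is the fraction of null
   stresses strictly greater than the observed one. Mean-distance and gain
   comparisons use Wilcoxon rank-sum / signed-rank tests, and a two-sided
   one-sample z-test power analysis gives the minimal detectable effect at
   n = 28 pairs.

## The synthetic population generator

No recordings ship with the package; `simulate_population()` generates
sessions with the statistical structure the analysis assumes, so every stage
can be exercised and validated end to end.

```{r}
cfg <- sim_config(n_cells_ait = 12, n_cells_lip = 12, seed = 1)
sim <- simulate_population(cfg)
sim
count(sim$trials, task)
```

What it emulates, and the main tunable parameters:

* **Design**: 85 AIT-like and 53 LIP-like cells by default; 8 shapes; 8
  equally spaced locations at a per-cell eccentricity drawn uniformly from
  the area's band (AIT 2-6 deg, LIP 7-12 deg); active subsets of 3 shapes
  (two strongest + weakest) and 3 locations (best angle +/-120 deg); 12
  repetitions of each of the 9 sample conditions per attention task (216
  non-catch attention trials per cell); 4 passive-shape and 12
  passive-location repetitions; 20% catch trials, generated and flagged but
  excluded from analysis.
* **Tuning**: von Mises spatial tuning `exp(kappa * (cos(theta - pref) - 1))`
  with `location_kappa` per area (0.8 AIT-like, 3 LIP-like) and
  `pref_spread` controlling preferred-angle coverage (clustered in the
  AIT-like area, uniform in the LIP-like area). Shape tuning is per-cell
  i.i.d. lognormal around `base_rate` (25 spikes/s) with
  `shape_lognormal_sigma = 0.7`.
* **Trial noise**: Poisson spike counts in a fixed `window` (0.5 s),
  converted back to rates. The counting window is a free parameter because
  the underlying experimental literature does not pin down the sample-period
  window; all analysis consumes precomputed rates.
* **Attention**: one multiplicative state gain per (cell, task) for all four
  tasks, drawn lognormal with per-(area, task) `meanlog` and a per-cell
  latent shared across tasks (`sdlog`), plus a small task-specific residual
  (`gain_sdlog_resid`, default 0.02). The four attentional gain factors the
  analysis recovers are the ratios attention-state gain / passive-state
  gain. The defaults make shape-decode gain factors exceed 1 in both areas
  (larger in the LIP-like area) and location-decode factors fall below 1 in
  the LIP-like area.
* **Warping mechanisms** (`warp_mode`, off by default): `gain_heterogeneity`
  draws per-cell, per-stimulus lognormal gain jitter of sdlog
  `warp_magnitude` in the attention tasks; `tuning_shift` displaces spatial
  tuning toward the attended location by `warp_magnitude * 22.5` degrees and
  blends shape responses toward the attended shape with weight
  `warp_magnitude`; `both` combines them. `warp_areas` restricts warping to
  one area (default the AIT-like one).

### Design choices worth knowing about

**Why one state gain per task rather than one per (task, decode space).**
The analysis produces four gain factors per cell, but a trial can only carry
one firing rate, and the shape-decode and location-decode analyses share the
(best-shape, best-location) attention condition. The only self-consistent
generative model is a per-task state gain, with the four recovered factors
arising as ratios to the two different passive baselines. This also mirrors
the logic of the experimental design, where the two passive tasks are
separate behavioral states.

**Why the shared per-cell gain latent.** Marginal gain-factor histograms are
broad, yet unwarped populations must be statistically null for the
stress comparison: both are satisfied when a cell's log state gains share
one latent across tasks (broad marginals) while the between-task residual
stays below the ~5% slope-estimation noise floor (near-constant per-cell
gain ratios). Independent per-task draws would make every condition pair
look warped, which is not the structure the analysis is designed to detect.

**Active-angle placement.** The best-angle +/-120 deg triplet is snapped to
the nearest grid angle and jittered by U(-10, 10) deg per location, so the
mean interpolation shift is about 5 deg — the scale of mismatch the
interpolation stage exists to handle.

**What the analysis can and cannot detect.** Because attention-condition
matrices are gain-scaled passive tuning, any generator mechanism reaches the
population geometry only through the per-cell scalar slope. Heterogeneous
per-stimulus gain jitter changes slopes differentially across cells and is
detected with high power. A pure tuning shift under shallow spatial tuning
(kappa near 1) moves slopes by only a few percent and is largely invisible
to the stress test at realistic noise levels; it is provided as a generator
option, but warping power studies should use the heterogeneous-gain
mechanism. This is a genuine property of gain-based population decoding, not
an implementation artifact.

## A worked example

```{r}
report <- suppressMessages(
  run_full_analysis(sim$trials, n_boot = 100, seed = 2)
)
report$distances[, 1:6]
report$stress_comparisons
autoplot(report$embeddings[["ait.shape.shape_attention"]])
```

`stress_vs_physical()` compares each location-space embedding with the
physical stimulus ring; with the default tuning parameters the LIP-like
population represents physical space far more faithfully than the AIT-like
one (sharper, uniformly distributed spatial tuning), which is the
qualitative cross-area pattern the pipeline is designed to expose.

## Numerical choices

* **Spline**: cubic with periodic boundary conditions (the only boundary
  choice respecting the circular domain); negative overshoot is clamped to
  zero since firing rates are non-negative; angles are canonicalized to
  [0, 360) and angular distances computed modulo 360.
* **Correlation distance**: Pearson (the field default); eccentricity-band
  endpoints are inclusive; cells with constant response vectors across all
  stimuli are dropped with a warning before correlation (kept only in the
  degenerate case where dropping would leave fewer than 3 cells and the
  correlation is still defined). The triangle inequality is *not* assumed —
  correlation distance is not a metric.
* **MDS**: double centering plus eigendecomposition; negative eigenvalues of
  non-Euclidean inputs are excluded from coordinates and from the variance
  normalization (and reported when their mass exceeds 5% of the positive
  spectrum); each axis is reflected so its largest-magnitude component is
  positive, making output deterministic; `k` defaults to 2.
* **Procrustes/stress**: the alignment minimizes summed squared coordinate
  differences (reflections permitted); Eq.-style stress is then evaluated on
  the aligned pair over unique point pairs. Stress is asymmetric — the
  denominator comes from the first configuration — so the pipeline always
  passes the first-named condition as configuration 1 and records the
  order. A configuration with all pairwise distances equal (e.g. an
  equilateral triangle) has no defined stress as reference and errors.
* **Bootstrap**: shuffling is within each (cell, stimulus) pair — a global
  shuffle would destroy stimulus identity and make stress meaningless; the
  p-value is the raw strictly-greater exceedance fraction (no +1
  smoothing), so the smallest reportable p is `1 / n_boot`; gains are
  re-estimated inside every iteration; `n_boot` defaults to 10,000 for
  final analyses and should be reduced for exploration. For
  attention-vs-passive comparisons the passive arm's overlap trials are
  taken at the grid angles nearest the active angles.
* **Ties**: active-shape selection resolves ties toward the lowest index;
  rank tests use exact distributions whenever there are no ties, and the
  normal approximation without continuity correction otherwise (so
  identical samples give p = 1).
* **Power analysis**: exact two-sided z-test power
  `pnorm(e - z) + pnorm(-e - z)`, solved by root finding; at zero effect the
  power equals alpha.

## Validation scale

The test suite validates the numerical core against independent oracles
(direct-formula stress, exhaustive enumeration of rank tests up to n = 8,
Euclidean-recovery checks of the embedding, `cmdscale` and
`vegan::procrustes` as cross-checks) and the statistical machinery by
simulation: type-I calibration of the shuffle-split test uses 500 null
sessions of 16 cells x 6 repetitions at 200 bootstrap iterations, and the
cross-area directional pattern uses 50 sessions at the full default design
with 99 iterations per test. These sizes were chosen to make the whole
suite run comfortably on a single CPU while leaving Monte-Carlo margins
well clear of the asserted thresholds.

## Limitations

* Shape tuning is i.i.d. lognormal across cells, so simulated shape spaces
  have no low-dimensional structure: 2-D variance explained is ~50-60%,
  lower than for real shape-selective populations. Location spaces, tuned
  on a ring, concentrate 85-100% of variance in 2-D.
* The generator produces rates, not spike trains; Fano factors, noise
  correlations and synchrony are out of scope, as are behavioral reaction
  times and errors.
* Passing the directional and calibration suites shows the pipeline behaves
  correctly on data satisfying its assumptions (multiplicative gain,
  Poisson-like noise, stable tuning); it does not certify the assumptions
  themselves in any particular real dataset.
* p-values across the comparison grid are reported uncorrected for multiple
  testing, matching the analysis convention the pipeline reproduces; the
  report structure makes that explicit rather than hiding it.
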