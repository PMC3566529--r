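---
title: "Mapping informational connectivity in block-design fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping informational connectivity in block-design fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoconn)
```

## The problem

Conventional seed-based functional connectivity (FC) asks which brain
regions' *mean* activation timeseries rise and fall together. Multi-voxel
pattern analysis (MVPA) showed, however, that much of what a region encodes
lives in the fine-grained spatial pattern of activity across its voxels,
with little or no trace in the regional mean. Two regions can exchange
stimulus information while their mean signals are uncorrelated — and,
conversely, co-activate strongly while encoding nothing in common.

Informational connectivity (IC) targets the first case. Instead of
correlating mean signals, it tracks — time-point by time-point — how
*discriminable* the current stimulus condition is from a region's
multi-voxel pattern, and asks which brain areas' discriminability
time-courses covary with a seed region's. Synchronized fluctuations in
pattern quality are taken as evidence that the two areas share condition
information.

## The discriminability metric

All analyses operate on a multi-run block design: conditions are presented
in blocks of contiguous TRs separated by rest, one block per condition per
run. After preprocessing (below), the analyzed TRs are those carrying a
condition label (shifted to account for the hemodynamic delay).

For a voxel set of size $m$ (a seed region, or a spherical searchlight of
radius 3 voxels and hence 123 voxels), a leave-one-run-out sweep is run.
For the fold that holds out run $r$, the *prototype* of condition $c$ is
the arithmetic mean pattern $\bar y_c$ over all of $c$'s labeled TRs in the
other runs. For an analyzed time-point $n$ in run $r$, with activity
pattern $\bar x[n]$:

$$ r_c[n] = \operatorname{corr}(\bar x[n],\, \bar y_c), \qquad
   r_i[n] = \max_{i \ne c} \operatorname{corr}(\bar x[n],\, \bar y_i), $$

$$ \text{discriminability}[n] \;=\; \operatorname{artanh}(r_c[n]) -
   \operatorname{artanh}(r_i[n]). $$

Correlations are Pearson's $r$, computed as the normalized-vector dot
product (the two formulations agree to machine precision; the package
tests assert this). The artanh (Fisher) transform variance-stabilizes the
correlations before the subtraction. The value is positive exactly when a
correlation-based classifier — predict the condition whose prototype
correlates most strongly — would classify the time-point correctly, so the
series is a graded, per-TR generalization of classification accuracy
(chance for four conditions: 25%).

`discriminability_timeseries()` returns the series as a tibble with one
row per analyzed time-point (`n`, `tr`, `run`, `block`, `condition`,
`value`, `predicted`); `autoplot()` draws the familiar trace.

## From series to maps and group inference

- **IC map** (`ic_map()`): the seed's discriminability series is compared
  with the equivalent series of a searchlight centered on every masked
  voxel, using Spearman's rank correlation (average ranks on ties); the
  $r_s$ value is placed at the searchlight's center voxel.
- **FC map** (`fc_map()`): the matched univariate control. The seed's mean
  activation series over the *same* analyzed TRs is associated with every
  voxel's (or every searchlight-mean) timeseries in a GLM with the
  nuisance regressors as covariates; the stored value is the partial
  correlation given those covariates.
- Per-subject maps are Fisher-transformed (`fisher_map()`) and smoothed
  with an 8 mm FWHM mask-aware Gaussian kernel (`smooth_map()`); per-axis
  sigma is $\mathrm{FWHM}/\mathrm{voxel}/(2\sqrt{2\ln 2})$ voxels.
- **Group stage** (`group_connectivity()`): a voxelwise one-sided
  one-sample t-test for values above zero, thresholded at $p < 0.001$
  (0.005 as a robustness option), with cluster-extent correction from a
  block-permutation null: each subject's *seed* series is shuffled by
  swapping whole presentation blocks (within-block order preserved; only
  blocks of equal length exchange positions, optionally only within run),
  each permuted series is pushed through the identical
  re-correlation + Fisher + smoothing pipeline, and 1000 null group maps
  (each sampling one of 100 permuted maps per subject) yield a null
  distribution of maximum cluster sizes. At $\alpha = 0.05$ the corrected
  threshold is the 50th-largest null size; real clusters strictly larger
  are significant. Face (6-neighbor) adjacency is the default, 18/26
  available.

Searchlights that overlap the seed region measure self-correlation; they
are flagged (`seed_overlap_zone()`, `characterize_searchlights()`) and
removed at the reporting stage rather than at the map stage.

## Preprocessing contract

`preprocess_bold()` applies, per voxel and per run: second-order polynomial
detrending, ordinary-least-squares residualization on the nuisance set
(six motion parameters and the mean white-matter signal, plus an
intercept), then z-scoring to mean 0 / unit variance over the run's task
*and* rest TRs (sample, $n-1$, standard deviation). The order — detrend,
residualize, z-score — makes z-scoring the final normalization before
pattern analysis; the steps are also exported individually so either order
can be composed. Condition labels are shifted 2 TRs forward within each
run (`shift_labels()`; labels falling off a run's end are dropped, never
wrapped into the next run). Constant voxel-run segments z-score to zeros
(with a warning) instead of being removed, so volumes keep their shape.
All TR and voxel indices in user-facing tables are 1-based, matching R's
indexing.

## The synthetic testbed

`synthetic_spec()` / `generate_subject()` emulate the session the method
was designed around: 12 runs, 4 conditions, 9-TR (~24 s at TR = 2.5 s)
blocks separated by 5 rest TRs, which after the 2-TR shift leaves 108
labeled TRs per condition and 432 analyzed time-points. Each region
receives, during the (hemodynamically delayed) blocks of condition $c$:

$$ \text{mean amplitude} \cdot u_g(\text{block}) \;+\;
   \text{SNR} \cdot s_g(\text{block}) \cdot \text{pattern}_c \;+\;
   \text{iid } \mathcal N(0, \sigma^2), $$

where the condition patterns are fixed zero-mean unit-norm spatial vectors
(pairwise $|r| \le 0.3$), and $s_g$, $u_g$ are block-wise log-normal
(median 1) fluctuation series shared within a coupling group and
independent across groups and subjects. Informational coupling (shared
$s$) and univariate coupling (shared $u$) are therefore controlled
independently — the two constructs IC and FC must dissociate.

Defaults, chosen once as realistic for this design and stated here rather
than tuned: noise sd 1; base SNR 3 (pattern correlations around 0.2–0.4
and 4-way accuracies well above chance but far from ceiling, as in real
object-vision data); mean amplitude 2 for univariately responsive regions;
log-normal sdlog 0.5 for both fluctuation series; motion-like nuisance
regressors as smooth AR(0.95) random walks with zero true contribution;
signal injected 2 TRs after the written labels so the analysis-side shift
realigns them. The default scene (`default_paper_design()`) is a 24³
volume (voxels 3.5 × 3.75 × 3.75 mm) with a spherical brain mask and four
123-voxel regions at tetrahedron vertices ~14 voxels apart — far enough
that no radius-3 searchlight, nor the 8 mm smoothing kernel, can bridge
two regions:

| region  | patterns | mean response | coupling to seed  | detected by |
|---------|----------|---------------|-------------------|-------------|
| seed    | yes      | yes           | —                 | (is seed)   |
| partner | yes      | no            | shared $s$        | IC, not FC  |
| univar  | no       | yes           | shared $u$        | FC, not IC  |
| control | yes      | no            | none              | neither*    |

The `partner` and `control` regions are univariately silent by
construction: a region whose mean responds to the task co-activates with
every other responsive region through the shared block timing, which FC
picks up regardless of coupling — the dissociation requires the
information-coupled region to be decodable while univariately flat.

What the generator does **not** emulate: hemodynamic response convolution
(a canonical-shape delay is collapsed into the 2-TR lag; an AR(1) noise
option exists, but temporal autocorrelation within noise is off by
default), physiological noise structure, spatial noise correlations,
inter-subject anatomical variability, and scanner artifacts. Passing tests
therefore certify the estimator and inference machinery, not robustness to
every property of real BOLD data.

## Numerical choices

- Correlations are clipped to $\pm(1 - 10^{-7})$ before artanh, so a test
  pattern identical to a prototype stays finite.
- Degenerate cases never abort a map: constant test patterns score 0 with
  no prediction (counted incorrect); rank- or residual-degenerate series
  give correlation 0 and are counted in `n_degenerate`. A target lying in
  the covariate span is detected by a relative residual-norm tolerance
  (1e-10), not exact zero.
- Classifier ties (exactly equal correlations) resolve to the first
  condition in sorted order — a measure-zero event on continuous data.
- Smoothing is FFT-based with the kernel truncated at 3 sigma and
  renormalized over the in-mask support, so values at the mask edge are
  unattenuated and off-mask voxels are neither read nor written.
- "50th largest" is read literally: the threshold is the
  $k = \alpha N$-th order statistic of the null maximum cluster sizes, and
  only strictly larger real clusters are significant.
- Permutation across the whole session is the default; equal-length
  constraint keeps the permuted series aligned with the block slots, and a
  within-run mode is available.
- One master RNG seed fans out deterministically to per-subject and
  per-stage child seeds; identical configuration and seed reproduce
  byte-identical results end to end.

## Problem sizes used in the test-suite

The packaged checks run the full pipeline at reduced but honest sizes: the
recovery/dissociation analysis uses 10 simulated subjects at the default
24³ scene with 50 permutations per subject and 200 null group maps; the
type-I analyses use 6 subjects and 4–6 replicates; unit tests use volumes
of 6³–16³. These sizes were chosen so the whole suite exercises every
stage, including the permutation null, in a few minutes of CPU time.

## Known limitations

**Regression-induced coupling of discriminability series.** Per-run
regression preprocessing (polynomial detrending and nuisance
residualization) leaves every voxel with the *same* temporal profile of
residual-noise leverage and task-signal absorption. Any two regions that
carry decodable patterns therefore share a time-varying effective SNR, and
their discriminability series correlate weakly (about $r_s \approx 0.1$ at
these session conditions) even when their underlying SNR fluctuations are
statistically independent. We verified the source directly: on raw or
merely z-scored synthetic data the spurious coupling is absent
(≈ 0.03 ± 0.03), it appears with detrending (≈ 0.09) and grows with
nuisance regression (≈ 0.15). Because block-permuting the seed series
destroys the temporal alignment, the permutation null does not contain
this component, and with enough subjects the group test flags
decodable-but-decoupled regions as informationally connected — the
corresponding packaged check states the intended property and is expected
to fail, by design, as a documented caveat. Under a true global null (no
decodable patterns anywhere outside the seed) the corrected inference is
calibrated at $\alpha$, which a separate test verifies. Practically: IC
contrasts between regions, or against well-matched control seeds, are
trustworthy; the absolute claim "these two decodable regions are coupled"
inherits a small positive floor from any shared preprocessing.

**Other limitations.** Searchlights at mask edges are truncated rather
than skipped (member counts are reported for filtering); radius is
measured on the isotropic voxel index grid, ignoring voxel anisotropy —
the convention under which a 3-voxel radius means 123 voxels; only the
correlation-based classifier is implemented (the discriminability
interface would extend to other classifiers' condition weights, but that
is out of scope here); and inference is the permutation scheme only — no
random-field or FDR correction is provided.
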