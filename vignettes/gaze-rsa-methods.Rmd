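---
title: "Methods: gaze-to-brain representational similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gaze-to-brain representational similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazersa)
```

This vignette documents the statistical model behind `gazersa`, the
choices made where conventions had to be fixed, what the synthetic-data
generator does and does not emulate, and the package's known limitations.

## The analysis in one paragraph

For each participant, the fixation density maps of the scenes they viewed
are correlated pairwise (Pearson, on the flattened pixel vectors) to form
a gaze representational similarity matrix (RSM); for each fMRI subject
and region of interest (ROI), voxel activation patterns are correlated
pairwise to form fMRI RSMs. Representational similarity is the Spearman
rank correlation between the strictly-lower-triangle entries of the gaze
RSM and an fMRI RSM over the same scenes; it is computed against every
fMRI subject separately and then averaged, yielding one estimate per
participant × ROI. These estimates are the response in a Gaussian linear
mixed model with age group and ROI as crossed fixed factors and a random
participant intercept; adults are modelled separately without an age
factor. Estimates are interpreted relative to a noise ceiling obtained by
multiplying the gaze and fMRI leave-one-out ceilings.

## Fixation preprocessing

Trials are excluded, in order, when (1) the trial did not begin with the
participant fixating the screen centre, (2) every fixation fell outside
the image, (3) the trial contains fewer than three fixations in total, or
(4) the summed fixation duration is below 1000 ms. Attributing each
excluded trial to the *first* violated rule makes the per-rule
percentages sequential ("of remaining trials"), which is how such
exclusion cascades are conventionally reported. Participants with fewer
than 18 usable trials are then removed. Two points were genuinely open
and are fixed as follows: individual off-image fixations are dropped from
density maps while trial-level rules see the full fixation list (rule 2
excludes a trial only when *all* fixations are off-image), and off-image
fixations still count toward the fewer-than-three rule.

## Density maps

Each trial's map starts as a zero matrix the size of the image; a count
of 1 is added at the pixel of every fixation except the first (scene
onset pulls gaze from the centre, so the trial-initial centre fixation is
uninformative and always dropped). Counts are smoothed with an isotropic
Gaussian and min–max rescaled so the least-fixated pixel is 0 and the
most-fixated is 1; an all-constant smoothed map is defined to rescale to
all zeros.

Numerical conventions that had to be pinned down:

* **Kernel.** The smoothing sd is `sigma_px` (default 7.21 px at
  1000 px image scale); the equivalent −6 dB cutoff frequency is stored
  as metadata only, because the cutoff-to-sigma convention is not
  self-evident and sigma is what the computation needs. "Circular
  boundary" is implemented as a circularly *symmetric* (isotropic) kernel
  with zero-padded edges, not wrap-around convolution — wrap-around would
  bleed gaze mass between opposite image edges, which is physically
  wrong.
* **Exactness.** Smoothing is computed as two full Toeplitz matrix
  products (`K_row %*% M %*% K_col`), i.e. separable convolution with no
  kernel truncation; tests verify agreement with brute-force dense
  convolution to 1e−8. The 1-D weights are normalized by the infinite
  discrete Gaussian mass, so pre-normalization map mass equals the
  countable fixation count minus boundary truncation loss (≤ 0.1% when
  fixations stay ≥ 4σ from the border).
* **Coordinates.** 0-based pixels, x = column, y = row, origin top-left;
  real-valued coordinates are rounded half away from zero, which is fixed
  for bit-reproducibility.

## RSMs and similarity

The diagonal of an RSM is constant 1, so similarity uses the strictly
lower triangle only — including the diagonal would distort ranks.
Spearman ties get average ranks. Averaging across fMRI subjects is the
plain arithmetic mean of the per-subject ρ values (no Fisher z), and the
package deliberately offers no path that averages RSMs across subjects
before correlation: averaging correlation matrices can misrepresent the
common geometry, and a test asserts that the pipeline's estimate equals
per-subject-ρ-then-mean and differs from mean-RSM-first.

Salience control is implemented as a *partial* (not semi-partial) rank
correlation: the lower triangles of the gaze, fMRI and salience RSMs are
rank-transformed; gaze and fMRI ranks are residualized on the salience
ranks by least squares with intercept; the Pearson correlation of the
residuals is reported. "Controlling for" is ambiguous between partial
and semi-partial; the symmetric variant was chosen because neither data
source has privileged status, and on tie-free inputs it equals the
textbook partial-correlation formula applied to rank correlations (a
test asserts this to 1e−10). A triangle that is collinear with the
nuisance has partial correlation 0 by definition.

## Noise ceilings

With one RSM per subject, the upper bound is the mean over subjects of
the Spearman correlation between that subject's RSM and the group mean
RSM including the subject; the lower bound uses the mean excluding the
subject. This leave-one-out construction is the standard way to bracket
the best achievable RSM correlation given measurement noise; the mean
RSM is entrywise, tolerating subjects with different scene subsets (each
entry averages the subjects that have it). The gaze and fMRI ceilings
are estimated separately (gaze: participants within an age group; fMRI:
the eight fMRI subjects per ROI) and combined by multiplying lower with
lower and upper with upper, since the attainable gaze-to-brain
correlation is attenuated by both noise sources. The upper bound is
biased upward at small subject counts (each subject is part of the mean
it is correlated with), which is why both bounds shrink toward zero as
independent subjects are added — a property the tests check.

## Group inference

The infant model is `rho ~ age * ROI + (1 | participant)`, fitted by
REML with sum-to-zero contrasts and Type-III F tests (`method = "lmm"`,
via `lmerTest`); on a balanced complete design this reproduces the
classical two-way mixed-design ANOVA decomposition exactly, and
`method = "anova"` computes that closed form directly (the two routes
are tested for equality to 1e−6; the Monte-Carlo harnesses use the
closed form for speed). Denominator degrees of freedom follow the
balanced convention — between-subject df for age, subject × ROI df for
within effects — which Satterthwaite reproduces on balanced data.
Estimated marginal means carry model-based standard errors and 95% CIs
(cells are flagged when the CI excludes zero, the chance level for a
correlation); pairwise ROI contrasts are Holm-corrected *within* each
age group, that being the stated correction family; between-age
contrasts per ROI use the Satterthwaite combination of the two mean
squares, giving the familiar intermediate df. Adults are analyzed in a
separate ROI-only model: adult data serve as a comparison endpoint and
pooling them with infants would let the (much less noisy) adult
responses dominate the variance estimates.

### Power and family-wise error simulations

Simulated datasets follow `y = delta[group, roi] + subject + error` with
unit total variance split so that `within_subject_correlation` is the
subject-intercept share. Cohen's f for the planted doubly-centred
interaction is defined **relative to the unit within-cell sd**; under
this convention interaction power at fixed f rises steeply with the
within-subject correlation (the interaction test's error term is the
residual variance only). The default correlation 0.75 is the value at
which the canonical design point — two groups of 40, three ROIs,
f = 0.1 — reaches power 0.8, consistent with the kind of a-priori power
simulation such designs are built on; it is an explicit parameter, not a
hidden constant, because no empirical estimate of it is available here.

The FWER harness simulates the global null, fits the model, forms the
within-group ROI contrasts, Holm-corrects within group, and reports the
rate of correction *families* containing at least one false rejection
(`family = "per_group"`, the default): that is the quantity Holm
controls at α. The union event over both groups' families
(`family = "any_group"`) is also available but approaches
1 − (1 − α)² by construction and is not controlled at α by any
within-group correction.

## The synthetic-study generator

The generator is a first-class, tested component, designed so that every
pipeline stage has recoverable ground truth:

* **Scenes.** Each scene has L spatial maps ("abstraction levels"):
  exponentiated Gaussian-smoothed white-noise fields normalized to sum 1,
  with strictly increasing smoothing scales (defaults 3, 8, 20 px on a
  64 px grid). A per-level contrast parameter (defaults 2, 1, 0.8)
  makes lower levels sparser and peakier — the natural analogue of
  sparse high-contrast low-level features versus diffuse abstract
  structure — and keeps the levels comparably recoverable from the ~9
  fixations an infant contributes per trial, without which fine-scale
  structure would be washed out by sampling noise relative to coarse
  structure. Level embeddings are 8 × 8 block means of each map.
* **Gaze.** Each age group samples fixation locations i.i.d. from the
  mixture of level maps under its weights (demo: young 1/0/0, old
  0.5/0.5/0, adult 0.45/0.45/0.1), with sub-pixel jitter; a centre
  fixation is prepended (it is the one preprocessing drops). Fixation
  counts are Poisson with the group's per-trial mean (9.14 / 9.50 /
  15.96, the centre fixation included); durations are log-normal with
  group means 443.63 / 435.13 / 297.38 ms (durations only feed the
  exclusion filters, not the RSMs). Small per-trial artifact rates
  (2.20% non-central start, 0.37% off-image-only for infants; 0 for
  adults) exercise the exclusion rules at realistic frequencies. The
  per-trial dispersion of fixation counts is not empirically
  constrained; Poisson is the neutral choice and it is configurable.
* **Voxel patterns.** Each ROI loads one or more levels. Row-centred,
  norm-standardized level embeddings pass through a per-subject random
  readout whose rows are orthonormal and orthogonal to the constant
  vector; consequently the *noise-free* pattern RSM equals the embedding
  RSM exactly (a closed-form oracle the tests use), different simulated
  fMRI subjects share geometry but not voxels, and Gaussian noise
  (default sd 0.05 against unit-RMS signal) yields fMRI ceilings in a
  realistic 0.6–0.98 range. This construction requires more voxels than
  embedding dimensions (n ≥ D + 1; default 200 ≥ 65).
* **Salience.** The level-1 map doubles as the per-scene salience map,
  so a pure-salience viewer's gaze shares its generative source with the
  salience nuisance. Note that partialing the *pixel-level* salience RSM
  attenuates but does not annihilate such a viewer's similarity to the
  level-1 ROI, because finite-sample density maps effectively
  coarse-grain the maps toward the embedding geometry; the exact
  analytic null (partial ρ = 0 when gaze RSM equals the nuisance RSM) is
  asserted at the operation level.

What the generator does **not** emulate: naturalistic image content,
saccade dynamics or any oculomotor model, calibration error structure,
hemodynamics, or spatial voxel correlations. Passing tests therefore
demonstrate that the pipeline recovers planted representational
structure under realistic sampling noise and exclusion rates — not that
any particular empirical effect size will replicate.

## Problem sizes and defaults

The full-scale configuration (`study_config()`) mirrors a realistic
study: 78 scenes, 47/46/45 participants per group, up to 50 trials each,
8 fMRI subjects. The tests and the demonstration use a reduced
configuration (`demo_config()`: 30 scenes, 20 participants per group,
64 × 64 px maps, 200 voxels, smoothing sd 2.5 px at this scale) chosen
so that a full study simulates and analyzes in a few seconds while
keeping every qualitative property of the full design; the planted
age × ROI interaction at this scale is detected essentially always
(replicate suites reject at α = 0.05 in far more than 80% of runs).
Monte-Carlo defaults: 2000 replicates for FWER, 1000 for power.

## Known limitations

* The closed-form ANOVA route requires a balanced complete design; use
  `method = "lmm"` for unbalanced data (missing cells, unequal groups).
* No Kenward–Roger or other small-sample df machinery beyond the
  balanced-design/Satterthwaite convention, and no Bayesian variants.
* Density-map vectors are correlated at full pixel resolution; for
  10^6-pixel maps RSM construction dominates runtime. Maps can be
  exported and decimated upstream if needed.
* Negative similarity values are reported as computed but, as with any
  RSA, are not usually interpretable.
* The voxel container on disk is a long-format CSV; very large pattern
  sets are better kept in memory or split per ROI.
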