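---
title: "Decoding guiding-object templates in context-guided visual search: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding guiding-object templates in context-guided visual search: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

When people search for an object in a structured scene, attention is often
guided not by the target's own features but by a contextually associated
"anchor" object — a large, easy-to-find object that predicts where the
target will be (a desk predicts a pen). `anchorsearch` implements the
analysis machinery for a combined fMRI / eye-tracking paradigm that
dissociates the two candidate contents of preparatory activity in visual
cortex: the *target* template and the *guiding anchor* template. Two target
categories are each associated with one of two anchor tables, and the
pairing reverses between two scene contexts. On preview-only trials the
participant prepares to search but no search display appears, isolating
preparatory activity.

The pivotal analysis is **cross-scene decoding**: a linear classifier is
trained to separate the two associated anchors from preparatory voxel
patterns in one scene context and tested in the other, where the
target–anchor pairings are reversed. Because of the reversal, the two
hypotheses make *opposite* predictions: a generalising anchor code yields
above-chance transfer (positive score), whereas a target code yields
below-chance transfer (negative score). The sign of the score is therefore
the finding, which is why the package treats it as the core statistic and
why the acceptance checks focus on sign recovery.

## Classifier information

Decoding is scored by a continuous distance-to-bound statistic rather than
binary accuracy. For $n$ test patterns with signed geometric distances
$d_i$ from the decision boundary and true labels $l_i \in \{-1, +1\}$,

$$\mathrm{information} = \frac{1}{n} \sum_{i=1}^{n} z(d_i)\, l_i,$$

where $z(\cdot)$ z-scores the $n$ distances (mean subtracted, population
standard deviation). The statistic is zero in expectation at chance,
positive when the classifier orders the classes correctly, and invariant
to positive affine rescaling of the distances — so whether raw decision
values or geometric distances are used is immaterial (the package uses
geometric distances, $w^\top x + b$ scaled by $1/\lVert w \rVert$). If the
distances have zero spread the score is defined as 0. Two scope choices
are not dictated by the formula and are therefore explicit options:

* **z-scoring scope.** Leave-one-run-out schemes pool the test distances
  of all folds and z-score once per hemisphere (the formula is written
  over all $n$ test patterns); `per_fold_z = TRUE` switches to per-fold
  scoring. Cross-scene schemes score each train/test direction separately
  and average the two directions.
* **Hemispheres** are decoded separately and averaged afterwards.

The classifier is a linear soft-margin SVM (libsvm via `e1071`), `cost =
1`, no feature scaling. Training rows are stably reordered so a positive
example comes first, pinning libsvm's internal label order and hence the
sign convention of decision values.

## The synthetic experiment

There is no real data in the package; every analysis runs on a generator
whose parameters are explicit ground truth, which is what makes parameter
recovery and calibration testable.

**Design.** Eight runs of 32 trials fully cross five binary factors (trial
type, target presence, target category, scene context, associated-anchor
side), so every run is exactly counterbalanced and 128 of 256 trials are
preview-only. Trial timing uses a 1 s cue, a preview jittered 3.1–4.0 s on
search trials and fixed at 4.4 s on preview-only trials, and a uniform
2–4 s inter-trial interval; response and feedback epochs are folded into
the inter-trial gap so a run fits 198 scans at TR 1.5 s. Target presence
and anchor side are generated (but have no stimulus consequence) on
preview-only trials so that the joint counterbalancing stays exact.

**Voxel patterns.** Run-wise condition betas are an additive mix of three
multivariate codes plus noise:

$$\beta(r, c, v) = a_A P_{\mathrm{anchor}(c)}(v) + a_T P_{\mathrm{target}(c)}(v)
  + a_C P_{\mathrm{context}(c)}(v) + \varepsilon,\qquad
  \varepsilon \sim \mathcal{N}(0, \sigma^2)$$

with fixed random patterns $P$ per participant and hemisphere. The anchor
pattern is keyed by the *associated* anchor under the association map, so
the same pattern recurs in both contexts wherever that anchor is the
associated one — exactly the structure cross-scene decoding detects.
Patterns are normalised to unit per-voxel RMS, so the amplitudes $a$ are
per-voxel effect sizes in units of the beta noise SD ($\sigma = 1$ by
default). Defaults ($a_A = 0.5$, $a_T = 0$, $a_C = 0.2$) encode the regime
the analyses probe: a reliable anchor code and no target code. The two
hemispheres get independent patterns; localizer patterns are independent
of task patterns by default (the package offers no shared component, as
task–localizer generalisation is not assumed).

**Gaze and responses.** Search trials get an onset fixation in the center
AOI (recorded with probability 0.94, centered with probability 0.83,
mirroring realistic dropout), then with probability 0.805 an
anchor-directed first fixation that lands on the associated anchor with
the participant's guidance probability $q$ (else the other anchor), with
latency $\mathcal{N}(229.53, 29.20)$ ms truncated at zero. The guidance
delta is $\Delta = 100\,(n_\mathrm{assoc} - n_\mathrm{other}) /
n_\mathrm{included}$ percentage points, so with anchor-directed fraction
$a$ its expectation is $100\,a\,(2q - 1)$. Population defaults
($q_\mathrm{absent} = 0.619$, $q_\mathrm{present} = 0.657$, SD 0.10
across participants) put the expected deltas near 19 and 25 pp.
Responses follow an equal-variance signal-detection model with criterion
0; participant sensitivity is $d' = \bar{d'} + s\,(\Delta_i -
\bar{\Delta}) + \eta$ with $\bar{d'} = 1.19$ (accuracy ≈ 72%) and the
slope $s$ calibrated by `guidance_dprime_slope()` so the *latent*
guidance–$d'$ correlation is 0.55; measured sample correlations are
attenuated below that by binomial measurement noise in $\hat\Delta$ and
$\hat{d'}$, which the recovery tests account for by checking coverage of
the sample-r distribution rather than its mean.

**AOI geometry.** The center AOI is 4.5° × 10.5° at fixation; anchor AOIs
are 7.5° × 10.5° at x = ±7.5°, y = −1.5° (the anchor centers are inputs,
not results; defaults place them peripherally and slightly below
fixation). Boundaries are inclusive and anchor labels take precedence
over the center label in the (non-default) event of overlap. A trial
enters the guidance analysis only if a fixation overlapping scene onset
(tolerance 0 ms, configurable) lies in the center AOI, and its label is
the next fixation's AOI.

## GLM stage

The GLM estimates run-wise condition betas from time series: boxcars from
preview onset to offset (preview-only trials only; search events stay in
the implicit baseline), convolved with a canonical double-gamma HRF (peak
delay 6 s, undershoot delay 16 s, unit dispersions, peak:undershoot 6,
32 s kernel, unit peak) at a microtime resolution of TR/16, sampled at
scan acquisition times (no slice-timing; preprocessing is out of scope).
Boxcars are half-open in time so their discrete area tracks the true
duration. Six motion regressors (zeros when none are supplied) and a
constant complete the design. Estimation is ordinary least squares via QR;
rank-deficient nuisance columns drop (silently when they are all-zero
placeholders), while rank-deficient *interest* columns are an error that
names the confounded conditions. Localizer selectivity is tested by a
one-way F across condition groups treating run betas as replicates, with
df $(k-1, N-k)$; zero within-group variance with distinct means reports
$F = \infty$, $p = 0$.

## ROI selection and sub-ROIs

Participant ROIs are the union of target-contrast and anchor-contrast
significant voxels ($p < \alpha$, uncorrected, default 0.05) within a
group mask; `alpha = 1` degenerates to the whole mask. Nested sub-ROIs of
sizes $\mathrm{round}(k \cdot \mathrm{max}/5)$ take equal numbers of the
most target- and most anchor-selective voxels per hemisphere (ranked by
F, ties broken by voxel id). Overlap between the two rankings is handled
by a deterministic alternating merge (target list first, duplicates
skipped): this realises "top $k/2$ of each list, overlap counted once,
deficit backfilled alternately", gives the target list the extra voxel at
odd sizes, and guarantees nesting by construction.

## Group inference

* **Participant bootstrap** (default 10000 iterations): resampled group
  means give a 95% percentile CI and a two-tailed, +1-corrected p-value
  capped at 1.
* **TFCE** integrates $e(h)^{E} h^{H} \mathrm{d}h$ over thresholds
  $h = \mathrm{d}h, 2\mathrm{d}h, \ldots$ up to the statistic at each
  position, where $e$ is the supra-threshold connected component size.
  Defaults $E = 0.5$, $H = 2$, $\mathrm{d}h = \max/100$ are the canonical
  choices; the exponents, step and permutation count are configurable
  because the method's parameters are conventions, not results. Sub-ROI
  curves are 1-D maps with chain adjacency (two-sided enhancement:
  positive and negated maps enhanced separately and subtracted); 3-D maps
  use face-connected lattices. Chains of up to 12 positions use an exact
  vectorised fast path (a lookup table over the $2^n$ supra-threshold
  patterns); both paths are verified against a brute-force per-position
  flood-fill oracle to $10^{-9}$.
* **Sign-flip max-statistic correction**: each permutation flips each
  participant's map by an independent ±1, recomputes the one-sample t map
  and its TFCE, and records the spatial maximum;
  $p = (\#\{\max^* \ge \mathrm{obs}\} + 1)/(n_\mathrm{perm} + 1)$, with
  $z = \Phi^{-1}(1 - p)$. The group statistic fed to TFCE is the
  one-sample t across participants (standard for sign-flip nulls).

## Searchlight

Sphere neighborhoods contain every integer offset with squared norm
$\le r^2$ (515 voxels at radius 5; a strict-inequality variant is
available because sphere-membership conventions differ between toolboxes,
and the convention is recorded in the neighborhood object). Spheres are
clipped at volume borders and to the analysis mask; centers with fewer
than two usable voxels are skipped with a count. The per-center score is
exactly the ROI decoder run on the sphere's voxel set, so the searchlight
inherits every scheme property. A feature mask can be built from
localizer decoding maps: per-voxel one-sample t against chance
(one-sided) for the target and anchor maps, union at uncorrected
$\alpha$, intersected with a cortex mask. Cluster tables report peak
world coordinates via the volume affine (2 mm isotropic by default) and
extent in voxels and mm³.

## Problem sizes and calibration choices

The study-scale conditions are 34 participants, 8 runs, 264 voxels per
hemisphere, two hemispheres. The repeated-replicate evaluations scale as
follows, chosen to keep each evaluation at desk scale while leaving the
tested conditions intact: the sign-recovery evaluation runs 100 seeded
group replicates at full scale; the bootstrap null calibration runs 2000
group datasets with decoding at 48 voxels × one hemisphere and
`n_boot = 2000`; the TFCE family-wise error calibration uses 500
pure-noise curve datasets × 400 permutations; the guidance-correlation
recovery uses 500 behavioral group replicates. The synthetic searchlight
volumes are 8–10 voxels per side with radius-1 spheres; translation
equivariance and per-sphere equality to the standalone decoder make the
behavior at larger radii a function of the same code paths.

## What passing tests do and do not show

The generator reproduces the *statistical structure* the analyses assume —
additive multivariate codes with the association-reversal geometry,
run-level noise independence, realistic dropout and guidance rates — not
real fMRI physiology. There are no spatial noise correlations, no
autocorrelated BOLD noise (the optional AR(1) time-series path exercises
the GLM, not the decoder), no motion artifacts, no between-run pattern
drift, and localizer and task codes are independent by construction.
Passing the suite therefore shows that the pipeline's inferences are
correct and calibrated *given* the generative assumptions, and that the
machinery recovers planted effects; it does not certify effect sizes on
real data. Degenerate inputs are handled by documented conventions rather
than silence: empty ROIs and single-class training sets are errors,
zero-spread distances score 0, ties at the accuracy boundary count 0.5,
extreme hit/false-alarm rates are corrected by the 1/(2N) rule, and
conditions with no included gaze trials yield missing values with a
warning.

## Known limitations

The SVM solution is deterministic for a fixed training-set ordering but
follows libsvm's termination tolerance (default $10^{-3}$); invariances
that are exact mathematically (e.g. relabeling symmetry of the cross-scene
directions) hold only to that tolerance. The chain TFCE fast path is
limited to 12 positions (the general path has no limit). The pipeline
simulates both hemispheres independently; real hemispheric asymmetries
and cross-hemisphere correlations are out of scope, as are surface-based
searchlights, nonlinear kernels, multiclass decoding and representational
similarity analysis.
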