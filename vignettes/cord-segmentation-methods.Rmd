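---
title: "Two-stage multi-atlas spinal cord and grey matter segmentation: methods"
author: "cordfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage multi-atlas spinal cord and grey matter segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cordfuse)
```

## The problem

Spinal cord atrophy — quantified as a decrease of the cross-sectional area
(CSA) of the cervical cord on axial MR slices — is an established imaging
marker of axonal loss in multiple sclerosis and related conditions, and the
grey-matter (GM) area inside the cord carries additional, independent
clinical signal. Both require accurate segmentation of small structures (a
cord of roughly 88 mm², a butterfly-shaped GM of roughly 14 mm², at
0.5 × 0.5 mm in-plane resolution and 5 mm slice thickness), in images where
focal lesions can blur the tissue boundaries. `cordfuse` implements a fully
automated two-stage multi-atlas approach:

1. **Localisation** — an OPAL-style PatchMatch label propagation against a
   template library gives a rough cord segmentation in well under a second.
   Its largest connected component, dilated eight times, becomes the region
   of interest (ROI) for everything downstream; its centre of mass
   initialises the registrations.
2. **Segmentation** — every library template is aligned to the target slice
   (block-matching affine, then a B-spline free-form deformation restricted
   to the ROI), the best-matching deformed templates are selected, and a
   STAPLE-type EM with per-voxel LNCC template selection and an MRF spatial
   prior (the STEPS scheme) fuses their cord and GM labels into consensus
   probability maps, thresholded at 0.5.

All processing is strictly 2D slice-wise; a subject is a 15 mm section of
three contiguous slices that are segmented independently and restacked.

## Stage 1: PatchMatch localisation

For every target pixel the algorithm maintains the `k_best = 10` most
similar 5 × 5 patches across the whole library. Similarity is the sum of
squared differences between z-normalised patches (patch mean removed,
divided by the patch standard deviation; constant patches normalise to
zero), which makes the search contrast-invariant. Starting from random
correspondences, `n_iterations = 5` sweeps alternate:

* **propagation** in scan order (direction alternating per sweep), testing
  each neighbour's matches shifted by one pixel;
* **random search** around the current best matches with exponentially
  shrinking radius (factor 0.5 per step) in both space and template index.

Matched centre labels are fused with weights `exp(-d / h)`, `h` being the
mean match distance over the field; the fused cord probability is
thresholded at 0.5. If no pixel reaches the threshold the input is declared
un-localisable and the pipeline stops with a dedicated error — this mirrors
the known failure mode of pure patch-based segmentation on heavily
pathological inputs and is exactly the situation the second stage cannot
rescue.

Design choices that the original description leaves open and that we fixed:
SSD on z-normalised patches as the metric, decay factor 0.5, exponential
label weights with a global bandwidth, largest-component filtering before
dilation, and lexicographic tie-breaking of equal-distance candidates (for
determinism). The dilation element is a 3 × 3 square: the published count
("dilated eight times") does not name an element, and eight 3 × 3 dilations
give the generous 8-pixel margin the registration masking needs.

## Stage 2: registration

**Affine.** "Six degrees of freedom" in a slice-wise setting is the full 2D
affine (2 × 2 linear part plus translation). The transform is estimated by
block matching: 4 × 4 target blocks inside the ROI are matched to the
template within a ±3-block search radius by normalised cross-correlation,
the best offset is refined to sub-pixel precision by a parabola fit on the
NCC surface, and a full affine is fitted by least-trimmed squares (best 50%
of correspondences, 5 refits). The estimate is symmetrised: forward and
backward fits are averaged in the matrix-logarithm domain (the standard
well-posed interpretation of "symmetric" when no further detail is given),
and the whole procedure is iterated a second time from the refined pose. A
candidate is only accepted if it improves the ROI-masked NCC over the
initialisation (the centre-of-mass offset); otherwise the initialisation is
returned unchanged.

**Free-form deformation.** The residual deformation is a cubic B-spline
field optimised by gradient ascent on the ROI-masked mean LNCC
(`sigma_sim = 1` pixel) minus a bending-energy penalty, coarse-to-fine over
a control-grid pyramid whose spacing halves per level down to 5 pixels at
the finest of 6 levels; levels whose control spacing exceeds the image are
skipped. We deliberately use a control-grid pyramid at full image
resolution rather than an image pyramid: on the 48 × 48 pixel slices this
package targets, an image pyramid degenerates after one level while the
control-grid pyramid provides the same coarse-to-fine behaviour. Only
improving steps are accepted (backtracking line search), which yields the
guarantee that the masked LNCC never falls below its affine-only starting
value, and makes a zero-iteration configuration return the affine exactly.

The bending-energy weight (0.01) is not stated in the source protocol; we
chose a weak regularisation consistent with the observation that the
free-form stage mainly needs to be *restrained* (it can add too much
flexibility around lesions), and surfaced it in
`registration_config(bending_weight = )`.

`registration_config()` defaults to `max_iter = 100`, `tol = 1e-5` per
level. The pipeline-level `run_config()` passes `max_iter = 30`,
`tol = 1e-4` instead: on 48 × 48 slices the masked mean LNCC sits around
0.9 and improvements below 1e-4 are far beneath the noise floor of the
fused result (the fused masks are identical under both settings), while the
looser stopping rule is about three times faster. Use
`run_config(registration = registration_config())` to get the conservative
setting everywhere.

## Stage 3: STEPS fusion

Deformed templates are first ranked by ROI-masked global NCC and cut to the
`global_cut` best (default 25; templates with undefined NCC rank last).
Per-voxel LNCC maps (`sigma_lncc = 1.5` pixels) then select the `X = 15`
locally best templates at each voxel. The consensus is estimated by a
STAPLE EM restricted per voxel to that selection:

* candidate labels are the warped (soft) template masks binarised at 0.5 —
  the Bernoulli rater model wants binary votes;
* the consensus probability `W` is initialised as the selected-label mean;
* each iteration first re-estimates every template's sensitivity `p_j` and
  specificity `q_j` from `W` (M-step, values clamped to
  `[1e-4, 1 - 1e-4]`), then updates `W` from the `p`, `q` and a mean-field
  Potts prior on the 4-neighbourhood with weight `mrf_beta = 0.55`
  (E-step); `beta = 0` reduces to the uniform prior;
* iteration stops when the relative change of the mean consensus falls
  below `em_tol = 1e-4` (at most `em_max_iter = 100` iterations).

Running the M-step first from the consensus initialisation (rather than an
E-step from `p = q = 0.95`) is what makes the two degenerate cases behave
as one expects: unanimous raters reproduce their mask to machine precision,
and a single rater reproduces its own labels up to the clamp. The initial
`p_init`/`q_init` values are kept as fallbacks for templates that have no
selected voxel. The MRF is applied as a deterministic mean-field prior
refreshed at each E-step, not as Gibbs sampling; the published protocol
gives only the scalar consistency weight, and the mean-field form is fast
and reproducible.

Cord and GM are fused as two independent binary problems; nesting
(GM ⊆ cord) is enforced at binarisation, where a voxel is foreground iff
`W >= 0.5`.

One ambiguity worth recording: it is not stated whether `X = 15` counts
globally best templates or per-voxel LNCC-ranked ones. We implement both —
a global NCC cut (`global_cut`) followed by per-voxel selection (`X`) — with
the per-voxel mechanism as the scientifically active one, matching the
published STEPS description. Likewise, the global NCC ranking is computed
inside the dilated ROI (where alignment matters); ranking over the full
slice would mostly measure background agreement. Whether localisation runs
before or after resampling is also unstated; we resample the target to the
library resolution first, so that patch sizes and kernel widths are always
in library pixels.

## The phantom cohort

Because no imaging data are distributed, every claim the package makes is
exercised on a seeded synthetic phantom that reproduces the study geometry:
0.5 × 0.5 mm pixels on a 24 mm field of view, 5 mm slices, three slices per
subject, per-subject cord area drawn from N(88.2, 6.2²) mm² and GM area
from N(14.0, 1.4²) mm² (the cohort's test–retest table values), a bright
CSF rim, and contrast ordering CSF > GM > WM > background as on
gradient-echo cord imaging (the source data's intensity statistics are not
published, so the four levels — 95/80/60/20 — are free parameters chosen
for that qualitative appearance). The GM is built as two mirrored crescents
joined by a posterior bridge, scaled by 1-D bisection until the rendered
pixel area hits the drawn target, and is contained in the cord by
construction. Each subject carries a random pose jitter (translation
±1.5 mm, rotation ±8°, anisotropic scale ±5%) applied identically to image
and masks, Rician noise (magnitude of a complex Gaussian, sd = 3% of the WM
level — a high-SNR averaged acquisition), and optionally hyperintense WM
lesions (intensity midway between WM and CSF) that perturb the appearance
but never the ground-truth masks. Generation is deterministic given
`(seed, subject index)`.

What the phantom does *not* emulate — and hence what passing benchmarks do
not show about real data: vertebral and paraspinal anatomy, through-plane
partial volume, bias fields, motion artefacts, rater disagreement, and true
pathological boundary blurring. The phantom's subjects are affinely related
by construction (plus independent GM scaling), so registration on it is
easier than on real anatomy; the benchmark numbers are an upper bound and
are used as regression floors, not as claims about clinical accuracy.

## Numerical conventions

* 1-based array indices (R-native), pixel-centre coordinates, half-open
  physical extents; world mapping through the NIfTI affine.
* Linear resampling uses reflection at borders; warping uses replicate
  clamping (the cord is central, so the border policy is inconsequential but
  fixed). Binary masks travel through nearest-neighbour interpolation only.
* LNCC pixels whose local variance is below 1e-6 of the global intensity
  variance are set to 0 (degenerate windows carry no similarity
  information).
* Surface distances are computed in-plane per slice and pooled over the
  3-slice stack: with 5 mm slices against 0.5 mm pixels, 3D boundary
  distances would be dominated by through-plane jumps that the slice-wise
  method never controls. The Hausdorff distance is the classical max-max
  (a percentile variant is exposed but off by default). The 3D Dice
  coefficient is the voxel-count formula on the stacked masks.
* Equal-distance PatchMatch candidates and equal-LNCC template selections
  break ties by the lowest (template, row, column) index — results are
  bit-reproducible for a given seed and independent of any parallelism.

## Problem sizes used by the tests

The test suite and the acceptance script size their simulations for a
single CPU: leave-one-out benchmarks run 20-subject cohorts (the
acceptance benchmark, with `global_cut = 10` and `prerank_cut = 15`) or
8-subject cohorts (the acceptance script, package defaults), registration
recovery runs 20 seeded trials, and the metric/EM oracle checks use
exhaustive or random instances up to 20 × 20 pixels. A full 48 × 48 slice
segments in a few seconds; a 20-subject leave-one-out pass takes a few
minutes.

## Known limitations

* The affine/FFD chain assumes the OPAL localisation succeeded; a grossly
  wrong ROI is not detected downstream (garbage in, garbage out).
* Fusion treats cord and GM independently; a joint multi-class model could
  share rater-performance information between the structures.
* The FFD optimiser is a plain gradient ascent with backtracking — adequate
  for the small, smooth slices targeted here, but not a general-purpose
  registration engine.
* Slice-wise processing ignores along-cord consistency; on long sections a
  3D coupling would suppress isolated per-slice errors.
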