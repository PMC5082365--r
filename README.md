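# cordfuse

Fully automated, slice-wise segmentation of the cervical spinal cord and its
grey matter (GM) from axial MR images, by chaining two multi-atlas label
fusion stages:

1. **Localisation** — OPAL-style PatchMatch label propagation against a
   template library roughly segments the cord; the largest component,
   dilated eight times, becomes the registration region of interest, and its
   centre of mass initialises the alignment.
2. **Segmentation** — each template is registered to the target slice
   (symmetric block-matching affine, then a cubic B-spline free-form
   deformation masked to the ROI and driven by locally normalised
   cross-correlation), and the STEPS fusion — global NCC ranking, per-voxel
   selection of the X = 15 locally best templates by LNCC (σ = 1.5), and a
   STAPLE expectation–maximisation with a Markov-random-field spatial prior
   (β = 0.55) — produces consensus probability maps for cord and GM,
   thresholded at 0.5 with GM ⊆ cord enforced.

The quantities of clinical interest are the cord cross-sectional area
(CSA, mm²) and GM area per slice, their section volumes, and the evaluation
metrics of the standard protocol: 3D Dice similarity coefficient (DSC),
mean surface distance (MSD) and Hausdorff distance (HD) against a
majority-vote consensus of three raters, under leave-one-out
cross-validation (the target subject and its left-right flip are removed
from the library).

For the STAPLE core, each template `j` votes `d_ij` at voxel `i`; the EM
jointly estimates the consensus probability `W_i` and the template
performance (sensitivity `p_j`, specificity `q_j`):

    W_i = a_i / (a_i + b_i)
    a_i = f_i(1) * prod_{j in sel(i)} p_j^d_ij (1 - p_j)^(1 - d_ij)
    b_i = f_i(0) * prod_{j in sel(i)} (1 - q_j)^d_ij q_j^(1 - d_ij)

with `f_i` a mean-field Potts prior on the 4-neighbourhood and `sel(i)` the
per-voxel LNCC selection. Because no imaging data ship with the package, a
seeded phantom generator (`phantom_spec()`, `generate_cohort()`) reproduces
the acquisition geometry — 0.5 × 0.5 mm pixels, 5 mm slices, 3 slices per
subject, cord ≈ 88.2 mm², GM ≈ 14.0 mm², optional hyperintense WM lesions —
so every stage is testable end to end. See the methods vignette
(`vignettes/cord-segmentation-methods.Rmd`) for the model, conventions and
limitations.

## Worked example

```r
library(cordfuse)

## a seeded 6-subject phantom cohort on disk (NIfTI + JSON manifest)
cohort <- generate_cohort(phantom_spec(n_subjects = 6, seed = 42), "cohort")

## leave-one-out: segment subject 1 with its own entries (and flips) removed
lib <- build_library(cohort$manifest)          # 6 x 3 slices x 2 flips = 36 entries
red <- subset_library(lib, "sub001")
vol <- read_nifti(cohort$subjects$sub001$image, id = "sub001")
seg <- segment_volume(vol, centre_index = 2, red, run_config(seed = 7))
seg$report
#>   structure area_mm2_s1 area_mm2_s2 area_mm2_s3 area_mm2_mean volume_mm3
#> 1      cord       98.75       97.25       97.25      97.75000    1466.25
#> 2        gm       17.25       17.75       17.00      17.33333     260.00

## accuracy against the generated ground truth
truth <- read_nifti(cohort$subjects$sub001$cord)
tm <- label_map(round(truth$data), vol$spacing, "cord", origin = vol$affine[1:2, 4])
dsc(seg$cord, tm)
#> [1] 0.9965812
surface_distances(seg$cord, tm)
#>        msd         hd 
#> 0.02162162 0.50000000
```

The per-slice areas (mm²) and section volume (mm³) are the morphometric
output; the DSC of 0.997 and sub-pixel mean surface distance (0.02 mm at
0.5 mm pixels) say the automated mask agrees with the ground truth to well
within one pixel. A full evaluation over every subject is one call:
`loo_run(cohort, run_config(seed = 7))` returns a per-target data.frame
with DSC/MSD/HD and areas, plus mean (sd) summaries.

A thin command-line front end with verbs `phantom`, `localise`, `segment`
and `loo` is installed at `inst/cli/cordfuse.R`
(`Rscript $(Rscript -e 'cat(system.file("cli/cordfuse.R", package = "cordfuse"))') segment --target T.nii --library manifest.json --out-dir out`).

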