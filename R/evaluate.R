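#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)` over all voxels (2D masks or 3-slice stacks; on a
#' stack this is the 3D DSC).  Two empty masks are defined to agree (DSC 1).
#'
#' @param A,B binary [label_map()]s on the same grid.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(A, B) {
  if (!identical(dim(A$data), dim(B$data))) stop_grid_mismatch("dsc")
  a <- A$data >= 0.5; b <- B$data >= 0.5
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a & b) / (sa + sb)
}

## boundary pixels: foreground with at least one background 4-neighbour
## (the image border counts as background)
boundary_pixels <- function(m) {
  nx <- nrow(m); ny <- ncol(m)
  p <- matrix(FALSE, nx + 2, ny + 2)
  p[2:(nx + 1), 2:(ny + 1)] <- m >= 0.5
  core <- p[2:(nx + 1), 2:(ny + 1)]
  nb <- p[1:nx, 2:(ny + 1)] & p[3:(nx + 2), 2:(ny + 1)] &
    p[2:(nx + 1), 1:ny] & p[2:(nx + 1), 3:(ny + 2)]
  which(core & !nb, arr.ind = TRUE)
}

directed_distances <- function(PA, PB, spacing) {
  XA <- PA[, 1] * spacing[1]; YA <- PA[, 2] * spacing[2]
  XB <- PB[, 1] * spacing[1]; YB <- PB[, 2] * spacing[2]
  d2 <- outer(XA, XB, "-")^2 + outer(YA, YB, "-")^2
  sqrt(apply(d2, 1, min))
}

#' Mean and Hausdorff surface distances
#'
#' Boundary pixels are foreground pixels with a background 4-neighbour;
#' distances are between boundary pixel centres in mm.  For 3-slice stacks
#' the distances are computed in-plane per slice and pooled, matching the
#' slice-wise segmentation protocol.  The mean surface distance is the
#' symmetric mean of the two directed mean distances; the Hausdorff distance
#' is the max of the two directed maxima (classical form; `percentile < 1`
#' gives the percentile variant).
#'
#' @param A,B binary [label_map()]s on the same grid (2D or stacks).
#' @param percentile quantile of directed distances used for the Hausdorff
#'   value (default 1 = classical maximum).
#' @return `c(msd = <mm>, hd = <mm>)`.
#' @export
surface_distances <- function(A, B, percentile = 1) {
  if (!identical(dim(A$data), dim(B$data))) stop_grid_mismatch("surface_distances")
  da <- A$data; db <- B$data
  if (length(dim(da)) == 2L) { da <- array(da, c(dim(da), 1L)); db <- array(db, c(dim(db), 1L)) }
  if (sum(da) == 0 || sum(db) == 0)
    stop("surface_distances: empty mask has no surface")
  sp <- A$spacing[1:2]
  dab <- c(); dba <- c()
  for (k in seq_len(dim(da)[3])) {
    PA <- boundary_pixels(da[, , k]); PB <- boundary_pixels(db[, , k])
    if (!nrow(PA) && !nrow(PB)) next
    if (!nrow(PA) || !nrow(PB))
      stop("surface_distances: structure present in only one mask on slice ", k)
    dab <- c(dab, directed_distances(PA, PB, sp))
    dba <- c(dba, directed_distances(PB, PA, sp))
  }
  msd <- (mean(dab) + mean(dba)) / 2
  hd <- max(quantile(dab, percentile, names = FALSE),
            quantile(dba, percentile, names = FALSE))
  c(msd = msd, hd = hd)
}

#' Majority-vote consensus of three rater masks
#'
#' A voxel is foreground iff at least two of the three raters mark it.
#'
#' @param masks list of exactly 3 binary [label_map()]s on the same grid.
#' @return A binary [label_map()].
#' @export
consensus <- function(masks) {
  if (length(masks) != 3L) stop("consensus: exactly 3 masks required")
  for (m in masks[-1]) if (!identical(dim(m$data), dim(masks[[1]]$data)))
    stop_grid_mismatch("consensus")
  votes <- Reduce(`+`, lapply(masks, function(m) (m$data >= 0.5) * 1L))
  out <- masks[[1]]
  out$data <- (votes >= 2L) * 1L
  out$binary <- TRUE
  out
}

#' Screen a rater triple for agreement
#'
#' Fails when any pairwise DSC falls below the cut-off (0.7), mirroring the
#' exclusion of subjects whose expert segmentations disagree.
#'
#' @param masks list of 3 binary [label_map()]s.
#' @param cutoff minimum acceptable pairwise DSC (default 0.7).
#' @return `list(pass = <logical>, pairwise = <named numeric of 3 DSCs>)`.
#' @export
screen_raters <- function(masks, cutoff = 0.7) {
  if (length(masks) != 3L) stop("screen_raters: exactly 3 masks required")
  pairs <- combn(3, 2)
  d <- apply(pairs, 2, function(p) dsc(masks[[p[1]]], masks[[p[2]]]))
  names(d) <- apply(pairs, 2, paste, collapse = "-")
  list(pass = all(d >= cutoff), pairwise = d)
}

#' Per-slice areas and total volume of a mask
#'
#' @param mask binary [label_map()] (2D or stack).
#' @param dz slice thickness in mm if not carried by the mask spacing.
#' @return `list(areas_mm2 = <per-slice>, volume_mm3 = <scalar>)`.
#' @export
area_volume <- function(mask, dz = NULL) {
  d <- mask$data
  if (length(dim(d)) == 2L) d <- array(d, c(dim(d), 1L))
  sp <- mask$spacing
  if (is.null(dz)) dz <- if (length(sp) >= 3) sp[3] else NA_real_
  areas <- apply(d >= 0.5, 3, sum) * sp[1] * sp[2]
  list(areas_mm2 = areas, volume_mm3 = sum(areas) * dz)
}

#' Coefficient of variation of repeated measurements
#'
#' `100 * sd / mean` with the sample (n - 1) standard deviation.
#'
#' @param values numeric vector of at least two repeated measurements.
#' @return Percentage.
#' @export
cov_percent <- function(values) {
  if (length(values) < 2) stop("cov_percent: need at least 2 values")
  if (mean(values) == 0) stop("cov_percent: zero mean")
  100 * sd(values) / mean(values)
}

#' Leave-one-out cross-validation over a phantom cohort
#'
#' For each target subject the template library is rebuilt without that
#' subject's entries (and their left-right flips), the full two-stage
#' pipeline segments the subject's 3-slice section, and 3D DSC, mean surface
#' distance and Hausdorff distance are computed against the ground truth.
#'
#' @param cohort result of [generate_cohort()] (manifest plus per-subject
#'   file paths).
#' @param cfg a [run_config()].
#' @param targets subject ids to evaluate (default: all).
#' @return A data.frame with one row per (target, structure):
#'   `target_id, structure, dsc, msd_mm, hd_mm, area_mm2_s1..s3, volume_mm3`,
#'   with per-structure `mean (sd)` summaries attached as attribute
#'   `"summary"`.
#' @export
loo_run <- function(cohort, cfg = run_config(), targets = NULL) {
  lib <- build_library(cohort$manifest)
  ids <- names(cohort$subjects)
  if (is.null(targets)) targets <- ids
  if (!all(targets %in% ids)) stop("loo_run: unknown target subject id")
  rows <- list()
  for (id in targets) {
    red <- subset_library(lib, id)
    vol <- read_nifti(cohort$subjects[[id]]$image, id = id)
    truth <- list(cord = read_nifti(cohort$subjects[[id]]$cord),
                  gm = read_nifti(cohort$subjects[[id]]$gm))
    centre <- (dim(vol$data)[3] + 1L) %/% 2L
    seg <- segment_volume(vol, centre, red, cfg)
    for (structure_tag in c("cord", "gm")) {
      pred <- seg[[structure_tag]]
      tr <- label_map(round(truth[[structure_tag]]$data), vol$spacing,
                      structure_tag, origin = vol$affine[1:2, 4])
      sdist <- surface_distances(pred, tr)
      av <- area_volume(pred, dz = vol$spacing[3])
      rows[[length(rows) + 1L]] <- data.frame(
        target_id = id, structure = structure_tag,
        dsc = dsc(pred, tr), msd_mm = sdist[["msd"]], hd_mm = sdist[["hd"]],
        area_mm2_s1 = av$areas_mm2[1], area_mm2_s2 = av$areas_mm2[2],
        area_mm2_s3 = av$areas_mm2[3], volume_mm3 = av$volume_mm3,
        stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  summ <- do.call(rbind, lapply(split(report, report$structure), function(g)
    data.frame(structure = g$structure[1], n = nrow(g),
               dsc_mean = mean(g$dsc), dsc_sd = sd(g$dsc),
               msd_mean = mean(g$msd_mm), msd_sd = sd(g$msd_mm),
               hd_mean = mean(g$hd_mm), hd_sd = sd(g$hd_mm),
               stringsAsFactors = FALSE)))
  attr(report, "summary") <- summ
  report
}

#' @importFrom stats quantile
#' @importFrom utils combn
NULL
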