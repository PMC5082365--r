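#' Specification of the synthetic spinal-cord phantom cohort
#'
#' Describes a cohort of axial cervical-cord slices matching the geometry of
#' a typical 3D fast-field-echo acquisition: 0.5 x 0.5 mm in-plane pixels,
#' 5 mm slices, three contiguous slices per subject, cord cross-sectional
#' area around 88.2 mm^2 and grey-matter area around 14.0 mm^2.  The cord is
#' an ellipse surrounded by a bright CSF rim; the grey matter is a
#' butterfly-shaped union of two mirrored crescents joined by a posterior
#' bridge, with intensity contrast GM > WM > background and CSF brightest.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param slices_per_subject slices per subject (default 3, a 15 mm section).
#' @param spacing in-plane pixel size, mm (default `c(0.5, 0.5)`).
#' @param slice_thickness through-plane spacing, mm (default 5).
#' @param fov_mm in-plane field of view, mm (default 24).
#' @param cord_area_mean,cord_area_sd per-subject cord area distribution, mm^2.
#' @param gm_area_mean,gm_area_sd per-subject grey-matter area distribution, mm^2.
#' @param slice_area_sd relative per-slice area modulation (sd of a factor ~ 1).
#' @param levels named intensities for background, CSF, WM and GM (arbitrary
#'   units, CSF > GM > WM > background).
#' @param noise_sd Rician noise level as a fraction of the WM intensity.
#' @param lesion_prob per-subject probability of hyperintense WM lesions.
#' @param lesion_radius_mm range of lesion radii, mm.
#' @param jitter_translation_mm,jitter_rotation_deg,jitter_scale per-subject
#'   pose perturbation ranges (uniform in +/- the given value; scale is
#'   anisotropic, in 1 +/- `jitter_scale`).
#' @param cord_aspect left-right over anterior-posterior cord axis ratio.
#' @param csf_thickness_mm thickness of the CSF rim, mm.
#' @param edge_blur_px Gaussian blur applied to the intensity image (pixels),
#'   softening tissue boundaries; ground-truth masks stay crisp.
#' @param seed base seed; each subject derives its own stream from
#'   (seed, subject index).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 20L, slices_per_subject = 3L,
                         spacing = c(0.5, 0.5), slice_thickness = 5,
                         fov_mm = 24,
                         cord_area_mean = 88.2, cord_area_sd = 6.2,
                         gm_area_mean = 14.0, gm_area_sd = 1.4,
                         slice_area_sd = 0.015,
                         levels = c(background = 20, csf = 95, wm = 60, gm = 80),
                         noise_sd = 0.03,
                         lesion_prob = 0, lesion_radius_mm = c(0.75, 1.5),
                         jitter_translation_mm = 1.5, jitter_rotation_deg = 8,
                         jitter_scale = 0.05,
                         cord_aspect = 1.25, csf_thickness_mm = 1.2,
                         edge_blur_px = 0.6, seed = 1L) {
  if (cord_area_mean <= 0 || gm_area_mean <= 0)
    stop("phantom_spec: areas must be positive")
  if (gm_area_mean >= cord_area_mean)
    stop("phantom_spec: grey-matter area must be smaller than the cord area")
  if (lesion_prob < 0 || lesion_prob > 1)
    stop("phantom_spec: lesion_prob must be in [0, 1]")
  spec <- list(n_subjects = as.integer(n_subjects),
               slices_per_subject = as.integer(slices_per_subject),
               spacing = spacing, slice_thickness = slice_thickness,
               fov_mm = fov_mm,
               cord_area_mean = cord_area_mean, cord_area_sd = cord_area_sd,
               gm_area_mean = gm_area_mean, gm_area_sd = gm_area_sd,
               slice_area_sd = slice_area_sd, levels = levels,
               noise_sd = noise_sd, lesion_prob = lesion_prob,
               lesion_radius_mm = lesion_radius_mm,
               jitter_translation_mm = jitter_translation_mm,
               jitter_rotation_deg = jitter_rotation_deg,
               jitter_scale = jitter_scale, cord_aspect = cord_aspect,
               csf_thickness_mm = csf_thickness_mm,
               edge_blur_px = edge_blur_px, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

## butterfly indicator in cord-normalised coordinates (u, v) in the unit disc;
## +v is posterior.  Two mirrored crescents (ellipse minus laterally shifted
## ellipse) joined by a posterior bridge.
gm_shape <- function(u, v, s) {
  u <- u / s; v <- v / s
  in_ell <- function(cu, cv, au, av) ((abs(u) - cu) / au)^2 + ((v - cv) / av)^2 <= 1
  body <- in_ell(0.40, 0.00, 0.34, 0.58)
  bite <- in_ell(0.72, -0.10, 0.34, 0.50)
  crescents <- body & !bite
  bridge <- (u / 0.45)^2 + ((v - 0.32) / 0.14)^2 <= 1
  crescents | bridge
}

## per-subject deterministic RNG stream
subject_seed <- function(spec, subject_index) {
  as.integer((as.numeric(spec$seed) * 1000003 + subject_index * 7919) %% 2147483647)
}

render_slice <- function(spec, pars, slice_factor) {
  n <- max(2L, as.integer(round(spec$fov_mm / spec$spacing[1])))
  origin <- -(n - 1) / 2 * spec$spacing
  wx <- axis_world(n, spec$spacing[1], origin[1])
  wy <- axis_world(n, spec$spacing[2], origin[2])
  X <- matrix(wx, n, n); Y <- matrix(wy, n, n, byrow = TRUE)
  ## inverse subject pose: world -> canonical
  th <- pars$rot
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  px <- X - pars$tx; py <- Y - pars$ty
  cx <- (R[1, 1] * px + R[2, 1] * py) / pars$sx
  cy <- (R[1, 2] * px + R[2, 2] * py) / pars$sy
  ## cord semi-axes hitting the target area after anisotropic scaling
  area_c <- pars$cord_area * slice_factor / (pars$sx * pars$sy)
  a <- sqrt(area_c * spec$cord_aspect / pi)
  b <- sqrt(area_c / (pi * spec$cord_aspect))
  cord <- (cx / a)^2 + (cy / b)^2 <= 1
  csf_out <- (cx / (a + spec$csf_thickness_mm))^2 +
    (cy / (b + spec$csf_thickness_mm))^2 <= 1
  u <- cx / a; v <- cy / b
  dxdy <- prod(spec$spacing)
  target_gm <- pars$gm_area * slice_factor
  ## bisection on the butterfly scale factor to hit the target area
  lo <- 0.2; hi <- 1.6
  for (it in 1:30) {
    mid <- (lo + hi) / 2
    area <- sum(gm_shape(u, v, mid) & cord) * dxdy
    if (area < target_gm) lo <- mid else hi <- mid
  }
  gm <- gm_shape(u, v, (lo + hi) / 2) & cord
  lv <- spec$levels
  img <- matrix(lv[["background"]], n, n)
  img[csf_out] <- lv[["csf"]]
  img[cord] <- lv[["wm"]]
  img[gm] <- lv[["gm"]]
  if (spec$edge_blur_px > 0) img <- gauss_filter(img, spec$edge_blur_px)
  list(img = img, cord = cord * 1L, gm = gm * 1L, origin = origin, n = n)
}

#' Generate one phantom subject
#'
#' Deterministic given `(spec$seed, subject_index)`.  Returns the noisy
#' intensity volume together with crisp ground-truth cord and grey-matter
#' masks; the same random pose perturbation is applied to image and masks.
#'
#' @param spec a [phantom_spec()].
#' @param subject_index integer subject number (1-based).
#' @return `list(volume, cord, gm, params)` with `volume` an
#'   [image_volume()] and the masks 3-slice [label_map()] stacks.
#' @export
generate_subject <- function(spec, subject_index) {
  if (!inherits(spec, "phantom_spec")) stop("generate_subject: need a phantom_spec")
  if (spec$gm_area_mean >= spec$cord_area_mean)
    stop("generate_subject: grey-matter area must be below the cord area")
  set.seed(subject_seed(spec, subject_index))
  pars <- list(
    cord_area = max(10, rnorm(1, spec$cord_area_mean, spec$cord_area_sd)),
    gm_area = max(2, rnorm(1, spec$gm_area_mean, spec$gm_area_sd)),
    tx = runif(1, -1, 1) * spec$jitter_translation_mm,
    ty = runif(1, -1, 1) * spec$jitter_translation_mm,
    rot = runif(1, -1, 1) * spec$jitter_rotation_deg * pi / 180,
    sx = 1 + runif(1, -1, 1) * spec$jitter_scale,
    sy = 1 + runif(1, -1, 1) * spec$jitter_scale)
  if (pars$gm_area >= pars$cord_area)
    stop("generate_subject: drawn grey-matter area exceeds the cord area")
  nz <- spec$slices_per_subject
  factors <- 1 + rnorm(nz, 0, spec$slice_area_sd)
  has_lesion <- runif(1) < spec$lesion_prob
  id <- sprintf("sub%03d", subject_index)
  slices <- vector("list", nz)
  for (k in seq_len(nz)) {
    r <- render_slice(spec, pars, factors[k])
    img <- r$img
    if (spec$noise_sd > 0) {
      s <- spec$noise_sd * spec$levels[["wm"]]
      img <- sqrt((img + rnorm(length(img), 0, s))^2 +
                    rnorm(length(img), 0, s)^2)
      dim(img) <- dim(r$img)
    }
    sl <- slice2d(img, spec$spacing, origin = r$origin,
                  parent_id = id, slice_index = k)
    cm <- label_map(r$cord, spec$spacing, "cord", origin = r$origin)
    gmm <- label_map(r$gm, spec$spacing, "gm", origin = r$origin)
    if (has_lesion) sl <- add_lesion(sl, cm, gmm, spec)
    slices[[k]] <- list(slice = sl, cord = cm, gm = gmm)
  }
  n <- nrow(slices[[1]]$slice$data)
  arr <- function(field) {
    a <- array(0, c(n, n, nz))
    for (k in seq_len(nz)) a[, , k] <- slices[[k]][[field]]$data
    a
  }
  stack <- function(field, structure) {
    a <- array(0L, c(n, n, nz))
    for (k in seq_len(nz)) a[, , k] <- slices[[k]][[field]]$data
    label_map(a, c(spec$spacing, spec$slice_thickness), structure,
              origin = slices[[1]]$slice$origin)
  }
  sp3 <- c(spec$spacing, spec$slice_thickness)
  aff <- diag(c(sp3, 1))
  aff[1:2, 4] <- slices[[1]]$slice$origin
  vol <- image_volume(arr("slice"), sp3, aff, id)
  list(volume = vol, cord = stack("cord", "cord"), gm = stack("gm", "gm"),
       params = pars)
}

#' Add a hyperintense white-matter lesion to a slice
#'
#' Places a bright blob (intensity between the WM and CSF levels) inside the
#' white matter (cord minus grey matter).  Ground-truth masks are not
#' modified: lesions perturb the appearance, not the anatomy.
#'
#' @param image a [slice2d()].
#' @param cord,gm binary [label_map()]s on the same grid.
#' @param spec a [phantom_spec()] providing levels and radius range.
#' @return The modified [slice2d()].
#' @export
add_lesion <- function(image, cord, gm, spec = phantom_spec(2)) {
  if (!same_grid(image, cord)) stop_grid_mismatch("add_lesion")
  wm <- cord$data == 1L & gm$data == 0L
  if (!any(wm)) stop("add_lesion: white-matter region is empty")
  idx <- which(wm, arr.ind = TRUE)
  pick <- idx[sample.int(nrow(idx), 1L), ]
  cx <- image$origin[1] + (pick[1] - 1) * image$spacing[1]
  cy <- image$origin[2] + (pick[2] - 1) * image$spacing[2]
  r <- runif(1, spec$lesion_radius_mm[1], spec$lesion_radius_mm[2])
  lv <- spec$levels
  level <- (lv[["wm"]] + lv[["csf"]]) / 2
  n <- dim(image$data)
  wx <- axis_world(n[1], image$spacing[1], image$origin[1])
  wy <- axis_world(n[2], image$spacing[2], image$origin[2])
  D <- sqrt(outer((wx - cx)^2, (wy - cy)^2, "+"))
  alpha <- pmin(1, pmax(0, (r - D) / (0.5 * image$spacing[1]) + 0.5))
  alpha[!wm] <- 0
  image$data <- image$data * (1 - alpha) + level * alpha
  image
}

#' Generate a phantom cohort on disk
#'
#' Writes per-subject NIfTI images and masks plus a JSON manifest, ready for
#' [build_library()] and leave-one-out evaluation.  Masks are written
#' uncompressed so repeated runs with the same seed are byte-identical.
#'
#' @param spec a [phantom_spec()] with `n_subjects >= 2`.
#' @param out_dir output directory (created if missing).
#' @return `list(manifest, subjects, spec)` where `subjects` maps each
#'   subject id to its image/cord/gm file paths.
#' @export
generate_cohort <- function(spec, out_dir) {
  if (spec$n_subjects < 2L)
    stop("generate_cohort: need at least 2 subjects (leave-one-out requires a remaining library)")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  subjects <- list()
  manifest <- list()
  for (s in seq_len(spec$n_subjects)) {
    sub <- generate_subject(spec, s)
    id <- sub$volume$id
    paths <- list(image = file.path(out_dir, paste0(id, "_image.nii")),
                  cord = file.path(out_dir, paste0(id, "_cord.nii")),
                  gm = file.path(out_dir, paste0(id, "_gm.nii")))
    write_nifti(sub$volume, paths$image)
    write_nifti(sub$cord, paths$cord)
    write_nifti(sub$gm, paths$gm)
    subjects[[id]] <- paths
    manifest[[length(manifest) + 1L]] <-
      list(subject_id = id, image = basename(paths$image),
           cord_mask = basename(paths$cord), gm_mask = basename(paths$gm),
           slices = seq_len(spec$slices_per_subject))
  }
  mpath <- file.path(out_dir, "manifest.json")
  write_manifest(manifest, mpath)
  list(manifest = mpath, subjects = subjects, spec = spec)
}
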