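#' Pipeline run configuration
#'
#' One authoritative defaults block for every stage: PatchMatch localisation,
#' registration, fusion, the ROI dilation count and the global pre-ranking
#' cut that bounds how many templates are affinely registered per slice.
#'
#' @param seed base seed; every slice derives its PatchMatch stream from it.
#' @param patchmatch a [patchmatch_config()].
#' @param registration a [registration_config()].
#' @param fusion a [fusion_config()].
#' @param dilations ROI dilation passes after localisation (default 8).
#' @param prerank_cut number of templates kept (by NCC after centre-of-mass
#'   alignment) for affine registration (default 25).
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 42L, patchmatch = patchmatch_config(),
                       registration = registration_config(max_iter = 30L,
                                                          tol = 1e-4),
                       fusion = fusion_config(), dilations = 8L,
                       prerank_cut = 25L) {
  structure(list(seed = as.integer(seed), patchmatch = patchmatch,
                 registration = registration, fusion = fusion,
                 dilations = as.integer(dilations),
                 prerank_cut = as.integer(prerank_cut)),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' Recognised keys mirror the stage parameter names, e.g. `patch_size`,
#' `iterations`, `k_best`, `dilations`, `X`, `sigma_lncc`, `mrf_beta`,
#' `threshold`, `pyramid_levels`, `grid_spacing`, `sigma_sim`, `seed`.
#'
#' @param path YAML file with an optional `defaults:` block.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  d <- if (!is.null(y$defaults)) y$defaults else y
  pick <- function(name, default) if (!is.null(d[[name]])) d[[name]] else default
  run_config(
    seed = pick("seed", 42L),
    patchmatch = patchmatch_config(
      patch_size = pick("patch_size", 5L),
      n_iterations = pick("iterations", 5L),
      k_best = pick("k_best", 10L)),
    registration = registration_config(
      pyramid_levels = pick("pyramid_levels", 6L),
      grid_spacing_px = pick("grid_spacing", 5L),
      sigma_sim = pick("sigma_sim", 1)),
    fusion = fusion_config(
      X = pick("X", 15L),
      sigma_lncc = pick("sigma_lncc", 1.5),
      mrf_beta = pick("mrf_beta", 0.55),
      threshold = pick("threshold", 0.5),
      global_cut = pick("global_cut", 25L)),
    dilations = pick("dilations", 8L),
    prerank_cut = pick("prerank_cut", 25L))
}

#' Segment one axial slice
#'
#' Executes the full two-stage chain: PatchMatch cord localisation (largest
#' component, dilated), resampling of the target to the library resolution,
#' centre-of-mass-initialised affine registration of the most similar
#' templates, ROI-masked free-form refinement of the globally best ones,
#' STEPS fusion of cord and grey matter, thresholding with nesting, and
#' resampling of the masks back to the native grid (nearest-neighbour, to
#' preserve their categorical nature).
#'
#' @param target a [slice2d()].
#' @param library a `template_library` (already leave-one-out reduced if
#'   applicable).
#' @param cfg a [run_config()].
#' @return `list(cord, gm, cord_prob, gm_prob, log)` with binary and
#'   probabilistic [label_map()]s on the native target grid.
#' @export
segment_slice <- function(target, library, cfg = run_config()) {
  if (!length(library$entries)) stop("segment_slice: empty template library")
  t0 <- proc.time()[[3]]
  native_grid <- grid_info(target)
  native_spacing <- target$spacing
  resampled <- any(abs(native_spacing - library$native_spacing) > 1e-9)
  work <- if (resampled)
    resample_to(target, library$native_spacing, "linear") else target

  pm_cfg <- cfg$patchmatch
  pm_cfg$seed <- as.integer((cfg$seed * 131071 +
                               max(target$slice_index, 1L, na.rm = TRUE)) %%
                              2147483647)
  roi <- localise_cord(work, library, pm_cfg, cfg$dilations)
  com_t <- centre_of_mass(attr(roi, "core"))
  t_loc <- proc.time()[[3]]

  tgrid <- grid_info(work)
  entries <- library$entries
  inits <- lapply(entries, function(e) {
    com_e <- centre_of_mass(e$cord)
    affine2d(diag(2), com_e - com_t, tgrid, grid_info(e$slice))
  })
  ## cheap centre-of-mass NCC pre-ranking bounds the affine workload
  pre_scores <- vapply(seq_along(entries), function(m) {
    tryCatch(ncc(work, warp(entries[[m]]$slice, inits[[m]], "linear"), roi),
             error = function(e) -Inf)
  }, numeric(1))
  pre_keep <- head(order(-pre_scores, seq_along(pre_scores)), cfg$prerank_cut)

  aff <- vector("list", length(pre_keep))
  warped_aff <- vector("list", length(pre_keep))
  for (m in seq_along(pre_keep)) {
    e <- entries[[pre_keep[m]]]
    aff[[m]] <- tryCatch(
      affine_register(work, e$slice, inits[[pre_keep[m]]], roi,
                      cfg$registration),
      error = function(err) inits[[pre_keep[m]]])
    warped_aff[[m]] <- warp(e$slice, aff[[m]], "linear")
  }
  ord <- rank_templates_global(work, warped_aff, roi)
  keep <- head(ord, cfg$fusion$global_cut)
  t_aff <- proc.time()[[3]]

  n_ffd <- length(keep)
  warped_imgs <- vector("list", n_ffd)
  warped_cord <- vector("list", n_ffd)
  warped_gm <- vector("list", n_ffd)
  for (m in seq_len(n_ffd)) {
    e <- entries[[pre_keep[keep[m]]]]
    tx <- tryCatch(
      ffd_register(work, e$slice, aff[[keep[m]]], roi, cfg$registration),
      error = function(err) aff[[keep[m]]])
    warped_imgs[[m]] <- warp(e$slice, tx, "linear")
    warped_cord[[m]] <- warp(e$cord, tx, "linear")
    warped_gm[[m]] <- warp(e$gm, tx, "linear")
  }
  t_ffd <- proc.time()[[3]]

  fcfg <- cfg$fusion
  cord_prob <- fuse_structure(work, warped_imgs, warped_cord, roi, fcfg, "cord")
  gm_prob <- fuse_structure(work, warped_imgs, warped_gm, roi, fcfg, "gm")
  cord_bin <- binarise(cord_prob, fcfg$threshold)
  if (!any(cord_bin$data > 0)) stop("segment_slice: empty fused cord mask")
  gm_bin <- binarise(gm_prob, fcfg$threshold, enforce_nesting = cord_bin)
  t_fuse <- proc.time()[[3]]

  if (resampled) {
    cord_bin <- resample_to(cord_bin, native_spacing, "nearest")
    gm_bin <- resample_to(gm_bin, native_spacing, "nearest")
    cord_prob <- resample_to(cord_prob, native_spacing, "linear")
    gm_prob <- resample_to(gm_prob, native_spacing, "linear")
  }
  st_c <- attr(cord_prob, "state"); st_g <- attr(gm_prob, "state")
  log <- list(seed = pm_cfg$seed,
              resampled = resampled,
              prerank_scores = pre_scores,
              template_order = pre_keep[ord],
              fused_templates = pre_keep[keep],
              em_iterations = c(cord = if (!is.null(st_c)) st_c$n_iter else NA,
                                gm = if (!is.null(st_g)) st_g$n_iter else NA),
              p_cord = if (!is.null(st_c)) st_c$p else NULL,
              q_cord = if (!is.null(st_c)) st_c$q else NULL,
              timings_s = c(localise = t_loc - t0, affine = t_aff - t_loc,
                            ffd = t_ffd - t_aff, fuse = t_fuse - t_ffd))
  list(cord = cord_bin, gm = gm_bin, cord_prob = cord_prob, gm_prob = gm_prob,
       log = log)
}

#' Segment a 3-slice section of a volume
#'
#' Extracts the section, segments each slice independently, stacks the
#' results into 3D masks and reports per-slice cross-sectional areas and the
#' section volume.
#'
#' @param vol an [image_volume()].
#' @param centre_index 1-based index of the middle slice.
#' @param library a `template_library`.
#' @param cfg a [run_config()].
#' @param n_slices number of slices (default 3).
#' @return `list(cord, gm, cord_prob, gm_prob, report, logs)` with 3D
#'   [label_map()] stacks and a per-structure area/volume data.frame.
#' @export
segment_volume <- function(vol, centre_index, library, cfg = run_config(),
                           n_slices = 3L) {
  slices <- extract_section(vol, centre_index, n_slices)
  segs <- lapply(slices, segment_slice, library = library, cfg = cfg)
  n <- dim(slices[[1]]$data)
  dz <- vol$spacing[3]
  stack <- function(field, structure, binary) {
    a <- array(if (binary) 0L else 0, c(nrow(segs[[1]][[field]]$data),
                                        ncol(segs[[1]][[field]]$data),
                                        length(segs)))
    for (k in seq_along(segs)) a[, , k] <- segs[[k]][[field]]$data
    label_map(a, c(segs[[1]][[field]]$spacing[1:2], dz), structure,
              binary = binary, origin = segs[[1]][[field]]$origin)
  }
  cord <- stack("cord", "cord", TRUE)
  gm <- stack("gm", "gm", TRUE)
  report <- do.call(rbind, lapply(c("cord", "gm"), function(s) {
    av <- area_volume(if (s == "cord") cord else gm)
    data.frame(structure = s,
               area_mm2_s1 = av$areas_mm2[1], area_mm2_s2 = av$areas_mm2[2],
               area_mm2_s3 = av$areas_mm2[3],
               area_mm2_mean = mean(av$areas_mm2),
               volume_mm3 = av$volume_mm3, stringsAsFactors = FALSE)
  }))
  list(cord = cord, gm = gm,
       cord_prob = stack("cord_prob", "cord", FALSE),
       gm_prob = stack("gm_prob", "gm", FALSE),
       report = report, logs = lapply(segs, `[[`, "log"))
}
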