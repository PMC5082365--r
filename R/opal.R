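#' PatchMatch configuration
#'
#' Defaults follow the published usage of OPAL for cord localisation:
#' 5 x 5 pixel patches, 5 inner iterations and 10 best matches, with
#' similarity measured as the sum of squared differences between
#' z-normalised patches.
#'
#' @param patch_size odd patch side in pixels (default 5).
#' @param n_iterations number of propagation/random-search sweeps (default 5).
#' @param k_best number of best matches kept per pixel (default 10).
#' @param search_radius_decay multiplicative radius decay per random-search
#'   step, in both space and template index (default 0.5).
#' @param seed RNG seed for the randomised search.
#' @return An object of class `patchmatch_config`.
#' @export
patchmatch_config <- function(patch_size = 5L, n_iterations = 5L,
                              k_best = 10L, search_radius_decay = 0.5,
                              seed = 1L) {
  if (patch_size %% 2 == 0) stop("patchmatch_config: patch_size must be odd")
  if (n_iterations < 1) stop("patchmatch_config: n_iterations must be >= 1")
  if (k_best < 1) stop("patchmatch_config: k_best must be >= 1")
  if (search_radius_decay <= 0 || search_radius_decay >= 1)
    stop("patchmatch_config: search_radius_decay must be in (0, 1)")
  structure(list(patch_size = as.integer(patch_size),
                 n_iterations = as.integer(n_iterations),
                 k_best = as.integer(k_best),
                 search_radius_decay = search_radius_decay,
                 seed = as.integer(seed)),
            class = "patchmatch_config")
}

#' PatchMatch correspondence search over a template library
#'
#' Finds, for every target pixel, the `k_best` approximately nearest
#' 5 x 5 patches across all library entries by random initialisation followed
#' by alternating scan-order propagation and random search over
#' exponentially shrinking radii (in both space and template index).
#'
#' @param target a [slice2d()].
#' @param library a `template_library` whose entries share the target spacing
#'   (resample first if not).
#' @param cfg a [patchmatch_config()].
#' @return A `match_field`: per-pixel `k_best` records of
#'   (template index, template pixel, distance), ascending in distance, plus
#'   a per-iteration best-distance trace.
#' @export
patchmatch <- function(target, library, cfg = patchmatch_config()) {
  if (!length(library$entries)) stop("patchmatch: empty library")
  if (any(abs(target$spacing - library$native_spacing) > 1e-6))
    stop("patchmatch: target spacing differs from the library; resample first")
  half <- cfg$patch_size %/% 2L
  if (any(dim(target$data) < cfg$patch_size))
    stop("patchmatch: patch larger than the image")
  ts <- patch_stats(target$data, half)
  tmpls <- lapply(library$entries, function(e) e$slice$data)
  stats <- lapply(tmpls, patch_stats, half = half)
  set.seed(cfg$seed)
  res <- pm_search(target$data, ts$mean, ts$sd,
                   tmpls, lapply(stats, `[[`, "mean"), lapply(stats, `[[`, "sd"),
                   half, cfg$k_best, cfg$n_iterations, cfg$search_radius_decay)
  structure(list(t = res$t + 1L, i = res$i + 1L, j = res$j + 1L, d = res$d,
                 trace = res$trace, dims = dim(target$data),
                 k = cfg$k_best, n_templates = length(tmpls),
                 spacing = target$spacing, origin = target$origin),
            class = "match_field")
}

#' Fuse matched labels into a probabilistic map
#'
#' Each pixel's value is the similarity-weighted average of the centre labels
#' of its `k_best` matched patches, with weights `exp(-distance / h)` where
#' `h` is the mean match distance over the whole field.
#'
#' @param field a `match_field` from [patchmatch()].
#' @param library the `template_library` the field was built against.
#' @param structure "cord" or "gm".
#' @return A probabilistic [label_map()] on the target grid.
#' @export
fuse_matches <- function(field, library, structure = c("cord", "gm")) {
  structure_tag <- match.arg(structure)
  if (length(library$entries) != field$n_templates)
    stop("fuse_matches: field was built against a different library")
  labs <- lapply(library$entries, function(e) e[[structure_tag]]$data)
  nxm <- nrow(labs[[1]])
  lab_stack <- vapply(labs, as.vector, numeric(length(labs[[1]])))
  flat <- (as.vector(field$j) - 1L) * nxm + as.vector(field$i)
  l <- lab_stack[cbind(flat, as.vector(field$t))]
  dim(l) <- dim(field$d)
  h <- mean(field$d)
  w <- if (h > 0) exp(-field$d / h) else matrix(1, nrow(field$d), ncol(field$d))
  v <- colSums(w * l) / colSums(w)
  prob <- matrix(pmin(1, pmax(0, v)), field$dims[1], field$dims[2])
  label_map(prob, field$spacing, structure_tag, binary = FALSE,
            origin = field$origin)
}

#' Localise the cord and build the registration region of interest
#'
#' Thresholds the fused PatchMatch cord probability at 0.5, keeps the largest
#' connected component, and dilates it (by default eight times with a 3 x 3
#' square element) to guarantee enough boundary context for registration.
#'
#' @param target a [slice2d()].
#' @param library a `template_library`.
#' @param cfg a [patchmatch_config()].
#' @param dilations number of 3 x 3 dilation passes (default 8).
#' @return A binary [label_map()] region of interest; the undilated core mask
#'   is attached as attribute `"core"` and the fused probability as `"prob"`.
#' @export
localise_cord <- function(target, library, cfg = patchmatch_config(),
                          dilations = 8L) {
  field <- patchmatch(target, library, cfg)
  prob <- fuse_matches(field, library, "cord")
  core <- prob$data >= 0.5
  if (!any(core))
    stop("localise_cord: localisation failed (no pixel reached the 0.5 threshold)")
  lab <- EBImage::bwlabel(core * 1L)
  sizes <- tabulate(lab[lab > 0])
  core <- (lab == which.max(sizes)) * 1L
  roi <- dilate_mask(core, dilations)
  out <- label_map(roi, target$spacing, "cord", origin = target$origin)
  attr(out, "core") <- label_map(core, target$spacing, "cord",
                                 origin = target$origin)
  attr(out, "prob") <- prob
  out
}

#' Morphological dilation with a 3 x 3 square element
#' @param mask binary matrix or [label_map()].
#' @param times number of dilation passes.
#' @return Same type as the input.
#' @export
dilate_mask <- function(mask, times = 1L) {
  m <- if (inherits(mask, "label_map")) mask$data else mask
  brush <- EBImage::makeBrush(3L, shape = "box")
  for (i in seq_len(times)) m <- EBImage::dilate(m, brush)
  m <- round(m)
  storage.mode(m) <- "integer"
  if (inherits(mask, "label_map")) { mask$data <- m; mask } else m
}

#' Centre of mass of a mask in world coordinates
#'
#' Intensity-unweighted centroid of the foreground pixel centres, mm.
#'
#' @param mask a binary [label_map()] (2D).
#' @return Numeric length-2 world (x, y).
#' @export
centre_of_mass <- function(mask) {
  idx <- which(mask$data >= 0.5, arr.ind = TRUE)
  if (!nrow(idx)) stop("centre_of_mass: empty mask")
  c(mask$origin[1] + (mean(idx[, 1]) - 1) * mask$spacing[1],
    mask$origin[2] + (mean(idx[, 2]) - 1) * mask$spacing[2])
}
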