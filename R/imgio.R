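#' Read a NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 3D payload.
#' @param id subject identifier to attach; defaults to the file stem.
#' @return An [image_volume()] with spacing taken from the header and
#'   intensities untouched.
#' @export
read_nifti <- function(path, id = NULL) {
  if (!file.exists(path)) stop("read_nifti: file does not exist: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("read_nifti: malformed NIfTI file '",
                                           path, "': ", conditionMessage(e)))
  a <- as.array(img)
  attributes(a) <- list(dim = dim(a))
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1, drop = TRUE]
  if (length(dim(a)) != 3L)
    stop("read_nifti: expected a 3D payload, got ",
         paste(dim(a), collapse = "x"), " in ", path)
  sp <- as.numeric(RNifti::pixdim(img))[1:3]
  aff <- tryCatch(unclass(RNifti::xform(img))[1:4, 1:4],
                  error = function(e) diag(c(sp, 1)))
  if (is.null(id)) id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  image_volume(a, sp, aff, id)
}

#' Write a volume or mask to NIfTI-1
#'
#' Binary masks are stored as uint8 in \{0, 1\}, probabilistic masks and
#' images as float32, so that mask round-trips are bit-exact.
#'
#' @param x an [image_volume()] or [label_map()] (2D maps are written as a
#'   single-slice volume).
#' @param path output path (`.nii` recommended for byte-stable output).
#' @param dz slice thickness to record when writing a 2D map, mm.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(x, path, dz = 5) {
  if (inherits(x, "image_volume")) {
    a <- x$data; sp <- x$spacing; dt <- "double"
  } else if (inherits(x, "label_map")) {
    a <- x$data
    if (length(dim(a)) == 2L) a <- array(a, c(dim(a), 1L))
    sp <- c(x$spacing[1:2], if (length(x$spacing) >= 3) x$spacing[3] else dz)
    dt <- if (x$binary) "uint8" else "float"
  } else stop("write_nifti: unsupported object of class ", class(x)[1])
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- sp
  aff <- if (inherits(x, "image_volume")) x$affine else {
    m <- diag(c(sp, 1))
    m[1:2, 4] <- x$origin
    m
  }
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = dt)
  invisible(path)
}

#' Extract a contiguous section of axial slices
#'
#' Mirrors the acquisition protocol of taking a short section (by default
#' 3 contiguous 5 mm slices, i.e. 15 mm) centred on a reference slice.
#'
#' @param vol an [image_volume()].
#' @param centre_index 1-based index of the middle slice.
#' @param n_slices odd number of slices to extract (default 3).
#' @return A list of [slice2d()] objects, middle one at `centre_index`.
#' @export
extract_section <- function(vol, centre_index, n_slices = 3L) {
  nz <- dim(vol$data)[3]
  h <- n_slices %/% 2L
  lo <- centre_index - h; hi <- centre_index + h
  if (lo < 1L || hi > nz)
    stop(sprintf(
      "extract_section: centre %d out of range; valid centres are %d..%d for %d slices",
      centre_index, 1L + h, nz - h, nz))
  origin <- vol$affine[1:2, 4]
  lapply(lo:hi, function(k)
    slice2d(vol$data[, , k], vol$spacing[1:2], origin = origin,
            parent_id = vol$id, slice_index = k))
}

#' Mirror a slice and its masks about the anatomical left-right axis
#'
#' Applying the operation twice restores the input exactly.  The left-right
#' axis is the first in-plane array axis (the default world-x axis of the
#' stored grids).
#'
#' @param s a [slice2d()].
#' @param masks list of [label_map()]s sharing `s`'s grid.
#' @return `list(slice = <flipped slice>, masks = <flipped masks>)`, with a
#'   `flipped` attribute toggled on the slice.
#' @export
flip_lr <- function(s, masks = list()) {
  for (m in masks) if (!same_grid(s, m)) stop_grid_mismatch("flip_lr")
  nx <- nrow(s$data)
  fl <- s
  fl$data <- s$data[nx:1, , drop = FALSE]
  attr(fl, "flipped") <- !isTRUE(attr(s, "flipped"))
  fmasks <- lapply(masks, function(m) {
    m$data <- m$data[nx:1, , drop = FALSE]
    m
  })
  list(slice = fl, masks = fmasks)
}

#' Resample a slice or mask to a new pixel spacing
#'
#' The physical field of view is preserved (to within one pixel).  Linear
#' interpolation (with reflection at the borders) is used for images and
#' probabilistic maps; nearest-neighbour preserves the categorical nature of
#' binary masks.
#'
#' @param x a [slice2d()] or [label_map()] (2D).
#' @param target_spacing numeric length-2 spacing in mm.
#' @param mode "linear" or "nearest".
#' @return The resampled object on the new grid.
#' @export
resample_to <- function(x, target_spacing, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  target_spacing <- rep_len(as.numeric(target_spacing), 2L)
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("resample_to: target spacing must be strictly positive")
  d <- x$data
  sp <- x$spacing[1:2]
  origin <- if (!is.null(x$origin)) x$origin else c(0, 0)
  if (all(abs(target_spacing - sp) < 1e-12)) return(x)
  n_old <- dim(d)
  n_new <- pmax(1L, as.integer(round(n_old * sp / target_spacing)))
  ## field of view starts half a pixel before the first centre
  new_origin <- origin - sp / 2 + target_spacing / 2
  wx <- axis_world(n_new[1], target_spacing[1], new_origin[1])
  wy <- axis_world(n_new[2], target_spacing[2], new_origin[2])
  ## continuous source pixel coordinates of the new centres
  px <- (wx - origin[1]) / sp[1] + 1
  py <- (wy - origin[2]) / sp[2] + 1
  xi <- matrix(px, n_new[1], n_new[2])
  yi <- matrix(py, n_new[1], n_new[2], byrow = TRUE)
  out <- matrix(interp2(d, as.vector(xi), as.vector(yi), mode, pad = "reflect"),
                n_new[1], n_new[2])
  if (inherits(x, "slice2d")) {
    slice2d(out, target_spacing, new_origin, x$parent_id, x$slice_index)
  } else {
    binary <- x$binary && mode == "nearest"
    if (binary) out <- round(out)
    label_map(out, target_spacing, x$structure, binary = binary,
              origin = new_origin)
  }
}

#' Write a template-library manifest
#'
#' @param entries list of lists with fields `subject_id`, `image`,
#'   `cord_mask`, `gm_mask`, `slices` (1-based slice indices).
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(entries, path) {
  jsonlite::write_json(entries, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build a flip-augmented template library from a manifest
#'
#' Loads each subject's image and cord/grey-matter masks, extracts the listed
#' slices, validates grey-matter containment in the cord, and doubles the
#' library by left-right flipping every entry.
#'
#' @param manifest path to a JSON manifest (see [write_manifest()]).
#' @param augment_flips logical; add the mirrored copy of every entry
#'   (default `TRUE`).
#' @return A `template_library`.
#' @export
build_library <- function(manifest, augment_flips = TRUE) {
  if (!file.exists(manifest)) stop("build_library: manifest not found: ", manifest)
  spec <- jsonlite::read_json(manifest, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!length(spec)) stop("build_library: manifest lists no subjects")
  base <- dirname(manifest)
  rel <- function(p) if (file.exists(p)) p else file.path(base, p)
  entries <- list()
  native_spacing <- NULL
  for (sub in spec) {
    vol <- read_nifti(rel(sub$image), id = sub$subject_id)
    cvol <- read_nifti(rel(sub$cord_mask))
    gvol <- read_nifti(rel(sub$gm_mask))
    slices <- as.integer(sub$slices)
    if (!length(slices)) slices <- seq_len(dim(vol$data)[3])
    for (k in slices) {
      s <- slice2d(vol$data[, , k], vol$spacing[1:2],
                   origin = vol$affine[1:2, 4],
                   parent_id = sub$subject_id, slice_index = k)
      cm <- label_map(round(cvol$data[, , k]), vol$spacing[1:2], "cord",
                      binary = TRUE, origin = s$origin)
      gmm <- label_map(round(gvol$data[, , k]), vol$spacing[1:2], "gm",
                       binary = TRUE, origin = s$origin)
      if (any(gmm$data > cm$data))
        stop(sprintf(
          "build_library: grey matter extends outside the cord for subject '%s' slice %d",
          sub$subject_id, k))
      if (is.null(native_spacing)) native_spacing <- s$spacing
      entries[[length(entries) + 1L]] <-
        list(slice = s, cord = cm, gm = gmm,
             subject_id = sub$subject_id, flipped = FALSE)
      if (augment_flips) {
        f <- flip_lr(s, list(cm, gmm))
        entries[[length(entries) + 1L]] <-
          list(slice = f$slice, cord = f$masks[[1]], gm = f$masks[[2]],
               subject_id = sub$subject_id, flipped = TRUE)
      }
    }
  }
  template_library(entries, native_spacing, manifest)
}
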