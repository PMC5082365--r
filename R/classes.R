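#' @useDynLib cordfuse, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd var
#' @importFrom utils head
NULL

## Grid convention used throughout the package: 1-based array indices,
## pixel-centre coordinates, half-open physical extents.  For a Slice2D the
## world position of pixel (i, j) is origin + (c(i, j) - 1) * spacing; the
## field of view is [origin - spacing/2, origin + (n - 1/2) * spacing).
## The first in-plane array axis is the world left-right axis unless the
## volume affine says otherwise.

#' Construct an image volume
#'
#' A 3D scalar grid with physical voxel spacing and a 4x4 voxel-to-world
#' affine, the unit every pipeline stage consumes.
#'
#' @param data 3D numeric array of intensities (arbitrary units).
#' @param spacing numeric length-3, voxel size in mm (dx, dy, dz); all > 0.
#' @param affine 4x4 voxel-to-world matrix; defaults to a diagonal map built
#'   from `spacing` with the origin at the first voxel centre.
#' @param id subject identifier string.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, affine = NULL, id = NA_character_) {
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop("image_volume: 'data' must be a 3D array, got ",
         length(dim(data)), " dimensions")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("image_volume: 'spacing' must be three strictly positive numbers")
  if (any(!is.finite(data)))
    stop("image_volume: 'data' contains non-finite values")
  if (is.null(affine)) {
    affine <- diag(c(spacing, 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)))
    stop("image_volume: 'affine' must be a 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine,
                 id = as.character(id)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("<image_volume '%s'> %s voxels, spacing %s mm\n", x$id,
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Construct a 2D slice
#'
#' @param data numeric matrix; first axis is the in-plane left-right axis.
#' @param spacing numeric length-2, pixel size in mm.
#' @param origin world (x, y) position of the centre of pixel (1, 1), mm.
#' @param parent_id identifier of the parent volume.
#' @param slice_index index of the slice in its parent volume.
#' @return An object of class `slice2d`.
#' @export
slice2d <- function(data, spacing, origin = c(0, 0),
                    parent_id = NA_character_, slice_index = NA_integer_) {
  data <- as.matrix(data)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 2L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("slice2d: 'spacing' must be two strictly positive numbers")
  if (any(!is.finite(data)))
    stop("slice2d: 'data' contains non-finite values")
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 parent_id = as.character(parent_id),
                 slice_index = as.integer(slice_index)),
            class = "slice2d")
}

#' @export
print.slice2d <- function(x, ...) {
  cat(sprintf("<slice2d %s px, spacing %s mm (parent '%s' slice %s)>\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$spacing), collapse = " x "),
              x$parent_id, x$slice_index))
  invisible(x)
}

#' Construct a label map
#'
#' A binary or probabilistic mask sharing the grid of the image it annotates.
#'
#' @param data numeric matrix (or 3-slice 3D array) of values in \[0, 1\].
#' @param spacing pixel size in mm (length 2 for a slice, 3 for a stack).
#' @param structure which anatomical structure is labelled: "cord" or "gm".
#' @param binary logical; if `TRUE` values must be exactly 0 or 1.
#' @param origin world position of the first pixel centre.
#' @return An object of class `label_map`.
#' @export
label_map <- function(data, spacing, structure = c("cord", "gm"),
                      binary = TRUE, origin = c(0, 0)) {
  structure_tag <- match.arg(structure)
  data <- unclass(data)
  if (is.null(dim(data))) data <- as.matrix(data)
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L))
    stop("label_map: 'data' must be 2D or 3D")
  spacing <- as.numeric(spacing)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("label_map: 'spacing' must be strictly positive")
  if (any(!is.finite(data)))
    stop("label_map: 'data' contains non-finite values")
  if (binary) {
    if (!all(data %in% c(0, 1)))
      stop("label_map: binary mask contains values outside {0, 1}")
    storage.mode(data) <- "integer"
  } else {
    if (min(data) < 0 || max(data) > 1)
      stop("label_map: probabilistic mask contains values outside [0, 1]")
  }
  structure(list(data = data, spacing = spacing, structure = structure_tag,
                 binary = binary, origin = as.numeric(origin)),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map '%s' %s, %s px, %d foreground>\n", x$structure,
              if (x$binary) "binary" else "probabilistic",
              paste(dim(x$data), collapse = "x"), sum(x$data >= 0.5)))
  invisible(x)
}

#' Binarise a label map in place at a threshold
#' @noRd
as_binary_map <- function(m, threshold = 0.5) {
  label_map((m$data >= threshold) * 1L, m$spacing, m$structure,
            binary = TRUE, origin = m$origin)
}

same_grid <- function(a, b, tol = 1e-6) {
  da <- dim(if (is.list(a)) a$data else a)
  db <- dim(if (is.list(b)) b$data else b)
  if (!identical(da, db)) return(FALSE)
  sa <- a$spacing[seq_len(2)]; sb <- b$spacing[seq_len(2)]
  oa <- if (!is.null(a$origin)) a$origin else c(0, 0)
  ob <- if (!is.null(b$origin)) b$origin else c(0, 0)
  all(abs(sa - sb) < tol) && all(abs(oa - ob) < tol)
}

stop_grid_mismatch <- function(what) {
  stop(what, ": inputs do not share the same grid (shape/spacing/origin)")
}

## world coordinates of pixel centres along one axis
axis_world <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing

#' Template library constructor (internal); see [build_library()]
#' @noRd
template_library <- function(entries, native_spacing, manifest_path = NA_character_) {
  if (!length(entries)) stop("template_library: no entries")
  shp <- dim(entries[[1]]$slice$data)
  for (e in entries) {
    if (!identical(dim(e$slice$data), shp))
      stop("template_library: entries differ in shape")
    if (any(abs(e$slice$spacing - native_spacing) > 1e-9))
      stop("template_library: entries differ in spacing")
  }
  structure(list(entries = entries, native_spacing = native_spacing,
                 manifest_path = manifest_path),
            class = "template_library")
}

#' @export
print.template_library <- function(x, ...) {
  n <- length(x$entries)
  subj <- unique(vapply(x$entries, function(e) e$subject_id, character(1)))
  cat(sprintf("<template_library> %d entries (%d subjects, flip-augmented: %s), spacing %s mm\n",
              n, length(subj),
              any(vapply(x$entries, function(e) isTRUE(e$flipped), logical(1))),
              paste(format(x$native_spacing), collapse = " x ")))
  invisible(x)
}

#' Remove a subject's entries (and their flips) from a template library
#'
#' Implements the leave-one-out exclusion rule: every entry belonging to the
#' excluded subjects, flipped or not, is dropped.
#'
#' @param library a `template_library`.
#' @param exclude_subjects character vector of subject ids to remove.
#' @return A reduced `template_library`.
#' @export
subset_library <- function(library, exclude_subjects) {
  keep <- vapply(library$entries,
                 function(e) !(e$subject_id %in% exclude_subjects), logical(1))
  if (!any(keep))
    stop("subset_library: reduced library is empty after exclusion")
  template_library(library$entries[keep], library$native_spacing,
                   library$manifest_path)
}

#' Quick image display of a slice or label map
#'
#' @param x a `slice2d` or `label_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.slice2d <- function(x, ...) {
  graphics::image(axis_world(nrow(x$data), x$spacing[1], x$origin[1]),
                  axis_world(ncol(x$data), x$spacing[2], x$origin[2]),
                  x$data, asp = 1, col = grDevices::gray.colors(128),
                  xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}

#' @rdname plot.slice2d
#' @export
plot.label_map <- function(x, ...) {
  d <- if (length(dim(x$data)) == 3L) x$data[, , 1] else x$data
  graphics::image(axis_world(nrow(d), x$spacing[1], x$origin[1]),
                  axis_world(ncol(d), x$spacing[2], x$origin[2]),
                  d, asp = 1, zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "viridis"),
                  xlab = "x (mm)", ylab = "y (mm)", ...)
  invisible(x)
}
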