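#' Registration configuration
#'
#' Settings for the symmetric block-matching affine stage and the cubic
#' B-spline free-form deformation (FFD) stage.  Defaults follow the
#' slice-wise protocol: 6-parameter (full 2D) affine estimated by block
#' matching with a robust least-trimmed-squares fit, then an FFD driven by
#' locally normalised cross-correlation (sigma = 1 pixel) over a 6-level
#' control-grid pyramid whose finest spacing is 5 pixels.
#'
#' @param block_size block side in pixels for block matching (default 4).
#' @param search_radius_blocks search radius in blocks (default 3).
#' @param trim_fraction fraction of correspondences kept by the trimmed fit.
#' @param lts_iters trimmed-fit refinement passes (default 5).
#' @param pyramid_levels FFD pyramid depth (default 6).
#' @param grid_spacing_px control-point spacing at the finest level, pixels.
#' @param sigma_sim LNCC kernel for the FFD similarity, pixels (default 1).
#' @param bending_weight bending-energy regularisation weight (default 0.01).
#' @param max_iter gradient-ascent iterations per level (default 100).
#' @param tol convergence tolerance on the similarity objective.
#' @return An object of class `registration_config`.
#' @export
registration_config <- function(block_size = 4L, search_radius_blocks = 3L,
                                trim_fraction = 0.5, lts_iters = 5L,
                                pyramid_levels = 6L, grid_spacing_px = 5L,
                                sigma_sim = 1, bending_weight = 0.01,
                                max_iter = 100L, tol = 1e-5) {
  if (trim_fraction <= 0 || trim_fraction > 1)
    stop("registration_config: trim_fraction must be in (0, 1]")
  if (block_size < 2 || search_radius_blocks < 1 || pyramid_levels < 1 ||
      grid_spacing_px < 1 || sigma_sim <= 0 || max_iter < 0)
    stop("registration_config: all sizes must be positive")
  structure(list(block_size = as.integer(block_size),
                 search_radius_blocks = as.integer(search_radius_blocks),
                 trim_fraction = trim_fraction, lts_iters = as.integer(lts_iters),
                 pyramid_levels = as.integer(pyramid_levels),
                 grid_spacing_px = as.integer(grid_spacing_px),
                 sigma_sim = sigma_sim, bending_weight = bending_weight,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "registration_config")
}

#' Grid descriptor of a slice or mask
#' @param x a [slice2d()] or [label_map()].
#' @return `list(shape, spacing, origin)`.
#' @export
grid_info <- function(x) list(shape = dim(x$data), spacing = x$spacing[1:2],
                              origin = if (!is.null(x$origin)) x$origin else c(0, 0))

#' 2D affine transform (world mm, target to template)
#'
#' @param linear 2x2 linear part (invertible).
#' @param translation length-2 translation, mm.
#' @param target_grid,moving_grid grid descriptors (`list(shape, spacing,
#'   origin)`) of the target and the template; [grid_info()] builds one from
#'   a slice or mask.
#' @return An object of class `affine2d`.
#' @export
affine2d <- function(linear = diag(2), translation = c(0, 0),
                     target_grid = NULL, moving_grid = NULL) {
  linear <- matrix(as.numeric(linear), 2, 2)
  if (abs(det(linear)) < 1e-6)
    stop("affine2d: linear part is (near) singular")
  structure(list(linear = linear, translation = as.numeric(translation),
                 target_grid = target_grid, moving_grid = moving_grid),
            class = "affine2d")
}

affine_matrix <- function(a) rbind(cbind(a$linear, a$translation), c(0, 0, 1))

affine_from_matrix <- function(M, target_grid = NULL, moving_grid = NULL)
  affine2d(M[1:2, 1:2], M[1:2, 3], target_grid, moving_grid)

#' @export
print.affine2d <- function(x, ...) {
  cat("<affine2d> linear:\n"); print(round(x$linear, 6))
  cat("translation (mm):", round(x$translation, 6), "\n")
  invisible(x)
}

invert_affine <- function(a) {
  Li <- solve(a$linear)
  affine2d(Li, -Li %*% a$translation, a$moving_grid, a$target_grid)
}

#' Serialise a transform to JSON
#' @param tx an `affine2d`.
#' @param path output path.
#' @export
write_transform <- function(tx, path) {
  jsonlite::write_json(list(type = "affine2d",
                            matrix = as.vector(t(affine_matrix(tx)[1:2, ]))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' 2D deformation field composed with an affine initialisation
#'
#' Maps a target-grid point x (world mm) to the template as
#' `A(x + d(x))` where `d` is the stored per-pixel displacement in mm.
#'
#' @param disp_x,disp_y displacement components on the target grid, mm.
#' @param affine the `affine2d` initialisation.
#' @return An object of class `deformation_field2d`.
#' @export
deformation_field2d <- function(disp_x, disp_y, affine) {
  if (!all(dim(disp_x) == dim(disp_y)))
    stop("deformation_field2d: component shapes differ")
  if (any(!is.finite(disp_x)) || any(!is.finite(disp_y)))
    stop("deformation_field2d: non-finite displacements")
  structure(list(disp_x = disp_x, disp_y = disp_y, affine = affine),
            class = "deformation_field2d")
}

## world coordinates of every target pixel centre for a grid descriptor
grid_world <- function(g) {
  nx <- g$shape[1]; ny <- g$shape[2]
  list(X = matrix(axis_world(nx, g$spacing[1], g$origin[1]), nx, ny),
       Y = matrix(axis_world(ny, g$spacing[2], g$origin[2]), nx, ny, byrow = TRUE))
}

## sample `moving` (matrix + grid descriptor) at world positions (px, py)
sample_world <- function(mdata, mgrid, px, py, mode) {
  xi <- (px - mgrid$origin[1]) / mgrid$spacing[1] + 1
  yi <- (py - mgrid$origin[2]) / mgrid$spacing[2] + 1
  interp2(mdata, as.vector(xi), as.vector(yi), mode, pad = "replicate")
}

#' Warp an image or mask onto the target grid of a transform
#'
#' @param moving a [slice2d()] or 2D [label_map()].
#' @param tx an `affine2d` or `deformation_field2d`.
#' @param mode "linear" (images, soft labels) or "nearest" (binary masks).
#' @return The warped object on the transform's target grid; binary masks
#'   warped linearly become probabilistic maps in \[0, 1\].
#' @export
warp <- function(moving, tx, mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  aff <- if (inherits(tx, "deformation_field2d")) tx$affine else tx
  if (!inherits(aff, "affine2d")) stop("warp: invalid transform")
  tg <- aff$target_grid
  if (is.null(tg)) stop("warp: transform carries no target grid")
  W <- grid_world(tg)
  X <- W$X; Y <- W$Y
  if (inherits(tx, "deformation_field2d")) {
    X <- X + tx$disp_x
    Y <- Y + tx$disp_y
  }
  px <- aff$linear[1, 1] * X + aff$linear[1, 2] * Y + aff$translation[1]
  py <- aff$linear[2, 1] * X + aff$linear[2, 2] * Y + aff$translation[2]
  mgrid <- grid_info(moving)
  v <- sample_world(moving$data, mgrid, px, py, mode)
  out <- matrix(v, tg$shape[1], tg$shape[2])
  if (inherits(moving, "slice2d")) {
    slice2d(out, tg$spacing, tg$origin, moving$parent_id, moving$slice_index)
  } else {
    if (mode == "nearest") {
      out <- round(out)
      label_map(out, tg$spacing, moving$structure, binary = TRUE,
                origin = tg$origin)
    } else {
      label_map(pmin(pmax(out, 0), 1), tg$spacing, moving$structure,
                binary = FALSE, origin = tg$origin)
    }
  }
}

#' Global normalised cross-correlation between two slices
#'
#' Pearson correlation of intensities over the (optionally masked) pixels.
#'
#' @param a,b [slice2d()]s on the same grid.
#' @param mask optional binary [label_map()] restricting the pixels used.
#' @return Scalar in \[-1, 1\].
#' @export
ncc <- function(a, b, mask = NULL) {
  if (!same_grid(a, b)) stop_grid_mismatch("ncc")
  va <- as.vector(a$data); vb <- as.vector(b$data)
  if (!is.null(mask)) {
    if (!same_grid(a, mask)) stop_grid_mismatch("ncc")
    keep <- as.vector(mask$data) >= 0.5
    va <- va[keep]; vb <- vb[keep]
  }
  if (length(va) < 2) stop("ncc: fewer than 2 pixels in the mask")
  if (sd(va) == 0 || sd(vb) == 0)
    stop("ncc: zero variance (degenerate/constant image)")
  sum((va - mean(va)) * (vb - mean(vb))) /
    ((length(va) - 1) * sd(va) * sd(vb))
}

#' Locally normalised cross-correlation map
#'
#' Correlation computed from Gaussian-weighted local means, variances and
#' covariance; pixels whose local variance falls below 1e-6 of the global
#' intensity variance are set to 0; values are clipped to \[-1, 1\].
#'
#' @param a,b [slice2d()]s (or plain matrices) on the same grid.
#' @param sigma Gaussian kernel standard deviation, pixels.
#' @return A matrix of per-pixel correlations.
#' @export
lncc <- function(a, b, sigma) {
  if (sigma <= 0) stop("lncc: sigma must be positive")
  A <- if (is.list(a)) a$data else a
  B <- if (is.list(b)) b$data else b
  if (!all(dim(A) == dim(B))) stop_grid_mismatch("lncc")
  mu_a <- gauss_filter(A, sigma); mu_b <- gauss_filter(B, sigma)
  va <- pmax(gauss_filter(A * A, sigma) - mu_a^2, 0)
  vb <- pmax(gauss_filter(B * B, sigma) - mu_b^2, 0)
  cab <- gauss_filter(A * B, sigma) - mu_a * mu_b
  eps_a <- max(1e-6 * var(as.vector(A)), 1e-12)
  eps_b <- max(1e-6 * var(as.vector(B)), 1e-12)
  out <- matrix(0, nrow(A), ncol(A))
  ok <- va > eps_a & vb > eps_b
  out[ok] <- pmin(1, pmax(-1, cab[ok] / sqrt(va[ok] * vb[ok])))
  out
}

## real matrix logarithm (affines near identity have one); falls back to NULL
safe_logm <- function(M) {
  L <- tryCatch(pracma::logm(M), error = function(e) NULL)
  if (is.null(L)) return(NULL)
  if (is.complex(L)) {
    if (max(abs(Im(L))) > 1e-8) return(NULL)
    L <- Re(L)
  }
  L
}

## least-trimmed-squares affine fit of point pairs P -> Q (n x 2 world mm)
lts_affine_fit <- function(P, Q, frac, iters) {
  n <- nrow(P)
  keep <- seq_len(n)
  fit <- NULL
  for (it in seq_len(iters)) {
    X <- cbind(P[keep, 1], P[keep, 2], 1)
    cf <- tryCatch(qr.solve(X, Q[keep, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(cf)) return(NULL)
    fit <- cf
    pred <- cbind(P[, 1], P[, 2], 1) %*% cf
    res <- sqrt(rowSums((pred - Q)^2))
    m <- max(3L, ceiling(frac * n))
    keep <- order(res)[seq_len(m)]
  }
  M <- diag(3)
  M[1:2, 1:2] <- t(fit[1:2, ])
  M[1:2, 3] <- fit[3, ]
  M
}

## one direction of block matching: target fixed, template pre-warped by init
blockmatch_direction <- function(target, tmpl_warped, roi, cfg) {
  B <- cfg$block_size
  nx <- nrow(target$data); ny <- ncol(target$data)
  st <- expand.grid(i = seq(1L, nx - B + 1L, by = B),
                    j = seq(1L, ny - B + 1L, by = B))
  inroi <- vapply(seq_len(nrow(st)), function(r) {
    any(roi$data[st$i[r]:(st$i[r] + B - 1L), st$j[r]:(st$j[r] + B - 1L)] >= 0.5)
  }, logical(1))
  st <- st[inroi, , drop = FALSE]
  if (!nrow(st)) return(NULL)
  rng <- diff(range(target$data))
  res <- block_match(target$data, tmpl_warped$data,
                     as.integer(st$i - 1L), as.integer(st$j - 1L),
                     B, cfg$search_radius_blocks * B,
                     max(1e-6 * rng, 1e-12))
  ok <- res$valid
  if (sum(ok) < 3) return(NULL)
  ctr <- (B - 1) / 2
  sp <- target$spacing; o <- target$origin
  P <- cbind(o[1] + (st$i[ok] - 1 + ctr) * sp[1],
             o[2] + (st$j[ok] - 1 + ctr) * sp[2])
  Q <- cbind(P[, 1] + res$du[ok] * sp[1], P[, 2] + res$dv[ok] * sp[2])
  list(P = P, Q = Q)
}

#' Symmetric affine registration by block matching
#'
#' Matches target blocks inside the region of interest to the best-NCC
#' template block within the search radius, fits a full 2D affine by a
#' least-trimmed-squares robust fit, estimates both directions, and averages
#' them in the matrix-logarithm domain.  Returns the initialisation if no
#' candidate improves the masked NCC.
#'
#' @param target,template [slice2d()]s.
#' @param init an `affine2d` initialisation (e.g. the centre-of-mass offset).
#' @param roi binary [label_map()] on the target grid.
#' @param cfg a [registration_config()].
#' @param passes number of estimation passes; the second pass restarts the
#'   block matching from the refined pose (default 2).
#' @return The estimated `affine2d` (target to template, world mm).
#' @export
affine_register <- function(target, template, init, roi,
                            cfg = registration_config(), passes = 2L) {
  if (is.null(init$target_grid)) init$target_grid <- grid_info(target)
  if (is.null(init$moving_grid)) init$moving_grid <- grid_info(template)
  if (!any(roi$data >= 0.5)) stop("affine_register: empty region of interest")

  one_pass <- function(cur) {
    tw <- warp(template, cur, "linear")
    fwd <- blockmatch_direction(target, tw, roi, cfg)
    if (is.null(fwd)) return(NULL)
    Mb <- lts_affine_fit(fwd$P, fwd$Q, cfg$trim_fraction, cfg$lts_iters)
    if (is.null(Mb)) return(NULL)
    M_cur <- affine_matrix(cur)
    M_fwd <- M_cur %*% Mb
    ## backward direction: the template is the fixed image
    inv_cur <- invert_affine(cur)
    roi_t <- warp(roi, inv_cur, "nearest")
    M_out <- M_fwd
    if (any(roi_t$data >= 0.5)) {
      tgt_w <- warp(target, inv_cur, "linear")
      bwd <- blockmatch_direction(template, tgt_w, roi_t, cfg)
      if (!is.null(bwd)) {
        Mc <- lts_affine_fit(bwd$P, bwd$Q, cfg$trim_fraction, cfg$lts_iters)
        if (!is.null(Mc)) {
          ## template -> target estimate; invert, then log-Euclidean average
          M_bwd_inv <- tryCatch(solve(solve(M_cur) %*% Mc),
                                error = function(e) NULL)
          if (!is.null(M_bwd_inv)) {
            Lf <- safe_logm(M_fwd); Lb <- safe_logm(M_bwd_inv)
            if (!is.null(Lf) && !is.null(Lb))
              M_out <- pracma::expm((Lf + Lb) / 2)
          }
        }
      }
    }
    affine_from_matrix(M_out, init$target_grid, init$moving_grid)
  }
  score <- function(a) {
    tryCatch(ncc(target, warp(template, a, "linear"), roi),
             error = function(e) -Inf)
  }
  best <- init; best_s <- score(init)
  cur <- init
  for (ps in seq_len(max(1L, passes))) {
    cand <- one_pass(cur)
    if (is.null(cand)) {
      if (ps == 1L)
        stop("affine_register: insufficient structure ",
             "(fewer than 3 valid block correspondences)")
      break
    }
    s <- score(cand)
    if (s <= best_s) break
    best <- cand; best_s <- s
    cur <- cand
  }
  best
}

## cubic B-spline basis weights for parameter t in [0,1)
bspline_w <- function(t) {
  cbind((1 - t)^3 / 6,
        (3 * t^3 - 6 * t^2 + 4) / 6,
        (-3 * t^3 + 3 * t^2 + 3 * t + 1) / 6,
        t^3 / 6)
}

## sparse basis matrix (npix x ncp) for a control lattice with `spacing_px`
## pixel spacing covering an nx x ny grid; also returns the lattice shape
bspline_basis <- function(nx, ny, spacing_px) {
  gx <- (0:(nx - 1)) / spacing_px
  gy <- (0:(ny - 1)) / spacing_px
  bx <- floor(gx); by <- floor(gy)
  wx <- bspline_w(gx - bx); wy <- bspline_w(gy - by)
  ncx <- max(bx) + 4L; ncy <- max(by) + 4L  # control indices bx..bx+3 (1-based +1)
  px <- rep(seq_len(nx), times = ny)
  py <- rep(seq_len(ny), each = nx)
  ii <- jj <- vv <- vector("list", 16L)
  n <- 0L
  for (a in 1:4) for (b in 1:4) {
    n <- n + 1L
    ci <- bx[px] + a          # 1-based control x index
    cj <- by[py] + b
    ii[[n]] <- px + (py - 1L) * nx
    jj[[n]] <- ci + (cj - 1L) * ncx
    vv[[n]] <- wx[px, a] * wy[py, b]
  }
  B <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(vv),
                            dims = c(nx * ny, ncx * ncy))
  list(B = B, ncx = ncx, ncy = ncy)
}

## grid-keyed cache: the basis depends only on (nx, ny, spacing)
bspline_basis_cached <- function(nx, ny, spacing_px) {
  key <- sprintf("bsp_%d_%d_%d", nx, ny, spacing_px)
  got <- .conv_cache[[key]]
  if (is.null(got)) {
    got <- bspline_basis(nx, ny, spacing_px)
    .conv_cache[[key]] <- got
  }
  got
}

## fixed-image local statistics, computed once per registration
lncc_fixed_stats <- function(A, sigma) {
  mu_a <- gauss_filter(A, sigma)
  va <- pmax(gauss_filter(A * A, sigma) - mu_a^2, 0)
  list(A = A, mu_a = mu_a, va = va,
       eps_a = max(1e-6 * var(as.vector(A)), 1e-12))
}

## ROI-masked mean LNCC (value only; same eps rule as lncc())
lncc_masked_value <- function(fs, Bimg, R, sigma) {
  mu_b <- gauss_filter(Bimg, sigma)
  vb <- pmax(gauss_filter(Bimg * Bimg, sigma) - mu_b^2, 0)
  cab <- gauss_filter(fs$A * Bimg, sigma) - fs$mu_a * mu_b
  eps_b <- max(1e-6 * var(as.vector(Bimg)), 1e-12)
  ok <- fs$va > fs$eps_a & vb > eps_b
  C <- matrix(0, nrow(fs$A), ncol(fs$A))
  C[ok] <- pmin(1, pmax(-1, cab[ok] / sqrt(fs$va[ok] * vb[ok])))
  sum(C * R) / sum(R)
}

## bending-energy quadratic form on the control lattice (thin-plate form,
## second differences): e = ||Dxx c||^2 + ||Dyy c||^2 + 2 ||Dxy c||^2
## expressed through a cached sparse matrix M with e = c' M c / 2, g = M c
bending_op_cached <- function(ncx, ncy) {
  key <- sprintf("bend_%d_%d", ncx, ncy)
  got <- .conv_cache[[key]]
  if (!is.null(got)) return(got)
  d2 <- function(n) {
    if (n < 3) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                           x = numeric(), dims = c(0, n)))
    Matrix::sparseMatrix(i = rep(seq_len(n - 2), 3),
                         j = c(seq_len(n - 2), seq_len(n - 2) + 1,
                               seq_len(n - 2) + 2),
                         x = rep(c(1, -2, 1), each = n - 2), dims = c(n - 2, n))
  }
  d1 <- function(n) {
    if (n < 2) return(Matrix::sparseMatrix(i = integer(), j = integer(),
                                           x = numeric(), dims = c(0, n)))
    Matrix::sparseMatrix(i = rep(seq_len(n - 1), 2),
                         j = c(seq_len(n - 1), seq_len(n - 1) + 1),
                         x = rep(c(-1, 1), each = n - 1), dims = c(n - 1, n))
  }
  Ix <- Matrix::Diagonal(ncx); Iy <- Matrix::Diagonal(ncy)
  Lxx <- Matrix::kronecker(Iy, d2(ncx))
  Lyy <- Matrix::kronecker(d2(ncy), Ix)
  Lxy <- Matrix::kronecker(d1(ncy), d1(ncx))
  M <- 2 * (Matrix::crossprod(Lxx) + Matrix::crossprod(Lyy) +
              2 * Matrix::crossprod(Lxy))
  .conv_cache[[key]] <- M
  M
}

bending <- function(cvec, ncx, ncy) {
  M <- bending_op_cached(ncx, ncy)
  g <- as.vector(M %*% cvec)
  list(e = 0.5 * sum(cvec * g), g = g)
}

## adjoint Gaussian filtering (transpose of the reflect-padded operator)
gauss_adj <- function(mat, sigma) {
  gx <- gauss_op(nrow(mat), sigma, "reflect")
  gy <- gauss_op(ncol(mat), sigma, "reflect")
  t(gx) %*% mat %*% gy
}

## masked mean LNCC and its voxel-wise gradient w.r.t. the warped image b
lncc_value_grad <- function(fs, Bimg, R, sigma) {
  A <- fs$A; mu_a <- fs$mu_a; va <- fs$va
  mu_b <- gauss_filter(Bimg, sigma)
  vb <- pmax(gauss_filter(Bimg * Bimg, sigma) - mu_b^2, 0)
  cab <- gauss_filter(A * Bimg, sigma) - mu_a * mu_b
  eps_b <- max(1e-6 * var(as.vector(Bimg)), 1e-12)
  ok <- va > fs$eps_a & vb > eps_b
  C <- matrix(0, nrow(A), ncol(A))
  C[ok] <- pmin(1, pmax(-1, cab[ok] / sqrt(va[ok] * vb[ok])))
  N <- sum(R)
  val <- sum(C * R) / N
  Rv <- R * ok
  inv_sasb <- matrix(0, nrow(A), ncol(A))
  inv_sasb[ok] <- 1 / sqrt(va[ok] * vb[ok])
  inv_vb <- matrix(0, nrow(A), ncol(A))
  inv_vb[ok] <- 1 / vb[ok]
  g <- A * gauss_adj(Rv * inv_sasb, sigma) -
    gauss_adj(Rv * mu_a * inv_sasb, sigma) -
    Bimg * gauss_adj(Rv * C * inv_vb, sigma) +
    gauss_adj(Rv * C * mu_b * inv_vb, sigma)
  list(value = val, grad = g / N)
}

#' Free-form deformation registration
#'
#' Refines an affine initialisation with a cubic B-spline deformation
#' optimised by gradient ascent on the ROI-masked mean LNCC minus a
#' bending-energy penalty, coarse-to-fine over a control-grid pyramid whose
#' spacing halves down to `grid_spacing_px` pixels.  Only improving steps are
#' accepted, so the masked mean LNCC never falls below its affine-only
#' starting value.
#'
#' @param target,template [slice2d()]s.
#' @param init an `affine2d` (target to template).
#' @param roi binary [label_map()] on the target grid.
#' @param cfg a [registration_config()].
#' @return A `deformation_field2d` (displacements in mm on the target grid,
#'   composed with `init`).
#' @export
ffd_register <- function(target, template, init, roi,
                         cfg = registration_config()) {
  if (is.null(init$target_grid)) init$target_grid <- grid_info(target)
  if (is.null(init$moving_grid)) init$moving_grid <- grid_info(template)
  nx <- nrow(target$data); ny <- ncol(target$data)
  R <- (roi$data >= 0.5) * 1
  if (!any(R > 0)) stop("ffd_register: empty region of interest")
  sp <- target$spacing
  ## pre-warp the template through the affine, with spatial gradients (per px)
  tw <- warp(template, init, "linear")
  TW <- tw$data
  gx <- (rbind(TW[-1, , drop = FALSE], TW[nx, , drop = FALSE]) -
           rbind(TW[1, , drop = FALSE], TW[-nx, , drop = FALSE])) / 2
  gy <- (cbind(TW[, -1, drop = FALSE], TW[, ny, drop = FALSE]) -
           cbind(TW[, 1, drop = FALSE], TW[, -ny, drop = FALSE])) / 2
  XI <- matrix(seq_len(nx), nx, ny)
  YI <- matrix(seq_len(ny), nx, ny, byrow = TRUE)
  Dx <- matrix(0, nx, ny); Dy <- matrix(0, nx, ny)  # displacement, pixels
  fs <- lncc_fixed_stats(target$data, cfg$sigma_sim)

  spacings <- cfg$grid_spacing_px * 2^((cfg$pyramid_levels - 1):0)
  spacings <- spacings[spacings < min(nx, ny)]
  for (s in spacings) {
    bs <- bspline_basis_cached(nx, ny, s)
    B <- bs$B; ncp <- bs$ncx * bs$ncy
    cx <- numeric(ncp); cy <- numeric(ncp)
    eval_value <- function(cx, cy) {
      dx <- Dx + matrix(as.vector(B %*% cx), nx, ny)
      dy <- Dy + matrix(as.vector(B %*% cy), nx, ny)
      Wimg <- matrix(interp2(TW, as.vector(XI + dx), as.vector(YI + dy),
                             "linear", "replicate"), nx, ny)
      v <- lncc_masked_value(fs, Wimg, R, cfg$sigma_sim) -
        cfg$bending_weight * (bending(cx, bs$ncx, bs$ncy)$e +
                                bending(cy, bs$ncx, bs$ncy)$e) / ncp
      list(obj = v, dx = dx, dy = dy)
    }
    cur <- eval_value(cx, cy)
    if (!is.finite(cur$obj))
      stop("ffd_register: objective is not finite at level with spacing ", s)
    step <- NULL
    for (it in seq_len(cfg$max_iter)) {
      ## gradient at the current warp
      Wimg <- matrix(interp2(TW, as.vector(XI + cur$dx), as.vector(YI + cur$dy),
                             "linear", "replicate"), nx, ny)
      sg <- lncc_value_grad(fs, Wimg, R, cfg$sigma_sim)
      gwx <- matrix(interp2(gx, as.vector(XI + cur$dx), as.vector(YI + cur$dy),
                            "linear", "replicate"), nx, ny)
      gwy <- matrix(interp2(gy, as.vector(XI + cur$dx), as.vector(YI + cur$dy),
                            "linear", "replicate"), nx, ny)
      gcx <- as.vector(Matrix::crossprod(B, as.vector(sg$grad * gwx))) -
        2 * cfg$bending_weight * bending(cx, bs$ncx, bs$ncy)$g / ncp
      gcy <- as.vector(Matrix::crossprod(B, as.vector(sg$grad * gwy))) -
        2 * cfg$bending_weight * bending(cy, bs$ncx, bs$ncy)$g / ncp
      gmax <- max(abs(c(as.vector(B %*% gcx), as.vector(B %*% gcy))))
      if (gmax < 1e-14) break
      if (is.null(step)) step <- 0.5 / gmax
      improved <- FALSE
      delta <- 0
      for (half in 1:6) {
        cand <- eval_value(cx + step * gcx, cy + step * gcy)
        if (is.nan(cand$obj))
          stop("ffd_register: divergence (objective NaN) at spacing ", s,
               " iteration ", it)
        if (cand$obj > cur$obj) {
          cx <- cx + step * gcx; cy <- cy + step * gcy
          delta <- cand$obj - cur$obj
          cur <- cand
          step <- step * 1.5
          improved <- TRUE
          break
        }
        step <- step / 2
      }
      if (!improved || delta < cfg$tol) break
    }
    Dx <- cur$dx; Dy <- cur$dy
  }
  deformation_field2d(Dx * sp[1], Dy * sp[2], init)
}
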