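## Separable Gaussian filtering and bilinear/nearest interpolation on plain
## matrices.  Filtering is implemented as two banded-matrix products with the
## requested border policy folded into the band matrix, so repeated calls on
## the same grid reuse cached operators.

.conv_cache <- new.env(parent = emptyenv())

## 1D Gaussian convolution operator (n x n dense matrix) with border policy.
## pad = "reflect" mirrors indices at the borders (weights always sum to 1);
## pad = "zero" truncates (used for ROI-restricted sums).
gauss_op <- function(n, sigma, pad = c("reflect", "zero")) {
  pad <- match.arg(pad)
  key <- sprintf("g_%d_%.8g_%s", n, sigma, pad)
  got <- .conv_cache[[key]]
  if (!is.null(got)) return(got)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-r:r) / sigma)^2)
  k <- k / sum(k)
  op <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- i + (-r:r)
    if (pad == "reflect") {
      ## periodic mirror: 0 -> 1, -1 -> 2, n+1 -> n, ... for any distance
      m <- (idx - 1L) %% (2L * n)
      idx <- ifelse(m < n, m + 1L, 2L * n - m)
      for (m in seq_along(idx)) op[i, idx[m]] <- op[i, idx[m]] + k[m]
    } else {
      ok <- idx >= 1L & idx <= n
      for (m in which(ok)) op[i, idx[m]] <- op[i, idx[m]] + k[m]
    }
  }
  .conv_cache[[key]] <- op
  op
}

gauss_filter <- function(mat, sigma, pad = "reflect") {
  gx <- gauss_op(nrow(mat), sigma, pad)
  gy <- gauss_op(ncol(mat), sigma, pad)
  gx %*% mat %*% t(gy)
}

## Bilinear / nearest sampling of `mat` at continuous 1-based pixel
## coordinates (xi, yi).  pad = "replicate" clamps, "reflect" mirrors.
interp2 <- function(mat, xi, yi, mode = c("linear", "nearest"),
                    pad = c("replicate", "reflect")) {
  mode <- match.arg(mode)
  pad <- match.arg(pad)
  nx <- nrow(mat); ny <- ncol(mat)
  fold <- function(v, n) {
    if (pad == "reflect") {
      ## mirror about pixel centres 1 and n
      v <- abs(v - 1) %% (2 * (n - 1))
      v <- ifelse(v > (n - 1), 2 * (n - 1) - v, v) + 1
    }
    pmin(pmax(v, 1), n)
  }
  if (mode == "nearest") {
    ## ties at exact midpoints go to the larger index (half-up), so the
    ## rule is shift-invariant: floor(v + k + 0.5) = floor(v + 0.5) + k
    i <- fold(floor(xi + 0.5), nx); j <- fold(floor(yi + 0.5), ny)
    return(mat[cbind(i, j)])
  }
  x <- fold(xi, nx); y <- fold(yi, ny)
  i0 <- pmin(floor(x), nx - 1); j0 <- pmin(floor(y), ny - 1)
  fx <- x - i0; fy <- y - j0
  v00 <- mat[cbind(i0, j0)];     v10 <- mat[cbind(i0 + 1, j0)]
  v01 <- mat[cbind(i0, j0 + 1)]; v11 <- mat[cbind(i0 + 1, j0 + 1)]
  (1 - fx) * (1 - fy) * v00 + fx * (1 - fy) * v10 +
    (1 - fx) * fy * v01 + fx * fy * v11
}

## Patch mean and sd maps (replicate-clamped square window), matching the
## clamped patch reads of the compiled PatchMatch kernel.
patch_stats <- function(mat, half) {
  nx <- nrow(mat); ny <- ncol(mat)
  idx <- function(n) {
    out <- matrix(0L, n, 2L * half + 1L)
    for (o in -half:half) out[, o + half + 1L] <- pmin(pmax(seq_len(n) + o, 1L), n)
    out
  }
  ix <- idx(nx); iy <- idx(ny)
  np <- (2L * half + 1L)^2
  s <- matrix(0, nx, ny); s2 <- matrix(0, nx, ny)
  for (a in seq_len(2L * half + 1L)) {
    rows <- mat[ix[, a], , drop = FALSE]
    for (b in seq_len(2L * half + 1L)) {
      v <- rows[, iy[, b], drop = FALSE]
      s <- s + v; s2 <- s2 + v * v
    }
  }
  mu <- s / np
  va <- pmax(s2 / np - mu * mu, 0)
  list(mean = mu, sd = sqrt(va))
}
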