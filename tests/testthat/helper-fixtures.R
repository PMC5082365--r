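## Shared fixtures and independent oracles used across the suite.

## A phantom spec with every source of inter-subject variation switched off:
## all subjects are then pixel-identical.
zero_variation_spec <- function(n_subjects = 3, seed = 1, ...) {
  phantom_spec(n_subjects = n_subjects, seed = seed,
               cord_area_sd = 0, gm_area_sd = 0, slice_area_sd = 0,
               noise_sd = 0, jitter_translation_mm = 0,
               jitter_rotation_deg = 0, jitter_scale = 0,
               lesion_prob = 0, ...)
}

## one mid slice (plus cord/gm masks) of a generated subject
subject_slice <- function(sub, k = 2) {
  sl <- slice2d(sub$volume$data[, , k], sub$volume$spacing[1:2],
                origin = sub$volume$affine[1:2, 4],
                parent_id = sub$volume$id, slice_index = k)
  cord <- label_map(sub$cord$data[, , k], sl$spacing, "cord", origin = sl$origin)
  gm <- label_map(sub$gm$data[, , k], sl$spacing, "gm", origin = sl$origin)
  list(slice = sl, cord = cord, gm = gm)
}

random_mask <- function(nx, ny, p = 0.4) {
  label_map(matrix(rbinom(nx * ny, 1, p), nx, ny), c(0.5, 0.5))
}

## ---- independent oracles -------------------------------------------------

## Dice by explicit pixel loop
oracle_dsc <- function(A, B) {
  a <- as.vector(A$data); b <- as.vector(B$data)
  inter <- 0; sa <- 0; sb <- 0
  for (i in seq_along(a)) {
    if (a[i] >= 0.5 && b[i] >= 0.5) inter <- inter + 1
    if (a[i] >= 0.5) sa <- sa + 1
    if (b[i] >= 0.5) sb <- sb + 1
  }
  if (sa + sb == 0) return(1)
  2 * inter / (sa + sb)
}

## boundary extraction + all-pairs distances by explicit loops
oracle_surface <- function(A, B) {
  bound <- function(m) {
    out <- NULL
    nx <- nrow(m); ny <- ncol(m)
    for (i in seq_len(nx)) for (j in seq_len(ny)) {
      if (m[i, j] >= 0.5) {
        nb <- c(if (i > 1) m[i - 1, j] else 0, if (i < nx) m[i + 1, j] else 0,
                if (j > 1) m[i, j - 1] else 0, if (j < ny) m[i, j + 1] else 0)
        if (any(nb < 0.5)) out <- rbind(out, c(i, j))
      }
    }
    out
  }
  dir_d <- function(P, Q, sp) {
    d <- numeric(nrow(P))
    for (r in seq_len(nrow(P))) {
      best <- Inf
      for (s in seq_len(nrow(Q))) {
        dd <- sqrt(((P[r, 1] - Q[s, 1]) * sp[1])^2 +
                     ((P[r, 2] - Q[s, 2]) * sp[2])^2)
        if (dd < best) best <- dd
      }
      d[r] <- best
    }
    d
  }
  sp <- A$spacing[1:2]
  PA <- bound(A$data); PB <- bound(B$data)
  dab <- dir_d(PA, PB, sp); dba <- dir_d(PB, PA, sp)
  c(msd = (mean(dab) + mean(dba)) / 2, hd = max(max(dab), max(dba)))
}

## per-pixel majority vote by counting
oracle_consensus <- function(masks) {
  d <- masks[[1]]$data
  out <- d * 0L
  for (i in seq_along(d)) {
    v <- sum(vapply(masks, function(m) m$data[i] >= 0.5, logical(1)))
    out[i] <- as.integer(v >= 2)
  }
  out
}

## brute-force STAPLE (beta = 0, all templates selected everywhere),
## coded with explicit per-voxel/per-rater loops; M-step first, starting
## from the mean-label consensus, iterated a fixed number of times
oracle_staple <- function(D, n_iter, p_init = 0.95, q_init = 0.95) {
  n <- nrow(D); J <- ncol(D)
  W <- rowMeans(D)
  clamp <- function(x) min(max(x, 1e-4), 1 - 1e-4)
  p <- rep(NA_real_, J); q <- rep(NA_real_, J)
  for (it in seq_len(n_iter)) {
    for (j in seq_len(J)) {
      num_p <- 0; den_p <- 0; num_q <- 0; den_q <- 0
      for (i in seq_len(n)) {
        num_p <- num_p + W[i] * D[i, j]
        den_p <- den_p + W[i]
        num_q <- num_q + (1 - W[i]) * (1 - D[i, j])
        den_q <- den_q + (1 - W[i])
      }
      p[j] <- clamp(if (den_p > 1e-12) num_p / den_p else p_init)
      q[j] <- clamp(if (den_q > 1e-12) num_q / den_q else q_init)
    }
    for (i in seq_len(n)) {
      a <- 0.5; b <- 0.5
      for (j in seq_len(J)) {
        if (D[i, j] == 1) { a <- a * p[j]; b <- b * (1 - q[j]) }
        else { a <- a * (1 - p[j]); b <- b * q[j] }
      }
      W[i] <- a / (a + b)
    }
  }
  list(W = W, p = p, q = q)
}

## exhaustive k-nearest patch search over a library (z-normalised SSD with
## replicate-clamped reads, like the compiled kernel)
oracle_patch_search <- function(target, tmpls, half, k) {
  clampi <- function(v, n) pmin(pmax(v, 1), n)
  zpatch <- function(M, i, j) {
    nx <- nrow(M); ny <- ncol(M)
    v <- as.vector(M[clampi(i + (-half:half), nx), clampi(j + (-half:half), ny)])
    s <- sd(v) * sqrt((length(v) - 1) / length(v))
    if (s > 1e-12) (v - mean(v)) / s else v * 0
  }
  nx <- nrow(target); ny <- ncol(target)
  best <- matrix(Inf, nx * ny, k)
  for (i in seq_len(nx)) for (j in seq_len(ny)) {
    tp <- zpatch(target, i, j)
    ds <- c()
    for (m in seq_along(tmpls)) {
      M <- tmpls[[m]]
      for (ii in seq_len(nrow(M))) for (jj in seq_len(ncol(M)))
        ds <- c(ds, sum((tp - zpatch(M, ii, jj))^2))
    }
    best[i + (j - 1) * nx, ] <- sort(ds)[seq_len(k)]
  }
  best
}
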