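#' Label-fusion configuration
#'
#' Defaults follow the published STEPS settings: the X = 15 locally best
#' templates (by LNCC with a sigma = 1.5 pixel kernel) participate at each
#' voxel, the Markov-random-field spatial consistency weight is 0.55, and the
#' consensus probability is thresholded at 0.5.  `global_cut` additionally
#' restricts fusion to the globally most similar deformed templates by NCC.
#'
#' @param X per-voxel number of best templates (default 15).
#' @param sigma_lncc Gaussian kernel for the LNCC ranking, pixels (default 1.5).
#' @param mrf_beta MRF spatial-consistency weight (default 0.55; 0 disables).
#' @param threshold binarisation threshold on the consensus (default 0.5).
#' @param em_max_iter,em_tol EM iteration cap and relative-change tolerance on
#'   the mean consensus probability.
#' @param p_init,q_init initial per-template sensitivity/specificity.
#' @param global_cut number of globally best deformed templates kept before
#'   per-voxel selection (default 25).
#' @return An object of class `fusion_config`.
#' @export
fusion_config <- function(X = 15L, sigma_lncc = 1.5, mrf_beta = 0.55,
                          threshold = 0.5, em_max_iter = 100L, em_tol = 1e-4,
                          p_init = 0.95, q_init = 0.95, global_cut = 25L) {
  if (X < 1) stop("fusion_config: X must be >= 1")
  if (sigma_lncc <= 0) stop("fusion_config: sigma_lncc must be positive")
  if (mrf_beta < 0) stop("fusion_config: mrf_beta must be >= 0")
  if (threshold <= 0 || threshold >= 1)
    stop("fusion_config: threshold must be in (0, 1)")
  structure(list(X = as.integer(X), sigma_lncc = sigma_lncc,
                 mrf_beta = mrf_beta, threshold = threshold,
                 em_max_iter = as.integer(em_max_iter), em_tol = em_tol,
                 p_init = p_init, q_init = q_init,
                 global_cut = as.integer(global_cut)),
            class = "fusion_config")
}

#' Rank deformed templates by global masked NCC
#'
#' @param target a [slice2d()].
#' @param warped list of [slice2d()]s on the target grid.
#' @param roi binary [label_map()] restricting the correlation.
#' @return Integer index vector, most similar first; templates with undefined
#'   NCC (constant inside the mask) rank last.  Ties break by index.
#' @export
rank_templates_global <- function(target, warped, roi = NULL) {
  if (!length(warped)) stop("rank_templates_global: empty template list")
  scores <- vapply(warped, function(w) {
    tryCatch(ncc(target, w, roi), error = function(e) -Inf)
  }, numeric(1))
  order(-scores, seq_along(scores))
}

#' Per-voxel selection of the X locally most similar templates
#'
#' @param lncc_maps list of per-template LNCC matrices on a shared grid.
#' @param X number of templates participating at each voxel.
#' @return Logical matrix (n voxels x n templates); exactly
#'   `min(X, n_templates)` `TRUE` per row, ties broken by template index.
#' @export
select_local <- function(lncc_maps, X) {
  if (X <= 0) stop("select_local: X must be positive")
  J <- length(lncc_maps)
  npix <- length(lncc_maps[[1]])
  M <- vapply(lncc_maps, as.vector, numeric(npix))
  if (J <= X) return(matrix(TRUE, npix, J))
  r <- t(apply(-M, 1, rank, ties.method = "first"))
  r <= X
}

#' Mean-field Markov-random-field prior on the consensus
#'
#' Potts prior on the 4-neighbourhood:
#' `f(1) ~ exp(beta * sum W_n)`, `f(0) ~ exp(beta * sum (1 - W_n))`,
#' normalised to sum to one per voxel.  `beta = 0` gives the uniform prior.
#'
#' @param W consensus probability matrix in \[0, 1\].
#' @param beta non-negative spatial-consistency weight.
#' @return `list(f1, f0)` of per-voxel prior matrices.
#' @export
mrf_prior <- function(W, beta) {
  if (beta < 0) stop("mrf_prior: beta must be >= 0")
  nx <- nrow(W); ny <- ncol(W)
  S1 <- matrix(0, nx, ny); S0 <- matrix(0, nx, ny)
  shifts <- list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  for (sh in shifts) {
    Wn <- matrix(0, nx, ny); Cn <- matrix(0, nx, ny)
    xi <- seq_len(nx) + sh[1]; yi <- seq_len(ny) + sh[2]
    okx <- xi >= 1 & xi <= nx; oky <- yi >= 1 & yi <= ny
    Wn[okx, oky] <- W[xi[okx], yi[oky]]
    Cn[okx, oky] <- 1
    S1 <- S1 + Wn
    S0 <- S0 + Cn - Wn
  }
  e1 <- exp(beta * S1); e0 <- exp(beta * S0)
  z <- e1 + e0
  list(f1 = e1 / z, f0 = e0 / z)
}

#' STAPLE expectation-maximisation with per-voxel template selection
#'
#' Jointly estimates the consensus probability `W` and each template's
#' sensitivity `p` and specificity `q` from binarised candidate labels,
#' restricted at every voxel to the locally selected templates, with a
#' mean-field MRF prior refreshed at each E-step.
#'
#' @param labels list of candidate [label_map()]s (soft values are binarised
#'   at 0.5 for the Bernoulli model).
#' @param selection logical matrix (n voxels x n templates) from
#'   [select_local()].
#' @param cfg a [fusion_config()].
#' @param roi binary [label_map()]; voxels outside get `W = 0`.
#' @return A `fusion_state`: consensus `W` (matrix), `p`, `q`, iteration
#'   count and the observed-data log-likelihood trace.
#' @export
staple_em <- function(labels, selection, cfg = fusion_config(), roi = NULL) {
  J <- length(labels)
  dims <- dim(labels[[1]]$data)
  npix <- prod(dims)
  D <- vapply(labels, function(l) as.numeric(as.vector(l$data) >= 0.5),
              numeric(npix))
  S <- selection
  if (is.null(S)) S <- matrix(TRUE, npix, J)
  storage.mode(S) <- "double"
  rvec <- if (is.null(roi)) rep(TRUE, npix) else as.vector(roi$data) >= 0.5
  if (any(rvec & rowSums(S) == 0))
    stop("staple_em: a voxel inside the ROI has no selected template")
  sel_d <- S * D
  sel_nd <- S * (1 - D)
  ## consensus initialisation: mean of the selected labels
  W <- rep(0, npix)
  W[rvec] <- (rowSums(sel_d) / pmax(rowSums(S), 1))[rvec]
  clamp <- function(x) pmin(pmax(x, 1e-4), 1 - 1e-4)
  loglik <- numeric(0)
  n_iter <- 0L
  for (it in seq_len(cfg$em_max_iter)) {
    n_iter <- it
    ## M-step: performance parameters from the current consensus
    den_p <- colSums(S * W * rvec); den_q <- colSums(S * (1 - W) * rvec)
    p <- ifelse(den_p > 1e-12, colSums(sel_d * W * rvec) / pmax(den_p, 1e-12),
                cfg$p_init)
    q <- ifelse(den_q > 1e-12,
                colSums(sel_nd * (1 - W) * rvec) / pmax(den_q, 1e-12),
                cfg$q_init)
    p <- clamp(p); q <- clamp(q)
    ## E-step: consensus from performance parameters and the MRF prior
    Wm <- matrix(W, dims[1], dims[2])
    f <- mrf_prior(Wm, cfg$mrf_beta)
    log_a <- log(as.vector(f$f1)) + sel_d %*% log(p) + sel_nd %*% log(1 - p)
    log_b <- log(as.vector(f$f0)) + sel_d %*% log(1 - q) + sel_nd %*% log(q)
    m <- pmax(log_a, log_b)
    loglik <- c(loglik, sum((m + log(exp(log_a - m) + exp(log_b - m)))[rvec]))
    W_new <- rep(0, npix)
    W_new[rvec] <- (1 / (1 + exp(log_b - log_a)))[rvec]
    delta <- mean(abs(W_new - W)) / max(mean(W), 1e-12)
    W <- W_new
    if (delta < cfg$em_tol) break
  }
  structure(list(W = matrix(W, dims[1], dims[2]), p = p, q = q,
                 selection = selection, n_iter = n_iter,
                 loglik_trace = loglik),
            class = "fusion_state")
}

#' @export
print.fusion_state <- function(x, ...) {
  cat(sprintf("<fusion_state> %d templates, %d EM iterations, mean W %.3f\n",
              length(x$p), x$n_iter, mean(x$W)))
  invisible(x)
}

#' Fuse one structure from registered templates
#'
#' Full STEPS chain: global NCC ranking and cut, per-template LNCC maps,
#' per-voxel selection of the X locally best templates, then STAPLE EM with
#' the MRF prior.  The consensus is zero outside the region of interest.
#'
#' @param target a [slice2d()].
#' @param warped_images list of registered template [slice2d()]s.
#' @param warped_labels list of corresponding warped [label_map()]s.
#' @param roi binary [label_map()].
#' @param cfg a [fusion_config()].
#' @param structure "cord" or "gm" (tag for the output).
#' @return A probabilistic [label_map()] with the `fusion_state` attached as
#'   attribute `"state"`.
#' @export
fuse_structure <- function(target, warped_images, warped_labels, roi,
                           cfg = fusion_config(), structure = c("cord", "gm")) {
  structure_tag <- match.arg(structure)
  if (!any(roi$data >= 0.5)) stop("fuse_structure: empty region of interest")
  if (!length(warped_images)) stop("fuse_structure: no templates")
  ord <- rank_templates_global(target, warped_images, roi)
  keep <- head(ord, cfg$global_cut)
  imgs <- warped_images[keep]
  labs <- warped_labels[keep]
  maps <- lapply(imgs, function(w) lncc(target, w, cfg$sigma_lncc))
  sel <- select_local(maps, cfg$X)
  st <- staple_em(labs, sel, cfg, roi)
  W <- st$W
  W[roi$data < 0.5] <- 0
  out <- label_map(pmin(pmax(W, 0), 1), target$spacing, structure_tag,
                   binary = FALSE, origin = target$origin)
  attr(out, "state") <- st
  attr(out, "ranking") <- ord
  out
}

#' Threshold a consensus probability map
#'
#' A voxel is foreground iff `W >= threshold`.  When a cord mask is supplied
#' the result is intersected with it, enforcing grey-matter nesting.
#'
#' @param W probabilistic [label_map()].
#' @param threshold threshold in (0, 1) (default 0.5).
#' @param enforce_nesting optional binary cord [label_map()].
#' @return A binary [label_map()].
#' @export
binarise <- function(W, threshold = 0.5, enforce_nesting = NULL) {
  out <- (W$data >= threshold) * 1L
  if (!is.null(enforce_nesting)) out <- out * (enforce_nesting$data >= 0.5)
  label_map(out * 1L, W$spacing, W$structure, binary = TRUE, origin = W$origin)
}
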