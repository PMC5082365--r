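soft_map <- function(m, spacing = c(0.5, 0.5))
  label_map(m, spacing, "cord", binary = FALSE)

test_that("global template ranking matches direct Pearson computation", {
  set.seed(21)
  t <- slice2d(matrix(runif(16), 4, 4), c(0.5, 0.5))
  w1 <- slice2d(t$data + 0.05 * matrix(rnorm(16), 4, 4), c(0.5, 0.5))
  w2 <- slice2d(matrix(runif(16), 4, 4), c(0.5, 0.5))
  w3 <- slice2d(t$data, c(0.5, 0.5))
  ord <- rank_templates_global(t, list(w1, w2, w3))
  scores <- c(cor(as.vector(t$data), as.vector(w1$data)),
              cor(as.vector(t$data), as.vector(w2$data)), 1)
  expect_equal(ord, order(-scores))
  expect_equal(ord[1], 3L)  # exact copy first, NCC 1
  ## constant template has undefined NCC and ranks last
  wc <- slice2d(matrix(2, 4, 4), c(0.5, 0.5))
  expect_equal(rank_templates_global(t, list(w1, wc))[2], 2L)
  expect_error(rank_templates_global(t, list()), "empty")
})

test_that("per-voxel selection keeps the X locally best templates", {
  maps <- list(matrix(1, 2, 2), matrix(0, 2, 2))
  sel <- select_local(maps, 5)
  expect_true(all(sel))  # n_templates <= X: all selected
  sel1 <- select_local(maps, 1)
  expect_true(all(sel1[, 1]) && !any(sel1[, 2]))
  ## hand-built 2x2 maps, X = 2 of 3: brute-force per-pixel top-2
  m1 <- matrix(c(.9, .1, .5, .3), 2, 2)
  m2 <- matrix(c(.8, .2, .6, .3), 2, 2)
  m3 <- matrix(c(.7, .3, .4, .3), 2, 2)
  sel2 <- select_local(list(m1, m2, m3), 2)
  for (i in 1:4) {
    v <- c(m1[i], m2[i], m3[i])
    expect_equal(which(sel2[i, ]),
                 sort(order(-v, seq_along(v))[1:2]))
  }
  expect_equal(rowSums(sel2), rep(2, 4))
  expect_error(select_local(maps, 0), "positive")
})

test_that("the MRF prior reproduces its closed form", {
  f0 <- mrf_prior(matrix(runif(9), 3, 3), 0)
  expect_true(all(f0$f1 == 0.5) && all(f0$f0 == 0.5))
  ## all-ones neighbourhood at beta = 0.55: f(1) = e^2.2 / (e^2.2 + 1)
  f <- mrf_prior(matrix(1, 3, 3), 0.55)
  expect_equal(f$f1[2, 2], exp(2.2) / (exp(2.2) + 1), tolerance = 1e-12)
  ## half-certain neighbours are uninformative
  fh <- mrf_prior(matrix(0.5, 3, 3), 0.55)
  expect_true(all(abs(fh$f1 - 0.5) < 1e-12))
  expect_error(mrf_prior(matrix(0.5, 3, 3), -1), "beta")
})

test_that("STAPLE fixed points: agreement, single rater, majority", {
  m <- soft_map(matrix(c(0, 1, 1, 0, 1, 1, 0, 0, 0), 3, 3))
  st <- staple_em(list(m, m, m), NULL, fusion_config(mrf_beta = 0))
  expect_lt(max(abs(st$W - m$data)), 1e-6)
  expect_true(all(st$p >= 1 - 1e-4 - 1e-12))
  ## a single rater reproduces its own labels (up to the p/q clamp)
  st1 <- staple_em(list(m), NULL, fusion_config(mrf_beta = 0))
  expect_lt(max(abs(st1$W - m$data)), 1e-3)
  ## strip with votes (1,1,0) on foreground voxels (plus one background
  ## voxel so rater performance is identifiable): the majority wins
  strip <- matrix(c(1, 1, 1, 1, 0), 1, 5)
  votes <- list(soft_map(strip), soft_map(strip),
                soft_map(matrix(0, 1, 5)))
  stv <- staple_em(votes, NULL, fusion_config(mrf_beta = 0))
  expect_true(all(stv$W[, 1:4] > 0.5))
})

test_that("STAPLE EM matches an independently coded brute force on tiny instances", {
  set.seed(31)
  for (trial in 1:5) {
    n <- sample(4:10, 1); J <- sample(2:4, 1)
    D <- matrix(rbinom(n * J, 1, 0.5), n, J)
    labs <- lapply(seq_len(J), function(j) soft_map(matrix(D[, j], n, 1)))
    cfg <- fusion_config(mrf_beta = 0, em_max_iter = 15, em_tol = 0)
    st <- staple_em(labs, NULL, cfg)
    bf <- oracle_staple(D, 15)
    expect_lt(max(abs(as.vector(st$W) - bf$W)), 1e-8)
    expect_lt(max(abs(st$p - bf$p)), 1e-8)
    expect_lt(max(abs(st$q - bf$q)), 1e-8)
  }
})

test_that("the EM log-likelihood is non-decreasing (flat prior)", {
  set.seed(33)
  D <- matrix(rbinom(8 * 3, 1, 0.5), 8, 3)
  labs <- lapply(1:3, function(j) soft_map(matrix(D[, j], 8, 1)))
  st <- staple_em(labs, NULL, fusion_config(mrf_beta = 0, em_max_iter = 25,
                                            em_tol = 0))
  expect_true(all(diff(st$loglik_trace) > -1e-9))
  expect_true(all(st$W >= 0 & st$W <= 1))
})

test_that("fusion is invariant to template order and rewards exact copies", {
  spec <- phantom_spec(n_subjects = 4, seed = 23, noise_sd = 0.02)
  target <- subject_slice(generate_subject(spec, 1))
  roi <- dilate_mask(target$cord, 8)
  others <- lapply(2:4, function(i) subject_slice(generate_subject(spec, i)))
  imgs <- c(list(target$slice), lapply(others, `[[`, "slice"))
  labs <- c(list(soft_map(target$cord$data + 0)),
            lapply(others, function(o) soft_map(o$cord$data + 0)))
  cfg <- fusion_config(global_cut = 4, X = 4)
  f1 <- fuse_structure(target$slice, imgs, labs, roi, cfg, "cord")
  perm <- c(3, 1, 4, 2)
  f2 <- fuse_structure(target$slice, imgs[perm], labs[perm], roi, cfg, "cord")
  expect_lt(max(abs(f1$data - f2$data)), 1e-9)
  ## adding an exact copy of the truth never decreases thresholded DSC
  d_before <- dsc(binarise(f2), target$cord)
  f3 <- fuse_structure(target$slice, c(imgs, list(target$slice)),
                       c(labs, list(soft_map(target$cord$data + 0))), roi,
                       fusion_config(global_cut = 5, X = 5), "cord")
  expect_gte(dsc(binarise(f3), target$cord), d_before)
  expect_error(fuse_structure(target$slice, imgs, labs,
                              label_map(matrix(0L, 48, 48), c(0.5, 0.5)),
                              cfg, "cord"), "empty")
})

test_that("identical templates fix the consensus to the ground truth", {
  spec <- zero_variation_spec(3, seed = 2)
  target <- subject_slice(generate_subject(spec, 1))
  roi <- dilate_mask(target$cord, 8)
  imgs <- rep(list(target$slice), 3)
  labs <- rep(list(soft_map(target$cord$data + 0)), 3)
  f <- fuse_structure(target$slice, imgs, labs, roi, fusion_config(), "cord")
  expect_identical(binarise(f)$data, target$cord$data)
})

test_that("binarise applies the >= convention and grey-matter nesting", {
  W <- soft_map(matrix(0.5, 3, 3))
  expect_true(all(binarise(W)$data == 1L))
  W49 <- soft_map(matrix(0.49, 3, 3))
  expect_true(all(binarise(W49)$data == 0L))
  gmW <- label_map(matrix(c(0.9, 0.9, 0, 0, 0, 0, 0, 0, 0), 3, 3),
                   c(0.5, 0.5), "gm", binary = FALSE)
  cord <- label_map(matrix(c(1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L), 3, 3),
                    c(0.5, 0.5))
  nested <- binarise(gmW, 0.5, enforce_nesting = cord)
  expect_equal(sum(nested$data), 1L)
  expect_equal(nested$data[1, 1], 1L)
  expect_equal(nested$data[2, 1], 0L)  # 0.9 outside the cord is removed
})
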