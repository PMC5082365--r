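phantom_slice_fixture <- function(seed = 3, noise_sd = 0.02) {
  spec <- phantom_spec(n_subjects = 2, seed = seed, noise_sd = noise_sd)
  sub <- generate_subject(spec, 1)
  sl <- subject_slice(sub)
  roi <- dilate_mask(sl$cord, 8)
  list(slice = sl$slice, cord = sl$cord, roi = roi,
       grid = grid_info(sl$slice))
}

test_that("global NCC behaves like a Pearson correlation", {
  a <- slice2d(matrix(runif(64), 8, 8), c(0.5, 0.5))
  expect_equal(ncc(a, a), 1)
  neg <- a; neg$data <- -a$data
  expect_equal(ncc(a, neg), -1)
  shifted <- a; shifted$data <- a$data + 10
  expect_equal(ncc(a, shifted), 1)
  const <- a; const$data <- a$data * 0 + 2
  expect_error(ncc(a, const), "zero variance")
  small_mask <- label_map(matrix(c(1L, rep(0L, 63)), 8, 8), c(0.5, 0.5))
  expect_error(ncc(a, a, small_mask), "fewer than 2")
})

test_that("LNCC is 1 on identical images, 0 on constants, and tends to NCC", {
  set.seed(5)
  a <- slice2d(cordfuse:::gauss_filter(matrix(runif(32 * 32), 32, 32), 1), c(0.5, 0.5))
  m <- lncc(a, a, 1.5)
  expect_true(all(abs(m[m != 0] - 1) < 1e-9))
  expect_true(all(lncc(a, slice2d(matrix(7, 32, 32), c(0.5, 0.5)), 1.5) == 0))
  expect_error(lncc(a, a, 0), "sigma")
  ## large-sigma limit approaches the global correlation (quadratically in
  ## width/sigma: ~1e-2 at 10x the image width, well under 1e-3 at 100x)
  b <- a; b$data <- a$data^1.5 + 0.1 * matrix(runif(32 * 32), 32, 32)
  g <- ncc(a, b)
  expect_lt(max(abs(lncc(a, b, 10 * 32) - g)), 1e-2)
  expect_lt(max(abs(lncc(a, b, 100 * 32) - g)), 1e-3)
})

test_that("affine registration recovers known transforms", {
  fx <- phantom_slice_fixture()
  id <- affine2d(diag(2), c(0, 0), fx$grid, fx$grid)
  ## self-registration stays at the identity
  est0 <- affine_register(fx$slice, fx$slice, id, fx$roi)
  expect_lt(max(abs(est0$linear - diag(2))), 1e-3)
  expect_lt(max(abs(est0$translation)) / 0.5, 0.1)
  ## pure translation of 2.5 / -1.5 px recovered within a quarter pixel
  tx <- affine2d(diag(2), c(2.5, -1.5) * 0.5, fx$grid, fx$grid)
  tmpl <- warp(fx$slice, tx, "linear")
  est <- affine_register(fx$slice, tmpl, id, fx$roi)
  expect_lt(max(abs(est$translation - (-c(2.5, -1.5) * 0.5))) / 0.5, 0.25)
  ## constant template has no structure to match
  const <- slice2d(matrix(1, 48, 48), c(0.5, 0.5),
                   origin = fx$slice$origin)
  expect_error(affine_register(fx$slice, const, id, fx$roi),
               "insufficient structure")
})

test_that("affine registration is inverse-consistent on phantoms", {
  ## an exactly affinely-related pair: registering A -> B and B -> A must
  ## compose to the identity within half a pixel over the ROI
  spec <- phantom_spec(n_subjects = 2, seed = 17, noise_sd = 0.02)
  a <- subject_slice(generate_subject(spec, 1))
  roi_a <- dilate_mask(a$cord, 8)
  g <- grid_info(a$slice)
  th <- 4 * pi / 180
  L <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2) %*% diag(c(1.04, 0.97))
  tx <- affine2d(L, c(0.8, -0.6), g, g)
  b_img <- warp(a$slice, tx, "linear")
  roi_b <- warp(roi_a, tx, "nearest")
  id <- affine2d(diag(2), c(0, 0), g, g)
  ab <- affine_register(a$slice, b_img, id, roi_a)
  ba <- affine_register(b_img, a$slice, id, roi_b)
  comp <- cordfuse:::affine_matrix(ba) %*% cordfuse:::affine_matrix(ab)
  idx <- which(roi_a$data >= 0.5, arr.ind = TRUE)
  W <- cbind(a$slice$origin[1] + (idx[, 1] - 1) * 0.5,
             a$slice$origin[2] + (idx[, 2] - 1) * 0.5, 1)
  mapped <- W %*% t(comp)
  disp_px <- sqrt(rowSums((mapped[, 1:2] - W[, 1:2])^2)) / 0.5
  expect_lt(max(disp_px), 0.5)
})

test_that("warp respects transform modes and convexity", {
  fx <- phantom_slice_fixture()
  id <- affine2d(diag(2), c(0, 0), fx$grid, fx$grid)
  expect_equal(warp(fx$slice, id, "linear")$data, fx$slice$data)
  soft <- warp(fx$cord, id, "linear")
  expect_false(soft$binary)
  expect_true(all(soft$data >= 0 & soft$data <= 1))
  ## translation by exactly one pixel in nearest mode is a shifted copy
  one_px <- affine2d(diag(2), c(0.5, 0), fx$grid, fx$grid)
  sh <- warp(fx$cord, one_px, "nearest")
  expect_identical(sh$data[1:47, ], fx$cord$data[2:48, ])
})

test_that("FFD leaves an aligned pair untouched and never degrades masked LNCC", {
  fx <- phantom_slice_fixture()
  id <- affine2d(diag(2), c(0, 0), fx$grid, fx$grid)
  ## zero iterations: field is exactly the affine initialisation
  f0 <- ffd_register(fx$slice, fx$slice, id, fx$roi,
                     registration_config(max_iter = 0))
  expect_true(all(f0$disp_x == 0) && all(f0$disp_y == 0))
  ## already-aligned template: near-zero residual displacement
  fa <- ffd_register(fx$slice, fx$slice, id, fx$roi)
  inroi <- fx$roi$data >= 0.5
  expect_lt(mean(sqrt(fa$disp_x^2 + fa$disp_y^2)[inroi]) / 0.5, 0.3)
})

test_that("FFD recovers a smooth synthetic deformation", {
  fx <- phantom_slice_fixture()
  id <- affine2d(diag(2), c(0, 0), fx$grid, fx$grid)
  W <- cordfuse:::grid_world(fx$grid)
  ux <- 0.8 * exp(-((W$X - 1)^2 + (W$Y - 2)^2) / 18)
  uy <- -0.6 * exp(-((W$X + 2)^2 + (W$Y + 1)^2) / 18)
  tmpl <- warp(fx$slice, deformation_field2d(ux, uy, id), "linear")
  ffd <- ffd_register(fx$slice, tmpl, id, fx$roi)
  inroi <- fx$roi$data >= 0.5
  ## the recovered field inverts the applied one
  epe_px <- sqrt((ffd$disp_x + ux)^2 + (ffd$disp_y + uy)^2)[inroi] / 0.5
  expect_lt(mean(epe_px), 0.5)
  ## masked mean LNCC does not fall below the affine-only start
  l0 <- mean(lncc(fx$slice, warp(tmpl, id, "linear"), 1)[inroi])
  l1 <- mean(lncc(fx$slice, warp(tmpl, ffd, "linear"), 1)[inroi])
  expect_gte(l1, l0)
})
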