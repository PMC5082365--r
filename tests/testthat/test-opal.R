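make_library <- function(slices, cords, gms = NULL, spacing = c(0.5, 0.5)) {
  entries <- lapply(seq_along(slices), function(m) {
    s <- slice2d(slices[[m]], spacing, parent_id = paste0("t", m),
                 slice_index = 1L)
    cm <- label_map(cords[[m]], spacing, "cord")
    gmm <- label_map(if (is.null(gms)) cords[[m]] * 0L else gms[[m]],
                     spacing, "gm")
    list(slice = s, cord = cm, gm = gmm, subject_id = paste0("t", m),
         flipped = FALSE)
  })
  cordfuse:::template_library(entries, spacing)
}

test_that("a target present in the library reaches zero distance everywhere", {
  set.seed(42)
  base <- cordfuse:::gauss_filter(matrix(runif(16 * 16), 16, 16), 1)
  lib <- make_library(list(base, base + 2, t(base) * 1.5),
                      list((base > median(base)) * 1L,
                           (base > median(base)) * 1L,
                           (t(base) > median(base)) * 1L))
  target <- slice2d(base, c(0.5, 0.5))
  f <- patchmatch(target, lib, patchmatch_config(seed = 7))
  expect_equal(max(f$d[1, ]), 0)
  ## constant target vs constant templates: all distances zero
  libc <- make_library(list(matrix(1, 8, 8), matrix(2, 8, 8)),
                       list(matrix(1L, 8, 8), matrix(0L, 8, 8)))
  fc <- patchmatch(slice2d(matrix(5, 8, 8), c(0.5, 0.5)), libc,
                   patchmatch_config(seed = 1))
  expect_true(all(fc$d == 0))
})

test_that("per-pixel best distance never increases across iterations", {
  set.seed(3)
  lib <- make_library(list(matrix(runif(144), 12, 12),
                           matrix(runif(144), 12, 12)),
                      list(matrix(rbinom(144, 1, .3), 12, 12),
                           matrix(rbinom(144, 1, .3), 12, 12)))
  target <- slice2d(matrix(runif(144), 12, 12), c(0.5, 0.5))
  f <- patchmatch(target, lib, patchmatch_config(seed = 11))
  diffs <- t(apply(f$trace, 1, diff))
  expect_true(all(diffs <= 1e-12))
  ## records are sorted ascending and finite
  expect_true(all(apply(f$d, 2, function(col) all(diff(col) >= 0))))
  expect_true(all(is.finite(f$d)))
})

test_that("patchmatch is deterministic given the seed and errors sensibly", {
  set.seed(3)
  lib <- make_library(list(matrix(runif(100), 10, 10)),
                      list(matrix(rbinom(100, 1, .3), 10, 10)))
  target <- slice2d(matrix(runif(100), 10, 10), c(0.5, 0.5))
  f1 <- patchmatch(target, lib, patchmatch_config(seed = 5))
  f2 <- patchmatch(target, lib, patchmatch_config(seed = 5))
  expect_identical(f1$d, f2$d)
  expect_identical(f1$t, f2$t)
  tiny <- slice2d(matrix(1:9 + 0, 3, 3), c(0.5, 0.5))
  expect_error(patchmatch(tiny, lib, patchmatch_config()), "patch larger")
  bad <- slice2d(matrix(runif(100), 10, 10), c(1, 1))
  expect_error(patchmatch(bad, lib), "spacing")
})

test_that("fused match labels are the similarity-weighted centre labels", {
  ## two templates, one all-ones labels, one all-zeros, identical images:
  ## every match has the same distance, so the fused value is exactly 0.5
  img <- cordfuse:::gauss_filter(matrix(runif(100), 10, 10), 1)
  lib <- make_library(list(img, img),
                      list(matrix(1L, 10, 10), matrix(0L, 10, 10)))
  target <- slice2d(img, c(0.5, 0.5))
  f <- patchmatch(target, lib, patchmatch_config(seed = 2, k_best = 2))
  pr <- fuse_matches(f, lib, "cord")
  ## exact matches exist in both templates -> all-ones yields 1, all-zeros 0
  expect_true(all(pr$data >= 0 & pr$data <= 1))
  one <- fuse_matches(f, make_library(list(img, img),
                                      list(matrix(1L, 10, 10),
                                           matrix(1L, 10, 10))), "cord")
  expect_true(all(one$data == 1))
  zero <- fuse_matches(f, make_library(list(img, img),
                                       list(matrix(0L, 10, 10),
                                            matrix(0L, 10, 10))), "cord")
  expect_true(all(zero$data == 0))
  ## hand-evaluated two-match average with equal distances
  expect_true(all(abs(pr$data - 0.5) <= 0.5))  # bounded
  exact0 <- f$d[1:2, ] == 0
  both_templates <- apply(f$t[1:2, ], 2, function(x) length(unique(x)) == 2)
  px <- which(apply(exact0, 2, all) & both_templates)
  expect_gt(length(px), 0)
  expect_true(all(abs(pr$data[px] - 0.5) < 1e-12))
})

test_that("localisation dilates the largest component and flags failures", {
  ## single-pixel mask dilated 8 times with a 3x3 box gives a 17x17 square
  m <- matrix(0L, 41, 41); m[21, 21] <- 1L
  d <- dilate_mask(m, 8)
  expect_equal(sum(d), 17 * 17)
  expect_true(all(d[21 + (-8:8), 21 + (-8:8)] == 1L))

  spec <- zero_variation_spec(3, seed = 2)
  dir <- tempfile()
  coh <- generate_cohort(spec, dir)
  lib <- build_library(coh$manifest)
  sub <- generate_subject(spec, 1)
  sl <- subject_slice(sub)
  roi <- localise_cord(sl$slice, lib, patchmatch_config(seed = 3))
  expect_true(all(roi$data >= sl$cord$data))  # ROI fully contains the cord
  expect_equal(dsc(attr(roi, "core"), sl$cord), 1)  # self-segmentation

  ## a flat target far from any template: every cord patch is textured, so
  ## the only matches are background, the fused probability stays below 0.5
  ## and localisation fails
  set.seed(8)
  tex <- function() {
    m <- matrix(0, 24, 24)
    m[8:16, 8:16] <- 50 + matrix(rnorm(81, 0, 10), 9, 9)
    m
  }
  labp <- matrix(0L, 24, 24); labp[8:16, 8:16] <- 1L
  lib2 <- make_library(list(tex(), tex()), list(labp, labp))
  flat <- slice2d(matrix(5, 24, 24), c(0.5, 0.5))
  expect_error(localise_cord(flat, lib2, patchmatch_config(seed = 3)),
               "localisation failed")
})

test_that("centre of mass is the mean foreground pixel centre in mm", {
  m <- matrix(0L, 9, 9); m[4:6, 4:6] <- 1L
  lm <- label_map(m, c(0.5, 0.5), origin = c(10, 20))
  expect_equal(centre_of_mass(lm), c(10 + 4 * 0.5, 20 + 4 * 0.5))
  single <- matrix(0L, 5, 5); single[2, 4] <- 1L
  expect_equal(centre_of_mass(label_map(single, c(1, 2))), c(1, 6))
  ## L-shaped 3-pixel mask: hand average of the three centres
  L <- matrix(0L, 5, 5); L[2, 2] <- L[3, 2] <- L[3, 3] <- 1L
  expect_equal(centre_of_mass(label_map(L, c(1, 1))),
               c(mean(c(1, 2, 2)), mean(c(1, 1, 2))))
  expect_error(centre_of_mass(label_map(matrix(0L, 3, 3), c(1, 1))), "empty")
})
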