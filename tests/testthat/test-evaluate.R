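test_that("DSC matches hand counts and the pixel-loop oracle", {
  A <- label_map(matrix(0L, 6, 6), c(0.5, 0.5))
  A$data[2:3, 2:3] <- 1L
  B <- label_map(matrix(0L, 6, 6), c(0.5, 0.5))
  B$data[3:4, 2:3] <- 1L            # shifted by one pixel, overlap 2
  expect_equal(dsc(A, B), 0.5)
  expect_equal(dsc(A, A), 1)
  C <- label_map(matrix(0L, 6, 6), c(0.5, 0.5)); C$data[6, 6] <- 1L
  expect_equal(dsc(A, C), 0)
  empty <- label_map(matrix(0L, 6, 6), c(0.5, 0.5))
  expect_equal(dsc(empty, empty), 1)
  set.seed(41)
  for (i in 1:20) {
    X <- random_mask(7, 9); Y <- random_mask(7, 9)
    expect_identical(dsc(X, Y), oracle_dsc(X, Y))
    expect_identical(dsc(X, Y), dsc(Y, X))  # symmetry
  }
  expect_error(dsc(A, random_mask(3, 3)), "grid")
})

test_that("surface distances agree exactly with the all-pairs oracle", {
  A <- random_mask(10, 10, 0.5)
  expect_equal(surface_distances(A, A), c(msd = 0, hd = 0))
  ## two single pixels 3 px apart at 0.5 mm
  P <- label_map(matrix(0L, 8, 8), c(0.5, 0.5)); P$data[2, 4] <- 1L
  Q <- label_map(matrix(0L, 8, 8), c(0.5, 0.5)); Q$data[5, 4] <- 1L
  expect_equal(surface_distances(P, Q), c(msd = 1.5, hd = 1.5))
  ## nested squares and random masks against the brute-force oracle
  N1 <- label_map(matrix(0L, 12, 12), c(0.5, 0.5)); N1$data[3:10, 3:10] <- 1L
  N2 <- label_map(matrix(0L, 12, 12), c(0.5, 0.5)); N2$data[5:8, 5:8] <- 1L
  expect_equal(surface_distances(N1, N2), oracle_surface(N1, N2),
               tolerance = 1e-9)
  set.seed(43)
  for (i in 1:10) {
    X <- random_mask(9, 11, 0.5); Y <- random_mask(9, 11, 0.5)
    if (sum(X$data) == 0 || sum(Y$data) == 0) next
    expect_equal(surface_distances(X, Y), oracle_surface(X, Y),
                 tolerance = 1e-9)
    expect_equal(surface_distances(X, Y), surface_distances(Y, X))
    d <- surface_distances(X, Y)
    expect_lte(d[["msd"]], d[["hd"]])
  }
  expect_error(surface_distances(A, label_map(matrix(0L, 10, 10), c(.5, .5))),
               "no surface")
})

test_that("majority-vote consensus counts votes exactly", {
  m1 <- random_mask(6, 6); m2 <- random_mask(6, 6); m3 <- random_mask(6, 6)
  expect_identical(consensus(list(m1, m1, m1))$data, m1$data)
  cons <- consensus(list(m1, m2, m3))
  expect_identical(cons$data, oracle_consensus(list(m1, m2, m3)))
  ## votes (1,1,0) -> 1 ; (1,0,0) -> 0
  one <- label_map(matrix(1L, 2, 2), c(1, 1))
  zero <- label_map(matrix(0L, 2, 2), c(1, 1))
  expect_true(all(consensus(list(one, one, zero))$data == 1L))
  expect_true(all(consensus(list(one, zero, zero))$data == 0L))
  expect_error(consensus(list(m1, m2)), "exactly 3")
})

test_that("rater screening fails below the DSC cut-off", {
  m <- random_mask(8, 8, 0.5)
  ok <- screen_raters(list(m, m, m))
  expect_true(ok$pass)
  expect_equal(unname(ok$pairwise), c(1, 1, 1))
  full <- label_map(matrix(1L, 8, 8), c(0.5, 0.5))
  empty <- label_map(matrix(0L, 8, 8), c(0.5, 0.5))
  expect_false(screen_raters(list(empty, full, full))$pass)
  ## constructed triples straddling the 0.7 threshold by pixel counting:
  ## |A| = 100, |B| = 100, overlap k -> DSC = k/100
  base <- matrix(0L, 20, 20); base[1:10, 1:10] <- 1L
  shift_mask <- function(k) {
    b <- matrix(0L, 20, 20)
    b[which(base == 1L)[1:k]] <- 1L
    b[which(base == 0L)[seq_len(100 - k)]] <- 1L
    label_map(b, c(0.5, 0.5))
  }
  A <- label_map(base, c(0.5, 0.5))
  expect_false(screen_raters(list(A, shift_mask(69), A))$pass)
  expect_true(screen_raters(list(A, shift_mask(71), A))$pass)
})

test_that("areas, volumes and COV follow their definitions", {
  m <- label_map(matrix(0L, 6, 6), c(0.5, 0.5)); m$data[2:3, 2:3] <- 1L
  av <- area_volume(m, dz = 5)
  expect_equal(av$areas_mm2, 1.0)
  expect_equal(av$volume_mm3, 5.0)
  stack <- label_map(array(m$data, c(6, 6, 3)), c(0.5, 0.5, 5))
  avs <- area_volume(stack)
  expect_equal(avs$areas_mm2, rep(1.0, 3))
  expect_equal(avs$volume_mm3, 15.0)
  empty <- label_map(matrix(0L, 4, 4), c(0.5, 0.5))
  expect_equal(area_volume(empty, dz = 5)$volume_mm3, 0)

  expect_equal(cov_percent(c(5, 5, 5)), 0)
  expect_equal(cov_percent(c(90, 110)), 100 * sd(c(90, 110)) / 100)
  expect_equal(round(cov_percent(c(90, 110)), 2), 14.14)
  expect_error(cov_percent(100), "at least 2")
  expect_error(cov_percent(c(-1, 1)), "zero mean")
})

test_that("leave-one-out uses only the reduced library", {
  dir <- tempfile()
  coh <- generate_cohort(zero_variation_spec(2, seed = 6), dir)
  lib <- build_library(coh$manifest)
  red <- subset_library(lib, "sub001")
  ids <- vapply(red$entries, function(e) e$subject_id, character(1))
  expect_true(all(ids == "sub002"))
  expect_length(red$entries, 6)
})

test_that("a zero-variation cohort segments its targets perfectly", {
  dir <- tempfile()
  coh <- generate_cohort(zero_variation_spec(3, seed = 6), dir)
  cfg <- run_config(seed = 2, fusion = fusion_config(global_cut = 6),
                    prerank_cut = 8)
  rep <- loo_run(coh, cfg, targets = "sub001")
  expect_equal(rep$dsc, c(1, 1))
  expect_equal(rep$msd_mm, c(0, 0))
  expect_equal(rep$hd_mm, c(0, 0))
})
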