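test_that("boundary voxels follow the 6-connectivity convention", {
  # 3x3x3 solid cube in a 5x5x5 volume: all but the centre voxel are boundary
  m <- array(FALSE, c(5, 5, 5)); m[2:4, 2:4, 2:4] <- TRUE
  b <- boundary_voxels(m)
  expect_equal(nrow(b), 26)
  expect_false(any(b[, 1] == 3 & b[, 2] == 3 & b[, 3] == 3))
  # a single voxel is its own boundary
  s <- array(FALSE, c(3, 3, 3)); s[2, 2, 2] <- TRUE
  expect_equal(nrow(boundary_voxels(s)), 1)
  # full-volume mask: the shell touching the border counts (border = background)
  f <- array(TRUE, c(4, 4, 4))
  expect_equal(nrow(boundary_voxels(f)), 4^3 - 2^3)
  expect_equal(nrow(boundary_voxels(array(FALSE, c(2, 2, 2)))), 0)
})

test_that("distance map is the exact anisotropic Euclidean transform", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  dm <- distance_map(m, spacing = c(1, 1, 2.5))
  expect_equal(dm[3, 3, 3], 0)
  expect_equal(dm[3, 3, 4], 2.5)       # one z step
  expect_equal(dm[4, 4, 3], sqrt(2))   # in-plane diagonal
  expect_equal(dm[4, 4, 4], sqrt(1 + 1 + 2.5^2))
  expect_error(distance_map(array(FALSE, c(3, 3, 3))), "empty")
})

test_that("symmetric distances, mDTA and HD95 reproduce hand cases", {
  a <- array(FALSE, c(4, 4, 6)); a[2, 2, 2] <- TRUE
  b <- array(FALSE, c(4, 4, 6)); b[2, 2, 4] <- TRUE
  s <- symmetric_surface_distances(a, b, spacing = c(1, 1, 2.5))
  expect_equal(sort(s$pooled), c(5, 5))   # two slices apart at 2.5 mm
  expect_equal(mdta(s), 5)
  expect_equal(hd95(s), 5)
  # identical masks: all distances zero
  s0 <- symmetric_surface_distances(a, a, spacing = c(1, 1, 2.5))
  expect_true(all(s0$pooled == 0))
  expect_equal(mdta(s0), 0); expect_equal(hd95(s0), 0)
  # pooled size equals the sum of the two boundary cardinalities
  set.seed(7)
  m1 <- array(runif(8 * 8 * 4) < 0.4, c(8, 8, 4))
  m2 <- array(runif(8 * 8 * 4) < 0.4, c(8, 8, 4))
  m1[1] <- TRUE; m2[1] <- TRUE
  sp <- symmetric_surface_distances(m1, m2, c(1, 1, 2.5))
  expect_equal(length(sp$pooled),
               nrow(boundary_voxels(m1)) + nrow(boundary_voxels(m2)))
  # symmetry under swapping prediction and reference
  sq <- symmetric_surface_distances(m2, m1, c(1, 1, 2.5))
  expect_equal(mdta(sp), mdta(sq))
  expect_equal(hd95(sp), hd95(sq))
  # hd95 sits between 0 and the maximum; known percentile case
  pooled <- c(rep(0, 95), rep(10, 5))
  fake <- structure(list(pooled = pooled), class = "surface_distances")
  expect_true(hd95(fake) >= 9.5 - 1e-9 && hd95(fake) <= 10)
  expect_lte(hd95(sp), max(sp$pooled))
})

test_that("spacing scales distances linearly", {
  set.seed(8)
  m1 <- array(runif(6 * 6 * 4) < 0.3, c(6, 6, 4)); m1[1] <- TRUE
  m2 <- array(runif(6 * 6 * 4) < 0.3, c(6, 6, 4)); m2[2] <- TRUE
  s1 <- symmetric_surface_distances(m1, m2, c(1, 1, 2.5))
  s3 <- symmetric_surface_distances(m1, m2, 3 * c(1, 1, 2.5))
  expect_equal(s3$pooled, 3 * s1$pooled, tolerance = 1e-12)
})

test_that("DSC matches brute-force voxel counting", {
  a <- array(FALSE, c(8, 8, 8)); a[1:4, 1:4, 1:4] <- TRUE
  b <- array(FALSE, c(8, 8, 8)); b[3:6, 1:4, 1:4] <- TRUE  # half-overlap shift
  expect_equal(dsc(a, b), 2 * 32 / (64 + 64))
  expect_equal(dsc(a, a), 1)
  d <- array(FALSE, c(8, 8, 8)); d[8, 8, 8] <- TRUE
  expect_equal(dsc(a, d), 0)
  expect_warning(val <- dsc(array(FALSE, c(2, 2, 2)),
                            array(FALSE, c(2, 2, 2))), "empty")
  expect_equal(val, 1)
})

test_that("small boundary translations move mDTA by a spacing-scale amount", {
  # volume-overlap bias: a one-voxel shift of a large cube barely changes
  # DSC but moves mDTA by a spacing-dependent distance
  a <- array(FALSE, c(16, 16, 8)); a[3:14, 3:14, 2:7] <- TRUE
  b <- array(FALSE, c(16, 16, 8)); b[4:15, 3:14, 2:7] <- TRUE
  expect_gt(dsc(a, b), 0.85)
  md <- mdta(symmetric_surface_distances(a, b, c(1, 1, 2.5)))
  expect_gt(md, 0.1)
  expect_lt(md, 1)
})

test_that("observer comparison handles strong separation and degeneracy", {
  set.seed(9)
  a <- runif(20, 4, 6); b <- a + runif(20, 0.5, 1.5)  # all differences one sign
  r <- compare_observers(a, b)
  expect_lt(r$p_value, 0.01)
  # identical samples: degenerate, documented p = 1
  r0 <- compare_observers(a, a)
  expect_equal(r0$p_value, 1)
  expect_equal(r0$n_zero_diff, 20)
  # swapping the samples leaves the p-value unchanged
  r2 <- compare_observers(b, a)
  expect_equal(r2$p_value, r$p_value)
  expect_error(compare_observers(a, b[-1]), "equal length")
  expect_error(compare_observers(1:3, 2:4), "at least 5")
})

test_that("per-organ report covers all organs and flags empties", {
  case <- tiny_phantom()
  rep <- evaluate_segmentation(case$observer2, case$gold)
  expect_equal(nrow(rep), 5)
  expect_true(all(is.finite(rep$dsc)))
  expect_true(all(!rep$empty))
  # an empty prediction is flagged, not silently zeroed
  empty_pred <- label_map(array(0L, dim(case$gold$labels)), case$gold$spacing)
  expect_warning(evaluate_segmentation(empty_pred, case$gold, codes = 1L),
                 "empty")
  rep2 <- suppressWarnings(evaluate_segmentation(empty_pred, case$gold))
  expect_true(all(is.na(rep2$mdta_mm)))
  expect_true(all(rep2$empty))
})
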