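test_that("labels partition the grid and the shell has the configured width", {
  mask <- ellipsoid_mask(c(64, 64, 64), 1, c(32, 32, 32), c(20, 20, 20))
  dom <- build_domain(mask, 1, array(0.2, dim(mask)), dilation_voxels = 10)
  lab <- dom$labels
  expect_true(all(lab %in% 0:2))
  # reslicing an already-isotropic input changes no tumor voxels
  expect_equal(sum(lab == 2L), sum(mask))
  # shell thickness 10 voxels along the axes
  ctr <- round(dim(lab) / 2)
  xline <- lab[, ctr[2], ctr[3]]
  tumor_x <- range(which(xline == 2L))
  region_x <- range(which(xline > 0L))
  expect_equal(tumor_x - region_x, c(10, -10), ignore_attr = TRUE)
  # dilation monotonicity
  expect_true(all(which(lab == 2L) %in% which(lab > 0L)))
})

test_that("uniform K^trans yields an exact tumor mean", {
  mask <- ellipsoid_mask(c(24, 24, 24), 1, c(12, 12, 12), c(7, 6, 6))
  dom <- build_domain(mask, 1, array(0.37, dim(mask)), dilation_voxels = 4)
  expect_equal(dom$ktrans_mean, 0.37, tolerance = 1e-12)
  expect_true(all(is.na(dom$ktrans[dom$labels != 2L])))
})

test_that("anisotropic input reslices to the analytic ellipsoid volume", {
  # ball in world coordinates on a 1 x 1 x 3 mm grid
  shape <- c(40, 40, 14)
  sp <- c(1, 1, 3)
  mask <- ellipsoid_mask(shape, sp, c(20, 20, 21), c(12, 12, 12))
  dom <- build_domain(mask, sp, array(0.1, shape), dilation_voxels = 2)
  vol <- compute_tumor_volume(dom$labels == 2L, 1)
  expect_lt(abs(vol - 4 * pi * 12^3 / 3 / 1000) / (4 * pi * 12^3 / 3 / 1000),
            0.05)
})

test_that("tumor volume is voxel count times voxel volume in cm^3", {
  m <- array(FALSE, c(20, 10, 10))
  m[1:10, 1:10, 1:10] <- TRUE
  expect_equal(compute_tumor_volume(m, 1), 1.0)
  ell <- ellipsoid_mask(c(50, 40, 30), 1, c(25, 20, 15), c(20, 15, 10))
  vol <- compute_tumor_volume(ell, 1)
  ana <- 4 * pi * 20 * 15 * 10 / 3 / 1000
  expect_lt(abs(vol - ana) / ana, 0.02)
})

test_that("domains are padded when the dilation exceeds the grid", {
  mask <- array(FALSE, c(12, 12, 12))
  mask[2:5, 2:5, 2:5] <- TRUE
  dom <- build_domain(mask, 1, array(0.1, dim(mask)), dilation_voxels = 6)
  expect_true(dom$padded)
  expect_true(all(dim(dom$labels) > 12))
  expect_equal(sum(dom$labels == 2L), sum(mask))
  expect_error(build_domain(array(FALSE, c(4, 4, 4)), 1), "empty")
})

test_that("ball dilation matches the Euclidean distance criterion", {
  m <- array(FALSE, c(21, 21, 21)); m[11, 11, 11] <- TRUE
  d <- dilate_ball(m, 5)
  ii <- which(d, arr.ind = TRUE)
  r <- sqrt(rowSums(sweep(ii, 2, c(11, 11, 11), "-")^2))
  expect_true(all(r <= 5 + 1e-9))
  expect_equal(sum(d), sum(ellipsoid_mask(c(21, 21, 21), 1,
                                          c(10.5, 10.5, 10.5), c(5, 5, 5))))
})
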