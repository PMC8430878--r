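test_that("ball surface volume matches the closed form within 5%", {
  mask <- ellipsoid_mask(c(26, 26, 26), 1, c(13, 13, 13), c(10, 10, 10))
  mesh <- export_stl(mask, 1)
  ana <- 4 * pi * 10^3 / 3
  expect_lt(abs(mesh_volume(mesh) - ana) / ana, 0.05)
  # mesh volume also within 5% of the voxel volume it was extracted from
  vox <- sum(mask)
  expect_lt(abs(mesh_volume(mesh) - vox) / vox, 0.05)
})

test_that("degenerate masks are handled explicitly", {
  expect_error(export_stl(array(FALSE, c(5, 5, 5)), 1), "empty")
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  expect_warning(mesh <- export_stl(m, 1), "single-voxel")
  expect_equal(mesh_volume(mesh), 1, tolerance = 1e-9)
})

test_that("binary STL files round-trip the triangle count", {
  mask <- ellipsoid_mask(c(16, 16, 16), 1, c(8, 8, 8), c(5, 5, 5))
  p <- withr::local_tempfile(fileext = ".stl")
  mesh <- export_stl(mask, 1, path = p)
  con <- file(p, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", 80))
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  expect_equal(n, nrow(mesh$vertices))
  expect_equal(file.size(p), 84 + 50 * n)
})

test_that("re-voxelized surface overlaps the source mask (Dice >= 0.95)", {
  dims <- c(24, 24, 24)
  mask <- ellipsoid_mask(dims, 1, c(12, 12, 12), c(8, 6, 7))
  mesh <- export_stl(mask, 1)
  back <- voxelize_mesh(mesh, dims, 1)
  dice <- 2 * sum(back & mask) / (sum(back) + sum(mask))
  expect_gte(dice, 0.95)
})
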