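test_that("NIfTI volume/mask pairs round-trip through disk", {
  ph <- make_phantom(phantom_spec(radius_mm = 8, noise_sd = 3,
                                  voxel_spacing_mm = c(0.7, 0.7, 3)))
  d <- withr::local_tempdir()
  vp <- file.path(d, "v.nii.gz")
  mp <- file.path(d, "m.nii.gz")
  write_pair(ph$volume, ph$mask, vp, mp)
  pr <- load_pair(vp, mp)
  expect_equal(pr$volume$values, ph$volume$values, tolerance = 1e-6)
  expect_identical(pr$mask$values, ph$mask$values)
  expect_equal(pr$volume$spacing, ph$volume$spacing, tolerance = 1e-4)
})

test_that("an all-zero mask is rejected at load", {
  ph <- make_phantom(phantom_spec(radius_mm = 8))
  empty <- roi_mask(array(FALSE, dim(ph$mask$values)), ph$mask$spacing)
  d <- withr::local_tempdir()
  vp <- file.path(d, "v.nii.gz")
  mp <- file.path(d, "m0.nii.gz")
  write_pair(ph$volume, empty, vp, mp)
  expect_error(load_pair(vp, mp), class = "edrisk_degenerate_mask")
})

test_that("resampling preserves values on an already-isotropic grid", {
  ph <- make_phantom(phantom_spec(radius_mm = 8, noise_sd = 3))
  rs <- resample_isotropic(ph$volume, ph$mask, 1)
  expect_identical(dim(rs$volume$values), dim(ph$volume$values))
  expect_lt(max(abs(rs$volume$values - ph$volume$values)), 1e-6)
})

test_that("resampling yields the requested cubic voxels and conserves volume", {
  ph <- make_phantom(phantom_spec(radius_mm = 15,
                                  voxel_spacing_mm = c(0.7, 0.7, 3)))
  rs <- resample_isotropic(ph$volume, ph$mask, 1)
  expect_equal(rs$volume$spacing, c(1, 1, 1))
  expect_equal(sum(rs$mask$values), 4 / 3 * pi * 15^3, tolerance = 0.03)

  ph2 <- make_phantom(phantom_spec(radius_mm = 20, voxel_spacing_mm = 2))
  rs2 <- resample_isotropic(ph2$volume, ph2$mask, 1)
  expect_equal(sum(rs2$mask$values), 4 / 3 * pi * 20^3, tolerance = 0.03)
})

test_that("discretization covers its contract cases", {
  # uniform span over [0, 63] with 64 bins occupies every bin
  v <- image_volume(array(rep(0:63, length.out = 4^3), c(4, 4, 4)),
                    c(1, 1, 1))
  m <- roi_mask(array(TRUE, c(4, 4, 4)), c(1, 1, 1))
  d <- discretize(v, m, 64)
  expect_setequal(unique(as.vector(d$bins)), 1:64)

  # constant region maps to bin 1 with zero histogram entropy
  vc <- image_volume(array(7, c(3, 3, 3)), c(1, 1, 1))
  mc <- roi_mask(array(TRUE, c(3, 3, 3)), c(1, 1, 1))
  dc <- discretize(vc, mc, 64)
  expect_true(all(dc$bins[mc$values] == 1L))
  f <- intensity_features(vc, mc, discrete = dc)
  expect_equal(unname(f["ih.entropy"]), 0)

  # two-level phantom occupies exactly two bins
  ph <- make_phantom(phantom_spec(radius_mm = 8, necrotic_core = TRUE,
                                  core_fraction = 0.2))
  d2 <- discretize(ph$volume, ph$mask, 64)
  expect_length(unique(d2$bins[d2$bins > 0]), 2)
})

test_that("discretized bin labels are invariant to intensity shifts", {
  ph <- make_phantom(phantom_spec(radius_mm = 8, noise_sd = 4, seed = 9L))
  d1 <- discretize(ph$volume, ph$mask, 64)
  shifted <- image_volume(ph$volume$values + 123.4, ph$volume$spacing,
                          ph$volume$origin)
  d2 <- discretize(shifted, ph$mask, 64)
  expect_identical(d1$bins, d2$bins)
})

test_that("grid mismatches raise alignment errors", {
  v <- image_volume(array(0, c(4, 4, 4)), c(1, 1, 1))
  m <- roi_mask(array(TRUE, c(5, 5, 5)), c(1, 1, 1))
  expect_error(discretize(v, m), class = "edrisk_alignment_error")
})
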