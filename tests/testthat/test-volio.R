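test_that("NIfTI round trip preserves data, spacing and origin", {
  vol <- scalar_volume(array(rnorm(4 * 5 * 6, -800, 100), c(4, 5, 6)),
                       spacing = c(0.7, 0.7, 1.0), origin = c(10, -20, 5.5))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(vol, f)
  back <- read_volume(f)
  # float32 payload: compare against the float32-rounded original
  expect_equal(back$data,
               array(readBin(writeBin(as.vector(vol$data), raw(), size = 4),
                             "numeric", prod(dim(vol$data)), size = 4),
                     dim(vol$data)))
  expect_equal(back$spacing, vol$spacing, tolerance = 1e-6)
  expect_equal(back$origin, vol$origin, tolerance = 1e-6)
})

test_that("MetaImage round trip preserves data, spacing and origin", {
  vals <- array(round(rnorm(3 * 4 * 5, -500, 200), 2), c(3, 4, 5))
  vol <- scalar_volume(vals, spacing = c(1.2, 0.9, 2.5), origin = c(-4, 0, 7))
  for (ext in c(".mha", ".mhd")) {
    f <- tempfile(fileext = ext)
    write_volume(vol, f)
    back <- read_volume(f)
    expect_equal(back$data, vol$data, tolerance = 1e-6)
    expect_equal(back$spacing, vol$spacing)
    expect_equal(back$origin, vol$origin)
  }
})

test_that("integer masks survive a round trip exactly", {
  m <- array(as.numeric(runif(6^3) > 0.5), c(6, 6, 6))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(scalar_volume(m), f)
  expect_identical(read_volume(f)$data, m)
})

test_that("constant volumes round trip exactly", {
  f <- tempfile(fileext = ".nii.gz")
  write_volume(scalar_volume(array(-1000, c(4, 4, 4))), f)
  expect_true(all(read_volume(f)$data == -1000))
})

test_that("invalid volumes and paths are rejected", {
  expect_error(scalar_volume(array(c(NaN, rep(0, 7)), c(2, 2, 2))),
               "non-finite")
  expect_error(scalar_volume(array(0, c(2, 2, 2)), spacing = c(1, -1, 1)),
               "spacing")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
  vol <- scalar_volume(array(0, c(2, 2, 2)))
  expect_error(write_volume(vol, file.path(tempfile(), "x", "y.nii")),
               "directory")
  expect_error(read_volume(tempfile(fileext = ".txt")), "format")
})

test_that("deformation fields round trip through NIfTI", {
  set.seed(1)
  fld <- deformation_field(array(rnorm(5^3 * 3), c(5, 5, 5, 3)),
                           spacing = c(2, 2, 3), origin = c(1, 2, 3))
  f <- tempfile(fileext = ".nii.gz")
  write_field(fld, f)
  back <- read_field(f)
  expect_equal(back$disp, fld$disp, tolerance = 1e-6)
  expect_equal(back$spacing, fld$spacing, tolerance = 1e-6)
})

test_that("mask geometry mismatches are errors, not resamples", {
  vol <- scalar_volume(array(0, c(4, 4, 4)))
  m <- mask_set(array(1L, c(5, 5, 5)))
  expect_error(lungmech:::check_same_geometry(vol, m), "does not match")
  expect_error(mask_set(array(1L, c(4, 4, 4)),
                        airways = array(0L, c(3, 4, 4))), "shape")
  expect_error(mask_set(array(0L, c(4, 4, 4))), "empty")
  expect_error(mask_set(array(2L, c(4, 4, 4))), "binary")
})

test_that("two-point HU calibration maps ROI means exactly", {
  arr <- array(0, c(6, 6, 6))
  arr[1:3, 1, 1] <- -990      # trachea-like
  arr[4:6, 1, 1] <- 65        # aorta-like
  vol <- scalar_volume(arr)
  tr <- array(FALSE, dim(arr)); tr[1:3, 1, 1] <- TRUE
  ao <- array(FALSE, dim(arr)); ao[4:6, 1, 1] <- TRUE
  rois <- calibration_rois(tr, ao)
  cal <- calibrate_hu(vol, rois)
  expect_equal(mean(cal$data[tr]), -1000)
  expect_equal(mean(cal$data[ao]), 55)
  # -990 -> -1000 and 65 -> 55 implies a = 1, b = -10
  expect_equal(unname(attr(cal, "calibration")), c(1, -10))
})

test_that("calibration is idempotent and order preserving", {
  set.seed(4)
  arr <- array(rnorm(5^3, -500, 300), c(5, 5, 5))
  arr[1:4] <- c(-998, -1002, -1001, -999)
  arr[5:8] <- c(54, 56, 53, 57)
  vol <- scalar_volume(arr)
  rois <- calibration_rois(1:4, 5:8)
  cal1 <- calibrate_hu(vol, rois)
  cal2 <- calibrate_hu(cal1, rois)
  expect_equal(cal2$data, cal1$data, tolerance = 1e-12)
  expect_true(all(diff(cal1$data[order(vol$data)]) >= 0))
})

test_that("degenerate calibration ROIs raise an error", {
  vol <- scalar_volume(array(0, c(4, 4, 4)))
  expect_error(calibrate_hu(vol, calibration_rois(1:3, 4:6)), "degenerate")
  expect_error(calibration_rois(1:3, 3:5), "overlap")
  expect_error(calibration_rois(integer(0), 1:2), "empty")
})
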