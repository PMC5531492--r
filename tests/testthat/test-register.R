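test_that("SSTVD cost is zero for identical images under identity", {
  vol <- tiny_volume()
  mask <- ball_mask()
  E <- sstvd_cost(vol, vol, mask, identity_transform())
  expect_equal(as.numeric(E), 0)
})

test_that("a uniform HU shift gives the closed-form cost", {
  vol <- tiny_volume()
  mask <- ball_mask()
  shifted <- scalar_volume(vol$data + 10, vol$spacing, vol$origin)
  E <- sstvd_cost(vol, shifted, mask, identity_transform())
  n <- attr(E, "n_voxels")
  v <- voxel_volume(vol)
  expect_equal(as.numeric(E), (10 / 1055)^2 * v^2 * n, tolerance = 1e-9)
})

test_that("identity is the cost minimum for identical images", {
  vol <- tiny_volume()
  mask <- ball_mask()
  E0 <- as.numeric(sstvd_cost(vol, vol, mask, identity_transform()))
  set.seed(6)
  for (i in 1:5) {
    tr <- affine_transform(diag(3), rnorm(3, sd = 0.8))
    expect_gte(as.numeric(sstvd_cost(vol, vol, mask, tr)), E0)
  }
})

test_that("transforms leaving the floating extent raise a domain error", {
  vol <- tiny_volume()
  mask <- ball_mask()
  expect_error(sstvd_cost(vol, vol, mask, affine_transform(diag(3), c(500, 0, 0))),
               "outside the floating image")
})

test_that("warping with identity reproduces the floating image exactly", {
  vol <- tiny_volume()
  w <- warp_image(vol, identity_transform(), vol)
  expect_equal(w$data, vol$data, tolerance = 1e-12)
  expect_equal(attr(w, "n_outside"), 0)
})

test_that("warping by one voxel matches an index shift on the interior", {
  vol <- tiny_volume()
  tr <- affine_transform(diag(3), c(vol$spacing[1], 0, 0))  # +1 voxel in x
  w <- warp_image(vol, tr, vol)
  n <- dim(vol$data)[1]
  expect_equal(w$data[1:(n - 1), , ], vol$data[2:n, , ], tolerance = 1e-9)
  # out-of-extent samples are filled with air and flagged
  expect_equal(attr(w, "n_outside"), sum(w$data[n, , ] == -1000))
  expect_true(attr(w, "n_outside") >= prod(dim(vol$data)[2:3]))
})

test_that("registering a phantom against itself recovers the identity", {
  pair <- lesion_phantom()
  reg <- sstvd_register(pair$time1, pair$time1, pair$masks1, pair$masks1,
                        reg_control(levels = 3L, maxit = 100L))
  mag <- sqrt(rowSums(matrix(reg$field$disp, ncol = 3)^2))
  expect_lt(max(mag), 0.5 * min(pair$time1$spacing))
  expect_true(reg$converged)
  expect_equal(reg$neg_jac_frac, 0)
})

test_that("a known affine warp is recovered in the lung interior", {
  pair <- affine_phantom()
  reg <- affine_fit()
  dom <- lungmech:::erode_mask(pair$masks1$lung != 0, 2)
  idx <- which(dom)
  ijk <- arrayInd(idx, dim(dom)) - 1L
  pts <- voxel_coords(pair$time1, ijk)
  rec <- transform_points(reg$transform, pts)
  tru <- transform_points(pair$true_transform, pts)
  rms <- sqrt(mean(rowSums((rec - tru)^2)))
  expect_lt(rms, min(pair$time1$spacing))      # < 1 voxel RMS
  # the known warp reproduces the clean reference essentially exactly
  wc <- warp_image(scalar_volume(pair$clean0, pair$time0$spacing),
                   pair$true_transform,
                   scalar_volume(pair$clean1, pair$time1$spacing))
  expect_gt(cor(wc$data[dom], pair$clean1[dom]), 0.99)
  # the fitted warp matches the noisy reference up to the noise floor
  w <- predict(reg, pair$time0)
  expect_gt(cor(w$data[dom], pair$time1$data[dom]), 0.8)
})

test_that("accepted cost history is monotone and cost decreases", {
  reg <- affine_fit()
  h <- reg$cost_history
  for (l in unique(h$level)) {
    acc <- h$accepted[h$level == l]
    expect_true(all(diff(acc) <= 0))
  }
  expect_lt(min(h$accepted), h$E[1])
})

test_that("tissue mass is preserved under the recovered warp", {
  # radial no-lesion phantom: the deformation redistributes volume inside
  # the lung while the generator conserves tissue mass exactly
  pair <- lesion_phantom()
  reg <- lesion_fit()$registration
  dom <- pair$masks1$lung != 0
  idx <- which(dom)
  ijk <- arrayInd(idx, dim(dom)) - 1L
  pts <- voxel_coords(pair$time1, ijk)
  det <- transform_jacobian(reg$transform, pts)
  y <- transform_points(reg$transform, pts)
  smp <- lungmech:::cpp_trilinear(as.numeric(pair$time0$data),
                                  as.integer(dim(pair$time0$data)),
                                  pair$time0$spacing, pair$time0$origin,
                                  y, -1000, TRUE)
  v <- voxel_volume(pair$time1)
  warped_mass <- sum(v * det * tissue_fraction(smp$value))
  flt_mass <- sum(v * tissue_fraction(pair$time0$data[pair$masks0$lung != 0]))
  expect_lt(abs(warped_mass - flt_mass) / flt_mass, 0.02)
})

test_that("registration residuals shrink relative to the identity start", {
  reg <- affine_fit()
  r <- residuals(reg)
  E_id <- as.numeric(sstvd_cost(reg$ref, reg$flt, reg$ref_mask,
                                identity_transform()))
  expect_lt(sum(r^2), 0.5 * E_id)
})

test_that("a lesioned pair needs more optimization than a mild pair", {
  # convergence-style comparison: local lesion-like expansion vs a mild
  # warp, same settings; the lesioned pair takes noticeably more
  # evaluations yet still converges
  mk <- function(hr, seed) generate_phantom(phantom_spec(
    shape = c(36, 36, 36), spacing = c(3.4, 3.4, 3.4), vessel_count = 4,
    hyper_region = hr, seed = seed))
  mild <- mk(list(lung_fraction = 0.10, target_delta = 0.15), 61)
  les <- mk(list(lung_fraction = 0.15, target_delta = 1.0), 61)
  ctrl <- reg_control(levels = 2L, maxit = 300L)
  rm_ <- sstvd_register(mild$time1, mild$time0, mild$masks1, mild$masks0, ctrl)
  rl <- sstvd_register(les$time1, les$time0, les$masks1, les$masks0, ctrl)
  expect_gt(nrow(rl$cost_history), nrow(rm_$cost_history))
  # both runs end on a flat cost plateau: the last 10% of accepted
  # evaluations change the cost by well under 1%
  plateau <- function(r) {
    a <- r$cost_history$accepted
    n <- length(a)
    (a[ceiling(0.9 * n)] - a[n]) / a[n]
  }
  expect_lt(plateau(rl), 0.01)
  expect_lt(plateau(rm_), 0.01)
  # and the cost dropped substantially from its starting value
  drop <- function(r) min(r$cost_history$accepted) / r$cost_history$E[1]
  expect_lt(drop(rl), 0.5)
})

test_that("registration methods expose the usual modelling surface", {
  reg <- affine_fit()
  expect_s3_class(reg, "sstvd_registration")
  expect_output(print(reg), "SSTVD")
  s <- summary(reg)
  expect_s3_class(s, "summary.sstvd_registration")
  expect_output(print(s), "converged")
  cf <- coef(reg)
  expect_length(cf, reg$control$levels)
  expect_true(all(vapply(cf, is.matrix, TRUE)))
  pts <- matrix(c(60, 60, 60), 1)
  expect_equal(dim(predict(reg, pts)), c(1L, 3L))
  expect_s3_class(predict(reg), "deformation_field")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(reg); grDevices::dev.off()
  expect_true(file.exists(f))
})
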