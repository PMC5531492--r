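test_that("phantom generation is bit-reproducible from its seed", {
  spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(3, 3, 3),
                       hyper_region = list(lung_fraction = 0.1,
                                           target_delta = 0.6), seed = 5)
  a <- generate_phantom(spec)
  b <- generate_phantom(spec)
  expect_identical(a$time0$data, b$time0$data)
  expect_identical(a$time1$data, b$time1$data)
  expect_identical(a$true_delta_star, b$true_delta_star)
  c <- generate_phantom(phantom_spec(shape = c(24, 24, 24), spacing = c(3, 3, 3),
                                     hyper_region = list(lung_fraction = 0.1,
                                                         target_delta = 0.6),
                                     seed = 6))
  expect_false(identical(a$time0$data, c$time0$data))
})

test_that("identity phantoms differ only by noise and have zero truth", {
  spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(3, 3, 3),
                       noise_sd = 15, seed = 2)
  pair <- generate_phantom(spec)
  expect_equal(pair$clean0, pair$clean1, tolerance = 1e-12)
  expect_identical(pair$masks0$lung, pair$masks1$lung)
  dom <- pair$masks1$lung != 0
  expect_true(all(pair$true_delta_star[dom] == 0))
  expect_true(all(pair$true_J[dom] == 1))
  diffs <- pair$time1$data - pair$time0$data
  expect_lt(abs(sd(diffs) - sqrt(2) * 15), 1.5)
})

test_that("uniform affine deformation gives constant J and zero Delta*", {
  spec <- phantom_spec(shape = c(32, 32, 32), spacing = c(3, 3, 3),
                       deformation = "affine",
                       affine_scale = c(1.05, 1.05, 1.05), seed = 9)
  pair <- generate_phantom(spec)
  dom <- pair$masks1$lung != 0
  expect_equal(max(abs(pair$true_J[dom] - 1 / 1.05^3)), 0, tolerance = 1e-12)
  # voxelized global volumes make Delta* only approximately zero
  expect_lt(max(abs(pair$true_delta_star[dom])), 0.05)
  expect_lt(abs(pair$Vr / pair$Vf - 1 / 1.05^3), 0.03)
})

test_that("phantom truth satisfies the Delta* identity exactly", {
  pair <- lesion_phantom()
  dom <- pair$masks1$lung != 0
  expect_equal(pair$true_delta_star[dom],
               pair$true_J[dom] * pair$Vf / pair$Vr - 1, tolerance = 1e-12)
  expect_gt(min(1 / pair$true_J[dom]), 0)   # invertible on the lung
})

test_that("density decomposition of time1 recovers intended fractions", {
  pair <- lesion_phantom()
  spec <- pair$spec
  d <- lungmech::decompose(pair$time1, pair$masks1)
  intended <- tissue_fraction(pair$clean1)
  mae <- mean(abs(d$tissue_volume[d$domain] / d$v - intended[d$domain]))
  expect_lt(mae, 2 * spec$noise_sd / 1055)
})

test_that("tissue mass is conserved between time points (no lesion)", {
  # the radial hyper-expansion map moves volume, not tissue
  pair <- lesion_phantom()
  v <- voxel_volume(pair$time0)
  m0 <- sum(tissue_fraction(pair$clean0)[pair$masks0$lung != 0]) * v
  m1 <- sum(tissue_fraction(pair$clean1)[pair$masks1$lung != 0]) * v
  expect_lt(abs(m1 - m0) / m0, 0.01)
})

test_that("oracle summary reflects the geometric construction", {
  pair <- lesion_phantom()
  os <- oracle_summary(pair)
  # hyper fraction near the requested 15% of lung (voxelization + smooth
  # falloff shell allow a small excess)
  expect_gt(os$pct_hyper_at_50, 12)
  expect_lt(os$pct_hyper_at_50, 19)
  expect_true(all(diff(os$by_threshold$pct_lung_hyper) <= 0))
  expect_true(all(os$pair_hyperinflated))
  # hyper-expanded regions gain air
  expect_gt(os$air_sign["increase"], 100 * os$air_sign["decrease"] + 100)
  # identity pair: oracle flags nothing
  id <- generate_phantom(phantom_spec(shape = c(24, 24, 24),
                                      spacing = c(3, 3, 3), seed = 3))
  os0 <- oracle_summary(id)
  expect_true(all(os0$by_threshold$pct_lung_hyper == 0))
})

test_that("tissue lesions raise Delta_tissue* inside the lesion", {
  ext <- c(32, 32, 32) * 3
  ctr <- ext / 2
  spec <- phantom_spec(shape = c(32, 32, 32), spacing = c(3, 3, 3),
                       hyper_region = list(lung_fraction = 0.12,
                                           target_delta = 0.8),
                       tissue_lesion = list(center = ctr + c(0.15, 0, -0.15) *
                                              c(0.33, 0.28, 0.40) * ext,
                                            radius = 15, multiplier = 1.6),
                       noise_sd = 10, seed = 12)
  pair <- generate_phantom(spec)
  os <- oracle_summary(pair)
  expect_gt(os$pct_tissue_exp_at_50, 1)
  dom <- pair$masks1$lung != 0
  # far from the lesion the tissue change stays near zero
  expect_lt(abs(median(pair$true_delta_tissue_star[dom], na.rm = TRUE)), 0.1)
})

test_that("non-invertible deformation requests are refused", {
  spec <- phantom_spec(shape = c(24, 24, 24), spacing = c(3, 3, 3),
                       deformation = "bspline", bspline_amp = 60, seed = 1)
  expect_error(generate_phantom(spec), "not invertible")
  expect_error(phantom_spec(hyper_region = list(target_delta = -1.2)),
               "exceed -1")
})
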