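test_that("delta_star_map implements the normalized volume change", {
  # a region whose local-to-global contribution rose 50% has Delta* = 0.5
  expect_identical(delta_star_map(1.2, Vf = 1.25, Vr = 1), 0.5)
  expect_identical(delta_star_map(1, Vf = 3, Vr = 3), 0)
  # uniform global inflation: J == Vr/Vf everywhere gives identically 0
  Vr <- 1300; Vf <- 1000
  expect_equal(delta_star_map(rep(Vr / Vf, 5), Vf, Vr), rep(0, 5))
  expect_error(delta_star_map(1, 0, 1), "positive")
  expect_error(delta_star_map(1, 1, -2), "positive")
})

test_that("component maps follow the same normalized form", {
  expect_equal(delta_air_star_map(2, 1, Vf = 1, Vr = 1), 1)
  expect_equal(delta_air_star_map(1, 1, Vf = 2, Vr = 2), 0)
  expect_equal(delta_tissue_star_map(1.5, 1, Vf = 1, Vr = 1), 0.5)
  expect_equal(delta_tissue_star_map(3, 3, Vf = 5, Vr = 5), 0)
  expect_true(is.na(delta_air_star_map(1, 0, 1, 1)))
})

test_that("additive identity ties the three maps together", {
  # (1+D*) v^f = (1+Dair*) v_air^f + (1+Dtis*) v_tis^f on random fields
  set.seed(21)
  for (i in 1:20) {
    n <- 50
    vf <- runif(n, 0.5, 2)
    ftis_f <- runif(n, 0.05, 0.95)
    vtis_f <- vf * ftis_f
    vair_f <- vf - vtis_f
    vr <- runif(n, 0.5, 2)
    ftis_r <- runif(n, 0.05, 0.95)
    vtis_r <- vr * ftis_r
    vair_r <- vr - vtis_r
    Vf <- runif(1, 500, 2000); Vr <- runif(1, 500, 2000)
    J <- vr / vf
    lhs <- (1 + delta_star_map(J, Vf, Vr)) * vf
    rhs <- (1 + delta_air_star_map(vair_r, vair_f, Vf, Vr)) * vair_f +
      (1 + delta_tissue_star_map(vtis_r, vtis_f, Vf, Vr)) * vtis_f
    expect_lt(max(abs(lhs - rhs) / abs(lhs)), 1e-12)
  }
})

test_that("mechanics maps on an analytic warp honor the identities", {
  pair <- affine_phantom()
  maps <- mechanics_maps(pair$time1, pair$time0, pair$masks1, pair$masks0,
                         pair$true_transform)
  dom <- maps$domain
  # Delta* = J Vf/Vr - 1 exactly where defined
  expect_equal(maps$delta_star[dom],
               maps$J[dom] * maps$Vf / maps$Vr - 1, tolerance = 1e-12)
  # Delta* > -1 wherever J > 0
  expect_true(all(maps$delta_star[dom] > -1, na.rm = TRUE))
  # additive identity to 1e-9 relative where all components are defined
  ok <- dom & !is.na(maps$delta_air_star) & !is.na(maps$delta_tissue_star)
  vf <- maps$vair_f[ok] + maps$vtis_f[ok]
  lhs <- (1 + maps$delta_star[ok]) * vf
  rhs <- (1 + maps$delta_air_star[ok]) * maps$vair_f[ok] +
    (1 + maps$delta_tissue_star[ok]) * maps$vtis_f[ok]
  expect_lt(max(abs(lhs - rhs) / abs(lhs)), 1e-9)
  # uniform 5% deflation: Delta* ~ 0 across the lung interior
  er <- lungmech:::erode_mask(dom, 2)
  expect_lt(stats::quantile(abs(maps$delta_star[er]), 0.99, na.rm = TRUE), 0.05)
})

test_that("Delta* is invariant to uniform inflation of the floating lung", {
  # scaling the floating side uniformly changes J and Vf/Vr reciprocally
  pair <- affine_phantom()
  dom <- pair$masks1$lung != 0
  expect_lt(max(abs(pair$true_delta_star[dom]), na.rm = TRUE), 0.05)
})

test_that("forward and reverse maps are inverse-consistent", {
  # swapping the roles of the two time points with the inverse warp gives
  # (1 + D*_fwd(x)) * (1 + D*_rev(T(x))) ~ 1 in the lung interior
  pair <- affine_phantom()
  fwd <- mechanics_maps(pair$time1, pair$time0, pair$masks1, pair$masks0,
                        pair$true_transform)
  A <- pair$true_transform$A
  inv <- affine_transform(solve(A), -solve(A) %*% pair$true_transform$b)
  rev <- mechanics_maps(pair$time0, pair$time1, pair$masks0, pair$masks1, inv)
  er <- lungmech:::erode_mask(fwd$domain, 2)
  idx <- which(er)
  ijk <- arrayInd(idx, dim(er)) - 1L
  y <- transform_points(pair$true_transform, voxel_coords(pair$time1, ijk))
  drev <- lungmech:::cpp_trilinear(ifelse(is.na(rev$delta_star), 0,
                                          rev$delta_star),
                                   as.integer(dim(rev$delta_star)),
                                   pair$time0$spacing, pair$time0$origin,
                                   y, 0, TRUE)$value
  prod_ <- (1 + fwd$delta_star[idx]) * (1 + drev)
  expect_lt(max(abs(prod_ - 1), na.rm = TRUE), 0.05)
})

test_that("expansion summary counts and flags behave like percentages", {
  d <- c(3, 3, 3)
  dom <- array(TRUE, d)
  ds <- array(0, d)
  ds[1:3] <- 0.6                      # ~11.1% of 27 voxels
  maps <- list(delta_star = ds, delta_tissue_star = array(0, d),
               delta_air_star = array(0.1, d), domain = dom)
  s <- expansion_summary(maps, thresholds = c(0.2, 0.5, 1.0),
                         cutoffs = c(0.1, 0.5, 1, 2))
  expect_equal(s$pct_hyper_at_50, 100 * 3 / 27)
  expect_true(all(s$pair_hyperinflated))
  expect_true(all(diff(s$by_threshold$pct_lung_hyper) <= 0))
  # all-zero field: nothing hyper-expanded, pair not flagged
  maps0 <- list(delta_star = array(0, d), delta_tissue_star = array(0, d),
                delta_air_star = array(0, d), domain = dom)
  s0 <- expansion_summary(maps0)
  expect_true(all(s0$by_threshold$pct_lung_hyper == 0))
  expect_false(any(s0$pair_hyperinflated))
  expect_error(expansion_summary(list(delta_star = ds, domain = array(FALSE, d))),
               "empty")
})

test_that("exact-fraction fields give exact percentages", {
  d <- c(10, 10, 10)
  ds <- array(0, d)
  ds[1:100] <- 0.6                    # exactly 10%
  maps <- list(delta_star = ds, delta_tissue_star = array(0, d),
               delta_air_star = ds, domain = array(TRUE, d))
  s <- expansion_summary(maps)
  expect_equal(s$pct_hyper_at_50, 10)
  expect_true(all(s$pair_hyperinflated))
})

test_that("threshold monotonicity holds on random fields", {
  set.seed(31)
  d <- c(8, 8, 8)
  maps <- list(delta_star = array(rnorm(512, 0.2, 0.5), d),
               delta_tissue_star = array(rnorm(512, 0.2, 0.5), d),
               delta_air_star = array(rnorm(512), d),
               domain = array(runif(512) > 0.2, d))
  thr <- sort(runif(6, 0, 1.5))
  s <- expansion_summary(maps, thresholds = thr)
  expect_true(all(diff(s$by_threshold$pct_lung_hyper) <= 0))
  expect_true(all(diff(s$by_threshold$pct_lung_tissue_exp) <= 0))
  counts <- vapply(c(0.1, 0.5, 1, 2), function(ct)
    sum(s$pct_hyper_at_50 >= ct), 0)
  expect_true(all(diff(counts) <= 0))
})
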