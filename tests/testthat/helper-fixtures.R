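# Shared fixtures. Heavy objects (phantoms, registrations) are built once
# per test run and cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)
  .fixtures[[name]]
}

# Small textured volume with an off-centre bright blob, enough structure to
# drive a registration.
tiny_volume <- function(n = 16, spacing = c(2, 2, 2), seed = 7) {
  set.seed(seed)
  ax <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  arr <- -900 + 500 * exp(-r2 / (n / 2)^2) +
    array(rnorm(n^3, sd = 5), c(n, n, n))
  scalar_volume(arr, spacing = spacing)
}

# Ball lung mask covering the centre of an n^3 grid.
ball_mask <- function(n = 16, radius = n / 2 - 2) {
  ax <- seq_len(n) - (n + 1) / 2
  r2 <- outer(outer(ax^2, ax^2, "+"), ax^2, "+")
  mask_set(array(as.integer(r2 <= radius^2), c(n, n, n)))
}

# Lesioned 48^3 phantom and its registration, reused by the recovery,
# conservation and acceptance tests.
lesion_phantom <- function() {
  fixture("lesion_phantom", generate_phantom(phantom_spec(
    shape = c(64, 64, 64),
    hyper_region = list(lung_fraction = 0.15, target_delta = 0.8),
    seed = 101)))
}

lesion_fit <- function() {
  fixture("lesion_fit", {
    pair <- lesion_phantom()
    run_pair(pair$time1, pair$time0, pair$masks1, pair$masks0,
             control = reg_control(levels = 4L, downsample = c(4L, 2L, 1L, 1L),
                                   control_spacing = 4, maxit = 400L))
  })
}

# Mild no-lesion warp (uniform 5% lung inflation from Time 0 to Time 1,
# i.e. the reference-to-floating map contracts by 1/1.05) and its
# registration: used for affine recovery and tissue-mass conservation.
affine_phantom <- function() {
  fixture("affine_phantom", generate_phantom(phantom_spec(
    shape = c(48, 48, 48), spacing = c(2.6, 2.6, 2.6),
    deformation = "affine", affine_scale = rep(1 / 1.05, 3), seed = 33)))
}

affine_fit <- function() {
  fixture("affine_fit", {
    pair <- affine_phantom()
    sstvd_register(pair$time1, pair$time0, pair$masks1, pair$masks0,
                   reg_control(levels = 3L, maxit = 200L))
  })
}

# Synthetic two-group cohort: 7 identity-deformation controls vs 10
# lesioned phantoms, each run through the full registration pipeline at
# modest problem size.
synthetic_cohort_records <- function() {
  fixture("cohort_records", {
    ctrl <- reg_control(levels = 3L, maxit = 100L)
    run_one <- function(spec, group, id) {
      pair <- generate_phantom(spec)
      res <- run_pair(pair$time1, pair$time0, pair$masks1, pair$masks0, ctrl)
      pair_record(res, subject = id, pair = id, group = group)
    }
    recs <- list()
    for (i in 1:7) {
      recs[[length(recs) + 1L]] <- run_one(
        phantom_spec(shape = c(48, 48, 48), spacing = c(2.6, 2.6, 2.6),
                     seed = 300 + i), "control", paste0("c", i))
    }
    fracs <- rep(c(0.10, 0.13, 0.15, 0.17, 0.12), 2)
    deltas <- rep(c(0.7, 0.9, 0.8, 0.6, 1.0), 2)
    for (i in 1:10) {
      recs[[length(recs) + 1L]] <- run_one(
        phantom_spec(shape = c(48, 48, 48), spacing = c(2.6, 2.6, 2.6),
                     hyper_region = list(lung_fraction = fracs[i],
                                         target_delta = deltas[i]),
                     seed = 200 + i), "lesioned", paste0("s", i))
    }
    do.call(rbind, recs)
  })
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-12)), tol)
}
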