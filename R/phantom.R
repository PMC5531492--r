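## Digital serial-CT lung phantoms with analytically known deformation.
##
## The generator builds a Time 0 (floating) chest-like volume — soft-tissue
## body at +55 HU, an ellipsoidal lung of air-dominated parenchyma with a
## smooth texture field, a tracheal air column and bright vessel-like
## chords — applies a closed-form invertible warp, and synthesizes the
## Time 1 (reference) volume with the mass-preserving intensity update
## frac1(x) = det(dT/dx) * frac0(T(x)), so the decomposition of the warped
## image is consistent with conservation of tissue. Ground-truth J and
## Delta* maps come from the analytic Jacobian and the generator's own
## global volumes.

#' Phantom specification
#'
#' @param shape Grid size in voxels (length 3).
#' @param spacing Voxel spacing in mm.
#' @param lung_axes Semi-axes of the lung ellipsoid (mm); default 0.33,
#'   0.28, 0.40 of the grid extent.
#' @param lung_center World centre of the lung (mm); default grid centre.
#' @param parenchyma_hu Mean parenchymal intensity (HU) at full
#'   inspiration.
#' @param texture_sd Standard deviation of the smooth parenchymal texture
#'   field (HU).
#' @param texture_scale Correlation length of the texture (mm).
#' @param trachea_radius Radius of the tracheal air column (mm).
#' @param vessel_count,vessel_radius Number and radius (mm) of bright
#'   vessel-like chords through the lung.
#' @param deformation One of `"identity"`, `"radial"`, `"affine"`,
#'   `"bspline"` — the inter-scan warp family.
#' @param affine_scale Per-axis scale factors when `deformation="affine"`.
#' @param bspline_amp Coefficient SD in mm when `deformation="bspline"`
#'   (control spacing fixed at a quarter of the grid extent).
#' @param hyper_region `NULL`, or `list(lung_fraction=, target_delta=,
#'   center=)`: a spherical region covering `lung_fraction` of the
#'   reference lung whose normalized volume change is driven to
#'   `target_delta` (implies `deformation="radial"` composed with any
#'   affine part). `center=NULL` places it off-centre inside the lung.
#' @param tissue_lesion `NULL`, or `list(center=, radius=, multiplier=)`:
#'   multiplies the floating tissue fraction inside a sphere (world mm)
#'   before warping, emulating tissue gain (capped at a fraction of 1).
#' @param psf_sigma Gaussian point-spread-function sigma in mm applied to
#'   the clean Time 0 anatomy (Time 1 inherits it through the warp);
#'   default 0.6x the largest voxel dimension, 0 disables.
#' @param noise_sd Additive i.i.d. Gaussian HU noise, applied
#'   independently to both time points.
#' @param seed Integer seed; the pair is bit-reproducible given the spec.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64, 64, 64), spacing = c(2, 2, 2),
                         lung_axes = NULL, lung_center = NULL,
                         parenchyma_hu = -860, texture_sd = 30,
                         texture_scale = 8, trachea_radius = 5,
                         vessel_count = 6, vessel_radius = 1.2,
                         deformation = c("identity", "radial", "affine",
                                         "bspline"),
                         affine_scale = c(1.05, 1.05, 1.05),
                         bspline_amp = 2,
                         hyper_region = NULL, tissue_lesion = NULL,
                         psf_sigma = NULL, noise_sd = 20, seed = 1L) {
  deformation <- match.arg(deformation)
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  extent <- shape * spacing
  if (is.null(lung_axes)) lung_axes <- c(0.33, 0.28, 0.40) * extent
  if (is.null(lung_center)) lung_center <- extent / 2
  if (!is.null(hyper_region)) {
    hr <- hyper_region
    if (is.null(hr$lung_fraction)) hr$lung_fraction <- 0.15
    if (is.null(hr$target_delta)) hr$target_delta <- 0.8
    if (hr$target_delta <= -1) stop("target_delta must exceed -1")
    hyper_region <- hr
    deformation <- if (deformation == "affine") "affine" else "radial"
  }
  structure(list(shape = shape, spacing = spacing, lung_axes = lung_axes,
                 lung_center = lung_center, parenchyma_hu = parenchyma_hu,
                 texture_sd = texture_sd, texture_scale = texture_scale,
                 trachea_radius = trachea_radius,
                 vessel_count = as.integer(vessel_count),
                 vessel_radius = vessel_radius, deformation = deformation,
                 affine_scale = affine_scale, bspline_amp = bspline_amp,
                 hyper_region = hyper_region, tissue_lesion = tissue_lesion,
                 psf_sigma = psf_sigma,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

freq_sq <- function(n, h) {
  f <- c(0:(n %/% 2), -rev(seq_len(n - n %/% 2 - 1))) / (n * h)
  f^2
}

## Periodic Gaussian filtering via FFT (kernel scale in mm).
gaussian_filter <- function(arr, spacing, sigma) {
  d <- dim(arr)
  k2 <- outer(outer(freq_sq(d[1], spacing[1]), freq_sq(d[2], spacing[2]),
                    "+"),
              freq_sq(d[3], spacing[3]), "+")
  Re(stats::fft(stats::fft(arr) * exp(-2 * pi^2 * sigma^2 * k2),
                inverse = TRUE)) / prod(d)
}

## Smooth periodic Gaussian random field with unit variance.
smooth_noise_field <- function(shape, spacing, scale_mm) {
  w <- array(stats::rnorm(prod(shape)), shape)
  sm <- gaussian_filter(w, spacing, scale_mm)
  sm / stats::sd(sm)
}

#' Generate a synthetic serial-CT phantom pair
#'
#' @param spec A [phantom_spec()].
#' @return Object of class `phantom_pair` with components `time0`, `masks0`
#'   (floating image and masks), `time1`, `masks1` (reference),
#'   `true_transform` (analytic `lung_transform`), `true_field`
#'   ([deformation_field()]), ground-truth arrays `true_J`,
#'   `true_delta_star`, `true_delta_air_star`, `true_delta_tissue_star`
#'   (reference/floating volume-ratio J over the reference lung), and the
#'   global lung volumes `Vf`, `Vr`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  sp <- spec$spacing
  extent <- d * sp
  v <- prod(sp)
  ctr <- spec$lung_center
  ax <- spec$lung_axes
  if (any(ctr - ax < 0) || any(ctr + ax > extent))
    stop("lung ellipsoid extends beyond the grid")

  vol0 <- scalar_volume(array(0, d), spacing = sp, origin = c(0, 0, 0))
  pts <- voxel_coords(vol0)

  in_lung <- function(p) {
    rowSums(sweep(sweep(p, 2, ctr), 2, ax, "/")^2) <= 1
  }
  trachea_top <- ctr[3]
  in_trachea <- function(p) {
    (p[, 1] - ctr[1])^2 + (p[, 2] - ctr[2])^2 <= spec$trachea_radius^2 &
      p[, 3] >= trachea_top
  }

  ## vessel chords: random directions through points near the lung centre
  vessels <- vector("list", spec$vessel_count)
  for (i in seq_len(spec$vessel_count)) {
    o <- ctr + stats::runif(3, -0.5, 0.5) * ax
    u <- stats::rnorm(3)
    vessels[[i]] <- list(o = o, u = u / sqrt(sum(u^2)))
  }
  in_vessel <- function(p) {
    hit <- rep(FALSE, nrow(p))
    for (vs in vessels) {
      dp <- sweep(p, 2, vs$o)
      t <- dp %*% vs$u
      d2 <- rowSums((dp - t %*% t(vs$u))^2)
      hit <- hit | d2 <= spec$vessel_radius^2
    }
    hit
  }

  lung0 <- in_lung(pts)
  trach0 <- in_trachea(pts)
  ves0 <- in_vessel(pts) & lung0
  texture <- smooth_noise_field(d, sp, spec$texture_scale) * spec$texture_sd

  ## Analytic tissue-fraction field of the Time 0 anatomy: composing the
  ## geometric indicators with the (smoothly interpolated) texture keeps
  ## region boundaries crisp under warping — no air/body intensity mixing.
  frac_at <- function(p) {
    f <- rep(1, nrow(p))                       # soft-tissue body
    lg <- in_lung(p)
    if (any(lg)) {
      tex <- cpp_trilinear(as.numeric(texture), as.integer(d), sp,
                           c(0, 0, 0), p[lg, , drop = FALSE], 0, TRUE)$value
      f[lg] <- tissue_fraction(spec$parenchyma_hu + tex)
    }
    f[in_vessel(p) & lg] <- 1                  # bright vessel-like chords
    f[in_trachea(p)] <- 0                      # tracheal air
    f
  }

  ## Compose the anatomy, then apply a scanner-like point spread function:
  ## real CT boundaries are band-limited, and the softened edges keep the
  ## warp-resampled Time 1 consistent with interpolated evaluation of
  ## Time 0.
  psf <- spec$psf_sigma
  if (is.null(psf)) psf <- 0.6 * max(sp)
  clean0 <- array(-1000 + 1055 * frac_at(pts), d)
  if (psf > 0) clean0 <- gaussian_filter(clean0, sp, psf)
  clean0 <- pmin(pmax(clean0, -1000), 55)
  lung0_mask <- array(as.integer(lung0 & !trach0), d)
  masks0 <- mask_set(lung0_mask,
                     airways = array(as.integer(trach0), d),
                     vessels = array(as.integer(ves0), d))

  ## ---- analytic inter-scan transform (reference -> floating) ----
  V0 <- 4 / 3 * pi * prod(ax)
  transform <- identity_transform()
  if (spec$deformation == "affine") {
    transform <- scaling_transform(spec$affine_scale, center = ctr)
  } else if (spec$deformation == "bspline") {
    h <- max(extent) / 4
    grid <- list(gdim = as.integer(ceiling(extent / h) + 4L),
                 gorigin = -sp / 2 - h, gspacing = rep(h, 3))
    coef <- matrix(stats::rnorm(prod(grid$gdim) * 3, sd = spec$bspline_amp),
                   ncol = 3)
    transform <- bspline_transform(list(c(grid, list(coef = coef))))
  }
  if (!is.null(spec$hyper_region)) {
    hr <- spec$hyper_region
    g <- hr$lung_fraction
    delta <- hr$target_delta
    ## The radial map is identity outside its shell, so the global lung
    ## volume is unchanged (the shell compresses to balance the expanding
    ## core, exactly as a locally hyper-expanding region redistributes
    ## volume within a lung held at total lung capacity). With Vf = Vr the
    ## core volume ratio is simply J_core = 1 + target_delta.
    Jc <- 1 + delta
    s <- Jc^(-1 / 3)
    R1 <- (3 * g * V0 / (4 * pi))^(1 / 3)
    hc <- hr$center
    if (is.null(hc)) hc <- ctr + c(0.15, 0, -0.15) * ax
    R2 <- R1 * 1.25
    ## the whole shell should deform lung, not body: check on a sphere
    u <- matrix(stats::rnorm(300), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    surf <- sweep(u * R2, 2, hc, "+")
    if (any(rowSums(sweep(sweep(surf, 2, ctr), 2, ax, "/")^2) > 1))
      warning("hyper-expansion shell reaches the lung boundary")
    radial <- radial_transform(hc, r_core = R1, width = R1 / 4, s = s)
    transform <- if (spec$deformation == "affine")
      composite_transform(radial, transform) else radial
  }

  det <- transform_jacobian(transform, pts)
  if (min(det) <= 0)
    stop(sprintf("requested deformation is not invertible on the grid (min det = %.3g)",
                 min(det)))
  y <- transform_points(transform, pts)

  ## ---- mass-preserving Time 1 synthesis ----
  ## Time 1 is the warp-resampled Time 0 with the tissue fraction scaled
  ## by the local volume ratio; interpolating the PSF-filtered image means
  ## both time points share one band-limited sampling process.
  frac0_grid <- tissue_fraction(clean0)
  frac0_y <- cpp_trilinear(as.numeric(frac0_grid), as.integer(d), sp,
                           c(0, 0, 0), y, 1, TRUE)$value
  mult <- rep(1, nrow(pts))
  if (!is.null(spec$tissue_lesion)) {
    le <- spec$tissue_lesion
    inside <- rowSums(sweep(y, 2, le$center)^2) <= le$radius^2
    mult[inside] <- le$multiplier
  }
  frac1 <- pmin(det * mult * frac0_y, 1)
  clean1 <- array(-1000 + 1055 * frac1, d)

  lung1 <- in_lung(y) & !in_trachea(y)
  masks1 <- mask_set(array(as.integer(lung1), d),
                     airways = array(as.integer(in_trachea(y)), d),
                     vessels = array(as.integer(in_vessel(y) & in_lung(y)), d))

  Vf <- sum(masks0$lung) * v
  Vr <- sum(masks1$lung) * v

  ## ---- ground truth on the reference lung ----
  dom1 <- masks1$lung != 0L
  Jratio <- array(NA_real_, d)
  Jratio[dom1] <- 1 / det[dom1]
  tds <- array(NA_real_, d)
  tds[dom1] <- delta_star_map(Jratio[dom1], Vf, Vr)
  vtis_r <- v * frac1
  vtis_f <- v * det * frac0_y
  vair_r <- v - vtis_r
  vair_f <- v * det - vtis_f
  tdt <- array(NA_real_, d)
  tda <- array(NA_real_, d)
  selt <- dom1 & vtis_f > 0
  tdt[selt] <- delta_tissue_star_map(vtis_r[selt], vtis_f[selt], Vf, Vr)
  sela <- dom1 & vair_f > 0
  tda[sela] <- delta_air_star_map(vair_r[sela], vair_f[sela], Vf, Vr)

  time0 <- scalar_volume(clean0 + array(stats::rnorm(prod(d), 0, spec$noise_sd), d),
                         spacing = sp, origin = c(0, 0, 0))
  time1 <- scalar_volume(clean1 + array(stats::rnorm(prod(d), 0, spec$noise_sd), d),
                         spacing = sp, origin = c(0, 0, 0))

  structure(list(
    time0 = time0, masks0 = masks0, time1 = time1, masks1 = masks1,
    true_transform = transform,
    true_field = deformation_field(array(y - pts, c(d, 3)), spacing = sp,
                                   origin = c(0, 0, 0)),
    true_J = Jratio, true_delta_star = tds, true_delta_air_star = tda,
    true_delta_tissue_star = tdt,
    clean0 = clean0, clean1 = clean1,
    Vf = Vf, Vr = Vr, spec = spec), class = "phantom_pair")
}

#' @export
print.phantom_pair <- function(x, ...) {
  d <- x$spec$shape
  cat(sprintf("<phantom_pair> %dx%dx%d @ %s mm, deformation '%s', seed %d\n",
              d[1], d[2], d[3], paste(x$spec$spacing, collapse = "x"),
              x$spec$deformation, x$spec$seed))
  cat(sprintf("  lung volumes: Vf = %.1f mL, Vr = %.1f mL\n",
              x$Vf / 1000, x$Vr / 1000))
  if (!is.null(x$spec$hyper_region))
    cat(sprintf("  hyper region: %.0f%% of lung at target Delta* = %.2f\n",
                100 * x$spec$hyper_region$lung_fraction,
                x$spec$hyper_region$target_delta))
  invisible(x)
}

#' Ground-truth expansion summary of a phantom pair
#'
#' Applies [expansion_summary()] to the generator's analytic Delta* maps —
#' no registration involved. This is the oracle against which a recovered
#' [run_pair()] summary is judged.
#'
#' @param pair A [generate_phantom()] result.
#' @param thresholds,cutoffs As in [expansion_summary()].
#' @return An `expansion_summary`.
#' @export
oracle_summary <- function(pair, thresholds = c(0.2, 0.5, 1.0),
                           cutoffs = c(0.1, 0.5, 1, 2)) {
  stopifnot(inherits(pair, "phantom_pair"))
  maps <- list(delta_star = pair$true_delta_star,
               delta_tissue_star = pair$true_delta_tissue_star,
               delta_air_star = pair$true_delta_air_star,
               domain = pair$masks1$lung != 0L)
  expansion_summary(maps, thresholds, cutoffs)
}
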