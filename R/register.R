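## Mass-preserving non-rigid registration.
##
## The similarity metric is the sum of squared tissue volume differences
## (SSTVD) over the reference region of interest Omega:
##
##   E(T) = sum_{x in Omega} ( vt_r(x) - vt_f(T(x)) )^2        [mm^6]
##
## with vt_r(x) = v_r * frac(I_r(x)) and, in the mass-preserving
## discretization used here, vt_f(T(x)) = v_r * det(dT/dx) * frac(I_f(T(x))):
## the matched floating volume is the reference voxel volume scaled by the
## local volume ratio, so minimizing E approximately preserves tissue mass.
## T is a multilevel additive cubic B-spline free-form deformation,
## optimized coarse-to-fine with L-BFGS-B and analytic gradients.

#' Registration settings
#'
#' @param levels Number of resolution levels (coarse to fine).
#' @param downsample Integer image downsampling factor per level, finest
#'   last; length `levels`.
#' @param control_spacing Control-point spacing in mm at the finest level;
#'   doubled at each coarser level. Default: 4x the largest reference voxel
#'   dimension.
#' @param maxit Maximum L-BFGS-B iterations per level.
#' @param rel_tol Relative cost-decrease tolerance declaring convergence.
#' @param tol_iters Number of successive low-progress iterations required.
#' @param coef_bound Box bound on each B-spline coefficient, as a fraction
#'   of that level's control spacing; 0.4 keeps a single cubic FFD level
#'   diffeomorphic.
#' @param verbose Print per-level progress.
#' @return A list of class `reg_control`.
#' @export
reg_control <- function(levels = 3L, downsample = NULL, control_spacing = NULL,
                        maxit = 200L, rel_tol = 1e-6, tol_iters = 5L,
                        coef_bound = 0.4, verbose = FALSE) {
  levels <- as.integer(levels)
  stopifnot(levels >= 1L, maxit >= 1L, rel_tol > 0, coef_bound > 0)
  if (is.null(downsample)) downsample <- rev(2^(seq_len(levels) - 1L))
  downsample <- as.integer(downsample)
  stopifnot(length(downsample) == levels, all(downsample >= 1L))
  structure(list(levels = levels, downsample = downsample,
                 control_spacing = control_spacing, maxit = maxit,
                 rel_tol = rel_tol, tol_iters = tol_iters,
                 coef_bound = coef_bound, verbose = isTRUE(verbose)),
            class = "reg_control")
}

## Block-average image pyramid level; origin moves to the centre of the
## first block.
downsample_volume <- function(vol, f) {
  if (f == 1L) return(vol)
  d <- dim(vol$data)
  arr <- cpp_block_mean(as.numeric(vol$data), as.integer(d),
                        as.integer(rep(f, 3)))
  scalar_volume(arr, spacing = vol$spacing * f,
                origin = vol$origin + (f - 1) / 2 * vol$spacing)
}

downsample_mask <- function(mask_arr, f) {
  if (f == 1L) return(mask_arr != 0L)
  d <- dim(mask_arr)
  m <- cpp_block_mean(as.numeric(mask_arr), as.integer(d),
                      as.integer(rep(f, 3)))
  m >= 0.5
}

## Omega: the combined reference region driving the cost (union of lung,
## airway and vessel masks when provided).
combined_mask <- function(mask) {
  m <- mask$lung != 0L
  if (!is.null(mask$airways)) m <- m | mask$airways != 0L
  if (!is.null(mask$vessels)) m <- m | mask$vessels != 0L
  m
}

## Control lattice covering the world extent of a volume with a one-knot
## margin on every side.
make_control_grid <- function(vol, h) {
  d <- dim(vol$data)
  lo <- vol$origin - vol$spacing / 2
  hi <- vol$origin + (d - 1 + 0.5) * vol$spacing
  gdim <- as.integer(ceiling((hi - lo) / h) + 4L)
  list(gdim = gdim, gorigin = lo - h, gspacing = rep(h, 3))
}

#' SSTVD cost of a given transform
#'
#' Evaluates the registration cost for an arbitrary transform without
#' optimizing: useful as a diagnostic and for comparing candidate warps.
#' An error is raised when more than 5% of the region of interest maps
#' outside the floating image extent.
#'
#' @param ref,flt Calibrated [scalar_volume()] reference / floating images.
#' @param ref_mask [mask_set()] on the reference grid; the cost is summed
#'   over the union of its lung/airway/vessel masks.
#' @param transform A `lung_transform` mapping reference world positions
#'   into the floating image.
#' @return Cost E in mm^6, with attributes `n_voxels` and `n_outside`.
#' @export
sstvd_cost <- function(ref, flt, ref_mask, transform) {
  check_same_geometry(ref, ref_mask)
  omega <- which(combined_mask(ref_mask))
  d <- dim(ref$data)
  ijk <- arrayInd(omega, d) - 1L
  pts <- voxel_coords(ref, ijk)
  y <- transform_points(transform, pts)
  det <- transform_jacobian(transform, pts)
  fd <- dim(flt$data)
  smp <- cpp_trilinear(as.numeric(flt$data), as.integer(fd), flt$spacing,
                       flt$origin, y, HU_AIR, TRUE)
  n_out <- sum(smp$outside)
  if (n_out > 0.05 * length(omega))
    stop(sprintf("transform maps %.1f%% of the ROI outside the floating image",
                 100 * n_out / length(omega)))
  vr <- voxel_volume(ref)
  vtr <- vr * tissue_fraction(ref$data[omega])
  vtf <- vr * det * tissue_fraction(smp$value)
  E <- sum((vtr - vtf)^2)
  attr(E, "n_voxels") <- length(omega)
  attr(E, "n_outside") <- n_out
  E
}

#' Fit a mass-preserving SSTVD registration
#'
#' Estimates the warp `T(x)` from the reference (later time point) grid
#' into the floating (earlier time point) image by minimizing the SSTVD
#' cost over a coarse-to-fine stack of cubic B-spline displacement levels.
#' Both images should be HU-calibrated (see [calibrate_hu()]).
#'
#' @param ref,flt [scalar_volume()] reference (Time 1) and floating
#'   (Time 0) images in a common world frame.
#' @param ref_mask [mask_set()] for the reference image; the union of its
#'   lung/airway/vessel masks defines the matching region.
#' @param flt_mask Optional [mask_set()] for the floating image (carried
#'   through to downstream mechanics; not used by the cost).
#' @param control A [reg_control()] settings list.
#' @return An object of class `sstvd_registration` with components
#'   `transform` (a [bspline_transform()]), `field` (dense
#'   [deformation_field()] on the reference grid), `cost_history`
#'   (data frame: level, eval, E, accepted), `converged`, `iterations`,
#'   `neg_jac_frac`, `outside_frac`. Methods: `print`, `summary`, `coef`,
#'   `predict`, `residuals`, `plot`.
#' @seealso [run_pair()] for the full pipeline including mechanics maps.
#' @export
sstvd_register <- function(ref, flt, ref_mask, flt_mask = NULL,
                           control = reg_control()) {
  stopifnot(inherits(ref, "scalar_volume"), inherits(flt, "scalar_volume"),
            inherits(ref_mask, "mask_set"), inherits(control, "reg_control"))
  check_same_geometry(ref, ref_mask)
  if (!is.null(flt_mask)) check_same_geometry(flt, flt_mask, "floating mask")
  h_fine <- control$control_spacing
  if (is.null(h_fine)) h_fine <- 4 * max(ref$spacing)
  omega_full <- combined_mask(ref_mask)

  fit_levels <- list()
  history <- list()
  total_iter <- 0L
  level_conv <- logical(0)
  for (l in seq_len(control$levels)) {
    f <- control$downsample[l]
    h <- h_fine * 2^(control$levels - l)
    ref_l <- downsample_volume(ref, f)
    flt_l <- downsample_volume(flt, f)
    om_l <- downsample_mask(omega_full, f)
    if (!any(om_l)) stop("registration ROI vanished after downsampling")
    d_l <- dim(ref_l$data)
    ijk <- arrayInd(which(om_l), d_l) - 1L
    pts <- voxel_coords(ref_l, ijk)
    vr_l <- voxel_volume(ref_l)
    vtr <- vr_l * tissue_fraction(ref_l$data[om_l])
    grid <- make_control_grid(ref_l, h)
    ncp <- prod(grid$gdim)

    ## displacement and derivative tensor of the already-fitted levels
    if (length(fit_levels) > 0L) {
      uprev <- matrix(0, nrow(pts), 3)
      gprev <- matrix(0, nrow(pts), 9)
      for (lv in fit_levels) {
        r <- cpp_bspline_disp(pts, lv$coef, as.integer(lv$gdim),
                              lv$gorigin, lv$gspacing, TRUE)
        uprev <- uprev + r$u
        gprev <- gprev + r$G
      }
    } else {
      uprev <- matrix(0, 0, 3)
      gprev <- matrix(0, 0, 9)
    }

    fd_l <- dim(flt_l$data)
    flt_vec <- as.numeric(flt_l$data)
    evalcache <- new.env(parent = emptyenv())
    evalcache$par <- NULL
    evals <- numeric(0)
    eval_fn <- function(p, want_grad) {
      if (!identical(p, evalcache$par) ||
          (want_grad && is.null(evalcache$res$grad))) {
        evalcache$res <- cpp_sstvd_cost(
          flt_vec, as.integer(fd_l), flt_l$spacing, flt_l$origin,
          pts, vtr, vr_l, matrix(p, ncp, 3), as.integer(grid$gdim),
          grid$gorigin, grid$gspacing, uprev, gprev,
          HU_AIR, HU_TISSUE, want_grad)
        evalcache$par <- p
      }
      evalcache$res
    }
    fn <- function(p) {
      r <- eval_fn(p, FALSE)
      evals[length(evals) + 1L] <<- r$E
      if (!is.finite(r$E)) {
        hist_df <- do.call(rbind, history)
        stop(structure(class = c("sstvd_divergence", "error", "condition"),
                       list(message = "registration cost diverged",
                            call = sys.call(-1), history = hist_df)))
      }
      r$E
    }
    gr <- function(p) as.numeric(eval_fn(p, TRUE)$grad)
    bound <- control$coef_bound * h
    opt <- stats::optim(rep(0, 3 * ncp), fn, gr, method = "L-BFGS-B",
                        lower = -bound, upper = bound,
                        control = list(maxit = control$maxit,
                                       factr = control$rel_tol / 1e-15,
                                       pgtol = 0))
    accepted <- cummin(evals)
    history[[l]] <- data.frame(level = l, eval = seq_along(evals),
                               E = evals, accepted = accepted)
    total_iter <- total_iter + opt$counts[["function"]]
    ## converged: optimizer satisfied its criterion, or the last tol_iters
    ## accepted evaluations changed the cost by < rel_tol relatively
    tail_ok <- FALSE
    k <- control$tol_iters
    if (length(accepted) > k) {
      a <- accepted[(length(accepted) - k):length(accepted)]
      tail_ok <- (a[1] - a[length(a)]) <= control$rel_tol * max(a[1], 1e-300)
    }
    level_conv[l] <- opt$convergence == 0L || tail_ok
    fit_levels[[l]] <- list(gdim = grid$gdim, gorigin = grid$gorigin,
                            gspacing = grid$gspacing,
                            coef = matrix(opt$par, ncp, 3))
    if (control$verbose)
      message(sprintf("level %d (ds %d, h %.1f mm): E %.4g -> %.4g, %d evals",
                      l, f, h, evals[1], min(evals), length(evals)))
  }

  transform <- bspline_transform(fit_levels)
  field <- as_deformation_field(transform, ref)

  ## final diagnostics over the full-resolution lung ROI
  ijk <- arrayInd(which(omega_full), dim(ref$data)) - 1L
  pts <- voxel_coords(ref, ijk)
  det <- transform_jacobian(transform, pts)
  y <- transform_points(transform, pts)
  outs <- cpp_trilinear(as.numeric(flt$data), as.integer(dim(flt$data)),
                        flt$spacing, flt$origin, y, HU_AIR, FALSE)$outside
  neg_frac <- mean(det <= 0)
  if (neg_frac > 0.01)
    warning(sprintf(paste0("non-positive Jacobian in %.2f%% of the lung ",
                           "ROI; treat this registration with caution"),
                    100 * neg_frac))
  res <- structure(list(
    transform = transform, field = field,
    cost_history = do.call(rbind, history),
    converged = all(level_conv), level_converged = level_conv,
    iterations = total_iter, neg_jac_frac = neg_frac,
    outside_frac = mean(outs),
    control = control,
    ref = ref, flt = flt, ref_mask = ref_mask, flt_mask = flt_mask,
    call = match.call()), class = "sstvd_registration")
  res
}

#' @export
print.sstvd_registration <- function(x, ...) {
  hf <- x$cost_history
  cat("Mass-preserving SSTVD B-spline registration\n")
  cat(sprintf("  levels: %d, cost %.4g -> %.4g (%d evaluations)\n",
              x$control$levels, hf$E[1], min(hf$accepted), nrow(hf)))
  cat(sprintf("  converged: %s; negative-Jacobian fraction: %.3g%%\n",
              ifelse(x$converged, "yes", "no"), 100 * x$neg_jac_frac))
  invisible(x)
}

#' @export
summary.sstvd_registration <- function(object, ...) {
  hf <- object$cost_history
  per_level <- do.call(rbind, lapply(split(hf, hf$level), function(h)
    data.frame(level = h$level[1], evals = nrow(h), E_start = h$E[1],
               E_final = min(h$accepted))))
  u <- matrix(object$field$disp, ncol = 3)
  mag <- sqrt(rowSums(u^2))
  out <- list(per_level = per_level, converged = object$converged,
              iterations = object$iterations,
              neg_jac_frac = object$neg_jac_frac,
              outside_frac = object$outside_frac,
              max_displacement = max(mag), mean_displacement = mean(mag))
  class(out) <- "summary.sstvd_registration"
  out
}

#' @export
print.summary.sstvd_registration <- function(x, ...) {
  cat("SSTVD registration summary\n")
  print(x$per_level, row.names = FALSE)
  cat(sprintf("converged: %s; max |u| = %.3f mm; negative J: %.3g%%\n",
              ifelse(x$converged, "yes", "no"), x$max_displacement,
              100 * x$neg_jac_frac))
  invisible(x)
}

#' @export
coef.sstvd_registration <- function(object, ...) {
  lapply(object$transform$levels, `[[`, "coef")
}

#' Map points or resample an image through a fitted registration
#'
#' With a matrix `newdata`, returns the warped world positions `T(x)`;
#' with a [scalar_volume()], returns the floating image resampled onto the
#' reference grid (see [warp_image()]); with `NULL`, the dense displacement
#' field.
#'
#' @param object A fitted `sstvd_registration`.
#' @param newdata n x 3 matrix of world points, a `scalar_volume`, or NULL.
#' @param ... Unused.
#' @export
predict.sstvd_registration <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$field)
  if (is.matrix(newdata)) return(transform_points(object$transform, newdata))
  if (inherits(newdata, "scalar_volume"))
    return(warp_image(newdata, object$transform, object$ref))
  stop("`newdata` must be a point matrix, a scalar_volume, or NULL")
}

#' Per-voxel tissue-volume residuals of a fitted registration
#'
#' @param object A fitted `sstvd_registration`.
#' @param ... Unused.
#' @return Numeric vector `vt_r(x) - vt_f(T(x))` (mm^3) over the ROI.
#' @export
residuals.sstvd_registration <- function(object, ...) {
  omega <- which(combined_mask(object$ref_mask))
  ijk <- arrayInd(omega, dim(object$ref$data)) - 1L
  pts <- voxel_coords(object$ref, ijk)
  y <- transform_points(object$transform, pts)
  det <- transform_jacobian(object$transform, pts)
  smp <- cpp_trilinear(as.numeric(object$flt$data),
                       as.integer(dim(object$flt$data)),
                       object$flt$spacing, object$flt$origin, y, HU_AIR, TRUE)
  vr <- voxel_volume(object$ref)
  vr * tissue_fraction(object$ref$data[omega]) -
    vr * det * tissue_fraction(smp$value)
}

#' Plot the cost convergence of a registration
#'
#' One curve of the accepted (monotone) cost per resolution level against
#' cumulative evaluation count, on a log cost axis.
#'
#' @param x A fitted `sstvd_registration`. @param ... Passed to `plot`.
#' @export
plot.sstvd_registration <- function(x, ...) {
  hf <- x$cost_history
  hf$cum <- seq_len(nrow(hf))
  graphics::plot(hf$cum, hf$accepted, type = "n", log = "y",
                 xlab = "cost evaluation", ylab = "SSTVD cost E (mm^6)", ...)
  for (l in unique(hf$level)) {
    h <- hf[hf$level == l, ]
    graphics::lines(h$cum, h$accepted, col = l, lwd = 2)
  }
  graphics::legend("topright", legend = paste("level", unique(hf$level)),
                   col = unique(hf$level), lwd = 2, bty = "n")
  invisible(x)
}

#' Resample the floating image onto the reference grid
#'
#' Samples `flt` at `T(x)` for every reference voxel centre with trilinear
#' interpolation. Samples falling outside the floating extent are filled
#' with -1000 HU; their count is attached as attribute `n_outside`.
#'
#' @param flt Floating [scalar_volume()].
#' @param transform A `lung_transform` (or fitted `sstvd_registration`).
#' @param ref Reference [scalar_volume()] supplying the target grid.
#' @return A [scalar_volume()] on the reference grid.
#' @export
warp_image <- function(flt, transform, ref) {
  if (inherits(transform, "sstvd_registration")) transform <- transform$transform
  pts <- voxel_coords(ref)
  y <- transform_points(transform, pts)
  smp <- cpp_trilinear(as.numeric(flt$data), as.integer(dim(flt$data)),
                       flt$spacing, flt$origin, y, HU_AIR, FALSE)
  out <- scalar_volume(array(smp$value, dim(ref$data)),
                       spacing = ref$spacing, origin = ref$origin)
  attr(out, "n_outside") <- sum(smp$outside)
  out
}
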