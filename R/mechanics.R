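## Normalized regional lung mechanics.
##
## With J = v^r / v^f the local reference-to-floating volume ratio and
## V^r, V^f the global lung volumes, the normalized fractional volume
## change is
##
##   Delta* = J * V^f / V^r - 1
##
## so uniform global inflation gives Delta* = 0 everywhere, and
## Delta* = 0.5 means the region's contribution to the global lung volume
## grew by 50% between the two time points. The analogous air and tissue
## indices replace the volume ratio by the component-volume ratios at
## matched points.

#' Normalized fractional volume change map
#'
#' `Delta*(x) = J(x) * Vf / Vr - 1`, where `J = v^r/v^f` is the
#' reference/floating volume ratio (reciprocal of `det(dT/dx)` under this
#' package's warp convention) and `Vf`, `Vr` the global floating and
#' reference lung volumes.
#'
#' @param J Per-voxel volume ratio (vector or array), finite.
#' @param Vf,Vr Global lung volumes (mm^3), positive.
#' @return Delta* with the shape of `J`.
#' @examples
#' delta_star_map(1.2, Vf = 1.25, Vr = 1)  # 0.5
#' @export
delta_star_map <- function(J, Vf, Vr) {
  if (!is.finite(Vf) || !is.finite(Vr) || Vf <= 0 || Vr <= 0)
    stop("global lung volumes must be positive")
  J * (Vf / Vr) - 1
}

#' Normalized fractional air volume change map
#'
#' `Delta_air*(x) = (v_air^r / v_air^f) * Vf / Vr - 1` at matched points.
#'
#' @param vair_r,vair_f Per-voxel air volumes (mm^3) of the reference voxel
#'   and the matched floating region.
#' @param Vf,Vr Global lung volumes (mm^3), positive.
#' @return Delta_air*, `NA` where `vair_f` is not positive.
#' @export
delta_air_star_map <- function(vair_r, vair_f, Vf, Vr) {
  if (!is.finite(Vf) || !is.finite(Vr) || Vf <= 0 || Vr <= 0)
    stop("global lung volumes must be positive")
  out <- ifelse(vair_f > 0, (vair_r / vair_f) * (Vf / Vr) - 1, NA_real_)
  if (is.array(vair_r)) dim(out) <- dim(vair_r)
  out
}

#' Normalized fractional tissue volume change map
#'
#' `Delta_tissue*(x) = (v_tissue^r / v_tissue^f) * Vf / Vr - 1` at matched
#' points.
#'
#' @inheritParams delta_air_star_map
#' @param vtis_r,vtis_f Per-voxel tissue volumes (mm^3).
#' @return Delta_tissue*, `NA` where `vtis_f` is not positive.
#' @export
delta_tissue_star_map <- function(vtis_r, vtis_f, Vf, Vr) {
  if (!is.finite(Vf) || !is.finite(Vr) || Vf <= 0 || Vr <= 0)
    stop("global lung volumes must be positive")
  out <- ifelse(vtis_f > 0, (vtis_r / vtis_f) * (Vf / Vr) - 1, NA_real_)
  if (is.array(vtis_r)) dim(out) <- dim(vtis_r)
  out
}

#' Voxel-wise mechanics maps for a registered pair
#'
#' Computes J, Delta*, Delta_air* and Delta_tissue* on the reference lung
#' mask for any transform (a fitted [sstvd_register()] result or an
#' analytic `lung_transform`). Floating-side per-voxel volumes use the
#' mass-preserving matched volume `v^f = v_r * det(dT/dx)` split into air
#' and tissue by the interpolated floating intensity, which makes the
#' additive identity
#' `(1+Delta*) v^f = (1+Delta_air*) v_air^f + (1+Delta_tissue*) v_tissue^f`
#' hold exactly wherever all three maps are defined.
#'
#' Voxels whose floating air or tissue volume falls below `1e-6 * v_r`, or
#' that map outside the floating image, are excluded from the respective
#' map and counted.
#'
#' @param ref,flt Calibrated [scalar_volume()] images.
#' @param ref_mask,flt_mask [mask_set()] objects for each image.
#' @param transform `lung_transform` or fitted `sstvd_registration` mapping
#'   reference positions into the floating image.
#' @param exclude_vessels Drop vessel-mask voxels from the lung
#'   aggregation (limits contrast-agent influence).
#' @param erosion Integer number of 6-neighbourhood erosions applied to the
#'   lung domain before mapping (0 = none); discounts boundary artifacts.
#' @return Object of class `mechanics_maps`: 3D arrays `J`, `delta_star`,
#'   `delta_air_star`, `delta_tissue_star` (`NA` off-domain), the global
#'   volumes `Vr`, `Vf`, the logical `domain`, and exclusion counts.
#' @export
mechanics_maps <- function(ref, flt, ref_mask, flt_mask, transform,
                           exclude_vessels = FALSE, erosion = 0L) {
  if (inherits(transform, "sstvd_registration")) transform <- transform$transform
  check_same_geometry(ref, ref_mask)
  check_same_geometry(flt, flt_mask, "floating mask")
  dom <- ref_mask$lung != 0L
  if (exclude_vessels && !is.null(ref_mask$vessels))
    dom <- dom & ref_mask$vessels == 0L
  if (erosion > 0L) dom <- erode_mask(dom, erosion)
  if (!any(dom)) stop("mechanics_maps: empty lung domain")

  d <- dim(ref$data)
  v_r <- voxel_volume(ref)
  v_f <- voxel_volume(flt)
  fdom <- flt_mask$lung != 0L
  if (exclude_vessels && !is.null(flt_mask$vessels))
    fdom <- fdom & flt_mask$vessels == 0L
  Vr <- sum(dom) * v_r
  Vf <- sum(fdom) * v_f

  idx <- which(dom)
  ijk <- arrayInd(idx, d) - 1L
  pts <- voxel_coords(ref, ijk)
  det <- transform_jacobian(transform, pts)
  y <- transform_points(transform, pts)
  smp <- cpp_trilinear(as.numeric(flt$data), as.integer(dim(flt$data)),
                       flt$spacing, flt$origin, y, NA_real_, FALSE)
  n_outside <- sum(smp$outside)

  frac_r <- tissue_fraction(ref$data[idx])
  vtis_r <- v_r * frac_r
  vair_r <- v_r - vtis_r
  ok <- !smp$outside & det > 0
  frac_f <- rep(NA_real_, length(idx))
  frac_f[ok] <- tissue_fraction(smp$value[ok])
  vf_matched <- v_r * det           # matched floating volume per ref voxel
  vtis_f <- vf_matched * frac_f
  vair_f <- vf_matched - vtis_f
  n_negdet <- sum(det <= 0)

  fill <- function(vals) {
    a <- array(NA_real_, d)
    a[idx] <- vals
    a
  }
  J <- fill(ifelse(ok, 1 / det, NA_real_))
  ds <- fill(ifelse(ok, delta_star_map(1 / det, Vf, Vr), NA_real_))
  eps <- 1e-6 * v_r
  da_v <- rep(NA_real_, length(idx))
  sel <- ok & !is.na(vair_f) & vair_f >= eps
  da_v[sel] <- delta_air_star_map(vair_r[sel], vair_f[sel], Vf, Vr)
  dt_v <- rep(NA_real_, length(idx))
  selt <- ok & !is.na(vtis_f) & vtis_f >= eps
  dt_v[selt] <- delta_tissue_star_map(vtis_r[selt], vtis_f[selt], Vf, Vr)

  structure(list(
    J = J, delta_star = ds, delta_air_star = fill(da_v),
    delta_tissue_star = fill(dt_v), domain = dom, Vr = Vr, Vf = Vf,
    v_r = v_r, n_outside = n_outside, n_negdet = n_negdet,
    n_air_excluded = sum(ok) - sum(sel),
    n_tissue_excluded = sum(ok) - sum(selt),
    vair_r = fill(vair_r), vair_f = fill(vair_f),
    vtis_r = fill(vtis_r), vtis_f = fill(vtis_f)),
    class = "mechanics_maps")
}

#' @export
print.mechanics_maps <- function(x, ...) {
  n <- sum(x$domain)
  cat(sprintf("<mechanics_maps> %d lung voxels; Vr = %.1f mL, Vf = %.1f mL\n",
              n, x$Vr / 1000, x$Vf / 1000))
  q <- stats::quantile(x$delta_star[x$domain], c(0.05, 0.5, 0.95), na.rm = TRUE)
  cat(sprintf("  Delta* quantiles (5/50/95%%): %.3f / %.3f / %.3f\n",
              q[1], q[2], q[3]))
  invisible(x)
}

## 6-neighbourhood binary erosion, n iterations.
erode_mask <- function(m, n) {
  d <- dim(m)
  for (it in seq_len(n)) {
    keep <- m
    shift <- function(arr, axis, by) {
      out <- array(FALSE, d)
      src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
      nn <- d[axis]
      if (by > 0) { src[[axis]] <- 1:(nn - 1); dst[[axis]] <- 2:nn }
      else { src[[axis]] <- 2:nn; dst[[axis]] <- 1:(nn - 1) }
      out[dst[[1]], dst[[2]], dst[[3]]] <- arr[src[[1]], src[[2]], src[[3]]]
      out
    }
    for (axis in 1:3) for (by in c(-1, 1))
      keep <- keep & shift(m, axis, by)
    m <- keep
  }
  m
}

#' Threshold-based hyper-expansion summary
#'
#' For each threshold t, the percent of lung volume where `Delta* >= t`
#' (and analogously for `Delta_tissue*`); the pair-level hyperinflation
#' flag at each lung-volume cutoff, using the 50% threshold index; and a
#' split of the hyper-expanded (Delta* >= 0.5) voxels by the sign of their
#' normalized air-content change.
#'
#' @param maps A [mechanics_maps()] result (or a compatible list carrying
#'   `delta_star`, `delta_tissue_star`, `delta_air_star`, `domain`).
#' @param thresholds Fractional thresholds; defaults 0.2, 0.5, 1.0.
#' @param cutoffs Pair-classification cutoffs, in percent of lung volume;
#'   defaults 0.1, 0.5, 1, 2.
#' @return Object of class `expansion_summary`: data frame `by_threshold`
#'   (threshold, pct_lung_hyper, pct_lung_tissue_exp), `pct_hyper_at_50`,
#'   `pct_tissue_exp_at_50`, logical `pair_hyperinflated` (named by
#'   cutoff), and `air_sign` counts among hyper-expanded voxels.
#' @export
expansion_summary <- function(maps, thresholds = c(0.2, 0.5, 1.0),
                              cutoffs = c(0.1, 0.5, 1, 2)) {
  dom <- maps$domain
  if (is.null(dom) || !any(dom)) stop("expansion_summary: empty lung domain")
  n <- sum(dom)
  ds <- maps$delta_star[dom]
  dt <- maps$delta_tissue_star[dom]
  pct <- function(v, t) 100 * sum(!is.na(v) & v >= t) / n
  by_thr <- data.frame(
    threshold = thresholds,
    pct_lung_hyper = vapply(thresholds, function(t) pct(ds, t), 0),
    pct_lung_tissue_exp = vapply(thresholds, function(t) pct(dt, t), 0))
  p50 <- pct(ds, 0.5)
  p50_t <- pct(dt, 0.5)
  hyper <- !is.na(ds) & ds >= 0.5
  da <- maps$delta_air_star[dom]
  air_sign <- c(increase = sum(hyper & !is.na(da) & da > 0),
                decrease = sum(hyper & !is.na(da) & da < 0))
  flags <- p50 >= cutoffs
  names(flags) <- paste0(cutoffs, "%")
  structure(list(by_threshold = by_thr, pct_hyper_at_50 = p50,
                 pct_tissue_exp_at_50 = p50_t, pair_hyperinflated = flags,
                 cutoffs = cutoffs, air_sign = air_sign, n_lung = n),
            class = "expansion_summary")
}

#' @export
print.expansion_summary <- function(x, ...) {
  cat("Hyper-expansion summary (% of lung volume at or above threshold)\n")
  print(transform(x$by_threshold,
                  pct_lung_hyper = signif(pct_lung_hyper, 4),
                  pct_lung_tissue_exp = signif(pct_lung_tissue_exp, 4)),
        row.names = FALSE)
  cat(sprintf("pair hyperinflated (Delta50%%* = %.3g%%): %s\n",
              x$pct_hyper_at_50,
              paste(sprintf("%s:%s", names(x$pair_hyperinflated),
                            ifelse(x$pair_hyperinflated, "yes", "no")),
                    collapse = " ")))
  cat(sprintf("air content in hyper-expanded voxels: %d increased, %d decreased\n",
              x$air_sign["increase"], x$air_sign["decrease"]))
  invisible(x)
}

#' Full serial-pair pipeline: calibrate, register, map, summarize
#'
#' Runs HU calibration (when ROIs are supplied), SSTVD registration,
#' Jacobian/Delta-map computation and the threshold summary for one pair
#' of serial CT volumes.
#'
#' @param ref,flt Reference (Time 1) and floating (Time 0)
#'   [scalar_volume()] images.
#' @param ref_mask,flt_mask [mask_set()] objects.
#' @param control [reg_control()] registration settings.
#' @param thresholds,cutoffs Passed to [expansion_summary()].
#' @param ref_rois,flt_rois Optional [calibration_rois()] per image; when
#'   given, [calibrate_hu()] is applied first.
#' @param exclude_vessels,erosion Passed to [mechanics_maps()].
#' @return Object of class `lung_mechanics` with components
#'   `registration`, `maps`, `summary`, plus the calibrated inputs.
#' @export
run_pair <- function(ref, flt, ref_mask, flt_mask, control = reg_control(),
                     thresholds = c(0.2, 0.5, 1.0),
                     cutoffs = c(0.1, 0.5, 1, 2),
                     ref_rois = NULL, flt_rois = NULL,
                     exclude_vessels = FALSE, erosion = 0L) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(ref_rois)) ref <- stage("calibrate", calibrate_hu(ref, ref_rois))
  if (!is.null(flt_rois)) flt <- stage("calibrate", calibrate_hu(flt, flt_rois))
  reg <- stage("register",
               sstvd_register(ref, flt, ref_mask, flt_mask, control))
  maps <- stage("mechanics",
                mechanics_maps(ref, flt, ref_mask, flt_mask, reg$transform,
                               exclude_vessels = exclude_vessels,
                               erosion = erosion))
  summ <- stage("summary", expansion_summary(maps, thresholds, cutoffs))
  structure(list(registration = reg, maps = maps, summary = summ,
                 thresholds = thresholds, cutoffs = cutoffs),
            class = "lung_mechanics")
}

#' @export
print.lung_mechanics <- function(x, ...) {
  print(x$registration)
  print(x$maps)
  print(x$summary)
  invisible(x)
}

#' One-row record of a pair's expansion indices
#'
#' Flattens an [expansion_summary()] into the per-pair record format
#' consumed by [group_table()] and [classify_pairs()].
#'
#' @param summary An `expansion_summary` (or `lung_mechanics`).
#' @param subject,pair,group Identifiers attached to the row.
#' @return One-row data frame with `pct_hyper_at_50`,
#'   `pct_tissue_exp_at_50` and the identifier columns.
#' @export
pair_record <- function(summary, subject = NA, pair = NA, group = NA) {
  if (inherits(summary, "lung_mechanics")) summary <- summary$summary
  stopifnot(inherits(summary, "expansion_summary"))
  data.frame(subject = subject, pair = pair, group = group,
             pct_hyper_at_50 = summary$pct_hyper_at_50,
             pct_tissue_exp_at_50 = summary$pct_tissue_exp_at_50,
             stringsAsFactors = FALSE)
}
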