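## Air/tissue decomposition of CT density.
##
## Each voxel of geometric volume v is split into an air and a "tissue"
## (non-air: tissue, blood, fluid, cells, contrast) compartment from its
## HU value, linearly between HU_air = -1000 and HU_tissue = +55:
##   v_tissue = v * (I - HU_air) / (HU_tissue - HU_air),  v_air = v - v_tissue.

HU_AIR <- -1000
HU_TISSUE <- 55

#' Tissue fraction of a voxel from its CT intensity
#'
#' Maps HU linearly to the fractional non-air content, clamping intensities
#' to the air/tissue anchor range so the result lies in \[0, 1\]:
#' -1000 HU (pure air) gives 0, +55 HU (pure soft tissue) gives 1.
#'
#' @param intensity Numeric vector or array of HU values (finite).
#' @return Tissue fraction(s) in \[0, 1\], same shape as the input.
#' @examples
#' tissue_fraction(c(-1000, -472.5, 55))
#' @export
tissue_fraction <- function(intensity) {
  if (any(!is.finite(intensity)))
    stop("tissue_fraction: non-finite intensity")
  f <- (pmin(pmax(intensity, HU_AIR), HU_TISSUE) - HU_AIR) /
    (HU_TISSUE - HU_AIR)
  if (is.array(intensity)) dim(f) <- dim(intensity)
  f
}

#' Per-voxel air/tissue volume decomposition
#'
#' Applies [tissue_fraction()] over the lung mask and scales by the voxel
#' volume, so that `v_air + v_tissue` equals the geometric voxel volume
#' exactly at every voxel. Voxels outside the lung mask are `NA`.
#'
#' @param vol A calibrated [scalar_volume()] in HU.
#' @param mask A [mask_set()] sharing the volume's grid.
#' @param exclude_vessels If `TRUE` and a vessel mask is present, vessel
#'   voxels are dropped from the decomposition domain (useful to limit the
#'   influence of intravascular contrast on parenchymal densitometry).
#' @return An object of class `density_decomposition` with 3D arrays
#'   `tissue_volume` and `air_volume` (mm^3, `NA` off-domain), the logical
#'   `domain`, and the voxel volume `v`.
#' @export
decompose <- function(vol, mask, exclude_vessels = FALSE) {
  stopifnot(inherits(vol, "scalar_volume"), inherits(mask, "mask_set"))
  check_same_geometry(vol, mask)
  dom <- mask$lung != 0L
  if (exclude_vessels && !is.null(mask$vessels))
    dom <- dom & mask$vessels == 0L
  if (!any(dom)) stop("decompose: empty lung domain")
  v <- voxel_volume(vol)
  vt <- array(NA_real_, dim(vol$data))
  vt[dom] <- v * tissue_fraction(vol$data[dom])
  va <- array(NA_real_, dim(vol$data))
  va[dom] <- v - vt[dom]
  structure(list(tissue_volume = vt, air_volume = va, domain = dom, v = v,
                 hu_air = HU_AIR, hu_tissue = HU_TISSUE),
            class = "density_decomposition")
}

#' @export
print.density_decomposition <- function(x, ...) {
  n <- sum(x$domain)
  cat(sprintf("<density_decomposition> %d lung voxels, voxel volume %.3f mm^3\n",
              n, x$v))
  cat(sprintf("  mean tissue fraction %.3f\n",
              mean(x$tissue_volume[x$domain]) / x$v))
  invisible(x)
}

#' Global lung air, tissue and geometric volumes
#'
#' Sums the decomposition over its lung domain. The identity
#' `V = V_air + V_tissue` holds exactly.
#'
#' @param d A [decompose()] result.
#' @return A list with `V`, `V_air`, `V_tissue` (mm^3) and `n_voxels`.
#' @export
global_volumes <- function(d) {
  stopifnot(inherits(d, "density_decomposition"))
  Vt <- sum(d$tissue_volume[d$domain])
  n <- sum(d$domain)
  V <- n * d$v
  list(V = V, V_air = V - Vt, V_tissue = Vt, n_voxels = n)
}
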