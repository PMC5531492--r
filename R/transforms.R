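## Spatial transforms T(x) = x + u(x), world coordinates in mm.
##
## The warp convention throughout the package: T maps positions on the
## REFERENCE (later time point, Time 1) grid into the FLOATING (earlier,
## Time 0) image. det(dT/dx) is then the floating volume matched to a unit
## of reference volume; the volume-ratio convention J = v^r / v^f is its
## reciprocal (see jacobian_field()).

#' Affine transform
#'
#' `T(x) = A x + b` with constant Jacobian `det(A)`.
#'
#' @param A 3x3 matrix. @param b Length-3 translation (mm).
#' @return An object of class `c("affine_transform", "lung_transform")`.
#' @export
affine_transform <- function(A = diag(3), b = c(0, 0, 0)) {
  A <- matrix(as.numeric(A), 3, 3)
  b <- as.numeric(b)
  stopifnot(length(b) == 3L, all(is.finite(A)), all(is.finite(b)))
  structure(list(A = A, b = b),
            class = c("affine_transform", "lung_transform"))
}

#' Uniform / anisotropic scaling about a centre
#'
#' Convenience constructor: `T(x) = c + diag(s) (x - c)`.
#'
#' @param s Scale factor(s), length 1 or 3. @param center Fixed point (mm).
#' @export
scaling_transform <- function(s, center = c(0, 0, 0)) {
  s <- rep_len(as.numeric(s), 3L)
  A <- diag(s)
  affine_transform(A, b = as.numeric(center) - A %*% as.numeric(center))
}

#' Radial expansion transform with a C1 falloff shell
#'
#' A spherically symmetric map about `center`: inside the core radius
#' `r_core` it is the pure scaling `T(x) = center + s (x - center)` with
#' constant Jacobian `s^3`; beyond `r_core + width` it is the identity; in
#' the shell the radial profile is a monotone cubic Hermite blend, so the
#' map is C1 and invertible for the scales used here. `s < 1` contracts
#' reference positions towards the centre, i.e. the region has *expanded*
#' from the floating to the reference time point (volume ratio J = 1/s^3 > 1).
#'
#' @param center Length-3 world centre (mm).
#' @param r_core Core radius (mm). @param width Shell width (mm).
#' @param s Core scale factor (> 0).
#' @export
radial_transform <- function(center, r_core, width, s) {
  stopifnot(r_core > 0, width > 0, s > 0)
  structure(list(center = as.numeric(center), r_core = r_core,
                 width = width, s = s),
            class = c("radial_transform", "lung_transform"))
}

## Radial profile rho(r) and derivative: rho = s*r on [0, r1], Hermite blend
## on [r1, r2] with end values (s*r1, r2) and end slopes (s, 1), identity
## beyond.
radial_profile <- function(tr, r) {
  r1 <- tr$r_core
  r2 <- r1 + tr$width
  s <- tr$s
  h <- r2 - r1
  rho <- ifelse(r <= r1, s * r, r)
  drho <- ifelse(r <= r1, s, 1)
  mid <- r > r1 & r < r2
  if (any(mid)) {
    t <- (r[mid] - r1) / h
    h00 <- 2 * t^3 - 3 * t^2 + 1
    h10 <- t^3 - 2 * t^2 + t
    h01 <- -2 * t^3 + 3 * t^2
    h11 <- t^3 - t^2
    rho[mid] <- h00 * (s * r1) + h10 * h * s + h01 * r2 + h11 * h * 1
    ## d/dr = h00'(t)/h * p0 + h10'(t) * m0 + h01'(t)/h * p1 + h11'(t) * m1
    d00 <- (6 * t^2 - 6 * t) / h
    d10 <- (3 * t^2 - 4 * t + 1)
    d01 <- (-6 * t^2 + 6 * t) / h
    d11 <- (3 * t^2 - 2 * t)
    drho[mid] <- d00 * (s * r1) + d10 * s + d01 * r2 + d11 * 1
  }
  list(rho = rho, drho = drho)
}

#' Composite of two transforms
#'
#' `T(x) = outer(inner(x))`; the Jacobian determinant is the product of the
#' factors' determinants evaluated at the matched points.
#'
#' @param outer,inner `lung_transform` objects.
#' @export
composite_transform <- function(outer, inner) {
  stopifnot(inherits(outer, "lung_transform"), inherits(inner, "lung_transform"))
  if (inherits(outer, "affine_transform") && inherits(inner, "affine_transform"))
    return(affine_transform(outer$A %*% inner$A,
                            outer$A %*% inner$b + outer$b))
  structure(list(outer = outer, inner = inner),
            class = c("composite_transform", "lung_transform"))
}

#' Multilevel B-spline free-form deformation
#'
#' Additive stack of cubic B-spline displacement levels:
#' `T(x) = x + sum_l u_l(x)`. Each level carries its own control lattice
#' (dims, origin, spacing in mm) and an (ncp x 3) coefficient matrix.
#'
#' @param levels List of levels, each `list(gdim, gorigin, gspacing, coef)`.
#' @export
bspline_transform <- function(levels) {
  stopifnot(is.list(levels), length(levels) >= 1L)
  for (lv in levels)
    stopifnot(nrow(lv$coef) == prod(lv$gdim), ncol(lv$coef) == 3L)
  structure(list(levels = levels),
            class = c("bspline_transform", "lung_transform"))
}

#' Identity transform
#' @export
identity_transform <- function() affine_transform(diag(3), c(0, 0, 0))

#' Map points through a transform
#'
#' @param transform A `lung_transform`.
#' @param pts n x 3 matrix of world positions (mm).
#' @return n x 3 matrix `T(pts)`.
#' @export
transform_points <- function(transform, pts) {
  UseMethod("transform_points")
}

#' @export
transform_points.affine_transform <- function(transform, pts) {
  sweep(pts %*% t(transform$A), 2, transform$b, "+")
}

#' @export
transform_points.radial_transform <- function(transform, pts) {
  d <- sweep(pts, 2, transform$center)
  r <- sqrt(rowSums(d^2))
  p <- radial_profile(transform, r)
  fac <- ifelse(r > 0, p$rho / r, transform$s)
  sweep(d * fac, 2, transform$center, "+")
}

#' @export
transform_points.composite_transform <- function(transform, pts) {
  transform_points(transform$outer, transform_points(transform$inner, pts))
}

#' @export
transform_points.bspline_transform <- function(transform, pts) {
  u <- matrix(0, nrow(pts), 3)
  for (lv in transform$levels) {
    r <- cpp_bspline_disp(pts, lv$coef, as.integer(lv$gdim),
                          lv$gorigin, lv$gspacing, FALSE)
    u <- u + r$u
  }
  pts + u
}

#' Analytic Jacobian determinant of a transform at points
#'
#' Returns `det(dT/dx)` — the floating-volume-per-reference-volume ratio
#' under the package's warp convention. For affine maps this is exact; for
#' the radial map it is the closed form `rho'(r) (rho/r)^2`; for B-spline
#' stacks it uses the analytic basis derivatives.
#'
#' @param transform A `lung_transform`. @param pts n x 3 world points (mm).
#' @return Numeric vector of determinants.
#' @export
transform_jacobian <- function(transform, pts) {
  UseMethod("transform_jacobian")
}

#' @export
transform_jacobian.affine_transform <- function(transform, pts) {
  rep(det(transform$A), nrow(pts))
}

#' @export
transform_jacobian.radial_transform <- function(transform, pts) {
  d <- sweep(pts, 2, transform$center)
  r <- sqrt(rowSums(d^2))
  p <- radial_profile(transform, r)
  ifelse(r > 0, p$drho * (p$rho / r)^2, transform$s^3)
}

#' @export
transform_jacobian.composite_transform <- function(transform, pts) {
  ji <- transform_jacobian(transform$inner, pts)
  jo <- transform_jacobian(transform$outer,
                           transform_points(transform$inner, pts))
  jo * ji
}

#' @export
transform_jacobian.bspline_transform <- function(transform, pts) {
  G <- matrix(0, nrow(pts), 9)
  for (lv in transform$levels) {
    r <- cpp_bspline_disp(pts, lv$coef, as.integer(lv$gdim),
                          lv$gorigin, lv$gspacing, TRUE)
    G <- G + r$G
  }
  det_from_G(G)
}

## det(I + G) per row; G columns ordered du_a/dx_b for a, b in row-major
## (a0b0 a0b1 a0b2 a1b0 ...), matching cpp_bspline_disp.
det_from_G <- function(G) {
  F11 <- 1 + G[, 1]; F12 <- G[, 2]; F13 <- G[, 3]
  F21 <- G[, 4]; F22 <- 1 + G[, 5]; F23 <- G[, 6]
  F31 <- G[, 7]; F32 <- G[, 8]; F33 <- 1 + G[, 9]
  F11 * (F22 * F33 - F23 * F32) - F12 * (F21 * F33 - F23 * F31) +
    F13 * (F21 * F32 - F22 * F31)
}

## ---- sampled displacement fields ----------------------------------------

#' Dense displacement field on a reference grid
#'
#' @param disp 4D array (nx, ny, nz, 3) of displacements in mm.
#' @param spacing,origin Reference grid geometry (mm).
#' @return An object of class `c("deformation_field", "lung_transform")`.
#' @export
deformation_field <- function(disp, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(is.array(disp), length(dim(disp)) == 4L, dim(disp)[4] == 3L)
  if (any(!is.finite(disp))) stop("deformation_field: non-finite displacement")
  structure(list(disp = disp, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = c("deformation_field", "lung_transform"))
}

#' @export
transform_points.deformation_field <- function(transform, pts) {
  d <- dim(transform$disp)[1:3]
  u <- matrix(0, nrow(pts), 3)
  for (a in 1:3) {
    comp <- transform$disp[, , , a]
    r <- cpp_trilinear(as.numeric(comp), as.integer(d), transform$spacing,
                       transform$origin, pts, 0, TRUE)
    u[, a] <- r$value
  }
  pts + u
}

#' @export
transform_jacobian.deformation_field <- function(transform, pts) {
  ## sample the central-difference determinant grid at the points
  J <- fd_jacobian(transform)
  d <- dim(transform$disp)[1:3]
  cpp_trilinear(as.numeric(J), as.integer(d), transform$spacing,
                transform$origin, pts, 1, TRUE)$value
}

## Central-difference Jacobian determinant of a sampled field (one-sided at
## the grid faces).
fd_jacobian <- function(field) {
  d <- dim(field$disp)[1:3]
  G <- array(0, c(d, 9))
  for (a in 1:3) {
    comp <- field$disp[, , , a]
    for (b in 1:3) {
      G[, , , (a - 1) * 3 + b] <- array_gradient(comp, b, field$spacing[b])
    }
  }
  Gm <- matrix(G, ncol = 9)
  array(det_from_G(Gm), dim = d)
}

## d(arr)/d(axis), central differences, one-sided at the boundary slabs.
array_gradient <- function(arr, axis, h) {
  d <- dim(arr)
  n <- d[axis]
  if (n < 2) return(array(0, d))
  idx <- function(i) {
    sel <- list(quote(expr =), quote(expr =), quote(expr =))
    sel[[axis]] <- i
    do.call(`[`, c(list(arr), sel, list(drop = FALSE)))
  }
  up <- idx(c(2:n, n))
  lo <- idx(c(1, 1:(n - 1)))
  den <- array(2 * h, d)
  edge <- function(i, val) {
    sel <- list(quote(expr =), quote(expr =), quote(expr =))
    sel[[axis]] <- i
    do.call(`[<-`, c(list(den), sel, list(value = val)))
  }
  den <- edge(1, h)
  den <- edge(n, h)
  (up - lo) / den
}

#' Sample a transform as a dense displacement field
#'
#' Evaluates `T(x) - x` at every voxel centre of the geometry of `vol`.
#'
#' @param transform A `lung_transform`.
#' @param vol A [scalar_volume()] supplying the target grid.
#' @return A [deformation_field()].
#' @export
as_deformation_field <- function(transform, vol) {
  d <- dim(vol$data)
  pts <- voxel_coords(vol)
  u <- transform_points(transform, pts) - pts
  deformation_field(array(u, c(d, 3)), spacing = vol$spacing,
                    origin = vol$origin)
}

#' Jacobian determinant map over a volume grid
#'
#' Evaluates `det(dT/dx)` at every voxel centre: the local floating volume
#' matched to one unit of reference volume (e.g. a uniform scaling by 1.1
#' gives 1.331 everywhere). The reference/floating volume ratio `J = v^r/v^f`
#' used by the mechanics maps is the reciprocal; request it with
#' `convention = "ratio"`. For analytic transforms derivatives are exact;
#' for sampled `deformation_field` objects central differences are used.
#'
#' @param transform A `lung_transform`.
#' @param vol A [scalar_volume()] supplying the grid.
#' @param convention `"det"` (default) for `det(dT/dx)`; `"ratio"` for the
#'   reference/floating volume ratio `1/det`.
#' @return 3D array over the grid.
#' @export
jacobian_field <- function(transform, vol, convention = c("det", "ratio")) {
  convention <- match.arg(convention)
  d <- dim(vol$data)
  if (inherits(transform, "deformation_field")) {
    J <- fd_jacobian(transform)
    if (!identical(dim(J), d)) {
      pts <- voxel_coords(vol)
      J <- array(transform_jacobian(transform, pts), d)
    }
  } else {
    pts <- voxel_coords(vol)
    J <- array(transform_jacobian(transform, pts), d)
  }
  if (convention == "ratio") J <- 1 / J
  J
}
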