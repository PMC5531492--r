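#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Cubic B-spline basis on the unit interval: weights for the four control
// points i0-1 .. i0+2 given the fractional offset s = t - floor(t).
static inline void bspline_w(double s, double *w) {
  const double s2 = s * s, s3 = s2 * s;
  w[0] = (1.0 - 3.0 * s + 3.0 * s2 - s3) / 6.0;
  w[1] = (4.0 - 6.0 * s2 + 3.0 * s3) / 6.0;
  w[2] = (1.0 + 3.0 * s + 3.0 * s2 - 3.0 * s3) / 6.0;
  w[3] = s3 / 6.0;
}

static inline void bspline_dw(double s, double *d) {
  const double s2 = s * s;
  d[0] = (-3.0 + 6.0 * s - 3.0 * s2) / 6.0;
  d[1] = (-12.0 * s + 9.0 * s2) / 6.0;
  d[2] = (3.0 + 6.0 * s - 9.0 * s2) / 6.0;
  d[3] = 3.0 * s2 / 6.0;
}

// 3x3 determinant and cofactor matrix (C[a][b] = d det / d F[a][b]).
static inline double det3_cof(const double F[3][3], double C[3][3]) {
  C[0][0] = F[1][1] * F[2][2] - F[1][2] * F[2][1];
  C[0][1] = F[1][2] * F[2][0] - F[1][0] * F[2][2];
  C[0][2] = F[1][0] * F[2][1] - F[1][1] * F[2][0];
  C[1][0] = F[0][2] * F[2][1] - F[0][1] * F[2][2];
  C[1][1] = F[0][0] * F[2][2] - F[0][2] * F[2][0];
  C[1][2] = F[0][1] * F[2][0] - F[0][0] * F[2][1];
  C[2][0] = F[0][1] * F[1][2] - F[0][2] * F[1][1];
  C[2][1] = F[0][2] * F[1][0] - F[0][0] * F[1][2];
  C[2][2] = F[0][0] * F[1][1] - F[0][1] * F[1][0];
  return F[0][0] * C[0][0] + F[0][1] * C[0][1] + F[0][2] * C[0][2];
}

struct Grid3 {
  const double *img;
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz;
};

// Trilinear interpolation at world point (x,y,z); clamp-to-edge when clamp
// is true, otherwise report outside and return fill. Gradient (per mm) is
// written to g when non-null.
static inline double trilerp(const Grid3 &G, double x, double y, double z,
                             bool clamp, double fill, bool *outside,
                             double *g) {
  double px = (x - G.ox) / G.sx, py = (y - G.oy) / G.sy,
         pz = (z - G.oz) / G.sz;
  bool out = px < 0 || py < 0 || pz < 0 || px > G.nx - 1 || py > G.ny - 1 ||
             pz > G.nz - 1;
  if (outside) *outside = out;
  if (out && !clamp) {
    if (g) g[0] = g[1] = g[2] = 0.0;
    return fill;
  }
  if (px < 0) px = 0;
  if (py < 0) py = 0;
  if (pz < 0) pz = 0;
  if (px > G.nx - 1) px = G.nx - 1;
  if (py > G.ny - 1) py = G.ny - 1;
  if (pz > G.nz - 1) pz = G.nz - 1;
  int i = (int)std::floor(px), j = (int)std::floor(py),
      k = (int)std::floor(pz);
  if (i > G.nx - 2) i = G.nx - 2;
  if (j > G.ny - 2) j = G.ny - 2;
  if (k > G.nz - 2) k = G.nz - 2;
  if (G.nx == 1) i = 0;
  if (G.ny == 1) j = 0;
  if (G.nz == 1) k = 0;
  double fx = px - i, fy = py - j, fz = pz - k;
  const int nxy = G.nx * G.ny;
  const double *p = G.img + i + G.nx * j + nxy * k;
  int dx = (G.nx > 1) ? 1 : 0, dy = (G.ny > 1) ? G.nx : 0,
      dz = (G.nz > 1) ? nxy : 0;
  double c000 = p[0], c100 = p[dx], c010 = p[dy], c110 = p[dx + dy];
  double c001 = p[dz], c101 = p[dx + dz], c011 = p[dy + dz],
         c111 = p[dx + dy + dz];
  double c00 = c000 + fx * (c100 - c000), c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001), c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00), c1 = c01 + fy * (c11 - c01);
  double val = c0 + fz * (c1 - c0);
  if (g) {
    double gx0 = (c100 - c000) + fy * ((c110 - c010) - (c100 - c000));
    double gx1 = (c101 - c001) + fy * ((c111 - c011) - (c101 - c001));
    g[0] = (gx0 + fz * (gx1 - gx0)) / G.sx;
    double gy0 = (c10 - c00), gy1 = (c11 - c01);
    g[1] = (gy0 + fz * (gy1 - gy0)) / G.sy;
    g[2] = (c1 - c0) / G.sz;
  }
  return val;
}

// [[Rcpp::export]]
List cpp_trilinear(NumericVector img, IntegerVector dims,
                   NumericVector spacing, NumericVector origin,
                   NumericMatrix pts, double fill, bool clamp) {
  Grid3 G = {img.begin(),   dims[0],    dims[1],    dims[2],
             origin[0],     origin[1],  origin[2],  spacing[0],
             spacing[1],    spacing[2]};
  int n = pts.nrow();
  NumericVector val(n);
  LogicalVector outside(n);
  for (int t = 0; t < n; ++t) {
    bool out;
    val[t] = trilerp(G, pts(t, 0), pts(t, 1), pts(t, 2), clamp, fill, &out,
                     nullptr);
    outside[t] = out;
  }
  return List::create(_["value"] = val, _["outside"] = outside);
}

struct CtrlGrid {
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz;
};

// Compute the 4-point support indices and (derivative) weights along one
// axis; i0 is clamped so the support stays inside the control lattice.
static inline void axis_support(double x, double o, double h, int n, int *i0,
                                double *w, double *d) {
  double t = (x - o) / h;
  int i = (int)std::floor(t);
  if (i < 1) i = 1;
  if (i > n - 3) i = n - 3;
  double s = t - i;
  bspline_w(s, w);
  if (d) {
    bspline_dw(s, d);
    for (int q = 0; q < 4; ++q) d[q] /= h;
  }
  *i0 = i;
}

// Evaluate a cubic B-spline FFD (displacement and, optionally, the spatial
// derivative tensor du_a/dx_b) at arbitrary world points.
// coef is (ncp x 3) with control point (i,j,k) at row i + nx*(j + ny*k).
// [[Rcpp::export]]
List cpp_bspline_disp(NumericMatrix pts, NumericMatrix coef,
                      IntegerVector gdim, NumericVector gorigin,
                      NumericVector gspacing, bool want_jac) {
  CtrlGrid g = {gdim[0],     gdim[1],     gdim[2],    gorigin[0],
                gorigin[1],  gorigin[2],  gspacing[0], gspacing[1],
                gspacing[2]};
  int n = pts.nrow(), ncp = coef.nrow();
  if (ncp != g.nx * g.ny * g.nz) stop("coefficient/control-grid mismatch");
  NumericMatrix u(n, 3);
  NumericMatrix J;
  if (want_jac) J = NumericMatrix(n, 9);
  double wx[4], wy[4], wz[4], dx[4], dy[4], dz[4];
  const double *cf = coef.begin();
  for (int t = 0; t < n; ++t) {
    int i0, j0, k0;
    axis_support(pts(t, 0), g.ox, g.sx, g.nx, &i0, wx, want_jac ? dx : nullptr);
    axis_support(pts(t, 1), g.oy, g.sy, g.ny, &j0, wy, want_jac ? dy : nullptr);
    axis_support(pts(t, 2), g.oz, g.sz, g.nz, &k0, wz, want_jac ? dz : nullptr);
    double ua = 0, ub = 0, uc = 0;
    double G9[9] = {0, 0, 0, 0, 0, 0, 0, 0, 0};
    for (int kk = 0; kk < 4; ++kk) {
      for (int jj = 0; jj < 4; ++jj) {
        double wyz = wy[jj] * wz[kk];
        int base = g.nx * ((j0 - 1 + jj) + g.ny * (k0 - 1 + kk)) + i0 - 1;
        for (int ii = 0; ii < 4; ++ii) {
          int m = base + ii;
          double w = wx[ii] * wyz;
          double c0 = cf[m], c1 = cf[m + ncp], c2 = cf[m + 2 * ncp];
          ua += w * c0;
          ub += w * c1;
          uc += w * c2;
          if (want_jac) {
            double gx = dx[ii] * wyz;
            double gy = wx[ii] * dy[jj] * wz[kk];
            double gz = wx[ii] * wy[jj] * dz[kk];
            G9[0] += gx * c0; G9[1] += gy * c0; G9[2] += gz * c0;
            G9[3] += gx * c1; G9[4] += gy * c1; G9[5] += gz * c1;
            G9[6] += gx * c2; G9[7] += gy * c2; G9[8] += gz * c2;
          }
        }
      }
    }
    u(t, 0) = ua; u(t, 1) = ub; u(t, 2) = uc;
    if (want_jac) for (int q = 0; q < 9; ++q) J(t, q) = G9[q];
  }
  if (want_jac) return List::create(_["u"] = u, _["G"] = J);
  return List::create(_["u"] = u);
}

// SSTVD cost and analytic gradient with respect to the active level's
// B-spline coefficients.
//
//   E = sum_{x in Omega} ( vt_r(x) - v_r * det(F(x)) * frac(I_f(T(x))) )^2
//
// T(x) = x + u_prev(x) + u(x), F = I + G_prev + G, frac the clamped linear
// HU -> tissue-fraction map. The det(F) factor scales the reference voxel
// volume to the matched floating volume (mass-preserving convention).
// [[Rcpp::export]]
List cpp_sstvd_cost(NumericVector flt, IntegerVector fdim,
                    NumericVector fspacing, NumericVector forigin,
                    NumericMatrix omega_xyz, NumericVector vtr, double vref,
                    NumericMatrix coef, IntegerVector gdim,
                    NumericVector gorigin, NumericVector gspacing,
                    NumericMatrix uprev, NumericMatrix gprev,
                    double hu_air, double hu_tissue, bool want_grad) {
  Grid3 Gf = {flt.begin(),  fdim[0],     fdim[1],     fdim[2],
              forigin[0],   forigin[1],  forigin[2],  fspacing[0],
              fspacing[1],  fspacing[2]};
  CtrlGrid g = {gdim[0],    gdim[1],     gdim[2],     gorigin[0],
                gorigin[1], gorigin[2],  gspacing[0], gspacing[1],
                gspacing[2]};
  const int n = omega_xyz.nrow(), ncp = coef.nrow();
  const bool has_prev = uprev.nrow() == n;
  const double hu_range = hu_tissue - hu_air;
  NumericMatrix grad;
  if (want_grad) grad = NumericMatrix(ncp, 3);
  double E = 0.0;
  int n_outside = 0, n_negdet = 0;
  double wx[4], wy[4], wz[4], dwx[4], dwy[4], dwz[4];
  const double *cf = coef.begin();
  for (int t = 0; t < n; ++t) {
    const double x0 = omega_xyz(t, 0), x1 = omega_xyz(t, 1),
                 x2 = omega_xyz(t, 2);
    int i0, j0, k0;
    axis_support(x0, g.ox, g.sx, g.nx, &i0, wx, dwx);
    axis_support(x1, g.oy, g.sy, g.ny, &j0, wy, dwy);
    axis_support(x2, g.oz, g.sz, g.nz, &k0, wz, dwz);
    double u0 = 0, u1 = 0, u2 = 0;
    double F[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
    if (has_prev) {
      u0 = uprev(t, 0); u1 = uprev(t, 1); u2 = uprev(t, 2);
      F[0][0] += gprev(t, 0); F[0][1] += gprev(t, 1); F[0][2] += gprev(t, 2);
      F[1][0] += gprev(t, 3); F[1][1] += gprev(t, 4); F[1][2] += gprev(t, 5);
      F[2][0] += gprev(t, 6); F[2][1] += gprev(t, 7); F[2][2] += gprev(t, 8);
    }
    for (int kk = 0; kk < 4; ++kk) {
      for (int jj = 0; jj < 4; ++jj) {
        double wyz = wy[jj] * wz[kk];
        int base = g.nx * ((j0 - 1 + jj) + g.ny * (k0 - 1 + kk)) + i0 - 1;
        for (int ii = 0; ii < 4; ++ii) {
          int m = base + ii;
          double w = wx[ii] * wyz;
          double c0 = cf[m], c1 = cf[m + ncp], c2 = cf[m + 2 * ncp];
          u0 += w * c0; u1 += w * c1; u2 += w * c2;
          double gx = dwx[ii] * wyz;
          double gy = wx[ii] * dwy[jj] * wz[kk];
          double gz = wx[ii] * wy[jj] * dwz[kk];
          F[0][0] += gx * c0; F[0][1] += gy * c0; F[0][2] += gz * c0;
          F[1][0] += gx * c1; F[1][1] += gy * c1; F[1][2] += gz * c1;
          F[2][0] += gx * c2; F[2][1] += gy * c2; F[2][2] += gz * c2;
        }
      }
    }
    double C[3][3];
    double det = det3_cof(F, C);
    if (det <= 0) ++n_negdet;
    bool out;
    double gI[3];
    double I = trilerp(Gf, x0 + u0, x1 + u1, x2 + u2, true, 0.0, &out, gI);
    if (out) ++n_outside;
    double frac = (I - hu_air) / hu_range;
    double fracp = 1.0 / hu_range;
    if (frac < 0) { frac = 0; fracp = 0; }
    if (frac > 1) { frac = 1; fracp = 0; }
    if (out) { gI[0] = gI[1] = gI[2] = 0; }
    double resid = vtr[t] - vref * det * frac;
    E += resid * resid;
    if (want_grad) {
      // d resid / dc_{m,a} = -vref * ( det*fracp*gI[a]*w_m
      //                               + frac * sum_b C[a][b]*dw_m[b] )
      double k1 = -2.0 * resid * vref * det * fracp;
      double k2 = -2.0 * resid * vref * frac;
      double *G0 = grad.begin(), *G1 = G0 + ncp, *G2 = G1 + ncp;
      for (int kk = 0; kk < 4; ++kk) {
        for (int jj = 0; jj < 4; ++jj) {
          double wyz = wy[jj] * wz[kk];
          double wdyz = dwy[jj] * wz[kk];
          double wydz = wy[jj] * dwz[kk];
          int base = g.nx * ((j0 - 1 + jj) + g.ny * (k0 - 1 + kk)) + i0 - 1;
          for (int ii = 0; ii < 4; ++ii) {
            int m = base + ii;
            double w = wx[ii] * wyz;
            double dw0 = dwx[ii] * wyz;
            double dw1 = wx[ii] * wdyz;
            double dw2 = wx[ii] * wydz;
            G0[m] += k1 * gI[0] * w +
                     k2 * (C[0][0] * dw0 + C[0][1] * dw1 + C[0][2] * dw2);
            G1[m] += k1 * gI[1] * w +
                     k2 * (C[1][0] * dw0 + C[1][1] * dw1 + C[1][2] * dw2);
            G2[m] += k1 * gI[2] * w +
                     k2 * (C[2][0] * dw0 + C[2][1] * dw1 + C[2][2] * dw2);
          }
        }
      }
    }
  }
  List out = List::create(_["E"] = E, _["n_outside"] = n_outside,
                          _["n_negdet"] = n_negdet);
  if (want_grad) out["grad"] = grad;
  return out;
}

// Block-average downsampling by integer factors (trailing partial blocks
// are averaged over the voxels present).
// [[Rcpp::export]]
NumericVector cpp_block_mean(NumericVector img, IntegerVector dims,
                             IntegerVector factor) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int fx = factor[0], fy = factor[1], fz = factor[2];
  int mx = (nx + fx - 1) / fx, my = (ny + fy - 1) / fy, mz = (nz + fz - 1) / fz;
  NumericVector out(mx * my * mz);
  std::vector<int> cnt(mx * my * mz, 0);
  const double *p = img.begin();
  for (int k = 0; k < nz; ++k) {
    int ko = (k / fz) * mx * my;
    for (int j = 0; j < ny; ++j) {
      int jo = (j / fy) * mx + ko;
      for (int i = 0; i < nx; ++i) {
        int o = i / fx + jo;
        out[o] += p[i + nx * (j + (size_t)ny * k)];
        cnt[o] += 1;
      }
    }
  }
  for (int o = 0; o < mx * my * mz; ++o) out[o] /= cnt[o];
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}
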