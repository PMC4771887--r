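#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact radiological path through an axis-aligned voxel grid (incremental
// Siddon traversal).  The grid is centred on the origin with isotropic
// voxel size vs; mu is column-major [nx, ny, nz].  Ray runs from the
// source (sx,sy,sz) to the detector pixel (px,py,pz); the returned value
// is sum(mu_voxel * intersection length) in units of mu * mm.
static double siddon_ray(const double* mu, int nx, int ny, int nz, double vs,
                         double sx, double sy, double sz,
                         double px, double py, double pz) {
  const double dx = px - sx, dy = py - sy, dz = pz - sz;
  const double len = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (len <= 0.0) return 0.0;

  const double x0 = -0.5 * nx * vs;
  const double y0 = -0.5 * ny * vs;
  const double z0 = -0.5 * nz * vs;
  const double inf = std::numeric_limits<double>::infinity();

  // Clip parametric range [0,1] against the grid bounding box.
  double tmin = 0.0, tmax = 1.0;
  const double d[3]  = {dx, dy, dz};
  const double s0[3] = {sx, sy, sz};
  const double lo[3] = {x0, y0, z0};
  const double hi[3] = {x0 + nx * vs, y0 + ny * vs, z0 + nz * vs};
  for (int a = 0; a < 3; ++a) {
    if (d[a] == 0.0) {
      if (s0[a] < lo[a] || s0[a] > hi[a]) return 0.0;
    } else {
      double t1 = (lo[a] - s0[a]) / d[a];
      double t2 = (hi[a] - s0[a]) / d[a];
      if (t1 > t2) std::swap(t1, t2);
      if (t1 > tmin) tmin = t1;
      if (t2 < tmax) tmax = t2;
    }
  }
  if (tmin >= tmax) return 0.0;

  // Entry voxel: evaluate slightly inside the box to dodge face ties.
  const double tent = tmin + 1e-12 * (tmax - tmin);
  int ix = (int)std::floor((sx + tent * dx - x0) / vs);
  int iy = (int)std::floor((sy + tent * dy - y0) / vs);
  int iz = (int)std::floor((sz + tent * dz - z0) / vs);
  if (ix < 0) ix = 0;
  if (ix > nx - 1) ix = nx - 1;
  if (iy < 0) iy = 0;
  if (iy > ny - 1) iy = ny - 1;
  if (iz < 0) iz = 0;
  if (iz > nz - 1) iz = nz - 1;

  const int stepx = dx > 0 ? 1 : -1;
  const int stepy = dy > 0 ? 1 : -1;
  const int stepz = dz > 0 ? 1 : -1;
  const double tdx = dx != 0.0 ? vs / std::fabs(dx) : inf;
  const double tdy = dy != 0.0 ? vs / std::fabs(dy) : inf;
  const double tdz = dz != 0.0 ? vs / std::fabs(dz) : inf;

  // Parameter of the next axis-plane crossing for each axis.
  double tx = inf, ty = inf, tz = inf;
  if (dx != 0.0) {
    double bound = x0 + (dx > 0 ? (ix + 1) : ix) * vs;
    tx = (bound - sx) / dx;
  }
  if (dy != 0.0) {
    double bound = y0 + (dy > 0 ? (iy + 1) : iy) * vs;
    ty = (bound - sy) / dy;
  }
  if (dz != 0.0) {
    double bound = z0 + (dz > 0 ? (iz + 1) : iz) * vs;
    tz = (bound - sz) / dz;
  }

  double t = tmin, acc = 0.0;
  const int sxy = nx * ny;
  while (t < tmax) {
    double tnext = tx;
    int axis = 0;
    if (ty < tnext) { tnext = ty; axis = 1; }
    if (tz < tnext) { tnext = tz; axis = 2; }
    if (tnext > tmax) tnext = tmax;
    acc += mu[ix + nx * iy + sxy * iz] * (tnext - t);
    t = tnext;
    if (t >= tmax) break;
    if (axis == 0)      { ix += stepx; tx += tdx; if (ix < 0 || ix >= nx) break; }
    else if (axis == 1) { iy += stepy; ty += tdy; if (iy < 0 || iy >= ny) break; }
    else                { iz += stepz; tz += tdz; if (iz < 0 || iz >= nz) break; }
  }
  return acc * len;
}

// Cone-beam line integrals for a full projection stack.
// Source at DSO*(cos a, sin a, 0); flat detector perpendicular to the
// central ray at distance DSD from the source, columns along
// (-sin a, cos a, 0), rows along +z.  Returns [nrow, ncol, nview] of
// line integrals (dimensionless, mu * mm).
// [[Rcpp::export]]
NumericVector cpp_forward_project(NumericVector mu, IntegerVector dims,
                                  double vs, double dso, double dsd,
                                  double pitch, int nrow, int ncol,
                                  NumericVector angles) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int nview = angles.size();
  NumericVector out(nrow * (R_xlen_t)ncol * nview);
  const double* p = REAL(mu);
  const double uc = 0.5 * (ncol + 1);
  const double vc = 0.5 * (nrow + 1);
  for (int a = 0; a < nview; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    const double sx = dso * ca, sy = dso * sa, sz = 0.0;
    const double d0x = (dso - dsd) * ca, d0y = (dso - dsd) * sa;
    const double eux = -sa, euy = ca;  // detector column direction
    for (int i = 0; i < ncol; ++i) {
      const double u = (i + 1 - uc) * pitch;
      const double bx = d0x + u * eux, by = d0y + u * euy;
      for (int j = 0; j < nrow; ++j) {
        const double v = (j + 1 - vc) * pitch;
        out[j + nrow * (R_xlen_t)i + nrow * (R_xlen_t)ncol * a] =
          siddon_ray(p, nx, ny, nz, vs, sx, sy, sz, bx, by, v);
      }
    }
  }
  return out;
}

// Fan-beam backprojection (flat, equally spaced detector rescaled to a
// virtual detector line through the isocenter).  qf is the filtered
// sinogram [ncol_det, nview] sampled at virtual pitch ds; returns the
// central-slice image [npix, npix] with pixel size voxel (mm), x to the
// right, y up, centre of the grid at the isocenter.
// [[Rcpp::export]]
NumericMatrix cpp_fan_backproject(NumericMatrix qf, double ds, double dso,
                                  NumericVector angles, int npix,
                                  double voxel) {
  const int ndet = qf.nrow();
  const int nview = angles.size();
  NumericMatrix img(npix, npix);
  const double dbeta = M_PI / nview;  // 2*pi/nview times the full-scan redundancy factor 1/2
  const double cpix = 0.5 * (npix + 1);
  const double cdet = 0.5 * (ndet + 1);
  for (int a = 0; a < nview; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    const double* q = &qf(0, a);
    for (int iy = 0; iy < npix; ++iy) {
      const double y = (iy + 1 - cpix) * voxel;
      for (int ix = 0; ix < npix; ++ix) {
        const double x = (ix + 1 - cpix) * voxel;
        const double denom = dso - (x * ca + y * sa);
        if (denom <= 1e-6) continue;
        const double U = denom / dso;
        const double s = dso * (-x * sa + y * ca) / denom;
        const double fidx = s / ds + cdet - 1.0;  // 0-based
        const int i0 = (int)std::floor(fidx);
        if (i0 < 0 || i0 >= ndet - 1) continue;
        const double w = fidx - i0;
        const double val = (1.0 - w) * q[i0] + w * q[i0 + 1];
        img(ix, iy) += val / (U * U);
      }
    }
  }
  for (int k = 0; k < npix * npix; ++k) img[k] *= dbeta;
  return img;
}

// FDK cone-beam backprojection.  qf holds row-filtered, cosine-weighted
// projections [nrow, ncol, nview] on the physical detector (pitch mm);
// returns the volume [npix, npix, nslice] with isotropic voxel size,
// slices centred on the rotation plane.
// [[Rcpp::export]]
NumericVector cpp_fdk_backproject(NumericVector qf, IntegerVector pdims,
                                  double pitch, double dso, double dsd,
                                  NumericVector angles, int npix, int nslice,
                                  double voxel) {
  const int nrow = pdims[0], ncol = pdims[1];
  const int nview = angles.size();
  NumericVector vol(npix * (R_xlen_t)npix * nslice);
  const double dbeta = M_PI / nview;  // 2*pi/nview times the full-scan redundancy factor 1/2
  const double cpix = 0.5 * (npix + 1);
  const double cslc = 0.5 * (nslice + 1);
  const double cu = 0.5 * (ncol + 1);
  const double cv = 0.5 * (nrow + 1);
  const double* q = REAL(qf);
  for (int a = 0; a < nview; ++a) {
    const double ca = std::cos(angles[a]), sa = std::sin(angles[a]);
    const double* qa = q + nrow * (R_xlen_t)ncol * a;
    for (int iz = 0; iz < nslice; ++iz) {
      const double z = (iz + 1 - cslc) * voxel;
      for (int iy = 0; iy < npix; ++iy) {
        const double y = (iy + 1 - cpix) * voxel;
        for (int ix = 0; ix < npix; ++ix) {
          const double x = (ix + 1 - cpix) * voxel;
          const double denom = dso - (x * ca + y * sa);
          if (denom <= 1e-6) continue;
          const double mag = dsd / denom;
          const double u = mag * (-x * sa + y * ca);
          const double v = mag * z;
          const double fu = u / pitch + cu - 1.0;
          const double fv = v / pitch + cv - 1.0;
          const int iu = (int)std::floor(fu);
          const int iv = (int)std::floor(fv);
          if (iu < 0 || iu >= ncol - 1 || iv < 0 || iv >= nrow - 1) continue;
          const double wu = fu - iu, wv = fv - iv;
          const double val =
            (1.0 - wu) * ((1.0 - wv) * qa[iv + nrow * iu] +
                          wv * qa[iv + 1 + nrow * iu]) +
            wu * ((1.0 - wv) * qa[iv + nrow * (iu + 1)] +
                  wv * qa[iv + 1 + nrow * (iu + 1)]);
          const double U = denom / dso;
          vol[ix + npix * (R_xlen_t)iy + npix * (R_xlen_t)npix * iz] +=
            val / (U * U);
        }
      }
    }
  }
  for (R_xlen_t k = 0; k < vol.size(); ++k) vol[k] *= dbeta;
  return vol;
}
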