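#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Staggered-grid acoustic FDTD kernels: (2,4) Yee scheme (second order in
// time, fourth order in space) with a (2,2) fallback within one node of the
// domain faces. Pressure lives at integer nodes p[i,j,k] (column-major,
// i fastest); velocity components at half-offset nodes, so vx has dims
// (nx-1, ny, nz) with vx[i] between p[i] and p[i+1], etc.
//
// Damping enters the velocity update semi-implicitly:
//   v <- a * v - b * grad(p)
// where a = (1 - s)/(1 + s), b = (dt/rho_bar)/(1 + s), s = sigma_bar*dt/(2*rho_bar),
// precomputed per velocity node on the R side.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// [[Rcpp::export]]
void cpp_step_velocity(NumericVector p, NumericVector vx, NumericVector vy,
                       NumericVector vz, NumericVector ax, NumericVector bx,
                       NumericVector ay, NumericVector by, NumericVector az,
                       NumericVector bz, IntegerVector dims, double delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double c2 = 1.0 / delta;
  const double c24 = 1.0 / (24.0 * delta);
  const double *pp = REAL(p);
  double *pvx = REAL(vx), *pvy = REAL(vy), *pvz = REAL(vz);
  const double *pax = REAL(ax), *pbx = REAL(bx);
  const double *pay = REAL(ay), *pby = REAL(by);
  const double *paz = REAL(az), *pbz = REAL(bz);

  // x component: dims (nx-1, ny, nz)
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      const double *pc = pp + idx3(0, j, k, nx, ny);
      double *v = pvx + (nx - 1) * (j + ny * k);
      const double *a = pax + (nx - 1) * (j + ny * k);
      const double *b = pbx + (nx - 1) * (j + ny * k);
      if (nx >= 2) {
        double g = (pc[1] - pc[0]) * c2;
        v[0] = a[0] * v[0] - b[0] * g;
      }
      for (int i = 1; i <= nx - 3; ++i) {
        double g = (27.0 * (pc[i + 1] - pc[i]) - (pc[i + 2] - pc[i - 1])) * c24;
        v[i] = a[i] * v[i] - b[i] * g;
      }
      if (nx >= 3) {
        int i = nx - 2;
        double g = (pc[i + 1] - pc[i]) * c2;
        v[i] = a[i] * v[i] - b[i] * g;
      }
    }
  }

  // y component: dims (nx, ny-1, nz); stride between p(j) and p(j+1) is nx
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny - 1; ++j) {
      const bool wide = (j >= 1 && j <= ny - 3);
      const double *p0 = pp + idx3(0, j, k, nx, ny);
      double *v = pvy + nx * (j + (ny - 1) * k);
      const double *a = pay + nx * (j + (ny - 1) * k);
      const double *b = pby + nx * (j + (ny - 1) * k);
      if (wide) {
        for (int i = 0; i < nx; ++i) {
          double g = (27.0 * (p0[i + nx] - p0[i]) -
                      (p0[i + 2 * nx] - p0[i - nx])) * c24;
          v[i] = a[i] * v[i] - b[i] * g;
        }
      } else {
        for (int i = 0; i < nx; ++i) {
          double g = (p0[i + nx] - p0[i]) * c2;
          v[i] = a[i] * v[i] - b[i] * g;
        }
      }
    }
  }

  // z component: dims (nx, ny, nz-1); stride nx*ny
  const int sz = nx * ny;
  for (int k = 0; k < nz - 1; ++k) {
    const bool wide = (k >= 1 && k <= nz - 3);
    for (int j = 0; j < ny; ++j) {
      const double *p0 = pp + idx3(0, j, k, nx, ny);
      double *v = pvz + idx3(0, j, k, nx, ny);
      const double *a = paz + idx3(0, j, k, nx, ny);
      const double *b = pbz + idx3(0, j, k, nx, ny);
      if (wide) {
        for (int i = 0; i < nx; ++i) {
          double g = (27.0 * (p0[i + sz] - p0[i]) -
                      (p0[i + 2 * sz] - p0[i - sz])) * c24;
          v[i] = a[i] * v[i] - b[i] * g;
        }
      } else {
        for (int i = 0; i < nx; ++i) {
          double g = (p0[i + sz] - p0[i]) * c2;
          v[i] = a[i] * v[i] - b[i] * g;
        }
      }
    }
  }
}

// Pressure update: p <- p - kappa*dt * div(v). Outside the domain the normal
// velocity is taken as zero (rigid enclosure unless Mur is applied after).
// [[Rcpp::export]]
void cpp_step_pressure(NumericVector p, NumericVector vx, NumericVector vy,
                       NumericVector vz, NumericVector kdt, IntegerVector dims,
                       double delta) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double c2 = 1.0 / delta;
  const double c24 = 1.0 / (24.0 * delta);
  double *pp = REAL(p);
  const double *pvx = REAL(vx), *pvy = REAL(vy), *pvz = REAL(vz);
  const double *pk = REAL(kdt);
  const int sz = nx * ny;

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      double *pc = pp + idx3(0, j, k, nx, ny);
      const double *kc = pk + idx3(0, j, k, nx, ny);
      const double *vxr = pvx + (nx - 1) * (j + ny * k); // vx row, index i is node i+1/2
      // y neighbours of vy at this (j,k) row
      const double *vyc = pvy + nx * (j + (ny - 1) * k);       // vy(i, j+1/2, k)
      const double *vym = (j >= 1) ? pvy + nx * ((j - 1) + (ny - 1) * k) : NULL;
      const double *vym2 = (j >= 2) ? pvy + nx * ((j - 2) + (ny - 1) * k) : NULL;
      const double *vyp = (j <= ny - 3) ? pvy + nx * ((j + 1) + (ny - 1) * k) : NULL;
      const double *vzc = pvz + idx3(0, j, k, nx, ny);          // vz(i, j, k+1/2)
      const double *vzm = (k >= 1) ? pvz + idx3(0, j, k - 1, nx, ny) : NULL;
      const double *vzm2 = (k >= 2) ? pvz + idx3(0, j, k - 2, nx, ny) : NULL;
      const double *vzp = (k <= nz - 3) ? pvz + idx3(0, j, k + 1, nx, ny) : NULL;
      const bool wide_y = (j >= 2 && j <= ny - 3);
      const bool wide_z = (k >= 2 && k <= nz - 3);

      for (int i = 0; i < nx; ++i) {
        double dx;
        if (i == 0) {
          dx = vxr[0] * c2;
        } else if (i == nx - 1) {
          dx = -vxr[i - 1] * c2;
        } else if (i >= 2 && i <= nx - 3) {
          dx = (27.0 * (vxr[i] - vxr[i - 1]) - (vxr[i + 1] - vxr[i - 2])) * c24;
        } else {
          dx = (vxr[i] - vxr[i - 1]) * c2;
        }

        double dy;
        if (j == 0) {
          dy = vyc[i] * c2;
        } else if (j == ny - 1) {
          dy = -vym[i] * c2;
        } else if (wide_y) {
          dy = (27.0 * (vyc[i] - vym[i]) - (vyp[i] - vym2[i])) * c24;
        } else {
          dy = (vyc[i] - vym[i]) * c2;
        }

        double dz;
        if (k == 0) {
          dz = vzc[i] * c2;
        } else if (k == nz - 1) {
          dz = -vzm[i] * c2;
        } else if (wide_z) {
          dz = (27.0 * (vzc[i] - vzm[i]) - (vzp[i] - vzm2[i])) * c24;
        } else {
          dz = (vzc[i] - vzm[i]) * c2;
        }

        pc[i] -= kc[i] * (dx + dy + dz);
      }
    }
  }
}

// [[Rcpp::export]]
void cpp_copy(NumericVector src, NumericVector dst) {
  if (src.size() != dst.size()) stop("cpp_copy: size mismatch");
  std::memcpy(REAL(dst), REAL(src), sizeof(double) * src.size());
}

// First-order Mur absorbing update on the six domain faces. `p` holds the
// freshly updated field (time n+1), `p_prev` the field at time n (saved
// before the pressure update). coef = (c dt - delta)/(c dt + delta) with the
// local sound speed at the boundary node; one matrix per face.
// [[Rcpp::export]]
void cpp_apply_mur(NumericVector p, NumericVector p_prev, IntegerVector dims,
                   NumericMatrix cx0, NumericMatrix cx1, NumericMatrix cy0,
                   NumericMatrix cy1, NumericMatrix cz0, NumericMatrix cz1,
                   LogicalVector faces) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  double *pn = REAL(p);
  const double *po = REAL(p_prev);

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      if (faces[0]) {
        int b = idx3(0, j, k, nx, ny);
        pn[b] = po[b + 1] + cx0(j, k) * (pn[b + 1] - po[b]);
      }
      if (faces[1]) {
        int e = idx3(nx - 1, j, k, nx, ny);
        pn[e] = po[e - 1] + cx1(j, k) * (pn[e - 1] - po[e]);
      }
    }
  }
  for (int k = 0; k < nz; ++k) {
    for (int i = 0; i < nx; ++i) {
      if (faces[2]) {
        int b = idx3(i, 0, k, nx, ny);
        pn[b] = po[b + nx] + cy0(i, k) * (pn[b + nx] - po[b]);
      }
      if (faces[3]) {
        int e = idx3(i, ny - 1, k, nx, ny);
        pn[e] = po[e - nx] + cy1(i, k) * (pn[e - nx] - po[e]);
      }
    }
  }
  const int sz = nx * ny;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (faces[4]) {
        int b = idx3(i, j, 0, nx, ny);
        pn[b] = po[b + sz] + cz0(i, j) * (pn[b + sz] - po[b]);
      }
      if (faces[5]) {
        int e = idx3(i, j, nz - 1, nx, ny);
        pn[e] = po[e - sz] + cz1(i, j) * (pn[e - sz] - po[e]);
      }
    }
  }
}

// [[Rcpp::export]]
bool cpp_all_finite(NumericVector x) {
  const double *px = REAL(x);
  const R_xlen_t n = x.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!std::isfinite(px[i])) return false;
  }
  return true;
}

// Hard-source injection: overwrite pressure at the disc voxels.
// [[Rcpp::export]]
void cpp_inject(NumericVector p, IntegerVector idx, double value) {
  double *pp = REAL(p);
  const int n = idx.size();
  for (int m = 0; m < n; ++m) pp[idx[m] - 1] = value; // 1-based indices
}
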