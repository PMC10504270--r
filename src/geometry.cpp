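#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <map>
using namespace Rcpp;

// Accumulate one isotropic Gaussian per atom onto a regular grid.
// Grid convention: voxel (i,j,k) (0-based) is centered at origin + voxel * (i,j,k).
// [[Rcpp::export]]
NumericVector cpp_simulate_map(NumericMatrix coords, NumericVector weights,
                               IntegerVector dim, NumericVector origin,
                               double voxel, double sigma, double cutoff_sigmas) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz);
  const double cutoff = cutoff_sigmas * sigma;
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    const double w = weights[a];
    int i0 = (int)std::ceil((ax - cutoff - origin[0]) / voxel);
    int i1 = (int)std::floor((ax + cutoff - origin[0]) / voxel);
    int j0 = (int)std::ceil((ay - cutoff - origin[1]) / voxel);
    int j1 = (int)std::floor((ay + cutoff - origin[1]) / voxel);
    int k0 = (int)std::ceil((az - cutoff - origin[2]) / voxel);
    int k1 = (int)std::floor((az + cutoff - origin[2]) / voxel);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + voxel * k - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + voxel * j - ay;
        const double r2yz = dy * dy + dz * dz;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + voxel * i - ax;
          out[base + i] += w * std::exp(-(dx * dx + r2yz) * inv2s2);
        }
      }
    }
  }
  return out;
}

// Trilinear interpolation of grid values at arbitrary points; NA outside the grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector values, IntegerVector dim,
                            NumericVector origin, double voxel,
                            NumericMatrix coords) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int n = coords.nrow();
  NumericVector out(n);
  for (int a = 0; a < n; ++a) {
    double fx = (coords(a, 0) - origin[0]) / voxel;
    double fy = (coords(a, 1) - origin[1]) / voxel;
    double fz = (coords(a, 2) - origin[2]) / voxel;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || j < 0 || k < 0 || i > nx - 2 || j > ny - 2 || k > nz - 2) {
      // allow points exactly on the upper face
      bool edge_ok = fx >= 0 && fy >= 0 && fz >= 0 &&
                     fx <= nx - 1 && fy <= ny - 1 && fz <= nz - 1;
      if (!edge_ok) { out[a] = NA_REAL; continue; }
      if (i > nx - 2) i = nx - 2;
      if (j > ny - 2) j = ny - 2;
      if (k > nz - 2) k = nz - 2;
      if (nx < 2 || ny < 2 || nz < 2) { out[a] = NA_REAL; continue; }
    }
    double tx = fx - i, ty = fy - j, tz = fz - k;
    R_xlen_t b000 = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
    R_xlen_t bx = 1, by = nx, bz = (R_xlen_t)nx * ny;
    double c00 = values[b000] * (1 - tx) + values[b000 + bx] * tx;
    double c10 = values[b000 + by] * (1 - tx) + values[b000 + by + bx] * tx;
    double c01 = values[b000 + bz] * (1 - tx) + values[b000 + bz + bx] * tx;
    double c11 = values[b000 + bz + by] * (1 - tx) + values[b000 + bz + by + bx] * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    out[a] = c0 * (1 - tz) + c1 * tz;
  }
  return out;
}

// Count atom pairs with different group ids closer than cutoff, via cell lists.
// [[Rcpp::export]]
int cpp_cross_group_contacts(NumericMatrix coords, IntegerVector group,
                             double cutoff) {
  const int n = coords.nrow();
  if (n < 2) return 0;
  double mn[3], mx[3];
  for (int d = 0; d < 3; ++d) { mn[d] = R_PosInf; mx[d] = R_NegInf; }
  for (int a = 0; a < n; ++a)
    for (int d = 0; d < 3; ++d) {
      if (coords(a, d) < mn[d]) mn[d] = coords(a, d);
      if (coords(a, d) > mx[d]) mx[d] = coords(a, d);
    }
  const double cell = cutoff;
  int nc[3];
  for (int d = 0; d < 3; ++d)
    nc[d] = std::max(1, (int)std::floor((mx[d] - mn[d]) / cell) + 1);
  std::map<long long, std::vector<int> > cells;
  std::vector<long long> key(n);
  for (int a = 0; a < n; ++a) {
    long long ix = (long long)std::floor((coords(a, 0) - mn[0]) / cell);
    long long iy = (long long)std::floor((coords(a, 1) - mn[1]) / cell);
    long long iz = (long long)std::floor((coords(a, 2) - mn[2]) / cell);
    key[a] = (ix * nc[1] + iy) * nc[2] + iz;
    cells[key[a]].push_back(a);
  }
  const double cut2 = cutoff * cutoff;
  int count = 0;
  for (int a = 0; a < n; ++a) {
    long long ix = (long long)std::floor((coords(a, 0) - mn[0]) / cell);
    long long iy = (long long)std::floor((coords(a, 1) - mn[1]) / cell);
    long long iz = (long long)std::floor((coords(a, 2) - mn[2]) / cell);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          long long jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jy < 0 || jz < 0 || jx >= nc[0] || jy >= nc[1] || jz >= nc[2])
            continue;
          std::map<long long, std::vector<int> >::iterator it =
            cells.find((jx * nc[1] + jy) * nc[2] + jz);
          if (it == cells.end()) continue;
          const std::vector<int> &v = it->second;
          for (size_t q = 0; q < v.size(); ++q) {
            int b = v[q];
            if (b <= a || group[b] == group[a]) continue;
            double d0 = coords(a, 0) - coords(b, 0);
            double d1 = coords(a, 1) - coords(b, 1);
            double d2 = coords(a, 2) - coords(b, 2);
            if (d0 * d0 + d1 * d1 + d2 * d2 < cut2) ++count;
          }
        }
  }
  return count;
}

// Minimum distance between atoms belonging to different groups.
// [[Rcpp::export]]
double cpp_min_cross_group_dist(NumericMatrix coords, IntegerVector group) {
  const int n = coords.nrow();
  double best = R_PosInf;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      if (group[a] == group[b]) continue;
      double d0 = coords(a, 0) - coords(b, 0);
      double d1 = coords(a, 1) - coords(b, 1);
      double d2 = coords(a, 2) - coords(b, 2);
      double d2sum = d0 * d0 + d1 * d1 + d2 * d2;
      if (d2sum < best) best = d2sum;
    }
  return std::sqrt(best);
}

// Logical mask of voxels whose center lies within `radius` of any atom.
// [[Rcpp::export]]
LogicalVector cpp_near_atom_mask(IntegerVector dim, NumericVector origin,
                                 double voxel, NumericMatrix coords,
                                 double radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out(static_cast<R_xlen_t>(nx) * ny * nz, false);
  const double r2 = radius * radius;
  for (int a = 0; a < coords.nrow(); ++a) {
    const double ax = coords(a, 0), ay = coords(a, 1), az = coords(a, 2);
    int i0 = (int)std::ceil((ax - radius - origin[0]) / voxel);
    int i1 = (int)std::floor((ax + radius - origin[0]) / voxel);
    int j0 = (int)std::ceil((ay - radius - origin[1]) / voxel);
    int j1 = (int)std::floor((ay + radius - origin[1]) / voxel);
    int k0 = (int)std::ceil((az - radius - origin[2]) / voxel);
    int k1 = (int)std::floor((az + radius - origin[2]) / voxel);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0 < 0) k0 = 0; if (k1 > nz - 1) k1 = nz - 1;
    for (int k = k0; k <= k1; ++k) {
      const double dz = origin[2] + voxel * k - az;
      for (int j = j0; j <= j1; ++j) {
        const double dy = origin[1] + voxel * j - ay;
        const double ryz = dy * dy + dz * dz;
        if (ryz > r2) continue;
        R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
        for (int i = i0; i <= i1; ++i) {
          const double dx = origin[0] + voxel * i - ax;
          if (dx * dx + ryz <= r2) out[base + i] = true;
        }
      }
    }
  }
  return out;
}

static double overlap_score(const std::vector<double> &x,
                            const std::vector<double> &y,
                            const std::vector<double> &z,
                            const NumericVector &w, double wsum,
                            const NumericVector &values,
                            int nx, int ny, int nz,
                            const NumericVector &origin, double voxel) {
  double acc = 0.0;
  const int n = (int)x.size();
  for (int a = 0; a < n; ++a) {
    double fx = (x[a] - origin[0]) / voxel;
    double fy = (y[a] - origin[1]) / voxel;
    double fz = (z[a] - origin[2]) / voxel;
    int i = (int)std::floor(fx), j = (int)std::floor(fy), k = (int)std::floor(fz);
    if (i < 0 || j < 0 || k < 0 || i > nx - 2 || j > ny - 2 || k > nz - 2)
      continue;
    double tx = fx - i, ty = fy - j, tz = fz - k;
    R_xlen_t b = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx + i;
    R_xlen_t by = nx, bz = (R_xlen_t)nx * ny;
    double c00 = values[b] * (1 - tx) + values[b + 1] * tx;
    double c10 = values[b + by] * (1 - tx) + values[b + by + 1] * tx;
    double c01 = values[b + bz] * (1 - tx) + values[b + bz + 1] * tx;
    double c11 = values[b + bz + by] * (1 - tx) + values[b + bz + by + 1] * tx;
    double c0 = c00 * (1 - ty) + c10 * ty;
    double c1 = c01 * (1 - ty) + c11 * ty;
    acc += w[a] * (c0 * (1 - tz) + c1 * tz);
  }
  return acc / wsum;
}

static void axis_rot(int axis, double ang, double R[3][3]) {
  double c = std::cos(ang), s = std::sin(ang);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[i][j] = (i == j) ? 1.0 : 0.0;
  int i1 = (axis + 1) % 3, i2 = (axis + 2) % 3;
  R[i1][i1] = c; R[i1][i2] = -s; R[i2][i1] = s; R[i2][i2] = c;
}

// Greedy pattern search maximizing the density-overlap objective over
// rigid placements: +-step translations along axes and +-step rotations
// about axes through the model centroid, with step halving.
// [[Rcpp::export]]
List cpp_refine_overlap(NumericMatrix xyz0, NumericVector w,
                        NumericVector values, IntegerVector dim,
                        NumericVector origin, double voxel,
                        NumericMatrix R0, NumericVector t0,
                        double trans_step, double rot_step,
                        int max_iter, double tol) {
  const int n = xyz0.nrow();
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  double wsum = 0.0;
  for (int a = 0; a < n; ++a) wsum += w[a];
  double R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) R[i][j] = R0(i, j);
  double t[3] = { t0[0], t0[1], t0[2] };
  std::vector<double> px(n), py(n), pz(n);
  // placed coordinates under (R, t)
  #define PLACE(RR, TT)                                              \
    for (int a = 0; a < n; ++a) {                                    \
      double X = xyz0(a, 0), Y = xyz0(a, 1), Z = xyz0(a, 2);         \
      px[a] = RR[0][0] * X + RR[0][1] * Y + RR[0][2] * Z + TT[0];    \
      py[a] = RR[1][0] * X + RR[1][1] * Y + RR[1][2] * Z + TT[1];    \
      pz[a] = RR[2][0] * X + RR[2][1] * Y + RR[2][2] * Z + TT[2];    \
    }
  PLACE(R, t);
  double cur = overlap_score(px, py, pz, w, wsum, values, nx, ny, nz,
                             origin, voxel);
  double ts = trans_step, rs = rot_step;
  for (int it = 0; it < max_iter; ++it) {
    // centroid of current placement
    double cx = 0, cy = 0, cz = 0;
    for (int a = 0; a < n; ++a) { cx += px[a]; cy += py[a]; cz += pz[a]; }
    cx /= n; cy /= n; cz /= n;
    double bestR[3][3], bestT[3], best = cur;
    bool found = false;
    for (int d = 0; d < 3; ++d) {
      for (int s = -1; s <= 1; s += 2) {
        // translation move
        double t2[3] = { t[0], t[1], t[2] };
        t2[d] += s * ts;
        PLACE(R, t2);
        double sc = overlap_score(px, py, pz, w, wsum, values, nx, ny, nz,
                                  origin, voxel);
        if (sc > best) {
          best = sc; found = true;
          for (int i = 0; i < 3; ++i) {
            for (int j = 0; j < 3; ++j) bestR[i][j] = R[i][j];
            bestT[i] = t2[i];
          }
        }
        // rotation about centroid
        double Rs[3][3];
        axis_rot(d, s * rs, Rs);
        double Rn[3][3], tn[3];
        for (int i = 0; i < 3; ++i)
          for (int j = 0; j < 3; ++j) {
            Rn[i][j] = 0;
            for (int k = 0; k < 3; ++k) Rn[i][j] += Rs[i][k] * R[k][j];
          }
        double cvec[3] = { cx, cy, cz };
        for (int i = 0; i < 3; ++i) {
          double rc = 0;
          for (int k = 0; k < 3; ++k) rc += Rs[i][k] * cvec[k];
          tn[i] = cvec[i] - rc;
          double rt = 0;
          for (int k = 0; k < 3; ++k) rt += Rs[i][k] * t[k];
          tn[i] += rt;
        }
        PLACE(Rn, tn);
        sc = overlap_score(px, py, pz, w, wsum, values, nx, ny, nz,
                           origin, voxel);
        if (sc > best) {
          best = sc; found = true;
          for (int i = 0; i < 3; ++i) {
            for (int j = 0; j < 3; ++j) bestR[i][j] = Rn[i][j];
            bestT[i] = tn[i];
          }
        }
      }
    }
    if (!found || best - cur < tol) {
      if (ts <= trans_step / 8) break;
      ts /= 2; rs /= 2;
      if (found) {
        for (int i = 0; i < 3; ++i) {
          for (int j = 0; j < 3; ++j) R[i][j] = bestR[i][j];
          t[i] = bestT[i];
        }
        cur = best;
      }
    } else {
      for (int i = 0; i < 3; ++i) {
        for (int j = 0; j < 3; ++j) R[i][j] = bestR[i][j];
        t[i] = bestT[i];
      }
      cur = best;
    }
    PLACE(R, t);
  }
  #undef PLACE
  NumericMatrix Rout(3, 3);
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) Rout(i, j) = R[i][j];
  return List::create(_["rotation"] = Rout,
                      _["translation"] = NumericVector::create(t[0], t[1], t[2]),
                      _["score"] = cur);
}
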