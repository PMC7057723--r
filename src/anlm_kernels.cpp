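// ANLM filter kernels.
//
// All neighbourhood sums are computed as direct separable small-kernel sums
// (x, then y, then z, ascending offsets) so that every output voxel's value
// is produced by the same floating-point operations in the same order
// regardless of how the volume is partitioned into tiles. This is what makes
// the tiled execution path bit-identical to the untiled one.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cfloat>
#include <cstdint>

using namespace Rcpp;

static inline int reflect_index(int i, int n) {
  // symmetric (half-sample) mirror: -1 -> 0, -2 -> 1, n -> n-1, ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -1 - i;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// Mirror-pad a 3-D array by margin m on every side.
// [[Rcpp::export]]
NumericVector cpp_mirror_pad(NumericVector u, IntegerVector dims, int m) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = nx + 2 * m, py = ny + 2 * m, pz = nz + 2 * m;
  NumericVector out((R_xlen_t)px * py * pz);
  const double *src = u.begin();
  double *dst = out.begin();
  for (int z = 0; z < pz; ++z) {
    int sz = reflect_index(z - m, nz);
    for (int y = 0; y < py; ++y) {
      int sy = reflect_index(y - m, ny);
      const double *row = src + (R_xlen_t)nx * (sy + (R_xlen_t)ny * sz);
      double *orow = dst + (R_xlen_t)px * (y + (R_xlen_t)py * z);
      for (int x = 0; x < px; ++x)
        orow[x] = row[reflect_index(x - m, nx)];
    }
  }
  return out;
}

// Separable direct box sum of radius r along one axis, over the index range
// where the full window fits given that input is valid in [lo, n-hi) on that
// axis. Outside the computed range the output is left as-is.
static void axis_box_sum(const std::vector<double> &in, std::vector<double> &out,
                         int nx, int ny, int nz, int axis, int r,
                         int vx0, int vx1, int vy0, int vy1, int vz0, int vz1) {
  // valid output range shrinks by r along `axis` relative to input validity
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  int x0 = vx0 + (axis == 0 ? r : 0), x1 = vx1 - (axis == 0 ? r : 0);
  int y0 = vy0 + (axis == 1 ? r : 0), y1 = vy1 - (axis == 1 ? r : 0);
  int z0 = vz0 + (axis == 2 ? r : 0), z1 = vz1 - (axis == 2 ? r : 0);
  for (int z = z0; z < z1; ++z)
    for (int y = y0; y < y1; ++y) {
      R_xlen_t base = sx * x0 + sy * y + sz * z;
      const double *ip = in.data() + base;
      double *op = out.data() + base;
      for (int x = x0; x < x1; ++x, ip += 1, op += 1) {
        double s = 0.0;
        const double *q = ip - (R_xlen_t)r * stride;
        for (int k = 0; k < 2 * r + 1; ++k, q += stride) s += *q;
        *op = s;
      }
    }
}

static void axis_min(const std::vector<double> &in, std::vector<double> &out,
                     int nx, int ny, int nz, int axis, int r,
                     int vx0, int vx1, int vy0, int vy1, int vz0, int vz1) {
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride = axis == 0 ? sx : (axis == 1 ? sy : sz);
  int x0 = vx0 + (axis == 0 ? r : 0), x1 = vx1 - (axis == 0 ? r : 0);
  int y0 = vy0 + (axis == 1 ? r : 0), y1 = vy1 - (axis == 1 ? r : 0);
  int z0 = vz0 + (axis == 2 ? r : 0), z1 = vz1 - (axis == 2 ? r : 0);
  for (int z = z0; z < z1; ++z)
    for (int y = y0; y < y1; ++y) {
      R_xlen_t base = sx * x0 + sy * y + sz * z;
      const double *ip = in.data() + base;
      double *op = out.data() + base;
      for (int x = x0; x < x1; ++x, ip += 1, op += 1) {
        double s = DBL_MAX;
        const double *q = ip - (R_xlen_t)r * stride;
        for (int k = 0; k < 2 * r + 1; ++k, q += stride)
          if (*q < s) s = *q;
        *op = s;
      }
    }
}

// Box-filter mean with neighbourhoods clipped at the volume boundary and
// the divisor reduced to the actual voxel count (product of per-axis
// window extents).
// [[Rcpp::export]]
NumericVector cpp_box_mean_clipped(NumericVector u, IntegerVector dims, int rB) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> a(u.begin(), u.end()), b(n), cnt(n);
  // clipped separable sums, axis by axis
  for (int axis = 0; axis < 3; ++axis) {
    const int na = axis == 0 ? nx : (axis == 1 ? ny : nz);
    const R_xlen_t stride = axis == 0 ? 1 :
      (axis == 1 ? (R_xlen_t)nx : (R_xlen_t)nx * ny);
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int ia = axis == 0 ? x : (axis == 1 ? y : z);
          int k0 = ia - rB < 0 ? -ia : -rB;
          int k1 = ia + rB >= na ? na - 1 - ia : rB;
          R_xlen_t idx = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          double s = 0.0;
          for (int k = k0; k <= k1; ++k) s += a[idx + (R_xlen_t)k * stride];
          b[idx] = s;
          if (axis == 0) cnt[idx] = (double)(k1 - k0 + 1);
          else cnt[idx] *= (double)(k1 - k0 + 1);
        }
    std::swap(a, b);
  }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = a[i] / cnt[i];
  return out;
}

struct PaddedStats {
  std::vector<double> up, bm, bv; // padded input, box mean, box sample var
  std::vector<double> sigma2;     // adaptive noise variance, core voxels
  int px, py, pz, m;
};

// Full preprocessing pipeline on a mirror-padded copy of the volume:
// box mean/variance, pseudo-residual R = u - boxmean, locally averaged
// squared residual, search-volume minimum, calibration to an (approximately)
// unbiased white-noise variance estimate.
static void precompute(const NumericVector &u, const IntegerVector &dims,
                       int rV, int rP, int rB,
                       double gamma_total, double min_sigma,
                       PaddedStats &st) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int m = rV + std::max(rP, 2 * rB); // margin covering every read
  const int px = nx + 2 * m, py = ny + 2 * m, pz = nz + 2 * m;
  const R_xlen_t np = (R_xlen_t)px * py * pz;
  st.px = px; st.py = py; st.pz = pz; st.m = m;

  NumericVector upv = cpp_mirror_pad(u, dims, m);
  st.up.assign(upv.begin(), upv.end());

  const double NB = std::pow(2.0 * rB + 1.0, 3);
  std::vector<double> s1(np, 0.0), s2(np, 0.0), t1(np, 0.0);

  // box sums of u and u^2 (full windows; valid in [rB, p-rB) per axis)
  std::vector<double> u2(np);
  for (R_xlen_t i = 0; i < np; ++i) u2[i] = st.up[i] * st.up[i];
  std::vector<double> a = st.up, b(np, 0.0);
  axis_box_sum(a, b, px, py, pz, 0, rB, 0, px, 0, py, 0, pz);
  axis_box_sum(b, s1, px, py, pz, 1, rB, rB, px - rB, 0, py, 0, pz);
  std::fill(b.begin(), b.end(), 0.0);
  axis_box_sum(s1, b, px, py, pz, 2, rB, rB, px - rB, rB, py - rB, 0, pz);
  std::vector<double> bsum = b; // sum of u over box

  std::fill(b.begin(), b.end(), 0.0);
  axis_box_sum(u2, b, px, py, pz, 0, rB, 0, px, 0, py, 0, pz);
  std::fill(s1.begin(), s1.end(), 0.0);
  axis_box_sum(b, s1, px, py, pz, 1, rB, rB, px - rB, 0, py, 0, pz);
  std::fill(b.begin(), b.end(), 0.0);
  axis_box_sum(s1, b, px, py, pz, 2, rB, rB, px - rB, rB, py - rB, 0, pz);

  st.bm.assign(np, 0.0);
  st.bv.assign(np, 0.0);
  std::vector<double> R2(np, 0.0);
  for (int z = rB; z < pz - rB; ++z)
    for (int y = rB; y < py - rB; ++y)
      for (int x = rB; x < px - rB; ++x) {
        R_xlen_t i = x + (R_xlen_t)px * (y + (R_xlen_t)py * z);
        double mu = bsum[i] / NB;
        double ex2 = b[i] / NB;
        double v = (ex2 - mu * mu) * NB / (NB - 1.0);
        st.bm[i] = mu;
        st.bv[i] = v > 0.0 ? v : 0.0;
        double r = st.up[i] - mu;
        R2[i] = r * r;
      }

  // locally averaged squared residual (valid in [2rB, p-2rB))
  std::fill(s1.begin(), s1.end(), 0.0);
  std::fill(b.begin(), b.end(), 0.0);
  std::fill(t1.begin(), t1.end(), 0.0);
  axis_box_sum(R2, s1, px, py, pz, 0, rB, rB, px - rB, rB, py - rB, rB, pz - rB);
  axis_box_sum(s1, b, px, py, pz, 1, rB, 2 * rB, px - 2 * rB, rB, py - rB, rB, pz - rB);
  axis_box_sum(b, t1, px, py, pz, 2, rB, 2 * rB, px - 2 * rB, 2 * rB, py - 2 * rB, rB, pz - rB);
  std::vector<double> s2loc(np, DBL_MAX);
  for (int z = 2 * rB; z < pz - 2 * rB; ++z)
    for (int y = 2 * rB; y < py - 2 * rB; ++y)
      for (int x = 2 * rB; x < px - 2 * rB; ++x) {
        R_xlen_t i = x + (R_xlen_t)px * (y + (R_xlen_t)py * z);
        s2loc[i] = t1[i] / NB;
      }

  // minimum over the search volume (valid at the core)
  std::vector<double> mn1(np, DBL_MAX), mn2(np, DBL_MAX), mn3(np, DBL_MAX);
  int lo = 2 * rB;
  axis_min(s2loc, mn1, px, py, pz, 0, rV, lo, px - lo, lo, py - lo, lo, pz - lo);
  axis_min(mn1, mn2, px, py, pz, 1, rV, lo + rV, px - lo - rV, lo, py - lo, lo, pz - lo);
  axis_min(mn2, mn3, px, py, pz, 2, rV, lo + rV, px - lo - rV, lo + rV, py - lo - rV, lo, pz - lo);

  const double floor2 = min_sigma * min_sigma;
  st.sigma2.assign((R_xlen_t)nx * ny * nz, 0.0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t ip = (x + m) + (R_xlen_t)px * ((y + m) + (R_xlen_t)py * (z + m));
        double s = gamma_total * mn3[ip];
        if (s < floor2) s = floor2;
        st.sigma2[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] = s;
      }
}

// [[Rcpp::export]]
List cpp_anlm_precompute(NumericVector u, IntegerVector dims,
                         int rV, int rP, int rB,
                         double gamma_total, double min_sigma) {
  PaddedStats st;
  precompute(u, dims, rV, rP, rB, gamma_total, min_sigma, st);
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int px = st.px, py = st.py, m = st.m;
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector bm(n), bv(n), res(n), s2(n);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        R_xlen_t ic = x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
        R_xlen_t ip = (x + m) + (R_xlen_t)px * ((y + m) + (R_xlen_t)py * (z + m));
        bm[ic] = st.bm[ip];
        bv[ic] = st.bv[ip];
        res[ic] = st.up[ip] - st.bm[ip];
        s2[ic] = st.sigma2[ic];
      }
  return List::create(_["box_mean"] = bm, _["box_var"] = bv,
                      _["residual"] = res, _["sigma2"] = s2);
}

static inline bool ratio_ok(double a, double b, double lo, double hi,
                            double tiny) {
  if (b <= tiny) return a <= tiny;
  if (a <= tiny) return false;
  double r = a / b;
  return r >= lo && r <= hi;
}

// The weighted-average accumulation (Eqs. (1)-(2) structure) over one core
// region, given padded input and padded preselection statistics. `x0..z1`
// select the core sub-block (in core coordinates) to process, enabling
// tiled execution; arithmetic per voxel is independent of the sub-block.
static void accumulate_block(const PaddedStats &st, const IntegerVector &dims,
                             int rV, int rP, double beta,
                             double q, double vlo, double vhi,
                             double tiny_mean, double tiny_var,
                             bool rician,
                             int x0, int x1, int y0, int y1, int z0, int z1,
                             double *out) {
  const int nx = dims[0], ny = dims[1];
  const int px = st.px, py = st.py, m = st.m;
  const int bx = x1 - x0, by = y1 - y0, bz = z1 - z0;
  const double patchN = std::pow(2.0 * rP + 1.0, 3);
  const R_xlen_t nb = (R_xlen_t)bx * by * bz;

  std::vector<double> accw(nb, 0.0), accv(nb, 0.0), wmax(nb, 0.0);

  // scratch region: block core extended by rP for patch sums
  const int ex = bx + 2 * rP, ey = by + 2 * rP, ez = bz + 2 * rP;
  const R_xlen_t ne = (R_xlen_t)ex * ey * ez;
  std::vector<double> D(ne), S1(ne), S2(ne), S3(ne);

  for (int tz = -rV; tz <= rV; ++tz)
    for (int ty = -rV; ty <= rV; ++ty)
      for (int tx = -rV; tx <= rV; ++tx) {
        if (tx == 0 && ty == 0 && tz == 0) continue;
        const R_xlen_t toff = tx + (R_xlen_t)px * (ty + (R_xlen_t)py * tz);
        // squared differences over block +/- rP
        for (int z = 0; z < ez; ++z) {
          int pzc = z0 + z - rP + m; // padded z of scratch voxel
          for (int y = 0; y < ey; ++y) {
            int pyc = y0 + y - rP + m;
            const double *urow = st.up.data() + (R_xlen_t)(x0 - rP + m) +
              (R_xlen_t)px * (pyc + (R_xlen_t)py * pzc);
            double *drow = D.data() + (R_xlen_t)ex * (y + (R_xlen_t)ey * z);
            for (int x = 0; x < ex; ++x) {
              double d = urow[x] - urow[x + toff];
              drow[x] = d * d;
            }
          }
        }
        // separable patch sums (direct, fixed order)
        std::fill(S1.begin(), S1.end(), 0.0);
        std::fill(S2.begin(), S2.end(), 0.0);
        std::fill(S3.begin(), S3.end(), 0.0);
        axis_box_sum(D, S1, ex, ey, ez, 0, rP, 0, ex, 0, ey, 0, ez);
        axis_box_sum(S1, S2, ex, ey, ez, 1, rP, rP, ex - rP, 0, ey, 0, ez);
        axis_box_sum(S2, S3, ex, ey, ez, 2, rP, rP, ex - rP, rP, ey - rP, 0, ez);

        // accumulate weights for this offset
        for (int z = 0; z < bz; ++z)
          for (int y = 0; y < by; ++y) {
            const int pyc = y0 + y + m, pzc = z0 + z + m;
            const R_xlen_t prow = (R_xlen_t)(x0 + m) +
              (R_xlen_t)px * (pyc + (R_xlen_t)py * pzc);
            const R_xlen_t srow = (R_xlen_t)rP +
              (R_xlen_t)ex * ((y + rP) + (R_xlen_t)ey * (z + rP));
            const R_xlen_t crow = (R_xlen_t)bx * (y + (R_xlen_t)by * z);
            const R_xlen_t c0row = (R_xlen_t)x0 +
              (R_xlen_t)nx * ((R_xlen_t)(y0 + y) + (R_xlen_t)ny * (z0 + z));
            for (int x = 0; x < bx; ++x) {
              double s2i = st.sigma2[c0row + x];
              if (s2i <= 0.0) continue;
              R_xlen_t pi = prow + x, pj = pi + toff;
              if (!ratio_ok(st.bm[pi], st.bm[pj], q, 1.0 / q, tiny_mean))
                continue;
              if (!ratio_ok(st.bv[pi], st.bv[pj], vlo, vhi, tiny_var))
                continue;
              double d2 = S3[srow + x] / patchN;
              double h2 = 2.0 * beta * s2i;
              double arg = d2 / h2;
              double w = arg > 745.0 ? 0.0 : std::exp(-arg);
              R_xlen_t c = crow + x;
              double uj = st.up[pj];
              accw[c] += w;
              accv[c] += w * (rician ? uj * uj : uj);
              if (w > wmax[c]) wmax[c] = w;
            }
          }
      }

  // centre voxel: weight = max accepted non-centre weight (1 if none)
  for (int z = 0; z < bz; ++z)
    for (int y = 0; y < by; ++y)
      for (int x = 0; x < bx; ++x) {
        R_xlen_t c = x + (R_xlen_t)bx * (y + (R_xlen_t)by * z);
        R_xlen_t ic = (R_xlen_t)(x0 + x) +
          (R_xlen_t)nx * ((R_xlen_t)(y0 + y) + (R_xlen_t)ny * (z0 + z));
        R_xlen_t ip = (R_xlen_t)(x0 + x + m) +
          (R_xlen_t)px * ((R_xlen_t)(y0 + y + m) +
                          (R_xlen_t)py * (z0 + z + m));
        double ui = st.up[ip];
        double s2i = st.sigma2[ic];
        if (s2i <= 0.0) {
          out[c] = rician ? ui * ui : ui;
          continue;
        }
        double wc = wmax[c] > 0.0 ? wmax[c] : 1.0;
        double vc = rician ? ui * ui : ui;
        out[c] = (accv[c] + wc * vc) / (accw[c] + wc);
      }
}

// Full filter pass. block_dims of 0 means untiled (one block).
// [[Rcpp::export]]
NumericVector cpp_filter_pass(NumericVector u, IntegerVector dims,
                              int rV, int rP, int rB,
                              double beta, double presel_mean_ratio,
                              double presel_var_low, double presel_var_high,
                              double min_sigma, double gamma_total,
                              bool rician, IntegerVector block_dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  PaddedStats st;
  precompute(u, dims, rV, rP, rB, gamma_total, min_sigma, st);

  // scale-invariant zero tolerances for the preselection ratio tests
  double mmax = 0.0, vmax = 0.0;
  for (size_t i = 0; i < st.bm.size(); ++i) {
    if (st.bm[i] > mmax) mmax = st.bm[i];
    if (st.bv[i] > vmax) vmax = st.bv[i];
  }
  const double tiny_mean = 1e-12 * mmax, tiny_var = 1e-12 * vmax;

  int Tx = block_dims[0] > 0 ? block_dims[0] : nx;
  int Ty = block_dims[1] > 0 ? block_dims[1] : ny;
  int Tz = block_dims[2] > 0 ? block_dims[2] : nz;

  NumericVector outv((R_xlen_t)nx * ny * nz);
  std::vector<double> blockbuf;
  for (int z0 = 0; z0 < nz; z0 += Tz)
    for (int y0 = 0; y0 < ny; y0 += Ty)
      for (int x0 = 0; x0 < nx; x0 += Tx) {
        int x1 = std::min(x0 + Tx, nx);
        int y1 = std::min(y0 + Ty, ny);
        int z1 = std::min(z0 + Tz, nz);
        blockbuf.assign((R_xlen_t)(x1 - x0) * (y1 - y0) * (z1 - z0), 0.0);
        accumulate_block(st, dims, rV, rP, beta,
                         presel_mean_ratio, presel_var_low, presel_var_high,
                         tiny_mean, tiny_var, rician,
                         x0, x1, y0, y1, z0, z1, blockbuf.data());
        const int bx = x1 - x0, by = y1 - y0;
        for (int z = z0; z < z1; ++z)
          for (int y = y0; y < y1; ++y)
            for (int x = x0; x < x1; ++x)
              outv[x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z)] =
                blockbuf[(x - x0) +
                         (R_xlen_t)bx * ((y - y0) + (R_xlen_t)by * (z - z0))];
      }
  return outv;
}
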