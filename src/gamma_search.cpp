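// Gamma-index search kernel. For each included reference voxel, minimizes
// sqrt(|r|^2/DTA^2 + dDose^2/ddabs^2) over candidate positions of the
// evaluated grid: always over evaluated voxel centers within the capped
// search radius, and optionally (interp = true) over a sub-voxel lattice of
// step `step` with trilinear interpolation. Results are capped at `cap`.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Grid {
  const double* v;
  int n[3];
  double org[3], sp[3];
};

static inline bool trilin(const Grid& g, const double* p, double& out) {
  double f[3];
  int i0[3];
  double w[3];
  for (int a = 0; a < 3; ++a) {
    f[a] = (p[a] - g.org[a]) / g.sp[a];
    if (f[a] < -1e-9 || f[a] > g.n[a] - 1 + 1e-9) return false;
    if (f[a] < 0) f[a] = 0;
    if (f[a] > g.n[a] - 1) f[a] = g.n[a] - 1;
    if (g.n[a] == 1) { i0[a] = 0; w[a] = 0.0; }
    else {
      i0[a] = (int)std::floor(f[a]);
      if (i0[a] > g.n[a] - 2) i0[a] = g.n[a] - 2;
      w[a] = f[a] - i0[a];
    }
  }
  const int nx = g.n[0], nxy = g.n[0] * g.n[1];
  const int b = i0[0] + nx * i0[1] + nxy * i0[2];
  const int dx = (g.n[0] > 1) ? 1 : 0;
  const int dy = (g.n[1] > 1) ? nx : 0;
  const int dz = (g.n[2] > 1) ? nxy : 0;
  const double wx = w[0], wy = w[1], wz = w[2];
  out =
    (1 - wx) * (1 - wy) * (1 - wz) * g.v[b] +
    wx * (1 - wy) * (1 - wz) * g.v[b + dx] +
    (1 - wx) * wy * (1 - wz) * g.v[b + dy] +
    wx * wy * (1 - wz) * g.v[b + dx + dy] +
    (1 - wx) * (1 - wy) * wz * g.v[b + dz] +
    wx * (1 - wy) * wz * g.v[b + dx + dz] +
    (1 - wx) * wy * wz * g.v[b + dy + dz] +
    wx * wy * wz * g.v[b + dx + dy + dz];
  return true;
}

struct Offset { double d2, x, y, z; };

// [[Rcpp::export]]
NumericVector cpp_gamma_search(
    NumericVector ref_vals, IntegerVector ref_dim,
    NumericVector ref_org, NumericVector ref_sp,
    NumericVector ev_vals, IntegerVector ev_dim,
    NumericVector ev_org, NumericVector ev_sp,
    IntegerVector idx,     // 0-based linear indices of ref voxels to evaluate
    double dd_abs, double dta, double step, double cap, bool interp) {

  Grid ev;
  ev.v = ev_vals.begin();
  for (int a = 0; a < 3; ++a) {
    ev.n[a] = ev_dim[a]; ev.org[a] = ev_org[a]; ev.sp[a] = ev_sp[a];
  }
  const double rmax = cap * dta;
  const double dta2 = dta * dta, dd2 = dd_abs * dd_abs;

  // sub-voxel lattice offsets within the capped radius, nearest first
  std::vector<Offset> offs;
  if (interp) {
    int ns = (int)std::floor(rmax / step);
    offs.reserve((size_t)(2 * ns + 1) * (2 * ns + 1));
    for (int i = -ns; i <= ns; ++i)
      for (int j = -ns; j <= ns; ++j)
        for (int k = -ns; k <= ns; ++k) {
          double x = i * step, y = j * step, z = k * step;
          double d2 = x * x + y * y + z * z;
          if (d2 <= rmax * rmax) offs.push_back({d2, x, y, z});
        }
    std::sort(offs.begin(), offs.end(),
              [](const Offset& a, const Offset& b) { return a.d2 < b.d2; });
  }

  const int rnx = ref_dim[0], rny = ref_dim[1];
  const int m = idx.size();
  NumericVector out(m);

  for (int t = 0; t < m; ++t) {
    const int li = idx[t];
    const int ix = li % rnx, iy = (li / rnx) % rny, iz = li / (rnx * rny);
    const double px = ref_org[0] + ix * ref_sp[0];
    const double py = ref_org[1] + iy * ref_sp[1];
    const double pz = ref_org[2] + iz * ref_sp[2];
    const double dr = ref_vals[li];

    double best2 = cap * cap;

    // evaluated voxel centers inside the search sphere (exact values)
    int lo[3], hi[3];
    const double p[3] = {px, py, pz};
    bool any_axis = true;
    for (int a = 0; a < 3; ++a) {
      lo[a] = (int)std::ceil((p[a] - rmax - ev.org[a]) / ev.sp[a] - 1e-12);
      hi[a] = (int)std::floor((p[a] + rmax - ev.org[a]) / ev.sp[a] + 1e-12);
      if (lo[a] < 0) lo[a] = 0;
      if (hi[a] > ev.n[a] - 1) hi[a] = ev.n[a] - 1;
      if (lo[a] > hi[a]) any_axis = false;
    }
    if (any_axis) {
      for (int k = lo[2]; k <= hi[2]; ++k) {
        const double ddz = ev.org[2] + k * ev.sp[2] - pz;
        for (int j = lo[1]; j <= hi[1]; ++j) {
          const double ddy = ev.org[1] + j * ev.sp[1] - py;
          const double d2yz = ddz * ddz + ddy * ddy;
          if (d2yz / dta2 >= best2) continue;
          const double* row = ev.v + (size_t)ev.n[0] * (j + (size_t)ev.n[1] * k);
          for (int i = lo[0]; i <= hi[0]; ++i) {
            const double ddx = ev.org[0] + i * ev.sp[0] - px;
            const double d2 = d2yz + ddx * ddx;
            const double sterm = d2 / dta2;
            if (sterm >= best2) continue;
            const double dd = row[i] - dr;
            const double g2 = sterm + dd * dd / dd2;
            if (g2 < best2) best2 = g2;
          }
        }
      }
    }

    if (interp) {
      for (size_t s = 0; s < offs.size(); ++s) {
        const double sterm = offs[s].d2 / dta2;
        if (sterm >= best2) break;  // sorted: nothing further can win
        double q[3] = {px + offs[s].x, py + offs[s].y, pz + offs[s].z};
        double de;
        if (!trilin(ev, q, de)) continue;
        const double dd = de - dr;
        const double g2 = sterm + dd * dd / dd2;
        if (g2 < best2) best2 = g2;
      }
    }
    out[t] = std::sqrt(best2);
  }
  return out;
}
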