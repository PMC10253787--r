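#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Largest-probe radius in one axial slice, HOLE-style.
//
// The probe centre is constrained to the plane at height z, within
// lateral_bound of the running centre (cx, cy). The objective
//   f(p) = min_i ( |p - atom_i| - vdw_i )
// is maximised LOCALLY, tracking the pore basin the way HOLE's annealing
// does: five deterministic starts near the running centre, each climbed by
// a shrinking-step pattern search, then the best point refined against a
// small coarse grid and climbed again. Every stage compares objective
// values only, so the search path is invariant under a uniform shift of
// all vdW radii (which shifts f by a constant); this gives the exact
// monotonicity property of the profiler. Returns c(radius, x, y, capped).
//
// [[Rcpp::export(name = ".pore_slice_cpp")]]
NumericVector pore_slice_cpp(NumericMatrix coords, NumericVector radii,
                             double z, double cx, double cy,
                             double lateral_bound, double coarse_step,
                             double cap, double tol) {
  const int n = coords.nrow();
  std::vector<double> ax, ay, adz2, ar;
  ax.reserve(n); ay.reserve(n); adz2.reserve(n); ar.reserve(n);
  for (int i = 0; i < n; ++i) {
    const double dz = coords(i, 2) - z;
    // atoms that cannot bind the objective below the cap anywhere in the
    // search disc are dropped
    if (std::fabs(dz) > cap + radii[i]) continue;
    const double lx = coords(i, 0) - cx, ly = coords(i, 1) - cy;
    if (std::sqrt(lx * lx + ly * ly) > lateral_bound + cap + radii[i]) continue;
    ax.push_back(coords(i, 0));
    ay.push_back(coords(i, 1));
    adz2.push_back(dz * dz);
    ar.push_back(radii[i]);
  }
  if (ax.empty()) {
    return NumericVector::create(cap, cx, cy, 1.0);
  }
  const size_t m = ax.size();
  auto f = [&](double px, double py) {
    double best = R_PosInf;
    for (size_t i = 0; i < m; ++i) {
      const double dx = px - ax[i], dy = py - ay[i];
      const double d = std::sqrt(dx * dx + dy * dy + adz2[i]) - ar[i];
      if (d < best) best = d;
    }
    return best;
  };
  const double b2 = lateral_bound * lateral_bound;
  auto in_bound = [&](double px, double py) {
    const double ox = px - cx, oy = py - cy;
    return ox * ox + oy * oy <= b2;
  };
  // shrinking-step pattern search (compass directions)
  auto climb = [&](double sx, double sy, double step0,
                   double &bx, double &by, double &bf) {
    double px = sx, py = sy, pf = f(sx, sy);
    double step = step0;
    while (step > tol) {
      bool improved = false;
      const double dxs[4] = { step, -step, 0.0, 0.0 };
      const double dys[4] = { 0.0, 0.0, step, -step };
      for (int k = 0; k < 4; ++k) {
        const double qx = px + dxs[k], qy = py + dys[k];
        if (!in_bound(qx, qy)) continue;
        const double v = f(qx, qy);
        if (v > pf) { pf = v; px = qx; py = qy; improved = true; }
      }
      if (!improved) step *= 0.5;
    }
    if (pf > bf) { bf = pf; bx = px; by = py; }
  };
  double bx = cx, by = cy, bf = f(cx, cy);
  const double off = 4.0 * coarse_step;
  const double sxs[5] = { cx, cx + off, cx - off, cx + off, cx - off };
  const double sys[5] = { cy, cy + off, cy + off, cy - off, cy - off };
  for (int s = 0; s < 5; ++s) {
    if (!in_bound(sxs[s], sys[s])) continue;
    climb(sxs[s], sys[s], coarse_step, bx, by, bf);
  }
  // coarse-grid refinement around the incumbent, then a final climb
  const int ng = 4;
  double gx = bx, gy = by, gf = bf;
  for (int ix = -ng; ix <= ng; ++ix) {
    for (int iy = -ng; iy <= ng; ++iy) {
      const double qx = bx + ix * coarse_step, qy = by + iy * coarse_step;
      if (!in_bound(qx, qy)) continue;
      const double v = f(qx, qy);
      if (v > gf) { gf = v; gx = qx; gy = qy; }
    }
  }
  climb(gx, gy, coarse_step, bx, by, bf);
  bool capped = false;
  if (bf >= cap) { bf = cap; capped = true; }
  if (bf < 0.0) bf = 0.0;
  return NumericVector::create(bf, bx, by, capped ? 1.0 : 0.0);
}
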