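#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Boundary codes: 0 = closed (zero-flux walls), 1 = periodic, 2 = fixed
// (Dirichlet: outermost cells along that axis are held at their initial
// values, emulating a far-field reservoir).
//
// Flux-form update: for every interior face the diffusive flux
// -D (cR - cL)/h and the first-order upwind advective flux v * c_upwind are
// computed once and applied antisymmetrically to the two adjacent cells, so
// mass is conserved to round-off with closed/periodic walls.

static inline int wrap(int i, int n) { return (i + n) % n; }

// One explicit step on a 2-D field stored column-major like R:
// C(i, j), i = row (y), j = col (x).
static void step2d(NumericMatrix &cur, NumericMatrix &nxt,
                   double D, double vx, double vy, double h, double dt,
                   int by, int bx, double decay) {
  const int n = cur.nrow(), m = cur.ncol();
  const double r = dt / h;
  // start from current values
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) nxt(i, j) = cur(i, j);

  // x-direction faces: between columns j-1 and j
  for (int j = 0; j <= m; ++j) {
    int jl = j - 1, jr = j;
    bool wall = (j == 0 || j == m);
    if (wall) {
      // periodic: the wrap face is handled once, at j == 0
      if (bx == 1 && j == 0) { jl = wrap(j - 1, m); jr = 0; }
      else continue; // closed/fixed walls, or the duplicate periodic face
    }
    for (int i = 0; i < n; ++i) {
      double cl = cur(i, jl), cr = cur(i, jr);
      double F = -D * (cr - cl) / h + vx * (vx > 0 ? cl : cr);
      nxt(i, jl) -= r * F;
      nxt(i, jr) += r * F;
    }
  }
  // y-direction faces: between rows i-1 and i
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i <= n; ++i) {
      int il = i - 1, ir = i;
      bool wall = (i == 0 || i == n);
      if (wall) {
        if (by == 1 && i == 0) { il = wrap(i - 1, n); ir = 0; }
        else continue;
      }
      double cl = cur(il, j), cr = cur(ir, j);
      double F = -D * (cr - cl) / h + vy * (vy > 0 ? cl : cr);
      nxt(il, j) -= r * F;
      nxt(ir, j) += r * F;
    }
  }
  if (decay != 1.0) {
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) nxt(i, j) *= decay;
  }
  // fixed boundaries: restore edge cells to their pre-step values
  if (bx == 2) {
    for (int i = 0; i < n; ++i) { nxt(i, 0) = cur(i, 0); nxt(i, m - 1) = cur(i, m - 1); }
  }
  if (by == 2) {
    for (int j = 0; j < m; ++j) { nxt(0, j) = cur(0, j); nxt(n - 1, j) = cur(n - 1, j); }
  }
}

// [[Rcpp::export]]
NumericVector cpp_simulate2d(NumericMatrix C0, double D, double vx, double vy,
                             double h, double dt, int steps_per_frame,
                             int nframes, int by, int bx, double k) {
  const int n = C0.nrow(), m = C0.ncol();
  NumericMatrix cur(clone(C0)), nxt(n, m);
  NumericVector out(Dimension(n, m, nframes + 1));
  double decay = (k > 0) ? std::exp(-k * dt) : 1.0;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) out[i + n * j] = cur(i, j);
  for (int f = 1; f <= nframes; ++f) {
    for (int s = 0; s < steps_per_frame; ++s) {
      step2d(cur, nxt, D, vx, vy, h, dt, by, bx, decay);
      std::swap(cur, nxt);
    }
    const R_xlen_t off = (R_xlen_t)f * n * m;
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) out[off + i + n * j] = cur(i, j);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_step2d(NumericMatrix C0, double D, double vx, double vy,
                         double h, double dt, int by, int bx, double k) {
  NumericMatrix cur(clone(C0)), nxt(C0.nrow(), C0.ncol());
  double decay = (k > 0) ? std::exp(-k * dt) : 1.0;
  step2d(cur, nxt, D, vx, vy, h, dt, by, bx, decay);
  return nxt;
}

// 3-D thin-disk mode. Field stored as a flat vector with dims (n, m, p):
// index i + n*j + n*m*kk. Velocity lateral only (vx along j, vy along i).
// [[Rcpp::export]]
List cpp_simulate3d(NumericVector C0, int n, int m, int p,
                    double D, double vx, double vy,
                    double h, double dt, int steps_per_frame, int nframes,
                    int by, int bx, int bz, double k) {
  std::vector<double> cur(C0.begin(), C0.end()), nxt(cur.size());
  const double r = dt / h;
  const double decay = (k > 0) ? std::exp(-k * dt) : 1.0;
  const int zc = p / 2; // central slice (0-based), read-out plane
  NumericVector frames(Dimension(n, m, nframes + 1));
  auto idx = [&](int i, int j, int kk) { return (size_t)i + (size_t)n * j + (size_t)n * m * kk; };
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) frames[i + n * j] = cur[idx(i, j, zc)];

  for (int f = 1; f <= nframes; ++f) {
    for (int s = 0; s < steps_per_frame; ++s) {
      nxt = cur;
      // x faces
      for (int kk = 0; kk < p; ++kk)
        for (int j = 0; j <= m; ++j) {
          int jl = j - 1, jr = j;
          bool wall = (j == 0 || j == m);
          if (wall) { if (bx == 1 && j == 0) { jl = wrap(j - 1, m); jr = 0; } else continue; }
          for (int i = 0; i < n; ++i) {
            double cl = cur[idx(i, jl, kk)], cr = cur[idx(i, jr, kk)];
            double F = -D * (cr - cl) / h + vx * (vx > 0 ? cl : cr);
            nxt[idx(i, jl, kk)] -= r * F;
            nxt[idx(i, jr, kk)] += r * F;
          }
        }
      // y faces
      for (int kk = 0; kk < p; ++kk)
        for (int j = 0; j < m; ++j)
          for (int i = 0; i <= n; ++i) {
            int il = i - 1, ir = i;
            bool wall = (i == 0 || i == n);
            if (wall) { if (by == 1 && i == 0) { il = wrap(i - 1, n); ir = 0; } else continue; }
            double cl = cur[idx(il, j, kk)], cr = cur[idx(ir, j, kk)];
            double F = -D * (cr - cl) / h + vy * (vy > 0 ? cl : cr);
            nxt[idx(il, j, kk)] -= r * F;
            nxt[idx(ir, j, kk)] += r * F;
          }
      // z faces (diffusion only)
      for (int kk = 0; kk <= p; ++kk) {
        int kl = kk - 1, kr = kk;
        bool wall = (kk == 0 || kk == p);
        if (wall) { if (bz == 1 && kk == 0) { kl = wrap(kk - 1, p); kr = 0; } else continue; }
        for (int j = 0; j < m; ++j)
          for (int i = 0; i < n; ++i) {
            double cl = cur[idx(i, j, kl)], cr = cur[idx(i, j, kr)];
            double F = -D * (cr - cl) / h;
            nxt[idx(i, j, kl)] -= r * F;
            nxt[idx(i, j, kr)] += r * F;
          }
      }
      if (decay != 1.0) for (auto &v : nxt) v *= decay;
      if (bx == 2)
        for (int kk = 0; kk < p; ++kk)
          for (int i = 0; i < n; ++i) {
            nxt[idx(i, 0, kk)] = cur[idx(i, 0, kk)];
            nxt[idx(i, m - 1, kk)] = cur[idx(i, m - 1, kk)];
          }
      if (by == 2)
        for (int kk = 0; kk < p; ++kk)
          for (int j = 0; j < m; ++j) {
            nxt[idx(0, j, kk)] = cur[idx(0, j, kk)];
            nxt[idx(n - 1, j, kk)] = cur[idx(n - 1, j, kk)];
          }
      if (bz == 2)
        for (int j = 0; j < m; ++j)
          for (int i = 0; i < n; ++i) {
            nxt[idx(i, j, 0)] = cur[idx(i, j, 0)];
            nxt[idx(i, j, p - 1)] = cur[idx(i, j, p - 1)];
          }
      std::swap(cur, nxt);
    }
    const R_xlen_t off = (R_xlen_t)f * n * m;
    for (int j = 0; j < m; ++j)
      for (int i = 0; i < n; ++i) frames[off + i + n * j] = cur[idx(i, j, zc)];
  }
  NumericVector final_field(cur.begin(), cur.end());
  final_field.attr("dim") = IntegerVector::create(n, m, p);
  return List::create(_["frames"] = frames, _["final"] = final_field);
}

// Scanning-circle objective: for every candidate centre (pixel grid) inside
// [r0lo..r0hi] x [c0lo..c0hi] (0-based, inclusive), mean of diff over the
// disk mask given as integer offsets (di, dj). Candidates must keep the
// whole disk inside the image (caller guarantees).
// [[Rcpp::export]]
NumericMatrix cpp_scan_circle(NumericMatrix diff, IntegerVector di,
                              IntegerVector dj, int r0lo, int r0hi,
                              int c0lo, int c0hi) {
  const int nr = r0hi - r0lo + 1, nc = c0hi - c0lo + 1, K = di.size();
  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double s = 0;
      const int ci = r0lo + r, cj = c0lo + c;
      for (int k = 0; k < K; ++k) s += diff(ci + di[k], cj + dj[k]);
      out(r, c) = s / K;
    }
  return out;
}
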