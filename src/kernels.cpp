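// Low-level voxel kernels. All volumes are passed as flat vectors with
// dim = c(nz, ny, nx) and R's column-major layout: linear index
// i = z + y*nz + x*nz*ny (0-based). Physical spacing is (dz, dy, dx) in um.
#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>
#include <vector>
#include <unordered_map>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// ---------------------------------------------------------------------------
// Separable convolution along one axis (0 = z, 1 = y, 2 = x), replicate edges.
// [[Rcpp::export]]
NumericVector cpp_conv_axis(NumericVector x, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int K = kernel.size(), R = K / 2;
  NumericVector out(x.size());
  const double *px = x.begin(), *pk = kernel.begin();
  double *po = out.begin();
  const R_xlen_t sz = 1, sy = nz, sx = (R_xlen_t)nz * ny;
  R_xlen_t stride;
  int n;
  if (axis == 0)      { stride = sz; n = nz; }
  else if (axis == 1) { stride = sy; n = ny; }
  else                { stride = sx; n = nx; }
  // iterate over all lines along `axis`
  for (int x2 = 0; x2 < (axis == 2 ? 1 : nx); ++x2)
  for (int y2 = 0; y2 < (axis == 1 ? 1 : ny); ++y2)
  for (int z2 = 0; z2 < (axis == 0 ? 1 : nz); ++z2) {
    // base of this line
    R_xlen_t base;
    if (axis == 0)      base = (R_xlen_t)y2 * sy + (R_xlen_t)x2 * sx;
    else if (axis == 1) base = (R_xlen_t)z2 * sz + (R_xlen_t)x2 * sx;
    else                base = (R_xlen_t)z2 * sz + (R_xlen_t)y2 * sy;
    if (axis == 2) {
      for (int yy = 0; yy < ny; ++yy) for (int zz = 0; zz < nz; ++zz) {
        R_xlen_t b = (R_xlen_t)zz + (R_xlen_t)yy * sy;
        for (int i = 0; i < n; ++i) {
          double acc = 0;
          for (int k = 0; k < K; ++k) {
            int j = clampi(i + k - R, 0, n - 1);
            acc += pk[k] * px[b + (R_xlen_t)j * stride];
          }
          po[b + (R_xlen_t)i * stride] = acc;
        }
      }
      return out;  // handled all lines in the nested loop above
    }
    for (int i = 0; i < n; ++i) {
      double acc = 0;
      for (int k = 0; k < K; ++k) {
        int j = clampi(i + k - R, 0, n - 1);
        acc += pk[k] * px[base + (R_xlen_t)j * stride];
      }
      po[base + (R_xlen_t)i * stride] = acc;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3D median filter, cubic (2r+1)^3 neighbourhood, replicate edges.
// [[Rcpp::export]]
NumericVector cpp_median_filter3d(NumericVector x, IntegerVector dim, int r) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out(x.size());
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  const int K = 2 * r + 1, nn = K * K * K;
  std::vector<double> buf(nn);
  for (int xx = 0; xx < nx; ++xx)
  for (int yy = 0; yy < ny; ++yy)
  for (int zz = 0; zz < nz; ++zz) {
    int m = 0;
    for (int dx = -r; dx <= r; ++dx) {
      int x3 = clampi(xx + dx, 0, nx - 1);
      for (int dy = -r; dy <= r; ++dy) {
        int y3 = clampi(yy + dy, 0, ny - 1);
        for (int dz = -r; dz <= r; ++dz) {
          int z3 = clampi(zz + dz, 0, nz - 1);
          buf[m++] = px[z3 + y3 * sy + (R_xlen_t)x3 * sx];
        }
      }
    }
    std::nth_element(buf.begin(), buf.begin() + nn / 2, buf.begin() + nn);
    po[zz + yy * sy + (R_xlen_t)xx * sx] = buf[nn / 2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Non-flat (height-profile) grayscale erosion/dilation applied per z-slice.
// offs: k x 2 integer matrix of (dy, dx) offsets; h: height at each offset.
// op = 0 erode (min of x - h), op = 1 dilate (max of x + h).
// Out-of-bounds offsets are ignored.
// [[Rcpp::export]]
NumericVector cpp_ball_morph2d(NumericVector x, IntegerVector dim,
                               IntegerMatrix offs, NumericVector h, int op) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int k = offs.nrow();
  NumericVector out(x.size());
  const double *px = x.begin();
  double *po = out.begin();
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  std::vector<int> ody(k), odx(k);
  for (int i = 0; i < k; ++i) { ody[i] = offs(i, 0); odx[i] = offs(i, 1); }
  for (int xx = 0; xx < nx; ++xx)
  for (int yy = 0; yy < ny; ++yy)
  for (int zz = 0; zz < nz; ++zz) {
    double best = op == 0 ? R_PosInf : R_NegInf;
    for (int i = 0; i < k; ++i) {
      int y3 = yy + ody[i], x3 = xx + odx[i];
      if (y3 < 0 || y3 >= ny || x3 < 0 || x3 >= nx) continue;
      double v = px[zz + y3 * sy + (R_xlen_t)x3 * sx];
      if (op == 0) { v -= h[i]; if (v < best) best = v; }
      else         { v += h[i]; if (v > best) best = v; }
    }
    po[zz + yy * sy + (R_xlen_t)xx * sx] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Strict 26-neighbourhood local maxima above `thr`; an equal-valued plateau
// that is a maximum yields one seed at its lexicographically smallest
// (z, y, x). Returns n x 3 matrix of 1-based (z, y, x).
// [[Rcpp::export]]
IntegerMatrix cpp_local_maxima(NumericVector x, IntegerVector dim, double thr) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double *px = x.begin();
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  std::vector<char> visited(x.size(), 0);
  std::vector<std::array<int,3> > seeds;
  std::vector<R_xlen_t> stack, plateau;
  for (int xx = 0; xx < nx; ++xx)
  for (int yy = 0; yy < ny; ++yy)
  for (int zz = 0; zz < nz; ++zz) {
    R_xlen_t i = zz + yy * sy + (R_xlen_t)xx * sx;
    if (visited[i] || px[i] <= thr) continue;
    const double v = px[i];
    // quick reject: any strictly greater neighbour
    bool greater = false;
    for (int dx = -1; dx <= 1 && !greater; ++dx)
    for (int dy = -1; dy <= 1 && !greater; ++dy)
    for (int dz = -1; dz <= 1 && !greater; ++dz) {
      if (!dx && !dy && !dz) continue;
      int z3 = zz + dz, y3 = yy + dy, x3 = xx + dx;
      if (z3 < 0 || z3 >= nz || y3 < 0 || y3 >= ny || x3 < 0 || x3 >= nx) continue;
      if (px[z3 + y3 * sy + (R_xlen_t)x3 * sx] > v) greater = true;
    }
    if (greater) continue;
    // flood the equal-valued plateau; a maximum iff no member sees a greater
    // neighbour
    stack.clear(); plateau.clear();
    stack.push_back(i); visited[i] = 1;
    bool is_max = true;
    int bz = zz, by = yy, bx = xx;
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      plateau.push_back(j);
      int xj = (int)(j / sx), rem = (int)(j % sx);
      int yj = rem / nz, zj = rem % nz;
      if (zj < bz || (zj == bz && (yj < by || (yj == by && xj < bx)))) {
        bz = zj; by = yj; bx = xj;
      }
      for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int z3 = zj + dz, y3 = yj + dy, x3 = xj + dx;
        if (z3 < 0 || z3 >= nz || y3 < 0 || y3 >= ny || x3 < 0 || x3 >= nx) continue;
        R_xlen_t n3 = z3 + y3 * sy + (R_xlen_t)x3 * sx;
        double vn = px[n3];
        if (vn > v) { is_max = false; }
        else if (vn == v && !visited[n3]) { visited[n3] = 1; stack.push_back(n3); }
      }
    }
    if (is_max) seeds.push_back({bz + 1, by + 1, bx + 1});
  }
  std::sort(seeds.begin(), seeds.end());
  IntegerMatrix out(seeds.size(), 3);
  for (size_t s = 0; s < seeds.size(); ++s) {
    out(s, 0) = seeds[s][0]; out(s, 1) = seeds[s][1]; out(s, 2) = seeds[s][2];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seeded region growing. Seeds are 0-based linear indices, supplied in claim
// priority order (descending peak intensity); each grows over 26-connected
// voxels with x >= thr[s], capped at `cap` voxels, highest-intensity-first
// so the cap is deterministic. Already-claimed voxels are barriers.
// Labels are 1-based seed order positions.
// [[Rcpp::export]]
IntegerVector cpp_grow_spots(NumericVector x, IntegerVector dim,
                             NumericVector seeds, NumericVector thr, int cap) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double *px = x.begin();
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  IntegerVector lab(x.size());
  int *pl = lab.begin();
  typedef std::pair<double, double> QE;  // (value, -index) max-heap
  for (int s = 0; s < seeds.size(); ++s) {
    R_xlen_t seed = (R_xlen_t)seeds[s];
    if (pl[seed] != 0) continue;
    const double t = thr[s];
    if (px[seed] < t) continue;
    std::priority_queue<QE> q;
    q.push(QE(px[seed], -(double)seed));
    pl[seed] = s + 1;
    int size = 1;
    while (!q.empty() && size < cap) {
      R_xlen_t j = (R_xlen_t)(-q.top().second); q.pop();
      int xj = (int)(j / sx), rem = (int)(j % sx);
      int yj = rem / nz, zj = rem % nz;
      for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int z3 = zj + dz, y3 = yj + dy, x3 = xj + dx;
        if (z3 < 0 || z3 >= nz || y3 < 0 || y3 >= ny || x3 < 0 || x3 >= nx) continue;
        R_xlen_t n3 = z3 + y3 * sy + (R_xlen_t)x3 * sx;
        if (pl[n3] == 0 && px[n3] >= t) {
          pl[n3] = s + 1;
          ++size;
          q.push(QE(px[n3], -(double)n3));
          if (size >= cap) goto grown;
        }
      }
    }
    grown: ;
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling of a binary mask; scan-order labels.
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int *pm = mask.begin();
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  IntegerVector lab(mask.size());
  int *pl = lab.begin();
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < mask.size(); ++i) {
    if (!pm[i] || pl[i]) continue;
    ++next;
    stack.clear(); stack.push_back(i); pl[i] = next;
    while (!stack.empty()) {
      R_xlen_t j = stack.back(); stack.pop_back();
      int xj = (int)(j / sx), rem = (int)(j % sx);
      int yj = rem / nz, zj = rem % nz;
      for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
      for (int dz = -1; dz <= 1; ++dz) {
        if (!dx && !dy && !dz) continue;
        int z3 = zj + dz, y3 = yj + dy, x3 = xj + dx;
        if (z3 < 0 || z3 >= nz || y3 < 0 || y3 >= ny || x3 < 0 || x3 >= nx) continue;
        R_xlen_t n3 = z3 + y3 * sy + (R_xlen_t)x3 * sx;
        if (pm[n3] && !pl[n3]) { pl[n3] = next; stack.push_back(n3); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Exact anisotropic squared Euclidean distance transform
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, per axis).
static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double h2, std::vector<int> &v, std::vector<double> &zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -R_PosInf; zb[1] = R_PosInf;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + h2 * q * q) - (f[p] + h2 * p * p)) / (2.0 * h2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = R_PosInf;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    int p = v[k];
    d[q] = h2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt3d(IntegerVector seed, IntegerVector dim,
                        NumericVector spacing) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  const double BIG = 1e30;
  NumericVector out(seed.size());
  double *po = out.begin();
  for (R_xlen_t i = 0; i < seed.size(); ++i) po[i] = seed[i] ? 0.0 : BIG;
  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zb(nmax + 1);
  std::vector<int> v(nmax);
  // along z
  for (int xx = 0; xx < nx; ++xx) for (int yy = 0; yy < ny; ++yy) {
    R_xlen_t b = yy * sy + (R_xlen_t)xx * sx;
    for (int i = 0; i < nz; ++i) f[i] = po[b + i];
    dt1d(f, d, nz, dz * dz, v, zb);
    for (int i = 0; i < nz; ++i) po[b + i] = d[i];
  }
  // along y
  for (int xx = 0; xx < nx; ++xx) for (int zz = 0; zz < nz; ++zz) {
    R_xlen_t b = zz + (R_xlen_t)xx * sx;
    for (int i = 0; i < ny; ++i) f[i] = po[b + (R_xlen_t)i * sy];
    dt1d(f, d, ny, dy * dy, v, zb);
    for (int i = 0; i < ny; ++i) po[b + (R_xlen_t)i * sy] = d[i];
  }
  // along x
  for (int yy = 0; yy < ny; ++yy) for (int zz = 0; zz < nz; ++zz) {
    R_xlen_t b = zz + yy * sy;
    for (int i = 0; i < nx; ++i) f[i] = po[b + (R_xlen_t)i * sx];
    dt1d(f, d, nx, dx * dx, v, zb);
    for (int i = 0; i < nx; ++i) po[b + (R_xlen_t)i * sx] = d[i];
  }
  for (R_xlen_t i = 0; i < out.size(); ++i) po[i] = std::sqrt(po[i]);
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning to a curve skeleton.
// A voxel is deletable when it is a border voxel in the current subiteration
// direction, has >= 2 foreground 26-neighbours (endpoints of curves are
// kept), and is a simple point (Malandain-Bertrand characterization:
// exactly one 26-component of foreground in N26 and exactly one
// 6-component of background in N18 that is 6-adjacent to the centre).
// Candidates are re-checked at deletion time, so topology is preserved.

static int fg_components26(const bool nb[27]) {
  // cells indexed c = (dz+1) + 3*(dy+1) + 9*(dx+1); centre c == 13 excluded
  bool vis[27] = {false};
  int comps = 0;
  int stack[27], sp;
  for (int c0 = 0; c0 < 27; ++c0) {
    if (c0 == 13 || !nb[c0] || vis[c0]) continue;
    ++comps;
    sp = 0; stack[sp++] = c0; vis[c0] = true;
    while (sp) {
      int c = stack[--sp];
      int dz = c % 3 - 1, dy = (c / 3) % 3 - 1, dx = c / 9 - 1;
      for (int ax = -1; ax <= 1; ++ax)
      for (int ay = -1; ay <= 1; ++ay)
      for (int az = -1; az <= 1; ++az) {
        if (!ax && !ay && !az) continue;
        int ez = dz + az, ey = dy + ay, ex = dx + ax;
        if (ez < -1 || ez > 1 || ey < -1 || ey > 1 || ex < -1 || ex > 1) continue;
        int c2 = (ez + 1) + 3 * (ey + 1) + 9 * (ex + 1);
        if (c2 == 13 || vis[c2] || !nb[c2]) continue;
        vis[c2] = true; stack[sp++] = c2;
      }
    }
  }
  return comps;
}

static int bg_components6(const bool nb[27]) {
  // background 6-components within N18, counted only if they contain a
  // 6-neighbour of the centre
  bool vis[27] = {false};
  int comps = 0;
  int stack[27], sp;
  const int face[6] = {12, 14, 10, 16, 4, 22}; // (z-1),(z+1),(y-1),(y+1),(x-1),(x+1)
  for (int fi = 0; fi < 6; ++fi) {
    int c0 = face[fi];
    if (nb[c0] || vis[c0]) continue;
    ++comps;
    sp = 0; stack[sp++] = c0; vis[c0] = true;
    while (sp) {
      int c = stack[--sp];
      int dz = c % 3 - 1, dy = (c / 3) % 3 - 1, dx = c / 9 - 1;
      const int az[6] = {1, -1, 0, 0, 0, 0};
      const int ay[6] = {0, 0, 1, -1, 0, 0};
      const int ax[6] = {0, 0, 0, 0, 1, -1};
      for (int a = 0; a < 6; ++a) {
        int ez = dz + az[a], ey = dy + ay[a], ex = dx + ax[a];
        if (ez < -1 || ez > 1 || ey < -1 || ey > 1 || ex < -1 || ex > 1) continue;
        int manh = std::abs(ez) + std::abs(ey) + std::abs(ex);
        if (manh == 0 || manh == 3) continue;  // centre and corners not in N18
        int c2 = (ez + 1) + 3 * (ey + 1) + 9 * (ex + 1);
        if (vis[c2] || nb[c2]) continue;
        vis[c2] = true; stack[sp++] = c2;
      }
    }
  }
  return comps;
}

// `priority`: optional per-voxel intensity; within each subiteration,
// candidates are deleted dimmest-first so the retained line tracks the
// intensity ridge (ordered thinning). Empty vector = index order.
// [[Rcpp::export]]
IntegerVector cpp_thin3d(IntegerVector mask, IntegerVector dim,
                         NumericVector priority = NumericVector(0)) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const bool use_pri = priority.size() == mask.size();
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  IntegerVector fg = clone(mask);
  int *pf = fg.begin();
  const int ddz[6] = {-1, 1, 0, 0, 0, 0};
  const int ddy[6] = {0, 0, -1, 1, 0, 0};
  const int ddx[6] = {0, 0, 0, 0, -1, 1};
  bool nb[27];
  std::vector<R_xlen_t> cand;
  bool changed = true;
  auto load_nb = [&](int zz, int yy, int xx) {
    for (int dx = -1; dx <= 1; ++dx)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dz = -1; dz <= 1; ++dz) {
      int z3 = zz + dz, y3 = yy + dy, x3 = xx + dx;
      bool v = false;
      if (z3 >= 0 && z3 < nz && y3 >= 0 && y3 < ny && x3 >= 0 && x3 < nx)
        v = pf[z3 + y3 * sy + (R_xlen_t)x3 * sx] != 0;
      nb[(dz + 1) + 3 * (dy + 1) + 9 * (dx + 1)] = v;
    }
  };
  auto deletable = [&](int zz, int yy, int xx, int d) -> bool {
    int z3 = zz + ddz[d], y3 = yy + ddy[d], x3 = xx + ddx[d];
    bool border = true;
    if (z3 >= 0 && z3 < nz && y3 >= 0 && y3 < ny && x3 >= 0 && x3 < nx)
      border = pf[z3 + y3 * sy + (R_xlen_t)x3 * sx] == 0;
    if (!border) return false;
    load_nb(zz, yy, xx);
    int nfg = 0, fi[2] = {0, 0};
    for (int c = 0; c < 27; ++c) if (c != 13 && nb[c]) {
      if (nfg < 2) fi[nfg] = c;
      ++nfg;
    }
    if (nfg <= 1) return false;                 // keep curve endpoints
    if (nfg == 2) {
      // a forming tip: its two neighbours are mutually 26-adjacent and the
      // voxel is extremal along the current direction (no foreground in
      // the d-side plane of its neighbourhood)
      int az = fi[0] % 3 - (fi[1] % 3);
      int ay = (fi[0] / 3) % 3 - (fi[1] / 3) % 3;
      int ax = fi[0] / 9 - fi[1] / 9;
      if (std::abs(az) <= 1 && std::abs(ay) <= 1 && std::abs(ax) <= 1) {
        bool side_fg = false;
        for (int c = 0; c < 27; ++c) {
          if (!nb[c]) continue;
          int cz = c % 3 - 1, cy = (c / 3) % 3 - 1, cx = c / 9 - 1;
          if (cz * ddz[d] > 0 || cy * ddy[d] > 0 || cx * ddx[d] > 0)
            side_fg = true;
        }
        if (!side_fg) return false;
      }
    }
    if (fg_components26(nb) != 1) return false;
    if (bg_components6(nb) != 1) return false;
    return true;
  };
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int xx = 0; xx < nx; ++xx)
      for (int yy = 0; yy < ny; ++yy)
      for (int zz = 0; zz < nz; ++zz) {
        R_xlen_t i = zz + yy * sy + (R_xlen_t)xx * sx;
        if (!pf[i]) continue;
        if (deletable(zz, yy, xx, d)) cand.push_back(i);
      }
      if (use_pri)
        std::stable_sort(cand.begin(), cand.end(),
                         [&](R_xlen_t a, R_xlen_t b) {
                           return priority[a] < priority[b];
                         });
      // sequential re-checked deletion preserves topology
      for (size_t c = 0; c < cand.size(); ++c) {
        R_xlen_t i = cand[c];
        int xj = (int)(i / sx), rem = (int)(i % sx);
        int yj = rem / nz, zj = rem % nz;
        if (deletable(zj, yj, xj, d)) { pf[i] = 0; changed = true; }
      }
    }
  }
  return fg;
}

// ---------------------------------------------------------------------------
// Skeleton graph construction and branch tracing.
// vox: n x 3 matrix of 1-based (z, y, x) skeleton voxels. Edges join
// 26-adjacent voxels; a "shortcut" diagonal edge (a,c) is dropped when some
// voxel b is adjacent to both with both step weights strictly smaller, so
// staircases do not create spurious triangles/cycles. Branches are traced
// between nodes (degree != 2 voxels); pure cycles give one cyclic branch
// starting at the lexicographically smallest voxel (closed: first == last).
// [[Rcpp::export]]
List cpp_skeleton_graph(IntegerMatrix vox, IntegerVector dim,
                        NumericVector spacing) {
  const int n = vox.nrow();
  const int nz = dim[0], ny = dim[1];
  const R_xlen_t sy = nz, sx = (R_xlen_t)nz * ny;
  const double dz = spacing[0], dy = spacing[1], dx = spacing[2];
  // order voxels lexicographically by (z, y, x)
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (vox(a,0) != vox(b,0)) return vox(a,0) < vox(b,0);
    if (vox(a,1) != vox(b,1)) return vox(a,1) < vox(b,1);
    return vox(a,2) < vox(b,2);
  });
  std::unordered_map<R_xlen_t, int> pos;  // linear index -> original row
  pos.reserve(n * 2);
  for (int i = 0; i < n; ++i) {
    R_xlen_t li = (vox(i,0) - 1) + (R_xlen_t)(vox(i,1) - 1) * sy +
                  (R_xlen_t)(vox(i,2) - 1) * sx;
    pos[li] = i;
  }
  std::vector<std::vector<int> > adj(n);
  auto stepw = [&](int a, int b) {
    double wz = dz * (vox(a,0) - vox(b,0));
    double wy = dy * (vox(a,1) - vox(b,1));
    double wx = dx * (vox(a,2) - vox(b,2));
    return std::sqrt(wz * wz + wy * wy + wx * wx);
  };
  const int nxd = dim[2];
  for (int k = 0; k < n; ++k) {
    int i = ord[k];
    for (int ax = -1; ax <= 1; ++ax)
    for (int ay = -1; ay <= 1; ++ay)
    for (int az = -1; az <= 1; ++az) {
      if (!ax && !ay && !az) continue;
      int z3 = vox(i,0) + az, y3 = vox(i,1) + ay, x3 = vox(i,2) + ax;
      if (z3 < 1 || z3 > nz || y3 < 1 || y3 > ny || x3 < 1 || x3 > nxd) continue;
      R_xlen_t li = (z3 - 1) + (R_xlen_t)(y3 - 1) * sy + (R_xlen_t)(x3 - 1) * sx;
      auto it = pos.find(li);
      if (it != pos.end()) adj[i].push_back(it->second);
    }
  }
  // shortcut pruning on the original adjacency
  std::vector<std::vector<int> > adj2(n);
  const double eps = 1e-12;
  for (int a = 0; a < n; ++a) {
    for (int c : adj[a]) {
      double wac = stepw(a, c);
      bool redundant = false;
      for (int b : adj[a]) {
        if (b == c) continue;
        // is b adjacent to c?
        bool badj = false;
        for (int b2 : adj[c]) if (b2 == b) { badj = true; break; }
        if (!badj) continue;
        if (stepw(a, b) < wac - eps && stepw(b, c) < wac - eps) {
          redundant = true; break;
        }
      }
      if (!redundant) adj2[a].push_back(c);
    }
  }
  // sort neighbour lists lexicographically for deterministic walks
  auto lexless = [&](int a, int b) {
    if (vox(a,0) != vox(b,0)) return vox(a,0) < vox(b,0);
    if (vox(a,1) != vox(b,1)) return vox(a,1) < vox(b,1);
    return vox(a,2) < vox(b,2);
  };
  for (int i = 0; i < n; ++i) std::sort(adj2[i].begin(), adj2[i].end(), lexless);
  std::vector<int> deg(n);
  for (int i = 0; i < n; ++i) deg[i] = (int)adj2[i].size();
  // edge-visited flags keyed by (min, max) pair
  auto ekey = [&](int a, int b) {
    long long lo = std::min(a, b), hi = std::max(a, b);
    return lo * (long long)n + hi;
  };
  std::unordered_map<long long, char> evis;
  std::vector<std::vector<int> > branches;
  std::vector<bool> cyclic;
  // open branches from nodes
  for (int k = 0; k < n; ++k) {
    int v = ord[k];
    if (deg[v] == 2) continue;
    if (deg[v] == 0) { branches.push_back({v}); cyclic.push_back(false); continue; }
    for (int s = 0; s < (int)adj2[v].size(); ++s) {
      int nb0 = adj2[v][s];
      if (evis.count(ekey(v, nb0))) continue;
      std::vector<int> br;
      br.push_back(v);
      int prev = v, cur = nb0;
      evis[ekey(v, nb0)] = 1;
      br.push_back(cur);
      while (deg[cur] == 2) {
        int nxt = adj2[cur][0] == prev ? adj2[cur][1] : adj2[cur][0];
        if (evis.count(ekey(cur, nxt))) break;  // safety
        evis[ekey(cur, nxt)] = 1;
        br.push_back(nxt);
        prev = cur; cur = nxt;
      }
      branches.push_back(br);
      cyclic.push_back(false);
    }
  }
  // remaining pure cycles
  for (int k = 0; k < n; ++k) {
    int v = ord[k];
    if (deg[v] != 2) continue;
    bool has_unvis = false;
    for (int nb0 : adj2[v]) if (!evis.count(ekey(v, nb0))) { has_unvis = true; break; }
    if (!has_unvis) continue;
    std::vector<int> br;
    br.push_back(v);
    int prev = v, cur = adj2[v][0];
    evis[ekey(v, cur)] = 1;
    br.push_back(cur);
    while (cur != v) {
      int nxt = adj2[cur][0] == prev ? adj2[cur][1] : adj2[cur][0];
      evis[ekey(cur, nxt)] = 1;
      br.push_back(nxt);
      prev = cur; cur = nxt;
    }
    branches.push_back(br);
    cyclic.push_back(true);
  }
  long long n_edges = 0;
  for (int i = 0; i < n; ++i) n_edges += deg[i];
  n_edges /= 2;
  List brl(branches.size());
  for (size_t i = 0; i < branches.size(); ++i) {
    IntegerVector b(branches[i].size());
    for (size_t j = 0; j < branches[i].size(); ++j) b[j] = branches[i][j] + 1;
    brl[i] = b;
  }
  IntegerVector dg(n);
  for (int i = 0; i < n; ++i) dg[i] = deg[i];
  return List::create(_["branches"] = brl,
                      _["cyclic"] = LogicalVector(cyclic.begin(), cyclic.end()),
                      _["degree"] = dg,
                      _["n_edges"] = (double)n_edges);
}

// ---------------------------------------------------------------------------
// Hessian-eigenvalue tubeness: eigenvalues of the symmetric 3x3 Hessian per
// voxel (closed-form), sorted l1 >= l2 >= l3; score = norm * sqrt(l2*l3)
// when l2 < 0 and l3 < 0, else 0 (bright curvilinear structures).
// [[Rcpp::export]]
NumericVector cpp_tubeness_score(NumericVector hzz, NumericVector hyy,
                                 NumericVector hxx, NumericVector hzy,
                                 NumericVector hzx, NumericVector hyx,
                                 double norm) {
  R_xlen_t n = hzz.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a11 = hzz[i], a22 = hyy[i], a33 = hxx[i];
    double a12 = hzy[i], a13 = hzx[i], a23 = hyx[i];
    double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    double e1, e2, e3;
    if (p1 == 0) {
      e1 = a11; e2 = a22; e3 = a33;
      if (e1 < e2) std::swap(e1, e2);
      if (e2 < e3) std::swap(e2, e3);
      if (e1 < e2) std::swap(e1, e2);
    } else {
      double q = (a11 + a22 + a33) / 3.0;
      double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                  (a33 - q) * (a33 - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
      double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1) r = -1; else if (r > 1) r = 1;
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    out[i] = (e2 < 0 && e3 < 0) ? norm * std::sqrt(e2 * e3) : 0.0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sorted (descending) eigenvalues of the symmetric 3x3 Hessian per voxel.
// [[Rcpp::export]]
NumericMatrix cpp_sym3_eigs(NumericVector hzz, NumericVector hyy,
                            NumericVector hxx, NumericVector hzy,
                            NumericVector hzx, NumericVector hyx) {
  R_xlen_t n = hzz.size();
  NumericMatrix out(n, 3);
  for (R_xlen_t i = 0; i < n; ++i) {
    double a11 = hzz[i], a22 = hyy[i], a33 = hxx[i];
    double a12 = hzy[i], a13 = hzx[i], a23 = hyx[i];
    double p1 = a12 * a12 + a13 * a13 + a23 * a23;
    double e1, e2, e3;
    if (p1 == 0) {
      e1 = a11; e2 = a22; e3 = a33;
      if (e1 < e2) std::swap(e1, e2);
      if (e2 < e3) std::swap(e2, e3);
      if (e1 < e2) std::swap(e1, e2);
    } else {
      double q = (a11 + a22 + a33) / 3.0;
      double p2 = (a11 - q) * (a11 - q) + (a22 - q) * (a22 - q) +
                  (a33 - q) * (a33 - q) + 2.0 * p1;
      double p = std::sqrt(p2 / 6.0);
      double b11 = (a11 - q) / p, b22 = (a22 - q) / p, b33 = (a33 - q) / p;
      double b12 = a12 / p, b13 = a13 / p, b23 = a23 / p;
      double detB = b11 * (b22 * b33 - b23 * b23) -
                    b12 * (b12 * b33 - b23 * b13) +
                    b13 * (b12 * b23 - b22 * b13);
      double r = detB / 2.0;
      if (r < -1) r = -1; else if (r > 1) r = 1;
      double phi = std::acos(r) / 3.0;
      e1 = q + 2.0 * p * std::cos(phi);
      e3 = q + 2.0 * p * std::cos(phi + 2.0 * M_PI / 3.0);
      e2 = 3.0 * q - e1 - e3;
    }
    out(i, 0) = e1; out(i, 1) = e2; out(i, 2) = e3;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Exact minimum distance from each query point to a set of polylines
// (point-to-segment, continuous). pts: n x 3 (um); paths: list of m x 3.
// [[Rcpp::export]]
NumericVector cpp_min_dist_to_paths(NumericMatrix pts, List paths) {
  const int n = pts.nrow();
  NumericVector out(n, R_PosInf);
  for (int p = 0; p < paths.size(); ++p) {
    NumericMatrix pm = paths[p];
    const int m = pm.nrow();
    for (int i = 0; i < n; ++i) {
      double qz = pts(i,0), qy = pts(i,1), qx = pts(i,2);
      double best = out[i];
      for (int s = 0; s + 1 < m; ++s) {
        double az = pm(s,0), ay = pm(s,1), ax = pm(s,2);
        double bz = pm(s+1,0), by = pm(s+1,1), bx = pm(s+1,2);
        double vz = bz - az, vy = by - ay, vx = bx - ax;
        double wz = qz - az, wy = qy - ay, wx = qx - ax;
        double vv = vz * vz + vy * vy + vx * vx;
        double t = vv > 0 ? (wz * vz + wy * vy + wx * vx) / vv : 0.0;
        if (t < 0) t = 0; else if (t > 1) t = 1;
        double ez = wz - t * vz, ey = wy - t * vy, ex = wx - t * vx;
        double d2 = ez * ez + ey * ey + ex * ex;
        if (d2 < best * best) best = std::sqrt(d2);
      }
      if (m == 1) {
        double ez = qz - pm(0,0), ey = qy - pm(0,1), ex = qx - pm(0,2);
        double d = std::sqrt(ez * ez + ey * ey + ex * ex);
        if (d < best) best = d;
      }
      out[i] = best;
    }
  }
  return out;
}
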