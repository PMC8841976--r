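#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Volumes are R arrays with dim = (nz, ny, nx); linear index
// idx = z + y*nz + x*nz*ny with 0-based z,y,x. Physical voxel-center
// coordinate along an axis is (i + 0.5) * voxel_size + origin.

static inline int64_t lin(int z, int y, int x, int nz, int ny) {
  return (int64_t)z + (int64_t)y * nz + (int64_t)x * (int64_t)nz * ny;
}

// ---------------------------------------------------------------- cc_label

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dim,
                           int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  IntegerVector lab(n, 0);

  // neighbour offsets for the requested connectivity
  std::vector<int> dz, dy, dx;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int s = std::abs(a) + std::abs(b) + std::abs(c);
        if (s == 0) continue;
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2))
          continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
  const int noff = (int)dz.size();

  std::vector<int64_t> stack;
  int next = 0;
  for (int64_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int64_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int y = (int)((cur / nz) % ny);
      int x = (int)(cur / ((int64_t)nz * ny));
      for (int o = 0; o < noff; ++o) {
        int zz = z + dz[o], yy = y + dy[o], xx = x + dx[o];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int64_t j = lin(zz, yy, xx, nz, ny);
        if (mask[j] && lab[j] == 0) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// ------------------------------------------------------------ density_count

// Counts, for every voxel centre, the particles within radius R (nm), then
// clamps at k: equivalent to counting the k nearest particles inside R.
// [[Rcpp::export(name = ".density_count_cpp")]]
NumericVector density_count_cpp(NumericMatrix coords, IntegerVector dim,
                                NumericVector vs, NumericVector origin,
                                double R, int k) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  NumericVector out(n, 0.0);
  const double R2 = R * R;
  const int np = coords.nrow();
  for (int p = 0; p < np; ++p) {
    const double pz = coords(p, 0), py = coords(p, 1), px = coords(p, 2);
    int zlo = (int)std::floor((pz - R - origin[0]) / vs[0] - 0.5);
    int zhi = (int)std::ceil ((pz + R - origin[0]) / vs[0] - 0.5);
    int ylo = (int)std::floor((py - R - origin[1]) / vs[1] - 0.5);
    int yhi = (int)std::ceil ((py + R - origin[1]) / vs[1] - 0.5);
    int xlo = (int)std::floor((px - R - origin[2]) / vs[2] - 0.5);
    int xhi = (int)std::ceil ((px + R - origin[2]) / vs[2] - 0.5);
    if (zlo < 0) zlo = 0; if (zhi > nz - 1) zhi = nz - 1;
    if (ylo < 0) ylo = 0; if (yhi > ny - 1) yhi = ny - 1;
    if (xlo < 0) xlo = 0; if (xhi > nx - 1) xhi = nx - 1;
    for (int x = xlo; x <= xhi; ++x) {
      double cx = (x + 0.5) * vs[2] + origin[2];
      double ddx = (cx - px) * (cx - px);
      if (ddx > R2) continue;
      for (int y = ylo; y <= yhi; ++y) {
        double cy = (y + 0.5) * vs[1] + origin[1];
        double ddy = (cy - py) * (cy - py);
        if (ddx + ddy > R2) continue;
        int64_t base = (int64_t)y * nz + (int64_t)x * nz * ny;
        for (int z = zlo; z <= zhi; ++z) {
          double cz = (z + 0.5) * vs[0] + origin[0];
          double d2 = (cz - pz) * (cz - pz) + ddy + ddx;
          if (d2 <= R2) out[base + z] += 1.0;
        }
      }
    }
  }
  const double kk = (double)k;
  for (int64_t i = 0; i < n; ++i) if (out[i] > kk) out[i] = kk;
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------------ EDT

// Felzenszwalb-Huttenlocher 1D squared distance transform with spacing w.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &zbuf,
                 int n, double w) {
  const double INF = 1e30;
  int kk = 0;
  v[0] = 0;
  zbuf[0] = -INF; zbuf[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zbuf[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    zbuf[kk] = s;
    zbuf[kk + 1] = INF;
  }
  kk = 0;
  for (int q = 0; q < n; ++q) {
    while (zbuf[kk + 1] < q) ++kk;
    int p = v[kk];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// Exact squared Euclidean distance (nm^2) from each foreground voxel centre
// to the nearest background voxel centre; the caller pads the volume if the
// outside is to count as background.
// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim,
                         NumericVector vs) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  const double INF = 1e30;
  NumericVector D(n);
  for (int64_t i = 0; i < n; ++i) D[i] = mask[i] ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), zbuf(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      int64_t base = lin(0, y, x, nz, ny);
      for (int z = 0; z < nz; ++z) f[z] = D[base + z];
      dt1d(f, d, v, zbuf, nz, vs[0]);
      for (int z = 0; z < nz; ++z) D[base + z] = d[z];
    }
  // pass along y
  for (int x = 0; x < nx; ++x)
    for (int z = 0; z < nz; ++z) {
      int64_t base = lin(z, 0, x, nz, ny);
      for (int y = 0; y < ny; ++y) f[y] = D[base + (int64_t)y * nz];
      dt1d(f, d, v, zbuf, ny, vs[1]);
      for (int y = 0; y < ny; ++y) D[base + (int64_t)y * nz] = d[y];
    }
  // pass along x
  const int64_t sx = (int64_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int z = 0; z < nz; ++z) {
      int64_t base = lin(z, y, 0, nz, ny);
      for (int x = 0; x < nx; ++x) f[x] = D[base + (int64_t)x * sx];
      dt1d(f, d, v, zbuf, nx, vs[2]);
      for (int x = 0; x < nx; ++x) D[base + (int64_t)x * sx] = d[x];
    }
  D.attr("dim") = dim;
  return D;
}

// -------------------------------------------------------------- thinning

// 3x3x3 neighbourhood topology helpers. Positions are encoded 0..26 as
// p = (dz+1) + (dy+1)*3 + (dx+1)*9; centre = 13.

static bool object_connected26(const bool nb[27]) {
  // fg voxels in the neighbourhood minus the centre must form one
  // 26-connected component
  int first = -1, cnt = 0;
  for (int i = 0; i < 27; ++i)
    if (i != 13 && nb[i]) { if (first < 0) first = i; ++cnt; }
  if (cnt == 0) return false;
  bool vis[27] = {false};
  int stack[27], top = 0;
  stack[top++] = first; vis[first] = true;
  int seen = 1;
  while (top) {
    int cur = stack[--top];
    int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (!a && !b && !c) continue;
          int zz = cz + a, yy = cy + b, xx = cx + c;
          if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2)
            continue;
          int j = zz + yy * 3 + xx * 9;
          if (j == 13 || vis[j] || !nb[j]) continue;
          vis[j] = true; stack[top++] = j; ++seen;
        }
  }
  return seen == cnt;
}

static bool background_connected6(const bool nb[27]) {
  // bg voxels of the 18-neighbourhood must form one 6-connected component
  // that touches a face neighbour of the centre
  static const int faces[6] = {4, 10, 12, 14, 16, 22}; // |dz|+|dy|+|dx| == 1
  int start = -1;
  for (int f = 0; f < 6; ++f)
    if (!nb[faces[f]]) { start = faces[f]; break; }
  if (start < 0) return false; // interior voxel: no bg face neighbour
  bool vis[27] = {false};
  int stack[27], top = 0;
  stack[top++] = start; vis[start] = true;
  while (top) {
    int cur = stack[--top];
    int cz = cur % 3, cy = (cur / 3) % 3, cx = cur / 9;
    const int dzs[6] = {1, -1, 0, 0, 0, 0};
    const int dys[6] = {0, 0, 1, -1, 0, 0};
    const int dxs[6] = {0, 0, 0, 0, 1, -1};
    for (int o = 0; o < 6; ++o) {
      int zz = cz + dzs[o], yy = cy + dys[o], xx = cx + dxs[o];
      if (zz < 0 || zz > 2 || yy < 0 || yy > 2 || xx < 0 || xx > 2) continue;
      int j = zz + yy * 3 + xx * 9;
      int s = std::abs(zz - 1) + std::abs(yy - 1) + std::abs(xx - 1);
      if (s > 2 || j == 13) continue; // restrict to N18
      if (vis[j] || nb[j]) continue;
      vis[j] = true; stack[top++] = j;
    }
  }
  // every bg face neighbour must have been reached
  for (int f = 0; f < 6; ++f)
    if (!nb[faces[f]] && !vis[faces[f]]) return false;
  return true;
}

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask_in, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  std::vector<uint8_t> m(n);
  for (int64_t i = 0; i < n; ++i) m[i] = mask_in[i] ? 1 : 0;

  auto at = [&](int z, int y, int x) -> uint8_t {
    if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) return 0;
    return m[lin(z, y, x, nz, ny)];
  };
  auto neighborhood = [&](int z, int y, int x, bool nb[27]) {
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c)
          nb[(a + 1) + (b + 1) * 3 + (c + 1) * 9] =
            at(z + a, y + b, x + c) != 0;
  };
  auto fg_neighbors = [&](const bool nb[27]) {
    int cnt = 0;
    for (int i = 0; i < 27; ++i) if (i != 13 && nb[i]) ++cnt;
    return cnt;
  };

  // current foreground voxel list
  std::vector<int64_t> fgl;
  fgl.reserve(1024);
  for (int64_t i = 0; i < n; ++i) if (m[i]) fgl.push_back(i);

  const int dirs[6][3] = {{-1, 0, 0}, {1, 0, 0}, {0, -1, 0},
                          {0, 1, 0},  {0, 0, -1}, {0, 0, 1}};
  std::vector<int64_t> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (size_t t = 0; t < fgl.size(); ++t) {
        int64_t i = fgl[t];
        if (!m[i]) continue;
        int z = (int)(i % nz);
        int y = (int)((i / nz) % ny);
        int x = (int)(i / ((int64_t)nz * ny));
        if (at(z + dirs[d][0], y + dirs[d][1], x + dirs[d][2])) continue;
        bool nb[27];
        neighborhood(z, y, x, nb);
        int fn = fg_neighbors(nb);
        if (fn < 2) continue; // curve endpoint (or isolated): keep
        if (object_connected26(nb) && background_connected6(nb))
          cand.push_back(i);
      }
      // sequential re-checked deletion preserves topology
      for (size_t t = 0; t < cand.size(); ++t) {
        int64_t i = cand[t];
        int z = (int)(i % nz);
        int y = (int)((i / nz) % ny);
        int x = (int)(i / ((int64_t)nz * ny));
        bool nb[27];
        neighborhood(z, y, x, nb);
        if (fg_neighbors(nb) < 2) continue;
        if (object_connected26(nb) && background_connected6(nb)) {
          m[i] = 0;
          changed = true;
        }
      }
    }
    // compact the foreground list between cycles
    size_t w = 0;
    for (size_t t = 0; t < fgl.size(); ++t)
      if (m[fgl[t]]) fgl[w++] = fgl[t];
    fgl.resize(w);
  }

  LogicalVector out(n);
  for (int64_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------------ capsule_mask

// Voxels whose centres lie within radius r (nm) of any of the given
// segments (rows: z1,y1,x1,z2,y2,x2 in nm).
// [[Rcpp::export(name = ".capsule_mask_cpp")]]
LogicalVector capsule_mask_cpp(NumericMatrix segs, NumericVector radii,
                               IntegerVector dim, NumericVector vs,
                               NumericVector origin) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int64_t n = (int64_t)nz * ny * nx;
  LogicalVector out(n, false);
  for (int s = 0; s < segs.nrow(); ++s) {
    const double r = radii[s], r2 = r * r;
    double a[3] = {segs(s, 0), segs(s, 1), segs(s, 2)};
    double b[3] = {segs(s, 3), segs(s, 4), segs(s, 5)};
    double lo[3], hi[3];
    for (int j = 0; j < 3; ++j) {
      lo[j] = std::min(a[j], b[j]) - r;
      hi[j] = std::max(a[j], b[j]) + r;
    }
    int zlo = std::max(0, (int)std::floor((lo[0] - origin[0]) / vs[0] - 0.5));
    int zhi = std::min(nz - 1, (int)std::ceil((hi[0] - origin[0]) / vs[0] - 0.5));
    int ylo = std::max(0, (int)std::floor((lo[1] - origin[1]) / vs[1] - 0.5));
    int yhi = std::min(ny - 1, (int)std::ceil((hi[1] - origin[1]) / vs[1] - 0.5));
    int xlo = std::max(0, (int)std::floor((lo[2] - origin[2]) / vs[2] - 0.5));
    int xhi = std::min(nx - 1, (int)std::ceil((hi[2] - origin[2]) / vs[2] - 0.5));
    double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
    double len2 = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
    for (int x = xlo; x <= xhi; ++x) {
      double cx = (x + 0.5) * vs[2] + origin[2];
      for (int y = ylo; y <= yhi; ++y) {
        double cy = (y + 0.5) * vs[1] + origin[1];
        for (int z = zlo; z <= zhi; ++z) {
          int64_t i = lin(z, y, x, nz, ny);
          if (out[i]) continue;
          double cz = (z + 0.5) * vs[0] + origin[0];
          double ap[3] = {cz - a[0], cy - a[1], cx - a[2]};
          double t = 0.0;
          if (len2 > 0.0) {
            t = (ap[0] * ab[0] + ap[1] * ab[1] + ap[2] * ab[2]) / len2;
            if (t < 0.0) t = 0.0;
            if (t > 1.0) t = 1.0;
          }
          double dz = ap[0] - t * ab[0];
          double dy = ap[1] - t * ab[1];
          double dx = ap[2] - t * ab[2];
          if (dz * dz + dy * dy + dx * dx <= r2) out[i] = true;
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// ------------------------------------------------------- upsample_trilinear

// [[Rcpp::export(name = ".upsample_trilinear_cpp")]]
NumericVector upsample_trilinear_cpp(NumericVector coarse, IntegerVector cdim,
                                     NumericVector cvs, NumericVector corigin,
                                     IntegerVector fdim, NumericVector fvs,
                                     NumericVector forigin) {
  const int cnz = cdim[0], cny = cdim[1], cnx = cdim[2];
  const int nz = fdim[0], ny = fdim[1], nx = fdim[2];
  NumericVector out((int64_t)nz * ny * nx);
  auto cidx = [&](int z, int y, int x) {
    return coarse[lin(z, y, x, cnz, cny)];
  };
  for (int x = 0; x < nx; ++x) {
    double ux = ((x + 0.5) * fvs[2] + forigin[2] - corigin[2]) / cvs[2] - 0.5;
    int x0 = (int)std::floor(ux);
    double tx = ux - x0;
    if (x0 < 0) { x0 = 0; tx = 0.0; }
    if (x0 >= cnx - 1) { x0 = cnx - 2 >= 0 ? cnx - 2 : 0; tx = cnx > 1 ? 1.0 : 0.0; }
    int x1 = cnx > 1 ? x0 + 1 : x0;
    for (int y = 0; y < ny; ++y) {
      double uy = ((y + 0.5) * fvs[1] + forigin[1] - corigin[1]) / cvs[1] - 0.5;
      int y0 = (int)std::floor(uy);
      double ty = uy - y0;
      if (y0 < 0) { y0 = 0; ty = 0.0; }
      if (y0 >= cny - 1) { y0 = cny - 2 >= 0 ? cny - 2 : 0; ty = cny > 1 ? 1.0 : 0.0; }
      int y1 = cny > 1 ? y0 + 1 : y0;
      for (int z = 0; z < nz; ++z) {
        double uz = ((z + 0.5) * fvs[0] + forigin[0] - corigin[0]) / cvs[0] - 0.5;
        int z0 = (int)std::floor(uz);
        double tz = uz - z0;
        if (z0 < 0) { z0 = 0; tz = 0.0; }
        if (z0 >= cnz - 1) { z0 = cnz - 2 >= 0 ? cnz - 2 : 0; tz = cnz > 1 ? 1.0 : 0.0; }
        int z1 = cnz > 1 ? z0 + 1 : z0;
        double c00 = cidx(z0, y0, x0) * (1 - tz) + cidx(z1, y0, x0) * tz;
        double c10 = cidx(z0, y1, x0) * (1 - tz) + cidx(z1, y1, x0) * tz;
        double c01 = cidx(z0, y0, x1) * (1 - tz) + cidx(z1, y0, x1) * tz;
        double c11 = cidx(z0, y1, x1) * (1 - tz) + cidx(z1, y1, x1) * tz;
        double c0 = c00 * (1 - ty) + c10 * ty;
        double c1 = c01 * (1 - ty) + c11 * ty;
        out[lin(z, y, x, nz, ny)] = c0 * (1 - tx) + c1 * tx;
      }
    }
  }
  out.attr("dim") = fdim;
  return out;
}

// --------------------------------------------------------------- stamping

// Adds `weights[o]` at centres[p] + offsets[o] for every particle p,
// skipping out-of-bounds voxels. Centres and offsets are 0-based (z,y,x).
// [[Rcpp::export(name = ".stamp_add_cpp")]]
NumericVector stamp_add_cpp(NumericVector vol, IntegerVector dim,
                            IntegerMatrix centers, IntegerMatrix offsets,
                            NumericVector weights) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  NumericVector out = clone(vol);
  for (int p = 0; p < centers.nrow(); ++p) {
    for (int o = 0; o < offsets.nrow(); ++o) {
      int z = centers(p, 0) + offsets(o, 0);
      int y = centers(p, 1) + offsets(o, 1);
      int x = centers(p, 2) + offsets(o, 2);
      if (z < 0 || z >= nz || y < 0 || y >= ny || x < 0 || x >= nx) continue;
      out[lin(z, y, x, nz, ny)] += weights[o];
    }
  }
  out.attr("dim") = dim;
  return out;
}
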