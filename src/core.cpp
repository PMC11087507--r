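#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// Volumes are integer arrays with dim = (nz, ny, nx), R column-major, so the
// linear index of (z, y, x) (0-based) is z + nz * (y + ny * x).

static inline R_xlen_t lin(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)x);
}

static void get_dims(const IntegerVector &vol, int &nz, int &ny, int &nx) {
  IntegerVector d = vol.attr("dim");
  if (d.size() != 3) stop("expected a 3D array");
  nz = d[0]; ny = d[1]; nx = d[2];
}

// neighbor offset table for a connectivity; mode: 6, 18, 26, or 4 (planewise xy)
static std::vector<std::array<int,3>> neighbors(int connectivity) {
  std::vector<std::array<int,3>> off;
  if (connectivity == 4) { // in-plane 4-neighborhood, no z moves
    off = {{{0,-1,0}},{{0,1,0}},{{0,0,-1}},{{0,0,1}}};
    return off;
  }
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int a = std::abs(dz) + std::abs(dy) + std::abs(dx);
        if (a == 0) continue;
        if (connectivity == 6  && a > 1) continue;
        if (connectivity == 18 && a > 2) continue;
        off.push_back({{dz, dy, dx}});
      }
  return off;
}

// Connected-component labeling of a binary mask (any value > 0 is foreground).
// Components are numbered 1..K in order of their first voxel in linear scan
// order, which makes labeling deterministic.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(IntegerVector vol, int connectivity) {
  int nz, ny, nx; get_dims(vol, nz, ny, nx);
  std::vector<std::array<int,3>> off = neighbors(connectivity);
  R_xlen_t n = vol.size();
  IntegerVector lab(n, 0);
  lab.attr("dim") = vol.attr("dim");
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (vol[i] <= 0 || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int x = (int)(v / ((R_xlen_t)nz * ny));
      int rem = (int)(v - (R_xlen_t)x * nz * ny);
      int y = rem / nz, z = rem % nz;
      for (size_t k = 0; k < off.size(); ++k) {
        int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
        if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx) continue;
        R_xlen_t w = lin(zz, yy, xx, nz, ny);
        if (vol[w] > 0 && lab[w] == 0) { lab[w] = next; stack.push_back(w); }
      }
    }
  }
  return lab;
}

// Single-voxel-thick outer shell per instance: a voxel keeps its label iff some
// structuring-element neighbor is not the same label (background, another
// label, or outside the volume -- out-of-volume counts as background so faces
// at the volume boundary are shell). mode 0 = full 3D 6-neighbor cross,
// mode 1 = plane-wise xy 4-neighbor cross.
// [[Rcpp::export(name = ".shell_cpp")]]
IntegerVector shell_cpp(IntegerVector labels, int mode) {
  int nz, ny, nx; get_dims(labels, nz, ny, nx);
  std::vector<std::array<int,3>> off = neighbors(mode == 1 ? 4 : 6);
  IntegerVector out(labels.size(), 0);
  out.attr("dim") = labels.attr("dim");
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        int L = labels[i];
        if (L <= 0) continue;
        bool boundary = false;
        for (size_t k = 0; k < off.size() && !boundary; ++k) {
          int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
          if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx)
            boundary = true;
          else if (labels[lin(zz, yy, xx, nz, ny)] != L)
            boundary = true;
        }
        if (boundary) out[i] = L;
      }
  return out;
}

// Multi-source BFS distance from `sources` (> 0), not expanding into `blocked`
// (> 0) voxels, up to K steps. Realizes iterated one-voxel dilation: a voxel's
// value is the first dilation step that reaches it (0 on sources), -1 if not
// reached within K. Source voxels inside blocked regions still seed the front.
// mode 0 = 6-neighbor 3D (city-block), mode 1 = plane-wise xy 4-neighbor.
// [[Rcpp::export(name = ".bfs_dist_cpp")]]
IntegerVector bfs_dist_cpp(IntegerVector sources, IntegerVector blocked, int K, int mode) {
  int nz, ny, nx; get_dims(sources, nz, ny, nx);
  bool has_blocked = blocked.size() == sources.size();
  std::vector<std::array<int,3>> off = neighbors(mode == 1 ? 4 : 6);
  R_xlen_t n = sources.size();
  IntegerVector dist(n, -1);
  dist.attr("dim") = sources.attr("dim");
  std::queue<R_xlen_t> q;
  for (R_xlen_t i = 0; i < n; ++i)
    if (sources[i] > 0) { dist[i] = 0; q.push(i); }
  while (!q.empty()) {
    R_xlen_t v = q.front(); q.pop();
    int d = dist[v];
    if (d >= K) continue;
    int x = (int)(v / ((R_xlen_t)nz * ny));
    int rem = (int)(v - (R_xlen_t)x * nz * ny);
    int y = rem / nz, z = rem % nz;
    for (size_t k = 0; k < off.size(); ++k) {
      int zz = z + off[k][0], yy = y + off[k][1], xx = x + off[k][2];
      if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx) continue;
      R_xlen_t w = lin(zz, yy, xx, nz, ny);
      if (dist[w] != -1) continue;
      if (has_blocked && blocked[w] > 0) continue;
      dist[w] = d + 1;
      q.push(w);
    }
  }
  return dist;
}

// One pass of per-instance voxel statistics: voxel count, exposed-face area
// (voxel-face surface), centroid sums (0-based voxel indices), and a flag for
// touching the volume boundary. vs = voxel size (nm) per (z, y, x) axis.
// Returns a matrix with one row per label id present (rownames = id).
// [[Rcpp::export(name = ".voxel_stats_cpp")]]
NumericMatrix voxel_stats_cpp(IntegerVector labels, NumericVector vs) {
  int nz, ny, nx; get_dims(labels, nz, ny, nx);
  int maxlab = 0;
  for (R_xlen_t i = 0; i < labels.size(); ++i)
    if (labels[i] > maxlab) maxlab = labels[i];
  if (maxlab > 50000000) stop("label ids exceed supported range");
  std::vector<double> cnt(maxlab + 1, 0), sz(maxlab + 1, 0), sy(maxlab + 1, 0),
    sx(maxlab + 1, 0), faces(maxlab + 1, 0);
  std::vector<char> touch(maxlab + 1, 0);
  double az = vs[1] * vs[2]; // face normal to z
  double ay = vs[0] * vs[2];
  double ax = vs[0] * vs[1];
  const int dzs[6] = {-1, 1, 0, 0, 0, 0};
  const int dys[6] = {0, 0, -1, 1, 0, 0};
  const int dxs[6] = {0, 0, 0, 0, -1, 1};
  const double fa[6] = {az, az, ay, ay, ax, ax};
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y)
      for (int z = 0; z < nz; ++z) {
        R_xlen_t i = lin(z, y, x, nz, ny);
        int L = labels[i];
        if (L <= 0) continue;
        cnt[L] += 1; sz[L] += z; sy[L] += y; sx[L] += x;
        if (z == 0 || y == 0 || x == 0 || z == nz - 1 || y == ny - 1 || x == nx - 1)
          touch[L] = 1;
        for (int k = 0; k < 6; ++k) {
          int zz = z + dzs[k], yy = y + dys[k], xx = x + dxs[k];
          int nb = 0;
          if (zz >= 0 && yy >= 0 && xx >= 0 && zz < nz && yy < ny && xx < nx)
            nb = labels[lin(zz, yy, xx, nz, ny)];
          if (nb != L) faces[L] += fa[k];
        }
      }
  int present = 0;
  for (int L = 1; L <= maxlab; ++L) if (cnt[L] > 0) ++present;
  NumericMatrix out(present, 7);
  CharacterVector rn(present);
  int r = 0;
  for (int L = 1; L <= maxlab; ++L) {
    if (cnt[L] == 0) continue;
    out(r, 0) = L;
    out(r, 1) = cnt[L];
    out(r, 2) = sz[L] / cnt[L];
    out(r, 3) = sy[L] / cnt[L];
    out(r, 4) = sx[L] / cnt[L];
    out(r, 5) = faces[L];
    out(r, 6) = touch[L];
    rn[r] = std::to_string(L);
    ++r;
  }
  colnames(out) = CharacterVector::create("id", "voxels", "cz", "cy", "cx",
                                          "face_area", "touch");
  rownames(out) = rn;
  return out;
}

static inline double tri_area(const double a[3], const double b[3], const double c[3]) {
  double u[3] = {b[0]-a[0], b[1]-a[1], b[2]-a[2]};
  double v[3] = {c[0]-a[0], c[1]-a[1], c[2]-a[2]};
  double w0 = u[1]*v[2] - u[2]*v[1];
  double w1 = u[2]*v[0] - u[0]*v[2];
  double w2 = u[0]*v[1] - u[1]*v[0];
  return 0.5 * std::sqrt(w0*w0 + w1*w1 + w2*w2);
}

// ---- exact squared Euclidean distance transform (Felzenszwalb/Huttenlocher,
// separable lower-envelope-of-parabolas), in voxel units ----

static void dt1d(std::vector<double> &f, int n, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0; v[0] = 0; z[0] = -1e20; z[1] = 1e20;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) --k; else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = 1e20;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

static void edt3(std::vector<double> &g, int nz, int ny, int nx) {
  int mx = std::max(nz, std::max(ny, nx));
  std::vector<double> f(mx), d(mx), z(mx + 1);
  std::vector<int> v(mx);
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      for (int q = 0; q < nz; ++q) f[q] = g[lin(q, y, x, nz, ny)];
      dt1d(f, nz, d, v, z);
      for (int q = 0; q < nz; ++q) g[lin(q, y, x, nz, ny)] = d[q];
    }
  for (int x = 0; x < nx; ++x)
    for (int q = 0; q < nz; ++q) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(q, y, x, nz, ny)];
      dt1d(f, ny, d, v, z);
      for (int y = 0; y < ny; ++y) g[lin(q, y, x, nz, ny)] = d[y];
    }
  for (int y = 0; y < ny; ++y)
    for (int q = 0; q < nz; ++q) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(q, y, x, nz, ny)];
      dt1d(f, nx, d, v, z);
      for (int x = 0; x < nx; ++x) g[lin(q, y, x, nz, ny)] = d[x];
    }
}

// Mesh surface area of a binary sub-volume (values 0/1, dim (nz,ny,nx),
// caller pads with background). A signed Euclidean distance field
// (positive inside, negative outside, zero at the digital interface) is
// built from two exact distance transforms, mildly regularized with a
// separable Gaussian (sigma in voxels), and its zero-isosurface is
// triangulated by marching tetrahedra on the Kuhn 6-tetrahedra cell
// decomposition; triangle areas are summed in nm^2 with vertices scaled
// by the per-axis voxel size. The distance field, unlike the raw binary
// grid, carries true sub-voxel geometry, so the estimate converges to
// the continuous area as objects grow (digitization study in the
// package vignette).
// [[Rcpp::export(name = ".mesh_area_cpp")]]
double mesh_area_cpp(NumericVector vol, NumericVector vs, double sigma) {
  IntegerVector d = vol.attr("dim");
  int nz = d[0], ny = d[1], nx = d[2];
  R_xlen_t n = vol.size();
  std::vector<double> dout(n), din(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    dout[i] = vol[i] > 0.5 ? 0.0 : 1e20;
    din[i]  = vol[i] > 0.5 ? 1e20 : 0.0;
  }
  edt3(dout, nz, ny, nx);
  edt3(din, nz, ny, nx);
  std::vector<double> a(n), b(n);
  for (R_xlen_t i = 0; i < n; ++i)
    a[i] = std::sqrt(din[i]) - std::sqrt(dout[i]);

  if (sigma > 0) {
    int r = (int)std::ceil(3.0 * sigma);
    std::vector<double> ker(2 * r + 1);
    double s = 0;
    for (int k = -r; k <= r; ++k) { ker[k + r] = std::exp(-0.5 * k * k / (sigma * sigma)); s += ker[k + r]; }
    for (double &w : ker) w /= s;
    // zero-padded separable convolution along z, y, x
    for (int axis = 0; axis < 3; ++axis) {
      for (int x = 0; x < nx; ++x)
        for (int y = 0; y < ny; ++y)
          for (int z = 0; z < nz; ++z) {
            double acc = 0;
            for (int k = -r; k <= r; ++k) {
              int zz = z, yy = y, xx = x;
              if (axis == 0) zz += k; else if (axis == 1) yy += k; else xx += k;
              if (zz < 0 || yy < 0 || xx < 0 || zz >= nz || yy >= ny || xx >= nx) continue;
              acc += ker[k + r] * a[lin(zz, yy, xx, nz, ny)];
            }
            b[lin(z, y, x, nz, ny)] = acc;
          }
      std::swap(a, b);
    }
  }

  const double iso = 0.0;
  // Kuhn decomposition: tetrahedra {0, e_i, e_i + e_j, (1,1,1)} over axis
  // permutations; corner bitmask bit0 = x, bit1 = y, bit2 = z.
  const int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  const int axbit[3] = {1, 2, 4};
  double area = 0;
  double f[8]; double pos[8][3];
  for (int x = 0; x + 1 < nx; ++x)
    for (int y = 0; y + 1 < ny; ++y)
      for (int z = 0; z + 1 < nz; ++z) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int dx = c & 1, dy = (c >> 1) & 1, dzc = (c >> 2) & 1;
          f[c] = a[lin(z + dzc, y + dy, x + dx, nz, ny)];
          pos[c][0] = (x + dx) * vs[2];
          pos[c][1] = (y + dy) * vs[1];
          pos[c][2] = (z + dzc) * vs[0];
          if (f[c] > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int v0 = 0;
          int v1 = axbit[perms[t][0]];
          int v2 = v1 | axbit[perms[t][1]];
          int v3 = 7;
          int vid[4] = {v0, v1, v2, v3};
          int ins[4], nin = 0;
          for (int k = 0; k < 4; ++k) { ins[k] = f[vid[k]] > iso; nin += ins[k]; }
          if (nin == 0 || nin == 4) continue;
          auto interp = [&](int aidx, int bidx, double out[3]) {
            double fa = f[vid[aidx]], fb = f[vid[bidx]];
            double tt = (iso - fa) / (fb - fa);
            for (int m = 0; m < 3; ++m)
              out[m] = pos[vid[aidx]][m] + tt * (pos[vid[bidx]][m] - pos[vid[aidx]][m]);
          };
          if (nin == 1 || nin == 3) {
            int apex = -1;
            for (int k = 0; k < 4; ++k)
              if ((nin == 1 && ins[k]) || (nin == 3 && !ins[k])) apex = k;
            double p[3][3]; int m = 0;
            for (int k = 0; k < 4; ++k)
              if (k != apex) interp(apex, k, p[m++]);
            area += tri_area(p[0], p[1], p[2]);
          } else { // 2 in, 2 out: quad split into two triangles
            int ai[2], bi[2], na = 0, nb = 0;
            for (int k = 0; k < 4; ++k) { if (ins[k]) ai[na++] = k; else bi[nb++] = k; }
            double p1[3], p2[3], p3[3], p4[3];
            interp(ai[0], bi[0], p1);
            interp(ai[0], bi[1], p2);
            interp(ai[1], bi[1], p3);
            interp(ai[1], bi[0], p4);
            area += tri_area(p1, p2, p3) + tri_area(p1, p3, p4);
          }
        }
      }
  return area;
}

// Monte-Carlo permutation count for the two-sided difference-of-means test on
// pooled values x (first na values = group A). Returns the number of
// permutations with |diff of means| >= |observed| (small tolerance for FP
// ties). Uses R's RNG so results follow set.seed().
// [[Rcpp::export(name = ".perm_count_cpp")]]
int perm_count_cpp(NumericVector x, int na, int nperm) {
  int n = x.size(), nb = n - na;
  double tot = 0;
  for (int i = 0; i < n; ++i) tot += x[i];
  double sa = 0;
  for (int i = 0; i < na; ++i) sa += x[i];
  double obs = std::fabs(sa / na - (tot - sa) / nb);
  double eps = 1e-12 * (std::fabs(obs) + 1.0);
  std::vector<int> idx(n);
  int count = 0;
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) idx[i] = i;
    double s = 0;
    for (int i = 0; i < na; ++i) { // partial Fisher-Yates
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;
      std::swap(idx[i], idx[j]);
      s += x[idx[i]];
    }
    double stat = std::fabs(s / na - (tot - s) / nb);
    if (stat >= obs - eps) ++count;
  }
  return count;
}
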