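// Texture-matrix counting and mask geometry.
//
// All functions take a discretized level array (flattened 3D, column-major
// as R stores it, 0 = background / outside ROI, levels 1..ng) plus its
// dimensions.  Counting loops live here; feature formulas stay in R.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 13 unique 3D direction offsets at Chebyshev distance 1 (one per
// antipodal pair of the 26-neighborhood).
static const int NOFF = 13;
static const int OFF[NOFF][3] = {
  {0, 0, 1}, {0, 1, -1}, {0, 1, 0}, {0, 1, 1},
  {1, -1, -1}, {1, -1, 0}, {1, -1, 1},
  {1, 0, -1}, {1, 0, 0}, {1, 0, 1},
  {1, 1, -1}, {1, 1, 0}, {1, 1, 1}};

static inline int idx3(int i, int j, int k, int n1, int n2) {
  return i + n1 * (j + n2 * k);
}

// Symmetrized co-occurrence counts per direction: ng x ng x 13.
// [[Rcpp::export(name = ".cppGLCM")]]
NumericVector cppGLCM(IntegerVector levels, IntegerVector dims, int ng) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector out(ng * ng * NOFF);
  for (int d = 0; d < NOFF; ++d) {
    int di = OFF[d][0], dj = OFF[d][1], dk = OFF[d][2];
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int a = levels[idx3(i, j, k, n1, n2)];
          if (a == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
              kk < 0 || kk >= n3) continue;
          int b = levels[idx3(ii, jj, kk, n1, n2)];
          if (b == 0) continue;
          out[(a - 1) + ng * (b - 1) + ng * ng * d] += 1.0;
          out[(b - 1) + ng * (a - 1) + ng * ng * d] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, ng, NOFF);
  return out;
}

// Run-length counts per direction: ng x maxlen x 13.
// [[Rcpp::export(name = ".cppGLRLM")]]
NumericVector cppGLRLM(IntegerVector levels, IntegerVector dims, int ng) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int maxlen = std::max(n1, std::max(n2, n3));
  NumericVector out(ng * maxlen * NOFF);
  for (int d = 0; d < NOFF; ++d) {
    int di = OFF[d][0], dj = OFF[d][1], dk = OFF[d][2];
    for (int k = 0; k < n3; ++k)
      for (int j = 0; j < n2; ++j)
        for (int i = 0; i < n1; ++i) {
          int lev = levels[idx3(i, j, k, n1, n2)];
          if (lev == 0) continue;
          // run starts here iff the predecessor is absent or different
          int pi = i - di, pj = j - dj, pk = k - dk;
          if (pi >= 0 && pi < n1 && pj >= 0 && pj < n2 &&
              pk >= 0 && pk < n3 &&
              levels[idx3(pi, pj, pk, n1, n2)] == lev) continue;
          int len = 1;
          int ci = i + di, cj = j + dj, ck = k + dk;
          while (ci >= 0 && ci < n1 && cj >= 0 && cj < n2 &&
                 ck >= 0 && ck < n3 &&
                 levels[idx3(ci, cj, ck, n1, n2)] == lev) {
            ++len; ci += di; cj += dj; ck += dk;
          }
          out[(lev - 1) + ng * (len - 1) + ng * maxlen * d] += 1.0;
        }
  }
  out.attr("dim") = IntegerVector::create(ng, maxlen, NOFF);
  return out;
}

// Size zones: connected components (26-connectivity) of equal level.
// Returns per-zone (level, size) pairs.
// [[Rcpp::export(name = ".cppGLSZM")]]
List cppGLSZM(IntegerVector levels, IntegerVector dims) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  int n = n1 * n2 * n3;
  std::vector<char> seen(n, 0);
  std::vector<int> zoneLevel, zoneSize, stack;
  for (int s = 0; s < n; ++s) {
    if (seen[s] || levels[s] == 0) continue;
    int lev = levels[s];
    int size = 0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      ++size;
      int ci = cur % n1, cj = (cur / n1) % n2, ck = cur / (n1 * n2);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                kk < 0 || kk >= n3) continue;
            int t = idx3(ii, jj, kk, n1, n2);
            if (!seen[t] && levels[t] == lev) {
              seen[t] = 1;
              stack.push_back(t);
            }
          }
    }
    zoneLevel.push_back(lev);
    zoneSize.push_back(size);
  }
  return List::create(_["level"] = wrap(zoneLevel),
                      _["size"] = wrap(zoneSize));
}

// Dependence counts: ng x 27 matrix; dependence size = 1 (the center) +
// number of 26-neighbors whose level differs by at most alpha.
// [[Rcpp::export(name = ".cppGLDM")]]
NumericMatrix cppGLDM(IntegerVector levels, IntegerVector dims, int ng,
                      int alpha) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericMatrix out(ng, 27);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int lev = levels[idx3(i, j, k, n1, n2)];
        if (lev == 0) continue;
        int dep = 1;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3) continue;
              int b = levels[idx3(ii, jj, kk, n1, n2)];
              if (b != 0 && std::abs(b - lev) <= alpha) ++dep;
            }
        out(lev - 1, dep - 1) += 1.0;
      }
  return out;
}

// Neighboring gray-tone difference accumulators: per level, the count of
// valid voxels and the summed |level - mean(neighbor levels)|.  Voxels
// with no in-ROI neighbor are excluded.
// [[Rcpp::export(name = ".cppNGTDM")]]
List cppNGTDM(IntegerVector levels, IntegerVector dims, int ng) {
  int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  NumericVector s(ng), nvec(ng);
  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        int lev = levels[idx3(i, j, k, n1, n2)];
        if (lev == 0) continue;
        double sum = 0.0;
        int cnt = 0;
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 ||
                  kk < 0 || kk >= n3) continue;
              int b = levels[idx3(ii, jj, kk, n1, n2)];
              if (b != 0) { sum += b; ++cnt; }
            }
        if (cnt == 0) continue;
        nvec[lev - 1] += 1.0;
        s[lev - 1] += std::fabs((double)lev - sum / cnt);
      }
  return List::create(_["s"] = s, _["n"] = nvec);
}

// ---- Surface mesh of a binary mask: marching tetrahedra ----------------

struct Vec3 { double x, y, z; };
static inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
          a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// 6-tetrahedra decomposition of the unit cube around diagonal v0-v7
// (corner index bits: x = bit 0, y = bit 1, z = bit 2).
static const int TETS[6][4] = {
  {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
  {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};

// Iso-surface of a scalar field via marching tetrahedra with linear
// edge interpolation.  The field is sampled at voxel centers of a grid
// already padded by the caller so the surface closes.  Returns
// c(surface_area, enclosed_volume) in physical units.
// [[Rcpp::export(name = ".cppMarchingMesh")]]
NumericVector cppMarchingMesh(NumericVector field, IntegerVector dims,
                              NumericVector spacing, double iso) {
  int m1 = dims[0], m2 = dims[1], m3 = dims[2];
  double area = 0.0, vol = 0.0;
  Vec3 corner[8];
  double cv[8];
  for (int k = 0; k < m3 - 1; ++k)
    for (int j = 0; j < m2 - 1; ++j)
      for (int i = 0; i < m1 - 1; ++i) {
        int any1 = 0, any0 = 0;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1),
              ck = k + ((c >> 2) & 1);
          cv[c] = field[(size_t)ci + (size_t)m1 * (cj + (size_t)m2 * ck)];
          corner[c] = {ci * spacing[0], cj * spacing[1], ck * spacing[2]};
          if (cv[c] > iso) any1 = 1; else any0 = 1;
        }
        if (!any1 || !any0) continue;
        for (int t = 0; t < 6; ++t) {
          const int *T = TETS[t];
          int nin = 0;
          Vec3 qin = {0, 0, 0};
          for (int v = 0; v < 4; ++v)
            if (cv[T[v]] > iso) {
              ++nin;
              qin.x += corner[T[v]].x; qin.y += corner[T[v]].y;
              qin.z += corner[T[v]].z;
            }
          if (nin == 0 || nin == 4) continue;
          qin.x /= nin; qin.y /= nin; qin.z /= nin;
          // interpolated crossing points on inside->outside edges
          Vec3 tri[4];
          int ntri = 0;
          for (int a = 0; a < 4; ++a)
            for (int b = 0; b < 4; ++b) {
              if (!(cv[T[a]] > iso) || (cv[T[b]] > iso)) continue;
              double f0 = cv[T[a]], f1 = cv[T[b]];
              double tt = (std::fabs(f1 - f0) < 1e-12)
                            ? 0.5 : (iso - f0) / (f1 - f0);
              tri[ntri].x = corner[T[a]].x +
                            tt * (corner[T[b]].x - corner[T[a]].x);
              tri[ntri].y = corner[T[a]].y +
                            tt * (corner[T[b]].y - corner[T[a]].y);
              tri[ntri].z = corner[T[a]].z +
                            tt * (corner[T[b]].z - corner[T[a]].z);
              ++ntri;
            }
          // ntri = 3 (one triangle) or 4 (quad -> two triangles)
          int faces[2][3];
          int nf = 0;
          if (ntri == 3) {
            faces[0][0] = 0; faces[0][1] = 1; faces[0][2] = 2;
            nf = 1;
          } else {
            // midpoint order from the loop: (in0,out0),(in0,out1),
            // (in1,out0),(in1,out1); the quad cycle is 0-1-3-2
            faces[0][0] = 0; faces[0][1] = 1; faces[0][2] = 3;
            faces[1][0] = 0; faces[1][1] = 3; faces[1][2] = 2;
            nf = 2;
          }
          for (int f = 0; f < nf; ++f) {
            Vec3 p0 = tri[faces[f][0]], p1 = tri[faces[f][1]],
                 p2 = tri[faces[f][2]];
            Vec3 nrm = cross(sub(p1, p0), sub(p2, p0));
            Vec3 cen = {(p0.x + p1.x + p2.x) / 3,
                        (p0.y + p1.y + p2.y) / 3,
                        (p0.z + p1.z + p2.z) / 3};
            if (dot(nrm, sub(cen, qin)) < 0) {
              Vec3 tmp = p1; p1 = p2; p2 = tmp;
              nrm = cross(sub(p1, p0), sub(p2, p0));
            }
            double a2 = std::sqrt(dot(nrm, nrm));
            area += a2 / 2.0;
            vol += dot(p0, cross(p1, p2)) / 6.0;
          }
        }
      }
  return NumericVector::create(area, vol);
}

// Maximum pairwise Euclidean distance between rows of a coordinate matrix.
// [[Rcpp::export(name = ".cppMaxDist")]]
double cppMaxDist(NumericMatrix pts) {
  int n = pts.nrow(), d = pts.ncol();
  double best = 0.0;
  for (int a = 0; a < n; ++a)
    for (int b = a + 1; b < n; ++b) {
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double t = pts(a, c) - pts(b, c);
        s += t * t;
      }
      if (s > best) best = s;
    }
  return std::sqrt(best);
}
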