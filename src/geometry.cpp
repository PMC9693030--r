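// Geometry kernels: symmetric closest-point distances, exact point-to-mesh
// distance, topology-preserving 3D thinning, and tetrahedral iso-surfacing.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// ---- nearest-neighbour distances between point sets ------------------------

// For each row of A (n x 3), the Euclidean distance to the nearest row of B.
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B) {
  const int n = A.nrow(), m = B.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---- exact point-to-triangle distance (Ericson, Real-Time Collision
// Detection, closest point on triangle) ---------------------------------------

static inline double clamp01(double t) {
  return t < 0.0 ? 0.0 : (t > 1.0 ? 1.0 : t);
}

static double pt_tri_d2(const double p[3], const double a[3],
                        const double b[3], const double c[3]) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  double q[3];
  if (d1 <= 0.0 && d2 <= 0.0) { q[0] = a[0]; q[1] = a[1]; q[2] = a[2]; goto done; }
  {
    double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
    double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
    double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
    if (d3 >= 0.0 && d4 <= d3) { q[0] = b[0]; q[1] = b[1]; q[2] = b[2]; goto done; }
    double vc = d1 * d4 - d3 * d2;
    if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
      double v = (d1 - d3 != 0.0) ? d1 / (d1 - d3) : 0.0; v = clamp01(v);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + v * ab[k];
      goto done;
    }
    double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
    double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
    double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
    if (d6 >= 0.0 && d5 <= d6) { q[0] = c[0]; q[1] = c[1]; q[2] = c[2]; goto done; }
    double vb = d5 * d2 - d1 * d6;
    if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
      double w = (d2 - d6 != 0.0) ? d2 / (d2 - d6) : 0.0; w = clamp01(w);
      for (int k = 0; k < 3; ++k) q[k] = a[k] + w * ac[k];
      goto done;
    }
    double va = d3 * d6 - d5 * d4;
    if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
      double denom = (d4 - d3) + (d5 - d6);
      double w = denom != 0.0 ? (d4 - d3) / denom : 0.0; w = clamp01(w);
      for (int k = 0; k < 3; ++k) q[k] = b[k] + w * (c[k] - b[k]);
      goto done;
    }
    double denom = va + vb + vc;
    double v = denom != 0.0 ? vb / denom : 0.0;
    double w = denom != 0.0 ? vc / denom : 0.0;
    for (int k = 0; k < 3; ++k) q[k] = a[k] + ab[k] * v + ac[k] * w;
  }
done:
  double dx = p[0] - q[0], dy = p[1] - q[1], dz = p[2] - q[2];
  return dx * dx + dy * dy + dz * dz;
}

// For each point (rows of P), the distance to the closest point on any
// triangle of the mesh (V vertices, F 1-based triangle indices). A
// centroid/circumradius lower bound prunes most triangles; a vertex
// nearest-neighbour pass seeds the search radius.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_dists(NumericMatrix P, NumericMatrix V,
                                   IntegerMatrix F) {
  const int n = P.nrow(), m = F.nrow(), nv = V.nrow();
  std::vector<double> cx(m), cy(m), cz(m), rad(m);
  for (int t = 0; t < m; ++t) {
    int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
    double gx = (V(ia, 0) + V(ib, 0) + V(ic, 0)) / 3.0;
    double gy = (V(ia, 1) + V(ib, 1) + V(ic, 1)) / 3.0;
    double gz = (V(ia, 2) + V(ib, 2) + V(ic, 2)) / 3.0;
    cx[t] = gx; cy[t] = gy; cz[t] = gz;
    double r2 = 0.0;
    int ids[3] = {ia, ib, ic};
    for (int k = 0; k < 3; ++k) {
      double dx = V(ids[k], 0) - gx, dy = V(ids[k], 1) - gy,
             dz = V(ids[k], 2) - gz;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > r2) r2 = d2;
    }
    rad[t] = std::sqrt(r2);
  }
  // only vertices referenced by a triangle lie on the surface
  std::vector<char> used(nv, 0);
  for (int t = 0; t < m; ++t)
    for (int k = 0; k < 3; ++k) used[F(t, k) - 1] = 1;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    // seed with nearest referenced vertex (upper bound on the true distance)
    double best = R_PosInf;
    for (int j = 0; j < nv; ++j) {
      if (!used[j]) continue;
      double dx = p[0] - V(j, 0), dy = p[1] - V(j, 1), dz = p[2] - V(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    double bestd = std::sqrt(best);
    for (int t = 0; t < m; ++t) {
      double dx = p[0] - cx[t], dy = p[1] - cy[t], dz = p[2] - cz[t];
      double lb = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[t];
      if (lb >= bestd) continue;
      int ia = F(t, 0) - 1, ib = F(t, 1) - 1, ic = F(t, 2) - 1;
      double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
      double b[3] = {V(ib, 0), V(ib, 1), V(ib, 2)};
      double c[3] = {V(ic, 0), V(ic, 1), V(ic, 2)};
      double d2t = pt_tri_d2(p, a, b, c);
      if (d2t < best) { best = d2t; bestd = std::sqrt(best); }
    }
    out[i] = bestd;
  }
  return out;
}

// ---- topology-preserving 3D thinning ---------------------------------------

// 26-connected components of foreground within the 3x3x3 neighbourhood
// (centre removed) that touch the centre; and 6-connected components of
// background within the 18-neighbourhood that are 6-adjacent to the centre.
// A voxel is simple iff both counts equal 1 (Bertrand & Malandain).

static const int DX6[6] = {1, -1, 0, 0, 0, 0};
static const int DY6[6] = {0, 0, 1, -1, 0, 0};
static const int DZ6[6] = {0, 0, 0, 0, 1, -1};

static bool is_simple(const std::vector<unsigned char>& img, int nx, int ny,
                      int nz, int x, int y, int z) {
  unsigned char nb[27]; // local 3x3x3, index (dz+1)*9+(dy+1)*3+(dx+1)
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        unsigned char v = 0;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          v = img[(size_t)zz * nx * ny + (size_t)yy * nx + xx];
        nb[(dz + 1) * 9 + (dy + 1) * 3 + (dx + 1)] = v;
      }
  // foreground 26-components in N26 (centre excluded)
  int labels[27]; for (int i = 0; i < 27; ++i) labels[i] = 0;
  int ncomp_fg = 0;
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || labels[i]) continue;
    ++ncomp_fg;
    // BFS over 26-adjacency within the cube
    std::vector<int> stack(1, i); labels[i] = ncomp_fg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int czz = c / 9 - 1, cyy = (c % 9) / 3 - 1, cxx = c % 3 - 1;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nxx = cxx + dx, nyy = cyy + dy, nzz = czz + dz;
            if (nxx < -1 || nxx > 1 || nyy < -1 || nyy > 1 || nzz < -1 || nzz > 1)
              continue;
            int j = (nzz + 1) * 9 + (nyy + 1) * 3 + (nxx + 1);
            if (j == 13 || !nb[j] || labels[j]) continue;
            labels[j] = ncomp_fg; stack.push_back(j);
          }
    }
  }
  if (ncomp_fg != 1) return false;
  // background 6-components within N18 that are 6-adjacent to centre
  int blab[27]; for (int i = 0; i < 27; ++i) blab[i] = 0;
  int ncomp_bg = 0;
  for (int s = 0; s < 6; ++s) {
    int i = (DZ6[s] + 1) * 9 + (DY6[s] + 1) * 3 + (DX6[s] + 1);
    if (nb[i] || blab[i]) continue;
    ++ncomp_bg;
    std::vector<int> stack(1, i); blab[i] = ncomp_bg;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int czz = c / 9 - 1, cyy = (c % 9) / 3 - 1, cxx = c % 3 - 1;
      for (int s2 = 0; s2 < 6; ++s2) {
        int nxx = cxx + DX6[s2], nyy = cyy + DY6[s2], nzz = czz + DZ6[s2];
        if (nxx < -1 || nxx > 1 || nyy < -1 || nyy > 1 || nzz < -1 || nzz > 1)
          continue;
        // restrict to N18 (exclude the 8 cube corners) and exclude centre
        if (std::abs(nxx) + std::abs(nyy) + std::abs(nzz) > 2) continue;
        int j = (nzz + 1) * 9 + (nyy + 1) * 3 + (nxx + 1);
        if (j == 13 || nb[j] || blab[j]) continue;
        blab[j] = ncomp_bg; stack.push_back(j);
      }
    }
  }
  return ncomp_bg == 1;
}

static int count_fg26(const std::vector<unsigned char>& img, int nx, int ny,
                      int nz, int x, int y, int z) {
  int cnt = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int xx = x + dx, yy = y + dy, zz = z + dz;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz &&
            img[(size_t)zz * nx * ny + (size_t)yy * nx + xx]) ++cnt;
      }
  return cnt;
}

// Directional (6-subiteration) thinning to a curve skeleton: iteratively
// delete simple, non-endpoint border voxels; sequential re-checking inside
// each subiteration preserves topology.
// [[Rcpp::export]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> img(n);
  for (size_t i = 0; i < n; ++i) img[i] = mask[i] ? 1 : 0;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int dir = 0; dir < 6; ++dir) {
      std::vector<size_t> cand;
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t idx = (size_t)z * nx * ny + (size_t)y * nx + x;
            if (!img[idx]) continue;
            int xx = x + DX6[dir], yy = y + DY6[dir], zz = z + DZ6[dir];
            bool border = !(xx >= 0 && xx < nx && yy >= 0 && yy < ny &&
                            zz >= 0 && zz < nz &&
                            img[(size_t)zz * nx * ny + (size_t)yy * nx + xx]);
            if (!border) continue;
            if (count_fg26(img, nx, ny, nz, x, y, z) <= 1) continue; // endpoint
            if (is_simple(img, nx, ny, nz, x, y, z)) cand.push_back(idx);
          }
      for (size_t c : cand) {
        int x = c % nx, y = (c / nx) % ny, z = c / ((size_t)nx * ny);
        if (count_fg26(img, nx, ny, nz, x, y, z) <= 1) continue;
        if (is_simple(img, nx, ny, nz, x, y, z)) {
          img[c] = 0; changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = img[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---- marching tetrahedra iso-surface ---------------------------------------

// Each grid cube is split into 6 tetrahedra sharing the main diagonal; the
// iso-surface (value > iso inside) is triangulated per tetrahedron.
static const int TETS[6][4] = {
  {0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
  {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}
};
// cube corner offsets (x, y, z), corner id 0..7
static const int CO[8][3] = {
  {0, 0, 0}, {1, 0, 0}, {1, 1, 0}, {0, 1, 0},
  {0, 0, 1}, {1, 0, 1}, {1, 1, 1}, {0, 1, 1}
};

// [[Rcpp::export]]
List cpp_march_tets(NumericVector vol, IntegerVector dims, double iso,
                    NumericVector spacing, NumericVector origin) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> verts;
  auto val = [&](int x, int y, int z) {
    return vol[(size_t)z * nx * ny + (size_t)y * nx + x];
  };
  double cpos[8][3], cval[8];
  auto emit_edge = [&](int a, int b) {
    double va = cval[a], vb = cval[b];
    double t = (iso - va) / (vb - va);
    if (t < 0.0) t = 0.0; if (t > 1.0) t = 1.0;
    for (int k = 0; k < 3; ++k)
      verts.push_back(cpos[a][k] + t * (cpos[b][k] - cpos[a][k]));
  };
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        for (int c = 0; c < 8; ++c) {
          int cx = x + CO[c][0], cy = y + CO[c][1], cz = z + CO[c][2];
          cpos[c][0] = origin[0] + cx * spacing[0];
          cpos[c][1] = origin[1] + cy * spacing[1];
          cpos[c][2] = origin[2] + cz * spacing[2];
          cval[c] = val(cx, cy, cz);
        }
        for (int t = 0; t < 6; ++t) {
          int id[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int code = 0;
          for (int k = 0; k < 4; ++k)
            if (cval[id[k]] > iso) code |= (1 << k);
          if (code == 0 || code == 15) continue;
          // map so that "inside" corners are listed first
          int in[4], out[4], ni = 0, no = 0;
          for (int k = 0; k < 4; ++k) {
            if (code & (1 << k)) in[ni++] = id[k]; else out[no++] = id[k];
          }
          if (ni == 1) {
            emit_edge(in[0], out[0]);
            emit_edge(in[0], out[1]);
            emit_edge(in[0], out[2]);
          } else if (ni == 3) {
            emit_edge(out[0], in[0]);
            emit_edge(out[0], in[1]);
            emit_edge(out[0], in[2]);
          } else { // ni == 2: quad split into two triangles
            // edges: (in0,out0) (in0,out1) (in1,out1) (in1,out0)
            emit_edge(in[0], out[0]);
            emit_edge(in[0], out[1]);
            emit_edge(in[1], out[1]);
            emit_edge(in[0], out[0]);
            emit_edge(in[1], out[1]);
            emit_edge(in[1], out[0]);
          }
        }
      }
  int ntri = verts.size() / 9;
  NumericMatrix V(ntri * 3, 3);
  for (int i = 0; i < ntri * 3; ++i)
    for (int k = 0; k < 3; ++k) V(i, k) = verts[(size_t)i * 3 + k];
  IntegerMatrix Fm(ntri, 3);
  for (int t = 0; t < ntri; ++t) {
    Fm(t, 0) = 3 * t + 1; Fm(t, 1) = 3 * t + 2; Fm(t, 2) = 3 * t + 3;
  }
  return List::create(_["vertices"] = V, _["triangles"] = Fm);
}
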