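#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Iso-surface extraction from a 3D scalar field (typically a 0/1 tumor mask
// padded by one plane of zeros on every side) at a given iso level.
//
// Per cell the contour is built face-by-face: on each cube face the cut
// edges are paired so that the segment separates inside from outside
// corners; the ambiguous four-cut face always keeps the two inside corners
// apart.  Because the pairing depends only on the face's own corner values,
// the two cells sharing a face emit identical boundary segments, so the
// global mesh is watertight by construction.  Cycles are fan-triangulated
// from their centroid and oriented with outward normals.

namespace {

const int corner_off[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},
  {0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
// 12 cube edges as corner pairs
const int edge_c[12][2] = {
  {0,1},{1,2},{2,3},{3,0},
  {4,5},{5,6},{6,7},{7,4},
  {0,4},{1,5},{2,6},{3,7}
};
// axis of each edge (0=x,1=y,2=z) and lower-corner for canonical id
const int edge_axis[12] = {0,1,0,1, 0,1,0,1, 2,2,2,2};
const int edge_low[12]  = {0,1,3,0, 4,5,7,4, 0,1,2,3};
// 6 faces: 4 corners (cyclic) and the 4 edges between consecutive corners
const int face_c[6][4] = {
  {0,1,2,3},{4,5,6,7},{0,1,5,4},{3,2,6,7},{1,2,6,5},{0,3,7,4}
};
const int face_e[6][4] = {
  {0,1,2,3},{4,5,6,7},{0,9,4,8},{2,10,6,11},{1,10,5,9},{3,11,7,8}
};

struct Vec3 { double x, y, z; };

inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x*b.x + a.y*b.y + a.z*b.z;
}
inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x-b.x, a.y-b.y, a.z-b.z};
}

} // namespace

// [[Rcpp::export(name = ".mc_mesh")]]
List mc_mesh(NumericVector field, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double *f = REAL(field);
  auto F = [&](int x, int y, int z) -> double {
    return f[x + (size_t)nx * (y + (size_t)ny * z)];
  };

  std::vector<double> vx, vy, vz;            // vertex coords (grid units)
  std::vector<int> fa, fb, fc;               // 0-based face indices
  std::unordered_map<long long, int> vmap;   // canonical edge id -> vertex
  vmap.reserve(1 << 16);

  double cv[8];
  Vec3 cp[8];

  for (int z = 0; z + 1 < nz; ++z)
  for (int y = 0; y + 1 < ny; ++y)
  for (int x = 0; x + 1 < nx; ++x) {
    int n_in = 0;
    for (int k = 0; k < 8; ++k) {
      cv[k] = F(x + corner_off[k][0], y + corner_off[k][1], z + corner_off[k][2]);
      if (cv[k] > iso) ++n_in;
      cp[k] = Vec3{ (double)(x + corner_off[k][0]),
                    (double)(y + corner_off[k][1]),
                    (double)(z + corner_off[k][2]) };
    }
    if (n_in == 0 || n_in == 8) continue;

    // vertex id per cut cube edge (-1 = not cut)
    int evid[12];
    for (int e = 0; e < 12; ++e) {
      int a = edge_c[e][0], b = edge_c[e][1];
      bool ia = cv[a] > iso, ib = cv[b] > iso;
      if (ia == ib) { evid[e] = -1; continue; }
      int lc = edge_low[e];
      long long gx = x + corner_off[lc][0];
      long long gy = y + corner_off[lc][1];
      long long gz = z + corner_off[lc][2];
      long long key = ((gz * ny + gy) * nx + gx) * 3 + edge_axis[e];
      auto it = vmap.find(key);
      if (it != vmap.end()) { evid[e] = it->second; continue; }
      double t = (iso - cv[a]) / (cv[b] - cv[a]);
      Vec3 p{ cp[a].x + t * (cp[b].x - cp[a].x),
              cp[a].y + t * (cp[b].y - cp[a].y),
              cp[a].z + t * (cp[b].z - cp[a].z) };
      int id = (int)vx.size();
      vx.push_back(p.x); vy.push_back(p.y); vz.push_back(p.z);
      vmap[key] = id;
      evid[e] = id;
    }

    // face segments: pairs of cut edges; each cut edge appears in exactly
    // two segments (one per incident face), so segments chain into cycles
    int seg_a[24], seg_b[24];
    int nseg = 0;
    for (int fi = 0; fi < 6; ++fi) {
      int cut[4], ncut = 0;
      for (int s = 0; s < 4; ++s)
        if (evid[face_e[fi][s]] >= 0) cut[ncut++] = s;
      if (ncut == 2) {
        seg_a[nseg] = face_e[fi][cut[0]];
        seg_b[nseg] = face_e[fi][cut[1]];
        ++nseg;
      } else if (ncut == 4) {
        // ambiguous: pair the two edges flanking each inside corner
        for (int s = 0; s < 4; ++s) {
          if (cv[face_c[fi][s]] > iso) {
            seg_a[nseg] = face_e[fi][(s + 3) & 3];
            seg_b[nseg] = face_e[fi][s];
            ++nseg;
          }
        }
        // alternating pattern has exactly two inside corners -> 2 segments
      }
    }

    // trace cycles over segments
    bool used[24] = {false};
    for (int s0 = 0; s0 < nseg; ++s0) {
      if (used[s0]) continue;
      int cyc[12], clen = 0;
      int cur_edge = seg_a[s0];
      int cur_seg = s0;
      while (true) {
        used[cur_seg] = true;
        cyc[clen++] = cur_edge;
        int nxt = (seg_a[cur_seg] == cur_edge) ? seg_b[cur_seg] : seg_a[cur_seg];
        // find the other unused segment containing nxt
        int found = -1;
        for (int s = 0; s < nseg; ++s) {
          if (!used[s] && (seg_a[s] == nxt || seg_b[s] == nxt)) { found = s; break; }
        }
        if (found < 0) { cyc[clen++] = nxt; break; }
        cur_edge = nxt;
        cur_seg = found;
      }
      // last appended vertex closes back to the first; drop if duplicated
      if (clen > 1 && cyc[clen - 1] == cyc[0]) --clen;
      if (clen < 3) continue;

      // reference point: mean of inside endpoints of the cycle's edges
      Vec3 ref{0, 0, 0};
      int nref = 0;
      for (int i = 0; i < clen; ++i) {
        int e = cyc[i];
        int a = edge_c[e][0], b = edge_c[e][1];
        int in = (cv[a] > iso) ? a : b;
        ref.x += cp[in].x; ref.y += cp[in].y; ref.z += cp[in].z;
        ++nref;
      }
      ref.x /= nref; ref.y /= nref; ref.z /= nref;

      // polygon vertices
      Vec3 pc{0, 0, 0};
      for (int i = 0; i < clen; ++i) {
        int v = evid[cyc[i]];
        pc.x += vx[v]; pc.y += vy[v]; pc.z += vz[v];
      }
      pc.x /= clen; pc.y /= clen; pc.z /= clen;

      // Newell normal
      Vec3 nrm{0, 0, 0};
      for (int i = 0; i < clen; ++i) {
        int v1 = evid[cyc[i]], v2 = evid[cyc[(i + 1) % clen]];
        nrm.x += (vy[v1] - vy[v2]) * (vz[v1] + vz[v2]);
        nrm.y += (vz[v1] - vz[v2]) * (vx[v1] + vx[v2]);
        nrm.z += (vx[v1] - vx[v2]) * (vy[v1] + vy[v2]);
      }
      bool flip = dot(nrm, sub(pc, ref)) < 0;

      // centroid vertex + fan
      int cid = (int)vx.size();
      vx.push_back(pc.x); vy.push_back(pc.y); vz.push_back(pc.z);
      for (int i = 0; i < clen; ++i) {
        int v1 = evid[cyc[i]], v2 = evid[cyc[(i + 1) % clen]];
        if (flip) std::swap(v1, v2);
        fa.push_back(cid); fb.push_back(v1); fc.push_back(v2);
      }
    }
  }

  const int nv = (int)vx.size(), nf = (int)fa.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; ++i) { V(i,0) = vx[i]; V(i,1) = vy[i]; V(i,2) = vz[i]; }
  for (int i = 0; i < nf; ++i) { Fm(i,0) = fa[i] + 1; Fm(i,1) = fb[i] + 1; Fm(i,2) = fc[i] + 1; }
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// Maximum pairwise distances over mesh vertices: overall, and restricted to
// pairs lying (within half a voxel) in the same axial / coronal / sagittal
// plane.  Exact O(n^2) search.
// [[Rcpp::export(name = ".mc_diameters")]]
NumericVector mc_diameters(NumericMatrix V, NumericVector half_spacing) {
  const int n = V.nrow();
  const double hx = half_spacing[0], hy = half_spacing[1], hz = half_spacing[2];
  double best3 = 0, best_sl = 0, best_col = 0, best_row = 0;
  const double *X = &V(0,0), *Y = &V(0,1), *Z = &V(0,2);
  for (int i = 0; i < n; ++i) {
    const double xi = X[i], yi = Y[i], zi = Z[i];
    for (int j = i + 1; j < n; ++j) {
      const double dx = X[j] - xi, dy = Y[j] - yi, dz = Z[j] - zi;
      const double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > best3) best3 = d2;
      if (d2 > best_sl  && std::abs(dz) <= hz) best_sl  = d2;
      if (d2 > best_col && std::abs(dx) <= hx) best_col = d2;
      if (d2 > best_row && std::abs(dy) <= hy) best_row = d2;
    }
  }
  return NumericVector::create(std::sqrt(best3), std::sqrt(best_sl),
                               std::sqrt(best_col), std::sqrt(best_row));
}
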