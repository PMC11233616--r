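// Low-level geometric kernels: 3D convex hull (quickhull with conflict
// lists), point-in-mesh ray casting, and exact brute-force diameter.
// Kept in C++ because hulls of finely meshed sacs have every vertex
// extreme, which is quadratic-ish work no vectorised R can absorb.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#include <limits>

using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return Vec3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z,
              a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm3(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct HFace {
  int v[3];
  int nbr[3];  // neighbour across directed edge (v[i], v[(i+1)%3])
  Vec3 n;      // unit outward normal
  double off;  // n . vertex0
  std::vector<int> outside;  // conflict list (point ids strictly above)
  int far_pt;
  double far_d;
  bool alive;
};

inline double plane_dist(const HFace &f, const Vec3 &p) {
  return dot(f.n, p) - f.off;
}

// deterministic, input-independent pseudo-random joggle in [-1, 1]
inline double joggle_val(std::uint32_t i, std::uint32_t salt) {
  std::uint32_t h = i * 2654435761u + salt * 2246822519u + 374761393u;
  h ^= h >> 13;
  h *= 1274126177u;
  h ^= h >> 16;
  return (static_cast<double>(h) / 4294967295.0) * 2.0 - 1.0;
}

void make_face(HFace &f, const std::vector<Vec3> &P, int a, int b, int c) {
  f.v[0] = a;
  f.v[1] = b;
  f.v[2] = c;
  Vec3 nrm = cross(sub(P[b], P[a]), sub(P[c], P[a]));
  double ln = norm3(nrm);
  if (ln > 0) {
    nrm.x /= ln;
    nrm.y /= ln;
    nrm.z /= ln;
  }
  f.n = nrm;
  f.off = dot(nrm, P[a]);
  f.far_pt = -1;
  f.far_d = 0.0;
  f.alive = true;
}

}  // namespace

// Convex hull of a 3D point cloud.  Returns the hull triangulation with
// outward-oriented faces (1-based indices into the input), plus volume
// and surface area evaluated on the *original* coordinates.  Input is
// joggled internally by ~1e-10 of the extent to break co-spherical /
// coplanar degeneracies; the reported metrics keep that error.
// [[Rcpp::export]]
List quickhull3_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("convex hull needs at least 4 points");

  std::vector<Vec3> orig(n), P(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    orig[i] = Vec3{pts(i, 0), pts(i, 1), pts(i, 2)};
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  }
  double extent = 0.0;
  for (int d = 0; d < 3; ++d) extent = std::max(extent, hi[d] - lo[d]);
  if (!(extent > 0)) stop("degenerate point set: zero extent");
  const double jog = 1e-10 * extent;
  for (int i = 0; i < n; ++i) {
    P[i] = Vec3{orig[i].x + jog * joggle_val(i, 1u),
                orig[i].y + jog * joggle_val(i, 2u),
                orig[i].z + jog * joggle_val(i, 3u)};
  }
  const double eps = 1e-9 * extent;

  // initial simplex: extreme pair, then farthest from line, then from plane
  int i0 = 0, i1 = 0;
  {
    double best = -1.0;
    int ext[6];
    for (int d = 0; d < 3; ++d) {
      int lo_i = 0, hi_i = 0;
      double lo_v = R_PosInf, hi_v = R_NegInf;
      for (int i = 0; i < n; ++i) {
        double v = d == 0 ? P[i].x : (d == 1 ? P[i].y : P[i].z);
        if (v < lo_v) { lo_v = v; lo_i = i; }
        if (v > hi_v) { hi_v = v; hi_i = i; }
      }
      ext[2 * d] = lo_i;
      ext[2 * d + 1] = hi_i;
    }
    for (int a = 0; a < 6; ++a)
      for (int b = a + 1; b < 6; ++b) {
        double d2 = norm3(sub(P[ext[a]], P[ext[b]]));
        if (d2 > best) { best = d2; i0 = ext[a]; i1 = ext[b]; }
      }
    if (best < eps) stop("degenerate point set: all points coincide");
  }
  Vec3 dir = sub(P[i1], P[i0]);
  int i2 = -1;
  {
    double best = -1.0, dl = dot(dir, dir);
    for (int i = 0; i < n; ++i) {
      Vec3 w = sub(P[i], P[i0]);
      double t = dot(w, dir) / dl;
      Vec3 perp{w.x - t * dir.x, w.y - t * dir.y, w.z - t * dir.z};
      double d2 = norm3(perp);
      if (d2 > best) { best = d2; i2 = i; }
    }
    if (best < eps) stop("degenerate point set: collinear points");
  }
  Vec3 nrm0 = cross(dir, sub(P[i2], P[i0]));
  double nl = norm3(nrm0);
  nrm0.x /= nl; nrm0.y /= nl; nrm0.z /= nl;
  int i3 = -1;
  {
    double best = -1.0;
    for (int i = 0; i < n; ++i) {
      double d2 = std::fabs(dot(nrm0, sub(P[i], P[i0])));
      if (d2 > best) { best = d2; i3 = i; }
    }
    if (best < eps) stop("degenerate point set: coplanar points");
  }

  // interior reference point
  Vec3 c0{(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
          (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
          (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};

  std::vector<HFace> faces;
  faces.reserve(4 * n);
  int tet[4] = {i0, i1, i2, i3};
  int tri[4][3] = {{0, 1, 2}, {0, 3, 1}, {0, 2, 3}, {1, 3, 2}};
  for (int k = 0; k < 4; ++k) {
    HFace f;
    make_face(f, P, tet[tri[k][0]], tet[tri[k][1]], tet[tri[k][2]]);
    if (plane_dist(f, c0) > 0) {  // flip to outward
      std::swap(f.v[1], f.v[2]);
      make_face(f, P, f.v[0], f.v[1], f.v[2]);
    }
    faces.push_back(f);
  }
  // adjacency of the tetrahedron via directed-edge matching
  auto link_all = [&](const std::vector<int> &ids) {
    for (size_t a = 0; a < ids.size(); ++a) {
      HFace &fa = faces[ids[a]];
      for (int e = 0; e < 3; ++e) {
        int u = fa.v[e], v = fa.v[(e + 1) % 3];
        for (size_t b = 0; b < ids.size(); ++b) {
          if (a == b) continue;
          HFace &fb = faces[ids[b]];
          for (int e2 = 0; e2 < 3; ++e2) {
            if (fb.v[e2] == v && fb.v[(e2 + 1) % 3] == u) fa.nbr[e] = (int)ids[b];
          }
        }
      }
    }
  };
  {
    std::vector<int> ids{0, 1, 2, 3};
    link_all(ids);
  }

  // conflict lists
  std::vector<int> pending;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    double best = eps;
    int bf = -1;
    for (int k = 0; k < 4; ++k) {
      double d = plane_dist(faces[k], P[i]);
      if (d > best) { best = d; bf = k; }
    }
    if (bf >= 0) {
      faces[bf].outside.push_back(i);
      if (best > faces[bf].far_d) { faces[bf].far_d = best; faces[bf].far_pt = i; }
    }
  }
  std::vector<int> stack;
  for (int k = 0; k < 4; ++k)
    if (faces[k].far_pt >= 0) stack.push_back(k);

  std::vector<int> visible, horizon_face, horizon_edge;
  std::vector<char> visited;
  while (!stack.empty()) {
    int fid = stack.back();
    stack.pop_back();
    if (!faces[fid].alive || faces[fid].far_pt < 0) continue;
    int p = faces[fid].far_pt;
    const Vec3 &pp = P[p];

    // flood-fill the visible region from fid
    visible.clear();
    horizon_face.clear();
    horizon_edge.clear();
    if ((int)visited.size() < (int)faces.size()) visited.resize(faces.size(), 0);
    std::fill(visited.begin(), visited.end(), 0);
    std::vector<int> bfs{fid};
    visited[fid] = 1;
    while (!bfs.empty()) {
      int g = bfs.back();
      bfs.pop_back();
      visible.push_back(g);
      for (int e = 0; e < 3; ++e) {
        int h = faces[g].nbr[e];
        if (visited[h]) continue;
        if (plane_dist(faces[h], pp) > eps) {
          visited[h] = 2;
          bfs.push_back(h);
        } else {
          // horizon edge: directed edge e of face g, neighbour h stays
          horizon_face.push_back(g);
          horizon_edge.push_back(e);
          visited[h] = 0;  // may be probed again from another visible face
        }
      }
      visited[g] = 2;
    }

    // build the fan of new faces over the horizon loop
    const int m = (int)horizon_face.size();
    std::vector<int> new_ids(m);
    std::vector<int> first_of(0);
    // map from leading vertex -> new face id for fan linking
    std::vector<std::pair<int, int> > amap(m), bmap(m);
    for (int k = 0; k < m; ++k) {
      // copy everything we need before push_back may reallocate `faces`
      const int e = horizon_edge[k];
      const int a0 = faces[horizon_face[k]].v[e];
      const int b0 = faces[horizon_face[k]].v[(e + 1) % 3];
      const int gout = faces[horizon_face[k]].nbr[e];
      int a = a0, b = b0;
      HFace nf;
      make_face(nf, P, a, b, p);
      if (plane_dist(nf, c0) > 0) {
        // numerically flipped sliver; rebuild with swapped edge
        make_face(nf, P, b, a, p);
        std::swap(a, b);
      }
      nf.nbr[0] = gout;  // outside neighbour across the horizon edge
      faces.push_back(nf);
      int nid = (int)faces.size() - 1;
      new_ids[k] = nid;
      amap[k] = std::make_pair(nf.v[0], nid);
      bmap[k] = std::make_pair(nf.v[1], nid);
      // fix the outside neighbour's pointer to us; its directed edge is
      // the mirror (b0, a0) of the visible face's (a0, b0)
      HFace &out = faces[gout];
      for (int e2 = 0; e2 < 3; ++e2)
        if (out.v[e2] == b0 && out.v[(e2 + 1) % 3] == a0) out.nbr[e2] = nid;
    }
    // link consecutive fan faces: face (a,b,p) has edge (b,p) shared with
    // the new face whose leading vertex is b, and edge (p,a) with the one
    // whose second vertex is a
    for (int k = 0; k < m; ++k) {
      HFace &nf = faces[new_ids[k]];
      int a = nf.v[0], b = nf.v[1];
      int nb1 = -1, nb2 = -1;
      for (int j = 0; j < m; ++j) {
        if (amap[j].first == b) nb1 = amap[j].second;
        if (bmap[j].first == a) nb2 = bmap[j].second;
      }
      if (nb1 < 0 || nb2 < 0) stop("convex hull: open horizon loop (degenerate input)");
      nf.nbr[1] = nb1;
      nf.nbr[2] = nb2;
    }

    // retire visible faces, reassign their conflict points
    std::vector<int> orphans;
    for (size_t k = 0; k < visible.size(); ++k) {
      HFace &g = faces[visible[k]];
      g.alive = false;
      for (size_t q = 0; q < g.outside.size(); ++q)
        if (g.outside[q] != p) orphans.push_back(g.outside[q]);
      g.outside.clear();
    }
    for (size_t q = 0; q < orphans.size(); ++q) {
      int i = orphans[q];
      double best = eps;
      int bf = -1;
      for (int k = 0; k < m; ++k) {
        double d = plane_dist(faces[new_ids[k]], P[i]);
        if (d > best) { best = d; bf = new_ids[k]; }
      }
      if (bf >= 0) {
        faces[bf].outside.push_back(i);
        if (best > faces[bf].far_d) { faces[bf].far_d = best; faces[bf].far_pt = i; }
      }
    }
    for (int k = 0; k < m; ++k)
      if (faces[new_ids[k]].far_pt >= 0) stack.push_back(new_ids[k]);
  }

  // collect alive faces; metrics on original coordinates
  int nf = 0;
  for (size_t k = 0; k < faces.size(); ++k)
    if (faces[k].alive) ++nf;
  IntegerMatrix Fout(nf, 3);
  double vol = 0.0, area = 0.0;
  Vec3 ref{(lo[0] + hi[0]) / 2, (lo[1] + hi[1]) / 2, (lo[2] + hi[2]) / 2};
  int r = 0;
  for (size_t k = 0; k < faces.size(); ++k) {
    if (!faces[k].alive) continue;
    const HFace &f = faces[k];
    Fout(r, 0) = f.v[0] + 1;
    Fout(r, 1) = f.v[1] + 1;
    Fout(r, 2) = f.v[2] + 1;
    ++r;
    Vec3 a = sub(orig[f.v[0]], ref), b = sub(orig[f.v[1]], ref),
         c = sub(orig[f.v[2]], ref);
    vol += dot(a, cross(b, c)) / 6.0;
    area += norm3(cross(sub(orig[f.v[1]], orig[f.v[0]]),
                        sub(orig[f.v[2]], orig[f.v[0]]))) / 2.0;
  }
  return List::create(_["faces"] = Fout, _["volume"] = std::fabs(vol),
                      _["area"] = area);
}

// Point-in-mesh test for a watertight mesh by +z ray casting with a
// strip index on x.  Boundary grazing is measure-zero for random query
// points, which is the intended (Monte-Carlo) use.
// [[Rcpp::export]]
LogicalVector points_in_mesh_cpp(NumericMatrix query, NumericMatrix verts,
                                 IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  std::vector<double> x1(nf), y1(nf), z1(nf), x2(nf), y2(nf), z2(nf), x3(nf),
      y3(nf), z3(nf), xlo(nf), xhi(nf), ylo(nf), yhi(nf);
  double gxlo = R_PosInf, gxhi = R_NegInf;
  for (int f = 0; f < nf; ++f) {
    int a = faces(f, 0) - 1, b = faces(f, 1) - 1, c = faces(f, 2) - 1;
    x1[f] = verts(a, 0); y1[f] = verts(a, 1); z1[f] = verts(a, 2);
    x2[f] = verts(b, 0); y2[f] = verts(b, 1); z2[f] = verts(b, 2);
    x3[f] = verts(c, 0); y3[f] = verts(c, 1); z3[f] = verts(c, 2);
    xlo[f] = std::min(x1[f], std::min(x2[f], x3[f]));
    xhi[f] = std::max(x1[f], std::max(x2[f], x3[f]));
    ylo[f] = std::min(y1[f], std::min(y2[f], y3[f]));
    yhi[f] = std::max(y1[f], std::max(y2[f], y3[f]));
    gxlo = std::min(gxlo, xlo[f]);
    gxhi = std::max(gxhi, xhi[f]);
  }
  const int nstrip = 64;
  const double w = (gxhi - gxlo) / nstrip;
  std::vector<std::vector<int> > strip(nstrip);
  for (int f = 0; f < nf; ++f) {
    int s0 = std::max(0, std::min(nstrip - 1, (int)((xlo[f] - gxlo) / w)));
    int s1 = std::max(0, std::min(nstrip - 1, (int)((xhi[f] - gxlo) / w)));
    for (int s = s0; s <= s1; ++s) strip[s].push_back(f);
  }
  LogicalVector out(nq);
  for (int q = 0; q < nq; ++q) {
    double px = query(q, 0), py = query(q, 1), pz = query(q, 2);
    if (px < gxlo || px > gxhi) { out[q] = false; continue; }
    int s = std::max(0, std::min(nstrip - 1, (int)((px - gxlo) / w)));
    int crossings = 0;
    const std::vector<int> &fl = strip[s];
    for (size_t k = 0; k < fl.size(); ++k) {
      int f = fl[k];
      if (px < xlo[f] || px > xhi[f] || py < ylo[f] || py > yhi[f]) continue;
      double den = (y2[f] - y3[f]) * (x1[f] - x3[f]) +
                   (x3[f] - x2[f]) * (y1[f] - y3[f]);
      if (std::fabs(den) < 1e-300) continue;  // vertical triangle
      double l1 = ((y2[f] - y3[f]) * (px - x3[f]) +
                   (x3[f] - x2[f]) * (py - y3[f])) / den;
      double l2 = ((y3[f] - y1[f]) * (px - x3[f]) +
                   (x1[f] - x3[f]) * (py - y3[f])) / den;
      double l3 = 1.0 - l1 - l2;
      if (l1 < 0 || l2 < 0 || l3 < 0) continue;
      double z = l1 * z1[f] + l2 * z2[f] + l3 * z3[f];
      if (z > pz) ++crossings;
    }
    out[q] = (crossings % 2) == 1;
  }
  return out;
}

// Exact maximum pairwise distance; ties broken by the lexicographically
// smallest (i, j) index pair, which the ascending scan guarantees.
// [[Rcpp::export]]
List max_pairwise_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 2) stop("need at least 2 points");
  double best = -1.0;
  int bi = 0, bj = 1;
  for (int i = 0; i < n - 1; ++i) {
    double xi = pts(i, 0), yi = pts(i, 1), zi = pts(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(j, 0) - xi, dy = pts(j, 1) - yi, dz = pts(j, 2) - zi;
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) { best = d2; bi = i; bj = j; }
    }
  }
  return List::create(_["distance"] = std::sqrt(best),
                      _["i"] = bi + 1, _["j"] = bj + 1);
}
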