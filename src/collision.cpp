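// Triangle-mesh collision core: triangle-triangle intersection predicate,
// AABB median-split BVH construction, dual-tree traversal and a brute-force
// all-pairs reference path.
//
// Conventions (documented at the R level):
//   * closed triangles: touching counts as intersecting;
//   * tolerance 1e-10 relative to the coordinate scale, ties resolve
//     toward "intersecting";
//   * all indices crossing the R boundary are 1-based.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

static const double REL_EPS = 1e-10;

// ---------------------------------------------------------------------------
// small vector helpers
// ---------------------------------------------------------------------------

struct V3 {
  double x, y, z;
};

static inline V3 v3(double x, double y, double z) { V3 v; v.x = x; v.y = y; v.z = z; return v; }
static inline V3 sub(const V3& a, const V3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
static inline V3 add(const V3& a, const V3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
static inline V3 scl(const V3& a, double s) { return v3(a.x * s, a.y * s, a.z * s); }
static inline double dot(const V3& a, const V3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
static inline double absmax3(const V3& a) {
  return std::max(std::fabs(a.x), std::max(std::fabs(a.y), std::fabs(a.z)));
}

// ---------------------------------------------------------------------------
// triangle-triangle intersection (closed triangles, inclusive tolerance)
// ---------------------------------------------------------------------------

// 2D orientation with tolerance: >0 left, <0 right, 0 within eps
static inline double orient2d(double ax, double ay, double bx, double by,
                              double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// inclusive 2D segment intersection
static bool seg_seg_2d(double p1x, double p1y, double p2x, double p2y,
                       double q1x, double q1y, double q2x, double q2y,
                       double eps2) {
  double d1 = orient2d(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = orient2d(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = orient2d(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = orient2d(p1x, p1y, p2x, p2y, q2x, q2y);
  if (((d1 > eps2 && d2 < -eps2) || (d1 < -eps2 && d2 > eps2)) &&
      ((d3 > eps2 && d4 < -eps2) || (d3 < -eps2 && d4 > eps2)))
    return true;
  // collinear / touching cases: check bounding overlap for near-zero orientations
  auto on_seg = [eps2](double ax, double ay, double bx, double by,
                       double cx, double cy) {
    // c collinear-ish with a-b: inside the segment's bounding box (inclusive)?
    double minx = std::min(ax, bx), maxx = std::max(ax, bx);
    double miny = std::min(ay, by), maxy = std::max(ay, by);
    double slack = std::sqrt(eps2);
    return cx >= minx - slack && cx <= maxx + slack &&
           cy >= miny - slack && cy <= maxy + slack;
  };
  if (std::fabs(d1) <= eps2 && on_seg(q1x, q1y, q2x, q2y, p1x, p1y)) return true;
  if (std::fabs(d2) <= eps2 && on_seg(q1x, q1y, q2x, q2y, p2x, p2y)) return true;
  if (std::fabs(d3) <= eps2 && on_seg(p1x, p1y, p2x, p2y, q1x, q1y)) return true;
  if (std::fabs(d4) <= eps2 && on_seg(p1x, p1y, p2x, p2y, q2x, q2y)) return true;
  return false;
}

// inclusive point-in-triangle, 2D
static bool point_in_tri_2d(double px, double py,
                            double ax, double ay, double bx, double by,
                            double cx, double cy, double eps2) {
  double d1 = orient2d(ax, ay, bx, by, px, py);
  double d2 = orient2d(bx, by, cx, cy, px, py);
  double d3 = orient2d(cx, cy, ax, ay, px, py);
  bool has_neg = (d1 < -eps2) || (d2 < -eps2) || (d3 < -eps2);
  bool has_pos = (d1 > eps2) || (d2 > eps2) || (d3 > eps2);
  return !(has_neg && has_pos);
}

// coplanar 3D triangles: project to the dominant plane of n and test in 2D
static bool coplanar_tri_tri(const V3& n, const V3 t1[3], const V3 t2[3],
                             double eps) {
  double ax = std::fabs(n.x), ay = std::fabs(n.y), az = std::fabs(n.z);
  int i0, i1;  // kept coordinates
  if (ax >= ay && ax >= az)      { i0 = 1; i1 = 2; }
  else if (ay >= az)             { i0 = 0; i1 = 2; }
  else                           { i0 = 0; i1 = 1; }
  auto comp = [](const V3& v, int i) { return i == 0 ? v.x : (i == 1 ? v.y : v.z); };
  double p[3][2], q[3][2];
  for (int k = 0; k < 3; ++k) {
    p[k][0] = comp(t1[k], i0); p[k][1] = comp(t1[k], i1);
    q[k][0] = comp(t2[k], i0); q[k][1] = comp(t2[k], i1);
  }
  // orientation tolerance scales with squared length scale
  double scale = 1.0;
  for (int k = 0; k < 3; ++k) {
    scale = std::max(scale, std::max(std::fabs(p[k][0]), std::fabs(p[k][1])));
    scale = std::max(scale, std::max(std::fabs(q[k][0]), std::fabs(q[k][1])));
  }
  double eps2 = eps * scale * scale;
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j)
      if (seg_seg_2d(p[i][0], p[i][1], p[(i + 1) % 3][0], p[(i + 1) % 3][1],
                     q[j][0], q[j][1], q[(j + 1) % 3][0], q[(j + 1) % 3][1], eps2))
        return true;
  if (point_in_tri_2d(p[0][0], p[0][1], q[0][0], q[0][1], q[1][0], q[1][1],
                      q[2][0], q[2][1], eps2))
    return true;
  if (point_in_tri_2d(q[0][0], q[0][1], p[0][0], p[0][1], p[1][0], p[1][1],
                      p[2][0], p[2][1], eps2))
    return true;
  return false;
}

// interval of triangle t (signed distances d[]) on the plane-intersection
// line parameterised by t -> dot(dir, point); returns false if empty
static bool tri_plane_interval(const V3 t[3], const double d[3], const V3& dir,
                               double& lo, double& hi) {
  double ts[4];
  int nt = 0;
  for (int i = 0; i < 3; ++i) {
    if (d[i] == 0.0) ts[nt++] = dot(dir, t[i]);
    int j = (i + 1) % 3;
    if (d[i] * d[j] < 0.0) {
      double f = d[i] / (d[i] - d[j]);
      V3 p = add(t[i], scl(sub(t[j], t[i]), f));
      ts[nt++] = dot(dir, p);
    }
  }
  if (nt == 0) return false;
  lo = ts[0]; hi = ts[0];
  for (int i = 1; i < nt; ++i) {
    lo = std::min(lo, ts[i]);
    hi = std::max(hi, ts[i]);
  }
  return true;
}

// main predicate: do closed triangles t1, t2 share at least one point?
static bool tri_tri_intersect(const V3 t1[3], const V3 t2[3]) {
  double scale = 1.0;
  for (int k = 0; k < 3; ++k) {
    scale = std::max(scale, absmax3(t1[k]));
    scale = std::max(scale, absmax3(t2[k]));
  }
  double eps = REL_EPS * scale;

  V3 n1 = cross(sub(t1[1], t1[0]), sub(t1[2], t1[0]));
  V3 n2 = cross(sub(t2[1], t2[0]), sub(t2[2], t2[0]));
  double nrm1 = std::sqrt(dot(n1, n1)), nrm2 = std::sqrt(dot(n2, n2));

  // signed distances of t2's vertices to plane 1 (normalised scale)
  double d2[3], d1[3];
  for (int k = 0; k < 3; ++k) {
    d2[k] = dot(n1, sub(t2[k], t1[0])) / nrm1;
    if (std::fabs(d2[k]) <= eps) d2[k] = 0.0;
  }
  if ((d2[0] > 0 && d2[1] > 0 && d2[2] > 0) ||
      (d2[0] < 0 && d2[1] < 0 && d2[2] < 0))
    return false;
  for (int k = 0; k < 3; ++k) {
    d1[k] = dot(n2, sub(t1[k], t2[0])) / nrm2;
    if (std::fabs(d1[k]) <= eps) d1[k] = 0.0;
  }
  if ((d1[0] > 0 && d1[1] > 0 && d1[2] > 0) ||
      (d1[0] < 0 && d1[1] < 0 && d1[2] < 0))
    return false;

  if (d1[0] == 0 && d1[1] == 0 && d1[2] == 0)
    return coplanar_tri_tri(n1, t1, t2, REL_EPS);

  V3 dir = cross(n1, n2);
  double dn = std::sqrt(dot(dir, dir));
  if (dn <= eps * nrm1 * nrm2 / (scale * scale)) {
    // planes numerically parallel but straddling: treat as coplanar contact
    return coplanar_tri_tri(n1, t1, t2, REL_EPS);
  }
  dir = scl(dir, 1.0 / dn);

  double lo1, hi1, lo2, hi2;
  if (!tri_plane_interval(t1, d1, dir, lo1, hi1)) return false;
  if (!tri_plane_interval(t2, d2, dir, lo2, hi2)) return false;
  return std::max(lo1, lo2) <= std::min(hi1, hi2) + eps;
}

// ---------------------------------------------------------------------------
// R-facing triangle predicate
// ---------------------------------------------------------------------------

static void load_tri(const NumericMatrix& m, V3 t[3]) {
  for (int k = 0; k < 3; ++k) t[k] = v3(m(k, 0), m(k, 1), m(k, 2));
}

// [[Rcpp::export(name = ".cpp_tri_tri")]]
bool cpp_tri_tri(NumericMatrix t1, NumericMatrix t2) {
  V3 a[3], b[3];
  load_tri(t1, a);
  load_tri(t2, b);
  return tri_tri_intersect(a, b);
}

// ---------------------------------------------------------------------------
// mesh containers
// ---------------------------------------------------------------------------

struct Mesh {
  const double* v;  // column-major n x 3
  const int* f;     // column-major m x 3 (0-based)
  int nv, nf;
  V3 vert(int i) const { return v3(v[i], v[i + nv], v[i + 2 * nv]); }
  void tri(int t, V3 out[3]) const {
    out[0] = vert(f[t]);
    out[1] = vert(f[t + nf]);
    out[2] = vert(f[t + 2 * nf]);
  }
};

static Mesh make_mesh(const NumericMatrix& V, const IntegerMatrix& F,
                      std::vector<int>& fbuf) {
  Mesh m;
  m.v = REAL(V);
  m.nv = V.nrow();
  m.nf = F.nrow();
  fbuf.resize(static_cast<size_t>(m.nf) * 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < m.nf; ++i) fbuf[i + j * m.nf] = F(i, j) - 1;
  m.f = fbuf.data();
  return m;
}

static double mesh_scale(const Mesh& a, const Mesh& b) {
  double s = 1.0;
  for (int i = 0; i < a.nv * 3; ++i) s = std::max(s, std::fabs(a.v[i]));
  for (int i = 0; i < b.nv * 3; ++i) s = std::max(s, std::fabs(b.v[i]));
  return s;
}

// ---------------------------------------------------------------------------
// BVH: flat-array AABB tree, deterministic median split on the longest
// centroid axis, ties broken by triangle index
// ---------------------------------------------------------------------------

struct BVH {
  std::vector<double> nmin, nmax;  // 3 per node
  std::vector<int> left, right;    // -1 at leaves
  std::vector<int> start, count;   // leaf triangle range into order
  std::vector<int> order;          // permutation of 0..nf-1
};

static void tri_bounds(const Mesh& m, int t, double lo[3], double hi[3]) {
  V3 tv[3];
  m.tri(t, tv);
  lo[0] = std::min(tv[0].x, std::min(tv[1].x, tv[2].x));
  lo[1] = std::min(tv[0].y, std::min(tv[1].y, tv[2].y));
  lo[2] = std::min(tv[0].z, std::min(tv[1].z, tv[2].z));
  hi[0] = std::max(tv[0].x, std::max(tv[1].x, tv[2].x));
  hi[1] = std::max(tv[0].y, std::max(tv[1].y, tv[2].y));
  hi[2] = std::max(tv[0].z, std::max(tv[1].z, tv[2].z));
}

static int build_node(BVH& bvh, const Mesh& m,
                      const std::vector<double>& cent, int begin, int end,
                      int leaf_size) {
  int node = static_cast<int>(bvh.left.size());
  bvh.left.push_back(-1);
  bvh.right.push_back(-1);
  bvh.start.push_back(-1);
  bvh.count.push_back(0);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  double tlo[3], thi[3];
  for (int i = begin; i < end; ++i) {
    tri_bounds(m, bvh.order[i], tlo, thi);
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], tlo[k]);
      hi[k] = std::max(hi[k], thi[k]);
    }
  }
  bvh.nmin.insert(bvh.nmin.end(), lo, lo + 3);
  bvh.nmax.insert(bvh.nmax.end(), hi, hi + 3);

  if (end - begin <= leaf_size) {
    bvh.start[node] = begin;
    bvh.count[node] = end - begin;
    return node;
  }
  // longest axis of the centroid bounds
  double clo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double chi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = begin; i < end; ++i)
    for (int k = 0; k < 3; ++k) {
      double c = cent[bvh.order[i] * 3 + k];
      clo[k] = std::min(clo[k], c);
      chi[k] = std::max(chi[k], c);
    }
  int axis = 0;
  double ext = chi[0] - clo[0];
  for (int k = 1; k < 3; ++k)
    if (chi[k] - clo[k] > ext) { ext = chi[k] - clo[k]; axis = k; }

  int mid = (begin + end) / 2;
  std::nth_element(bvh.order.begin() + begin, bvh.order.begin() + mid,
                   bvh.order.begin() + end, [&](int a, int b) {
                     double ca = cent[a * 3 + axis], cb = cent[b * 3 + axis];
                     if (ca != cb) return ca < cb;
                     return a < b;
                   });
  // nth_element leaves both halves unordered; sort for full determinism
  std::sort(bvh.order.begin() + begin, bvh.order.begin() + mid, [&](int a, int b) {
    double ca = cent[a * 3 + axis], cb = cent[b * 3 + axis];
    if (ca != cb) return ca < cb;
    return a < b;
  });
  std::sort(bvh.order.begin() + mid, bvh.order.begin() + end, [&](int a, int b) {
    double ca = cent[a * 3 + axis], cb = cent[b * 3 + axis];
    if (ca != cb) return ca < cb;
    return a < b;
  });
  int l = build_node(bvh, m, cent, begin, mid, leaf_size);
  int r = build_node(bvh, m, cent, mid, end, leaf_size);
  bvh.left[node] = l;
  bvh.right[node] = r;
  return node;
}

static BVH build_bvh_internal(const Mesh& m, int leaf_size) {
  BVH bvh;
  bvh.order.resize(m.nf);
  for (int i = 0; i < m.nf; ++i) bvh.order[i] = i;
  std::vector<double> cent(static_cast<size_t>(m.nf) * 3);
  V3 tv[3];
  for (int t = 0; t < m.nf; ++t) {
    m.tri(t, tv);
    cent[t * 3 + 0] = (tv[0].x + tv[1].x + tv[2].x) / 3.0;
    cent[t * 3 + 1] = (tv[0].y + tv[1].y + tv[2].y) / 3.0;
    cent[t * 3 + 2] = (tv[0].z + tv[1].z + tv[2].z) / 3.0;
  }
  build_node(bvh, m, cent, 0, m.nf, leaf_size);
  return bvh;
}

// [[Rcpp::export(name = ".cpp_build_bvh")]]
List cpp_build_bvh(NumericMatrix V, IntegerMatrix F, int leaf_size) {
  std::vector<int> fbuf;
  Mesh m = make_mesh(V, F, fbuf);
  if (m.nf < 1) stop("mesh has no faces");
  BVH bvh = build_bvh_internal(m, leaf_size);
  int K = static_cast<int>(bvh.left.size());
  NumericMatrix nmin(K, 3), nmax(K, 3);
  IntegerVector left(K), right(K), start(K), count(K);
  for (int i = 0; i < K; ++i) {
    for (int k = 0; k < 3; ++k) {
      nmin(i, k) = bvh.nmin[i * 3 + k];
      nmax(i, k) = bvh.nmax[i * 3 + k];
    }
    left[i] = bvh.left[i] < 0 ? NA_INTEGER : bvh.left[i] + 1;
    right[i] = bvh.right[i] < 0 ? NA_INTEGER : bvh.right[i] + 1;
    start[i] = bvh.start[i] < 0 ? NA_INTEGER : bvh.start[i] + 1;
    count[i] = bvh.count[i];
  }
  IntegerVector order(m.nf);
  for (int i = 0; i < m.nf; ++i) order[i] = bvh.order[i] + 1;
  return List::create(_["node_min"] = nmin, _["node_max"] = nmax,
                      _["left"] = left, _["right"] = right,
                      _["start"] = start, _["count"] = count,
                      _["order"] = order, _["leaf_size"] = leaf_size,
                      _["n_faces"] = m.nf);
}

static BVH bvh_from_list(const List& l) {
  BVH bvh;
  NumericMatrix nmin = l["node_min"], nmax = l["node_max"];
  IntegerVector left = l["left"], right = l["right"];
  IntegerVector start = l["start"], count = l["count"], order = l["order"];
  int K = nmin.nrow();
  bvh.nmin.resize(static_cast<size_t>(K) * 3);
  bvh.nmax.resize(static_cast<size_t>(K) * 3);
  bvh.left.resize(K);
  bvh.right.resize(K);
  bvh.start.resize(K);
  bvh.count.resize(K);
  for (int i = 0; i < K; ++i) {
    for (int k = 0; k < 3; ++k) {
      bvh.nmin[i * 3 + k] = nmin(i, k);
      bvh.nmax[i * 3 + k] = nmax(i, k);
    }
    bvh.left[i] = left[i] == NA_INTEGER ? -1 : left[i] - 1;
    bvh.right[i] = right[i] == NA_INTEGER ? -1 : right[i] - 1;
    bvh.start[i] = start[i] == NA_INTEGER ? -1 : start[i] - 1;
    bvh.count[i] = count[i];
  }
  bvh.order.resize(order.size());
  for (int i = 0; i < order.size(); ++i) bvh.order[i] = order[i] - 1;
  return bvh;
}

static inline bool boxes_overlap(const BVH& a, int i, const BVH& b, int j,
                                 double eps) {
  for (int k = 0; k < 3; ++k) {
    if (a.nmin[i * 3 + k] > b.nmax[j * 3 + k] + eps) return false;
    if (b.nmin[j * 3 + k] > a.nmax[i * 3 + k] + eps) return false;
  }
  return true;
}

// [[Rcpp::export(name = ".cpp_bvh_collide")]]
List cpp_bvh_collide(NumericMatrix V1, IntegerMatrix F1, List bvh1l,
                     NumericMatrix V2, IntegerMatrix F2, List bvh2l) {
  std::vector<int> f1buf, f2buf;
  Mesh m1 = make_mesh(V1, F1, f1buf);
  Mesh m2 = make_mesh(V2, F2, f2buf);
  BVH b1 = bvh_from_list(bvh1l);
  BVH b2 = bvh_from_list(bvh2l);
  double eps = REL_EPS * mesh_scale(m1, m2);

  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, 0));
  V3 ta[3], tb[3];
  while (!stack.empty()) {
    std::pair<int, int> top = stack.back();
    stack.pop_back();
    int i = top.first, j = top.second;
    if (!boxes_overlap(b1, i, b2, j, eps)) continue;
    bool leaf1 = b1.left[i] < 0, leaf2 = b2.left[j] < 0;
    if (leaf1 && leaf2) {
      for (int p = 0; p < b1.count[i]; ++p) {
        int t1 = b1.order[b1.start[i] + p];
        m1.tri(t1, ta);
        for (int q = 0; q < b2.count[j]; ++q) {
          int t2 = b2.order[b2.start[j] + q];
          m2.tri(t2, tb);
          if (tri_tri_intersect(ta, tb))
            return List::create(_["colliding"] = true, _["tri1"] = t1 + 1,
                                _["tri2"] = t2 + 1);
        }
      }
    } else if (leaf2 || (!leaf1 && (b1.nmax[i * 3] - b1.nmin[i * 3] +
                                    b1.nmax[i * 3 + 1] - b1.nmin[i * 3 + 1] +
                                    b1.nmax[i * 3 + 2] - b1.nmin[i * 3 + 2]) >=
                                       (b2.nmax[j * 3] - b2.nmin[j * 3] +
                                        b2.nmax[j * 3 + 1] - b2.nmin[j * 3 + 1] +
                                        b2.nmax[j * 3 + 2] - b2.nmin[j * 3 + 2]))) {
      stack.push_back(std::make_pair(b1.right[i], j));
      stack.push_back(std::make_pair(b1.left[i], j));
    } else {
      stack.push_back(std::make_pair(i, b2.right[j]));
      stack.push_back(std::make_pair(i, b2.left[j]));
    }
  }
  return List::create(_["colliding"] = false, _["tri1"] = NA_INTEGER,
                      _["tri2"] = NA_INTEGER);
}

// [[Rcpp::export(name = ".cpp_brute_collide")]]
List cpp_brute_collide(NumericMatrix V1, IntegerMatrix F1, NumericMatrix V2,
                       IntegerMatrix F2) {
  std::vector<int> f1buf, f2buf;
  Mesh m1 = make_mesh(V1, F1, f1buf);
  Mesh m2 = make_mesh(V2, F2, f2buf);
  V3 ta[3], tb[3];
  for (int i = 0; i < m1.nf; ++i) {
    m1.tri(i, ta);
    for (int j = 0; j < m2.nf; ++j) {
      m2.tri(j, tb);
      if (tri_tri_intersect(ta, tb))
        return List::create(_["colliding"] = true, _["tri1"] = i + 1,
                            _["tri2"] = j + 1);
    }
  }
  return List::create(_["colliding"] = false, _["tri1"] = NA_INTEGER,
                      _["tri2"] = NA_INTEGER);
}
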