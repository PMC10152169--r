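// Quadric-error-metric edge contraction and point-to-triangle projection.
// Contractions collapse an edge onto one of its endpoints (subset selection),
// so the down-transform of a hierarchy level is a pure row-selector matrix.
#include <Rcpp.h>
#include <queue>
#include <set>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

// Symmetric 4x4 quadric stored as 10 coefficients:
// [a2 ab ac ad b2 bc bd c2 cd d2] for plane (a,b,c,d).
struct Quadric {
  double q[10];
  Quadric() { for (int i = 0; i < 10; ++i) q[i] = 0.0; }
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w * a * a; q[1] += w * a * b; q[2] += w * a * c; q[3] += w * a * d;
    q[4] += w * b * b; q[5] += w * b * c; q[6] += w * b * d;
    q[7] += w * c * c; q[8] += w * c * d; q[9] += w * d * d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  // v^T Q v for v = (x, y, z, 1)
  double eval(double x, double y, double z) const {
    return q[0] * x * x + 2 * q[1] * x * y + 2 * q[2] * x * z + 2 * q[3] * x
         + q[4] * y * y + 2 * q[5] * y * z + 2 * q[6] * y
         + q[7] * z * z + 2 * q[8] * z
         + q[9];
  }
};

struct HeapEntry {
  double cost;
  int a, b;           // a < b
  long stamp_a, stamp_b;
  bool operator>(const HeapEntry& o) const {
    if (cost != o.cost) return cost > o.cost;
    if (a != o.a) return a > o.a;
    return b > o.b;
  }
};

struct EdgeKey {
  int a, b;
  bool operator<(const EdgeKey& o) const {
    if (a != o.a) return a < o.a;
    return b < o.b;
  }
};

} // namespace

// [[Rcpp::export(name = ".qem_decimate_cpp")]]
List qem_decimate_cpp(NumericMatrix vertices, IntegerMatrix faces, int target,
                      double boundary_weight) {
  const int V = vertices.nrow();
  const int F = faces.nrow();
  if (target < 4 || target >= V)
    stop("target vertex count must be in [4, V)");

  std::vector<double> px(V), py(V), pz(V);
  for (int i = 0; i < V; ++i) {
    px[i] = vertices(i, 0); py[i] = vertices(i, 1); pz[i] = vertices(i, 2);
  }

  // Per-vertex quadrics from incident face planes.
  std::vector<Quadric> Q(V);
  // Count face multiplicity of each undirected edge for boundary detection.
  std::map<EdgeKey, int> edge_faces;
  std::map<EdgeKey, std::pair<int, int> > edge_one_face; // edge -> (face idx, opposite vertex)

  for (int f = 0; f < F; ++f) {
    int i = faces(f, 0) - 1, j = faces(f, 1) - 1, k = faces(f, 2) - 1;
    double ux = px[j] - px[i], uy = py[j] - py[i], uz = pz[j] - pz[i];
    double vx = px[k] - px[i], vy = py[k] - py[i], vz = pz[k] - pz[i];
    double nx = uy * vz - uz * vy;
    double ny = uz * vx - ux * vz;
    double nz = ux * vy - uy * vx;
    double nn = std::sqrt(nx * nx + ny * ny + nz * nz);
    if (nn > 1e-300) {
      nx /= nn; ny /= nn; nz /= nn;
      double d = -(nx * px[i] + ny * py[i] + nz * pz[i]);
      // Area-weighted plane quadric (Garland-Heckbert with area weights).
      double w = 0.5 * nn;
      Q[i].add_plane(nx, ny, nz, d, w);
      Q[j].add_plane(nx, ny, nz, d, w);
      Q[k].add_plane(nx, ny, nz, d, w);
    }
    int vs[3] = {i, j, k};
    for (int e = 0; e < 3; ++e) {
      int a = vs[e], b = vs[(e + 1) % 3];
      EdgeKey key = {std::min(a, b), std::max(a, b)};
      edge_faces[key] += 1;
      edge_one_face[key] = std::make_pair(f, vs[(e + 2) % 3]);
    }
  }

  // Boundary penalty: a plane through the boundary edge, perpendicular to
  // its single incident face, keeps the open rim in place.
  for (std::map<EdgeKey, int>::iterator it = edge_faces.begin();
       it != edge_faces.end(); ++it) {
    if (it->second != 1) continue;
    int a = it->first.a, b = it->first.b;
    int opp = edge_one_face[it->first].second;
    double ex = px[b] - px[a], ey = py[b] - py[a], ez = pz[b] - pz[a];
    // face normal
    double wx = px[opp] - px[a], wy = py[opp] - py[a], wz = pz[opp] - pz[a];
    double fnx = ey * wz - ez * wy, fny = ez * wx - ex * wz, fnz = ex * wy - ey * wx;
    // constraint plane normal = edge x face-normal
    double cx = ey * fnz - ez * fny, cy = ez * fnx - ex * fnz, cz = ex * fny - ey * fnx;
    double cn = std::sqrt(cx * cx + cy * cy + cz * cz);
    if (cn < 1e-300) continue;
    cx /= cn; cy /= cn; cz /= cn;
    double d = -(cx * px[a] + cy * py[a] + cz * pz[a]);
    double elen2 = ex * ex + ey * ey + ez * ez;
    Q[a].add_plane(cx, cy, cz, d, boundary_weight * elen2);
    Q[b].add_plane(cx, cy, cz, d, boundary_weight * elen2);
  }

  // Adjacency sets.
  std::vector<std::set<int> > adj(V);
  for (std::map<EdgeKey, int>::iterator it = edge_faces.begin();
       it != edge_faces.end(); ++it) {
    adj[it->first.a].insert(it->first.b);
    adj[it->first.b].insert(it->first.a);
  }

  std::vector<long> stamp(V, 0);
  std::vector<bool> alive(V, true);
  std::vector<int> collapsed_to(V);
  for (int i = 0; i < V; ++i) collapsed_to[i] = i;

  std::priority_queue<HeapEntry, std::vector<HeapEntry>, std::greater<HeapEntry> > heap;

  // Cost of contracting (a,b): keep the endpoint with the smaller combined
  // error; ties keep the lower vertex index.
  // push entry for edge (a<b)
  // returns nothing
  struct Pusher {
    std::vector<Quadric>* Q;
    std::vector<double> *px, *py, *pz;
    std::vector<long>* stamp;
    std::priority_queue<HeapEntry, std::vector<HeapEntry>, std::greater<HeapEntry> >* heap;
    void push(int a, int b) {
      if (a > b) std::swap(a, b);
      Quadric s = (*Q)[a];
      s.add((*Q)[b]);
      double ca = s.eval((*px)[a], (*py)[a], (*pz)[a]);
      double cb = s.eval((*px)[b], (*py)[b], (*pz)[b]);
      HeapEntry e;
      e.cost = std::min(ca, cb);
      e.a = a; e.b = b;
      e.stamp_a = (*stamp)[a]; e.stamp_b = (*stamp)[b];
      heap->push(e);
    }
  } pusher;
  pusher.Q = &Q; pusher.px = &px; pusher.py = &py; pusher.pz = &pz;
  pusher.stamp = &stamp; pusher.heap = &heap;

  for (std::map<EdgeKey, int>::iterator it = edge_faces.begin();
       it != edge_faces.end(); ++it)
    pusher.push(it->first.a, it->first.b);

  int n_alive = V;
  while (n_alive > target) {
    if (heap.empty())
      stop("decimation ran out of contractible edges before reaching target");
    HeapEntry e = heap.top();
    heap.pop();
    int a = e.a, b = e.b;
    if (!alive[a] || !alive[b]) continue;
    if (stamp[a] != e.stamp_a || stamp[b] != e.stamp_b) continue;
    if (adj[a].find(b) == adj[a].end()) continue;

    // choose kept endpoint
    Quadric s = Q[a];
    s.add(Q[b]);
    double ca = s.eval(px[a], py[a], pz[a]);
    double cb = s.eval(px[b], py[b], pz[b]);
    int keep, drop;
    if (ca < cb) { keep = a; drop = b; }
    else if (cb < ca) { keep = b; drop = a; }
    else { keep = std::min(a, b); drop = std::max(a, b); }

    // contract drop into keep
    Q[keep] = s;
    alive[drop] = false;
    collapsed_to[drop] = keep;
    adj[keep].erase(drop);
    for (std::set<int>::iterator nb = adj[drop].begin(); nb != adj[drop].end(); ++nb) {
      int n = *nb;
      if (n == keep) continue;
      adj[n].erase(drop);
      adj[n].insert(keep);
      adj[keep].insert(n);
    }
    adj[drop].clear();
    stamp[keep] += 1;
    stamp[drop] += 1;
    --n_alive;

    for (std::set<int>::iterator nb = adj[keep].begin(); nb != adj[keep].end(); ++nb)
      pusher.push(keep, *nb);
  }

  // Resolve collapse chains.
  std::vector<int> root(V);
  for (int i = 0; i < V; ++i) {
    int r = i;
    while (collapsed_to[r] != r) r = collapsed_to[r];
    root[i] = r;
  }

  // Kept vertices in original-index order.
  std::vector<int> kept;
  std::vector<int> slot(V, -1);
  for (int i = 0; i < V; ++i) {
    if (alive[i]) { slot[i] = (int)kept.size(); kept.push_back(i); }
  }

  // Remap faces; drop degenerate and duplicate ones (keep first occurrence).
  std::set<std::vector<int> > seen;
  std::vector<int> fa, fb, fc;
  for (int f = 0; f < F; ++f) {
    int i = slot[root[faces(f, 0) - 1]];
    int j = slot[root[faces(f, 1) - 1]];
    int k = slot[root[faces(f, 2) - 1]];
    if (i == j || j == k || i == k) continue;
    std::vector<int> key;
    key.push_back(i); key.push_back(j); key.push_back(k);
    std::sort(key.begin(), key.end());
    if (!seen.insert(key).second) continue;
    fa.push_back(i + 1); fb.push_back(j + 1); fc.push_back(k + 1);
  }
  if (fa.empty())
    stop("decimation destroyed all faces");

  NumericMatrix out_v((int)kept.size(), 3);
  IntegerVector kept_r((int)kept.size());
  for (size_t i = 0; i < kept.size(); ++i) {
    out_v(i, 0) = px[kept[i]];
    out_v(i, 1) = py[kept[i]];
    out_v(i, 2) = pz[kept[i]];
    kept_r[i] = kept[i] + 1;
  }
  IntegerMatrix out_f((int)fa.size(), 3);
  for (size_t f = 0; f < fa.size(); ++f) {
    out_f(f, 0) = fa[f]; out_f(f, 1) = fb[f]; out_f(f, 2) = fc[f];
  }
  IntegerVector map_r(V);
  for (int i = 0; i < V; ++i) map_r[i] = slot[root[i]] + 1;

  return List::create(_["vertices"] = out_v, _["faces"] = out_f,
                      _["kept"] = kept_r, _["vertex_map"] = map_r);
}

// For each query point: nearest triangle (by true closest-point distance)
// and barycentric coordinates of the orthogonal projection onto that
// triangle's plane (may fall outside the triangle; weights sum to 1).
// [[Rcpp::export(name = ".nearest_barycentric_cpp")]]
List nearest_barycentric_cpp(NumericMatrix points, NumericMatrix vertices,
                             IntegerMatrix faces) {
  const int P = points.nrow(), F = faces.nrow();
  IntegerVector face_id(P);
  NumericMatrix bary(P, 3);

  for (int p = 0; p < P; ++p) {
    double qx = points(p, 0), qy = points(p, 1), qz = points(p, 2);
    double best = std::numeric_limits<double>::infinity();
    int best_f = -1;
    double best_s = 0, best_t = 0;
    for (int f = 0; f < F; ++f) {
      int i = faces(f, 0) - 1, j = faces(f, 1) - 1, k = faces(f, 2) - 1;
      double ax = vertices(i, 0), ay = vertices(i, 1), az = vertices(i, 2);
      double abx = vertices(j, 0) - ax, aby = vertices(j, 1) - ay, abz = vertices(j, 2) - az;
      double acx = vertices(k, 0) - ax, acy = vertices(k, 1) - ay, acz = vertices(k, 2) - az;
      double apx = qx - ax, apy = qy - ay, apz = qz - az;
      double d1 = abx * apx + aby * apy + abz * apz;
      double d2 = acx * apx + acy * apy + acz * apz;
      double a11 = abx * abx + aby * aby + abz * abz;
      double a12 = abx * acx + aby * acy + abz * acz;
      double a22 = acx * acx + acy * acy + acz * acz;
      double det = a11 * a22 - a12 * a12;
      if (det < 1e-300) continue;
      // unclamped plane-projection barycentric coordinates
      double s = (a22 * d1 - a12 * d2) / det;
      double t = (a11 * d2 - a12 * d1) / det;
      // clamped coordinates for the true closest point on the triangle
      double cs = s, ct = t;
      if (cs < 0) cs = 0;
      if (ct < 0) ct = 0;
      if (cs + ct > 1) {
        double sum = cs + ct;
        cs /= sum; ct /= sum;
        // project onto edge bc properly: clamp along the edge
        double ex = acx - abx, ey = acy - aby, ez = acz - abz;
        double bx = ax + abx, by = ay + aby, bz = az + abz;
        double bpx = qx - bx, bpy = qy - by, bpz = qz - bz;
        double ee = ex * ex + ey * ey + ez * ez;
        double u = ee > 0 ? (ex * bpx + ey * bpy + ez * bpz) / ee : 0.0;
        if (u < 0) u = 0;
        if (u > 1) u = 1;
        cs = 1 - u; ct = u;
      }
      double cx = ax + cs * abx + ct * acx - qx;
      double cy = ay + cs * aby + ct * acy - qy;
      double cz = az + cs * abz + ct * acz - qz;
      double d = cx * cx + cy * cy + cz * cz;
      if (d < best) {
        best = d; best_f = f; best_s = s; best_t = t;
      }
    }
    face_id[p] = best_f + 1;
    bary(p, 0) = 1.0 - best_s - best_t;
    bary(p, 1) = best_s;
    bary(p, 2) = best_t;
  }
  return List::create(_["face"] = face_id, _["bary"] = bary);
}
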