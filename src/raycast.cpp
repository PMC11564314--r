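#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Watertight triangle-soup ray casting. Meshes may hold several closed
// components (constructive solid union); faces carry a component id and the
// solid is the union of component interiors. All lengths in millimetres.

namespace {

struct Hit {
  double t;
  int comp;       // component id (1-based)
  bool enter;     // ray passes from outside to inside this component
  int face;       // 0-based face index
};

struct MeshRef {
  const double *vx, *vy, *vz;
  const int *f0, *f1, *f2, *comp;
  int nface;
};

// Moller-Trumbore with slightly inclusive barycentric bounds so that hits on
// shared edges register on both incident triangles (deduplicated later:
// symbolic-perturbation "count once" rule).
inline bool ray_tri(const MeshRef &m, int f,
                    const double o[3], const double d[3],
                    double tmin, double &t, bool &enter) {
  const int ia = m.f0[f], ib = m.f1[f], ic = m.f2[f];
  const double ax = m.vx[ia], ay = m.vy[ia], az = m.vz[ia];
  const double e1x = m.vx[ib] - ax, e1y = m.vy[ib] - ay, e1z = m.vz[ib] - az;
  const double e2x = m.vx[ic] - ax, e2y = m.vy[ic] - ay, e2z = m.vz[ic] - az;
  // p = d x e2
  const double px = d[1] * e2z - d[2] * e2y;
  const double py = d[2] * e2x - d[0] * e2z;
  const double pz = d[0] * e2y - d[1] * e2x;
  const double det = e1x * px + e1y * py + e1z * pz;
  if (std::fabs(det) < 1e-14) return false;  // parallel / degenerate
  const double inv = 1.0 / det;
  const double sx = o[0] - ax, sy = o[1] - ay, sz = o[2] - az;
  const double u = (sx * px + sy * py + sz * pz) * inv;
  const double beps = 1e-10;
  if (u < -beps || u > 1.0 + beps) return false;
  // q = s x e1
  const double qx = sy * e1z - sz * e1y;
  const double qy = sz * e1x - sx * e1z;
  const double qz = sx * e1y - sy * e1x;
  const double v = (d[0] * qx + d[1] * qy + d[2] * qz) * inv;
  if (v < -beps || u + v > 1.0 + beps) return false;
  t = (e2x * qx + e2y * qy + e2z * qz) * inv;
  if (t <= tmin) return false;
  // outward normal n = e1 x e2; entering iff d . n < 0.
  // det = e1 . (d x e2) = -d . (e1 x e2), so entering iff det > 0.
  enter = det > 0.0;
  return true;
}

void collect_hits(const MeshRef &m, const double o[3], const double d[3],
                  double tmin, double tmax, std::vector<Hit> &hits) {
  hits.clear();
  double t;
  bool enter;
  for (int f = 0; f < m.nface; ++f) {
    if (ray_tri(m, f, o, d, tmin, t, enter) && t <= tmax) {
      hits.push_back(Hit{t, m.comp ? m.comp[f] : 1, enter, f});
    }
  }
  std::sort(hits.begin(), hits.end(),
            [](const Hit &a, const Hit &b) { return a.t < b.t; });
  // deduplicate grazing hits: same component, same crossing sense, same t
  std::vector<Hit> out;
  out.reserve(hits.size());
  for (const Hit &h : hits) {
    bool dup = false;
    for (size_t k = out.size(); k-- > 0;) {
      if (h.t - out[k].t > 1e-9) break;
      if (out[k].comp == h.comp && out[k].enter == h.enter) {
        dup = true;
        break;
      }
    }
    if (!dup) out.push_back(h);
  }
  hits.swap(out);
}

MeshRef make_ref(const NumericMatrix &V, const IntegerMatrix &F,
                 const IntegerVector &comp) {
  MeshRef m;
  m.vx = &V(0, 0);
  m.vy = &V(0, 1);
  m.vz = &V(0, 2);
  m.f0 = &F(0, 0);
  m.f1 = &F(0, 1);
  m.f2 = &F(0, 2);
  m.comp = comp.size() ? &comp[0] : nullptr;
  m.nface = F.nrow();
  return m;
}

// Merge per-component inside intervals into union intervals along the ray.
// `inside0` per component is inferred from the first event's sense.
void union_intervals(const std::vector<Hit> &hits, int ncomp, double tmax,
                     std::vector<std::pair<double, double> > &iv) {
  iv.clear();
  std::vector<int> state(ncomp + 1, -1);  // -1 unknown, 0 out, 1 in
  for (const Hit &h : hits)
    if (state[h.comp] == -1) state[h.comp] = h.enter ? 0 : 1;
  int inside = 0;
  for (int c = 1; c <= ncomp; ++c)
    if (state[c] == 1) ++inside;
  double start = 0.0;
  bool open = inside > 0;
  for (const Hit &h : hits) {
    int before = inside;
    if (h.enter) {
      if (state[h.comp] == 0) { state[h.comp] = 1; ++inside; }
    } else {
      if (state[h.comp] == 1) { state[h.comp] = 0; --inside; }
    }
    if (before == 0 && inside > 0) {
      start = h.t;
      open = true;
    } else if (before > 0 && inside == 0 && open) {
      iv.push_back(std::make_pair(start, h.t));
      open = false;
    }
  }
  if (open) iv.push_back(std::make_pair(start, tmax));
}

}  // namespace

// [[Rcpp::export]]
DataFrame cpp_ray_hits(NumericMatrix V, IntegerMatrix F, IntegerVector comp,
                       NumericVector origin, NumericVector dir) {
  MeshRef m = make_ref(V, F, comp);
  double o[3] = {origin[0], origin[1], origin[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  std::vector<Hit> hits;
  collect_hits(m, o, d, 1e-9, R_PosInf, hits);
  int n = (int)hits.size();
  NumericVector t(n), px(n), py(n), pz(n);
  LogicalVector enter(n);
  IntegerVector cp(n), face(n);
  for (int i = 0; i < n; ++i) {
    t[i] = hits[i].t;
    px[i] = o[0] + d[0] * hits[i].t;
    py[i] = o[1] + d[1] * hits[i].t;
    pz[i] = o[2] + d[2] * hits[i].t;
    enter[i] = hits[i].enter;
    cp[i] = hits[i].comp;
    face[i] = hits[i].face + 1;
  }
  return DataFrame::create(_["distance"] = t, _["x"] = px, _["y"] = py,
                           _["z"] = pz, _["entering"] = enter,
                           _["component"] = cp, _["face"] = face);
}

// Bi-cortical length for a batch of rays sharing one mesh. Origins are pushed
// `eps_push` along the ray so origins lying exactly on a surface classify as
// inside; the push is added back to the reported length. The screw terminates
// at the far end of the corridor reachable from the first bone entry without
// crossing a void wider than `void_bridge`.
// Returns a matrix: length, exit x/y/z, valid, entry distance.
// [[Rcpp::export]]
NumericMatrix cpp_bicortical_batch(NumericMatrix V, IntegerMatrix F,
                                   IntegerVector comp, NumericMatrix origins,
                                   NumericMatrix dirs, double max_length,
                                   double void_bridge, double eps_push) {
  MeshRef m = make_ref(V, F, comp);
  int ncomp = 1;
  for (int i = 0; i < comp.size(); ++i)
    if (comp[i] > ncomp) ncomp = comp[i];
  const int n = origins.nrow();
  NumericMatrix out(n, 6);
  std::vector<Hit> hits;
  std::vector<std::pair<double, double> > iv;
  for (int i = 0; i < n; ++i) {
    double o[3] = {origins(i, 0) + eps_push * dirs(i, 0),
                   origins(i, 1) + eps_push * dirs(i, 1),
                   origins(i, 2) + eps_push * dirs(i, 2)};
    double d[3] = {dirs(i, 0), dirs(i, 1), dirs(i, 2)};
    collect_hits(m, o, d, 1e-9, max_length, hits);
    union_intervals(hits, ncomp, max_length, iv);
    out(i, 4) = 0.0;
    if (iv.empty()) continue;
    // chain merged intervals across voids no wider than void_bridge
    double entry = iv[0].first;
    double end = iv[0].second;
    for (size_t k = 1; k < iv.size(); ++k) {
      if (iv[k].first - end <= void_bridge + 1e-12)
        end = iv[k].second;
      else
        break;
    }
    if (entry >= max_length) continue;
    double len = end + eps_push;  // from the original origin
    out(i, 0) = len;
    out(i, 1) = origins(i, 0) + dirs(i, 0) * len;
    out(i, 2) = origins(i, 1) + dirs(i, 1) * len;
    out(i, 3) = origins(i, 2) + dirs(i, 2) * len;
    out(i, 4) = 1.0;
    out(i, 5) = entry + eps_push;
  }
  return out;
}

// Minimal distance from each query point to the mesh surface (brute force
// point-triangle distance; used for landmark validation on small meshes).
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix V, IntegerMatrix F,
                                      NumericMatrix P) {
  const int n = P.nrow(), nf = F.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double p[3] = {P(i, 0), P(i, 1), P(i, 2)};
    for (int f = 0; f < nf; ++f) {
      const int ia = F(f, 0), ib = F(f, 1), ic = F(f, 2);
      double a[3] = {V(ia, 0), V(ia, 1), V(ia, 2)};
      double ab[3] = {V(ib, 0) - a[0], V(ib, 1) - a[1], V(ib, 2) - a[2]};
      double ac[3] = {V(ic, 0) - a[0], V(ic, 1) - a[1], V(ic, 2) - a[2]};
      double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
      // project into triangle plane via barycentric clamp (Ericson)
      double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
      double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
      double daa = ab[0] * ab[0] + ab[1] * ab[1] + ab[2] * ab[2];
      double dac = ab[0] * ac[0] + ab[1] * ac[1] + ab[2] * ac[2];
      double dcc = ac[0] * ac[0] + ac[1] * ac[1] + ac[2] * ac[2];
      double u, v;
      double det = daa * dcc - dac * dac;
      if (det > 1e-20) {
        u = (dcc * d1 - dac * d2) / det;
        v = (daa * d2 - dac * d1) / det;
      } else {
        u = v = -1.0;
      }
      double qx, qy, qz;
      if (u >= 0 && v >= 0 && u + v <= 1) {
        qx = a[0] + u * ab[0] + v * ac[0];
        qy = a[1] + u * ab[1] + v * ac[1];
        qz = a[2] + u * ab[2] + v * ac[2];
        double dx = p[0] - qx, dy = p[1] - qy, dz = p[2] - qz;
        double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (dd < best) best = dd;
      } else {
        // closest point on one of the three edges
        const double *e0[3] = {a, a, nullptr};
        double b3[3] = {a[0] + ab[0], a[1] + ab[1], a[2] + ab[2]};
        double c3[3] = {a[0] + ac[0], a[1] + ac[1], a[2] + ac[2]};
        const double *segs[3][2] = {{a, b3}, {a, c3}, {b3, c3}};
        (void)e0;
        for (int s = 0; s < 3; ++s) {
          const double *p0 = segs[s][0], *p1 = segs[s][1];
          double ex = p1[0] - p0[0], ey = p1[1] - p0[1], ez = p1[2] - p0[2];
          double wx = p[0] - p0[0], wy = p[1] - p0[1], wz = p[2] - p0[2];
          double ee = ex * ex + ey * ey + ez * ez;
          double tt = ee > 0 ? (wx * ex + wy * ey + wz * ez) / ee : 0.0;
          tt = std::max(0.0, std::min(1.0, tt));
          double dx = wx - tt * ex, dy = wy - tt * ey, dz = wz - tt * ez;
          double dd = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (dd < best) best = dd;
        }
      }
    }
    out[i] = best;
  }
  return out;
}
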