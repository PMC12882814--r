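#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cmath>

using namespace Rcpp;

// Bowyer-Watson Delaunay triangulation with ghost triangles.
//
// Instead of a finite super-triangle (which distorts the triangulation near
// the hull whenever a valid circumcircle is large enough to swallow the
// super vertices), the convex hull is closed by "ghost" triangles sharing a
// symbolic vertex at infinity (index -1). A ghost's limiting circumcircle
// is the closed half-plane outside its hull edge, so the in-circle
// predicate for ghosts is an orientation test on real coordinates only --
// no large synthetic coordinates ever enter the arithmetic.
//
// Points are assumed de-duplicated and not all collinear (the R wrapper
// handles those cases); near-cocircular quadruples are resolved by the sign
// of the incircle determinant, yielding an arbitrary valid member of the
// Delaunay family.

namespace {

struct Tri {
  int a, b, c;   // cyclic order, CCW; -1 marks the vertex at infinity
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 when d lies strictly inside the circumcircle of CCW triangle (a,b,c)
inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double dx, double dy) {
  const double adx = ax - dx, ady = ay - dy;
  const double bdx = bx - dx, bdy = by - dy;
  const double cdx = cx - dx, cdy = cy - dy;
  const double ad2 = adx * adx + ady * ady;
  const double bd2 = bdx * bdx + bdy * bdy;
  const double cd2 = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd2 - cdy * bd2)
       - ady * (bdx * cd2 - cdx * bd2)
       + ad2 * (bdx * cdy - cdx * bdy);
}

} // namespace

// [[Rcpp::export(name = ".delaunay_triangles")]]
IntegerMatrix delaunay_triangles(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points");
  const double* px = x.begin();
  const double* py = y.begin();

  // insertion order: points 0, 1, then the first point not collinear with
  // them, then everything else
  int i2 = -1;
  for (int j = 2; j < n; ++j) {
    if (orient2d(px[0], py[0], px[1], py[1], px[j], py[j]) != 0.0) {
      i2 = j;
      break;
    }
  }
  if (i2 < 0) stop("all points are collinear");
  std::vector<int> order;
  order.reserve(n);
  order.push_back(0);
  order.push_back(1);
  order.push_back(i2);
  for (int j = 2; j < n; ++j) if (j != i2) order.push_back(j);

  std::vector<Tri> tris;
  tris.reserve(6 * n);
  {
    int a = order[0], b = order[1], c = order[2];
    if (orient2d(px[a], py[a], px[b], py[b], px[c], py[c]) < 0) std::swap(b, c);
    Tri t0 = {a, b, c, true};
    tris.push_back(t0);
    // ghosts outside each directed edge: reversed real edge + infinity
    Tri g1 = {b, a, -1, true};
    Tri g2 = {c, b, -1, true};
    Tri g3 = {a, c, -1, true};
    tris.push_back(g1); tris.push_back(g2); tris.push_back(g3);
  }

  std::vector<int> bad;
  std::set< std::pair<int, int> > dir_edges;

  for (size_t oi = 3; oi < order.size(); ++oi) {
    const int p = order[oi];
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri& T = tris[t];
      bool is_bad;
      if (T.a >= 0 && T.b >= 0 && T.c >= 0) {
        is_bad = incircle(px[T.a], py[T.a], px[T.b], py[T.b],
                          px[T.c], py[T.c], px[p], py[p]) > 0.0;
      } else {
        // ghost: locate the real directed edge (u -> v) in cyclic order
        int u, v;
        if (T.c < 0)      { u = T.a; v = T.b; }
        else if (T.a < 0) { u = T.b; v = T.c; }
        else              { u = T.c; v = T.a; }
        is_bad = orient2d(px[u], py[u], px[v], py[v], px[p], py[p]) >= 0.0;
      }
      if (is_bad) bad.push_back((int)t);
    }

    // cavity boundary: directed edges whose reverse is not in the bad set
    dir_edges.clear();
    for (size_t k = 0; k < bad.size(); ++k) {
      const Tri& T = tris[bad[k]];
      dir_edges.insert(std::make_pair(T.a, T.b));
      dir_edges.insert(std::make_pair(T.b, T.c));
      dir_edges.insert(std::make_pair(T.c, T.a));
    }
    for (size_t k = 0; k < bad.size(); ++k) tris[bad[k]].alive = false;
    for (std::set< std::pair<int, int> >::const_iterator it = dir_edges.begin();
         it != dir_edges.end(); ++it) {
      if (dir_edges.count(std::make_pair(it->second, it->first))) continue;
      Tri nt = {it->first, it->second, p, true};
      tris.push_back(nt);
    }
  }

  int m = 0;
  for (size_t t = 0; t < tris.size(); ++t)
    if (tris[t].alive && tris[t].a >= 0 && tris[t].b >= 0 && tris[t].c >= 0)
      ++m;
  IntegerMatrix out(m, 3);
  int r = 0;
  for (size_t t = 0; t < tris.size(); ++t) {
    const Tri& T = tris[t];
    if (!T.alive || T.a < 0 || T.b < 0 || T.c < 0) continue;
    out(r, 0) = T.a + 1; out(r, 1) = T.b + 1; out(r, 2) = T.c + 1;
    ++r;
  }
  return out;
}
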