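// Bowyer-Watson Delaunay triangulation of a planar point set.
//
// Used by the 2D mesh generators: points are boundary polyline vertices
// plus interior lattice points; triangles whose centroid falls outside the
// domain polygon are discarded afterwards (R side), which handles the
// non-convex shapes (dumbbell, star) at adequate boundary resolution.
// Plain O(n * T) cavity search: meshes here are a few thousand points.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <array>

using namespace Rcpp;

namespace {

struct Tri { int a, b, c; bool alive; };

// > 0 if d strictly inside circumcircle of (a, b, c) given CCW orientation
inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double dx, double dy) {
  const double adx = ax - dx, ady = ay - dy;
  const double bdx = bx - dx, bdy = by - dy;
  const double cdx = cx - dx, cdy = cy - dy;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy)
       - ady * (bdx * cd - bd * cdx)
       + ad  * (bdx * cdy - bdy * cdx);
}

inline double orient(double ax, double ay, double bx, double by,
                     double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

} // namespace

//' @name delaunay_cpp
//' @title Delaunay triangulation (Bowyer-Watson, internal)
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix delaunay_cpp(NumericVector px, NumericVector py) {
  const int n = px.size();
  if (n < 3) stop("need at least 3 points");

  std::vector<double> x(px.begin(), px.end()), y(py.begin(), py.end());

  // super-triangle enclosing everything
  double xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 1; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double dmax = std::max(xmax - xmin, ymax - ymin) * 10.0 + 1.0;
  const double cx = (xmin + xmax) / 2.0, cy = (ymin + ymax) / 2.0;
  x.push_back(cx - 2.0 * dmax); y.push_back(cy - dmax);
  x.push_back(cx + 2.0 * dmax); y.push_back(cy - dmax);
  x.push_back(cx);              y.push_back(cy + 2.0 * dmax);

  std::vector<Tri> tris;
  tris.push_back({n, n + 1, n + 2, true});

  std::vector<int> bad;
  std::vector<std::array<int, 2>> edges;

  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (size_t t = 0; t < tris.size(); ++t) {
      if (!tris[t].alive) continue;
      const Tri& T = tris[t];
      // ensure CCW when testing
      double o = orient(x[T.a], y[T.a], x[T.b], y[T.b], x[T.c], y[T.c]);
      double ic = (o >= 0)
        ? incircle(x[T.a], y[T.a], x[T.b], y[T.b], x[T.c], y[T.c], x[p], y[p])
        : incircle(x[T.a], y[T.a], x[T.c], y[T.c], x[T.b], y[T.b], x[p], y[p]);
      if (ic > 0) bad.push_back((int)t);
    }
    if (bad.empty()) continue;  // duplicate / degenerate point: skip

    // cavity boundary: edges of bad triangles appearing exactly once
    edges.clear();
    for (int t : bad) {
      const Tri& T = tris[t];
      const int e[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
      for (int k = 0; k < 3; ++k) {
        bool shared = false;
        for (size_t j = 0; j < edges.size(); ++j) {
          if ((edges[j][0] == e[k][1] && edges[j][1] == e[k][0]) ||
              (edges[j][0] == e[k][0] && edges[j][1] == e[k][1])) {
            edges.erase(edges.begin() + j);
            shared = true;
            break;
          }
        }
        if (!shared) edges.push_back({e[k][0], e[k][1]});
      }
    }
    for (int t : bad) tris[t].alive = false;
    for (const auto& e : edges) {
      // orient new triangle CCW
      if (orient(x[e[0]], y[e[0]], x[e[1]], y[e[1]], x[p], y[p]) > 0)
        tris.push_back({e[0], e[1], p, true});
      else
        tris.push_back({e[1], e[0], p, true});
    }
  }

  std::vector<std::array<int, 3>> out;
  for (const Tri& T : tris) {
    if (!T.alive) continue;
    if (T.a >= n || T.b >= n || T.c >= n) continue;  // touches super-tri
    out.push_back({T.a, T.b, T.c});
  }
  IntegerMatrix res(out.size(), 3);
  for (size_t i = 0; i < out.size(); ++i) {
    res(i, 0) = out[i][0] + 1;
    res(i, 1) = out[i][1] + 1;
    res(i, 2) = out[i][2] + 1;
  }
  return res;
}
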