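#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each query point to a polyline.
// verts is an n x 2 matrix of polyline vertices; when closed, the edge
// from the last vertex back to the first is included.
// [[Rcpp::export(name = ".cpp_dist_to_polyline")]]
NumericVector cpp_dist_to_polyline(NumericMatrix pts, NumericMatrix verts,
                                   bool closed) {
  const int np = pts.nrow();
  const int nv = verts.nrow();
  const int ne = closed ? nv : nv - 1;
  NumericVector out(np);

  std::vector<double> ax(ne), ay(ne), dx(ne), dy(ne), len2(ne);
  for (int e = 0; e < ne; ++e) {
    int j = (e + 1) % nv;
    ax[e] = verts(e, 0);
    ay[e] = verts(e, 1);
    dx[e] = verts(j, 0) - ax[e];
    dy[e] = verts(j, 1) - ay[e];
    len2[e] = dx[e] * dx[e] + dy[e] * dy[e];
  }

  for (int i = 0; i < np; ++i) {
    const double px = pts(i, 0), py = pts(i, 1);
    double best = R_PosInf;
    for (int e = 0; e < ne; ++e) {
      double t = 0.0;
      if (len2[e] > 0.0) {
        t = ((px - ax[e]) * dx[e] + (py - ay[e]) * dy[e]) / len2[e];
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double qx = ax[e] + t * dx[e] - px;
      const double qy = ay[e] + t * dy[e] - py;
      const double d2 = qx * qx + qy * qy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Nearest point on a polyline for each query point (same edge handling).
// Returns an np x 2 matrix of foot points.
// [[Rcpp::export(name = ".cpp_nearest_on_polyline")]]
NumericMatrix cpp_nearest_on_polyline(NumericMatrix pts, NumericMatrix verts,
                                      bool closed) {
  const int np = pts.nrow();
  const int nv = verts.nrow();
  const int ne = closed ? nv : nv - 1;
  NumericMatrix out(np, 2);

  for (int i = 0; i < np; ++i) {
    const double px = pts(i, 0), py = pts(i, 1);
    double best = R_PosInf, bx = verts(0, 0), by = verts(0, 1);
    for (int e = 0; e < ne; ++e) {
      int j = (e + 1) % nv;
      const double axe = verts(e, 0), aye = verts(e, 1);
      const double dxe = verts(j, 0) - axe, dye = verts(j, 1) - aye;
      const double l2 = dxe * dxe + dye * dye;
      double t = 0.0;
      if (l2 > 0.0) {
        t = ((px - axe) * dxe + (py - aye) * dye) / l2;
        if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      }
      const double qx = axe + t * dxe, qy = aye + t * dye;
      const double d2 = (qx - px) * (qx - px) + (qy - py) * (qy - py);
      if (d2 < best) { best = d2; bx = qx; by = qy; }
    }
    out(i, 0) = bx;
    out(i, 1) = by;
  }
  return out;
}

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static inline bool on_segment(double ax, double ay, double bx, double by,
                              double px, double py) {
  return std::min(ax, bx) <= px && px <= std::max(ax, bx) &&
         std::min(ay, by) <= py && py <= std::max(ay, by);
}

// Simple-polygon test: no two non-adjacent edges of the closed polygon
// described by verts may intersect.  Shared endpoints of adjacent edges
// are allowed.
// [[Rcpp::export(name = ".cpp_polygon_is_simple")]]
bool cpp_polygon_is_simple(NumericMatrix verts) {
  const int n = verts.nrow();
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    const double ax = verts(i, 0), ay = verts(i, 1);
    const double bx = verts(i2, 0), by = verts(i2, 1);
    for (int j = i + 1; j < n; ++j) {
      const int j2 = (j + 1) % n;
      // skip adjacent edges (they share a vertex)
      if (j == i || j2 == i || j == i2) continue;
      const double cx = verts(j, 0), cy = verts(j, 1);
      const double dx2 = verts(j2, 0), dy2 = verts(j2, 1);
      const double o1 = orient(ax, ay, bx, by, cx, cy);
      const double o2 = orient(ax, ay, bx, by, dx2, dy2);
      const double o3 = orient(cx, cy, dx2, dy2, ax, ay);
      const double o4 = orient(cx, cy, dx2, dy2, bx, by);
      if (((o1 > 0) != (o2 > 0)) && ((o3 > 0) != (o4 > 0)) &&
          o1 != 0 && o2 != 0 && o3 != 0 && o4 != 0)
        return false;
      // collinear overlap cases
      if (o1 == 0 && on_segment(ax, ay, bx, by, cx, cy)) return false;
      if (o2 == 0 && on_segment(ax, ay, bx, by, dx2, dy2)) return false;
      if (o3 == 0 && on_segment(cx, cy, dx2, dy2, ax, ay)) return false;
      if (o4 == 0 && on_segment(cx, cy, dx2, dy2, bx, by)) return false;
    }
  }
  return true;
}
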