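#include <Rcpp.h>
using namespace Rcpp;

// Distance from one point to one closed segment.
static inline double seg_dist(double px, double py,
                              double ax, double ay,
                              double bx, double by) {
  const double dx = bx - ax, dy = by - ay;
  const double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - ax) * dx + (py - ay) * dy) / len2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  const double ex = px - (ax + t * dx), ey = py - (ay + t * dy);
  return std::sqrt(ex * ex + ey * ey);
}

// For each point, the minimum distance over a set of segments.
// [[Rcpp::export]]
NumericVector cpp_min_dist_points_segments(NumericVector px, NumericVector py,
                                           NumericVector ax, NumericVector ay,
                                           NumericVector bx, NumericVector by) {
  const R_xlen_t n = px.size(), m = ax.size();
  if (py.size() != n || ay.size() != m || bx.size() != m || by.size() != m)
    stop("coordinate vectors have inconsistent lengths");
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double x = px[i], y = py[i];
    for (R_xlen_t j = 0; j < m; ++j) {
      const double d = seg_dist(x, y, ax[j], ay[j], bx[j], by[j]);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// For each point, the index (1-based) of the nearest segment and the distance.
// [[Rcpp::export]]
List cpp_nearest_segment(NumericVector px, NumericVector py,
                         NumericVector ax, NumericVector ay,
                         NumericVector bx, NumericVector by) {
  const R_xlen_t n = px.size(), m = ax.size();
  NumericVector dist(n);
  IntegerVector idx(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    double best = R_PosInf;
    R_xlen_t bj = 0;
    for (R_xlen_t j = 0; j < m; ++j) {
      const double d = seg_dist(px[i], py[i], ax[j], ay[j], bx[j], by[j]);
      if (d < best) { best = d; bj = j; }
    }
    dist[i] = best;
    idx[i] = (int)(bj + 1);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Even-odd point-in-polygon; points exactly on the boundary count as inside.
// [[Rcpp::export]]
LogicalVector cpp_point_in_polygon(NumericVector px, NumericVector py,
                                   NumericVector vx, NumericVector vy) {
  const R_xlen_t n = px.size(), m = vx.size();
  if (m < 3) stop("polygon needs at least 3 vertices");
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double x = px[i], y = py[i];
    bool inside = false, boundary = false;
    for (R_xlen_t j = 0, k = m - 1; j < m; k = j++) {
      const double xj = vx[j], yj = vy[j], xk = vx[k], yk = vy[k];
      // boundary check: point on segment (j,k)
      if (seg_dist(x, y, xj, yj, xk, yk) <= 1e-12) { boundary = true; break; }
      const bool cross = ((yj > y) != (yk > y)) &&
        (x < (xk - xj) * (y - yj) / (yk - yj) + xj);
      if (cross) inside = !inside;
    }
    out[i] = boundary || inside;
  }
  return out;
}
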