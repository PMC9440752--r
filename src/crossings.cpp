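#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Transversal crossings between two polylines.
//
// Generic case: a segment pair contributes one crossing when the segments
// properly intersect (strict sign tests).  Degenerate incidences are given
// transversality semantics by a local side-change analysis: a vertex of one
// path lying exactly on the other counts one crossing when its off-path
// neighbours lie strictly on opposite sides of the other path there (so a
// pass-through at a vertex counts exactly once and a tangential touch
// counts nothing); a collinear overlap stretch counts one crossing when it
// is entered from one side and left on the other; a contact at an endpoint
// of either path counts nothing.  The count is symmetric in the two paths
// and invariant under rigid motions applied to both.

static inline double cross2(double ox, double oy, double ax, double ay,
                            double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// signed side of point p relative to directed segment j of path (qx, qy)
static inline double side_of(const NumericVector &qx, const NumericVector &qy,
                             int j, double px, double py) {
  return cross2(qx[j], qy[j], qx[j + 1], qy[j + 1], px, py);
}

// index of the first segment of (qx, qy) containing point p, or -1
static int on_segment_of(const NumericVector &qx, const NumericVector &qy,
                         double px, double py) {
  const int m = qx.size() - 1;
  for (int j = 0; j < m; ++j) {
    const double minx = std::min(qx[j], qx[j + 1]),
                 maxx = std::max(qx[j], qx[j + 1]),
                 miny = std::min(qy[j], qy[j + 1]),
                 maxy = std::max(qy[j], qy[j + 1]);
    if (px < minx || px > maxx || py < miny || py > maxy) continue;
    if (side_of(qx, qy, j, px, py) == 0.0) return j;
  }
  return -1;
}

// crossings contributed by vertices of P lying exactly on Q
static int vertex_events(const NumericVector &px, const NumericVector &py,
                         const NumericVector &qx, const NumericVector &qy,
                         bool skip_shared_vertices) {
  const int n = px.size();
  const int mq = qx.size();
  std::vector<int> onq(n);
  for (int k = 0; k < n; ++k) {
    onq[k] = on_segment_of(qx, qy, px[k], py[k]);
    if (onq[k] >= 0 && skip_shared_vertices) {
      for (int j = 0; j < mq; ++j) {
        if (px[k] == qx[j] && py[k] == qy[j]) { onq[k] = -1; break; }
      }
    }
  }
  int count = 0;
  int k = 0;
  while (k < n) {
    if (onq[k] < 0) { ++k; continue; }
    int e = k;
    while (e + 1 < n && onq[e + 1] >= 0) ++e;
    bool interior = (k > 0) && (e < n - 1);
    if (interior) {
      // a contact at an endpoint of Q is a touch, not a crossing
      bool at_q_end = false;
      for (int v = k; v <= e; ++v) {
        if ((px[v] == qx[0] && py[v] == qy[0]) ||
            (px[v] == qx[mq - 1] && py[v] == qy[mq - 1])) {
          at_q_end = true;
          break;
        }
      }
      if (!at_q_end) {
        const double s_prev = side_of(qx, qy, onq[k], px[k - 1], py[k - 1]);
        const double s_next = side_of(qx, qy, onq[e], px[e + 1], py[e + 1]);
        if (s_prev * s_next < 0) ++count;
      }
    }
    k = e + 1;
  }
  return count;
}

//' @noRd
// [[Rcpp::export]]
int count_crossings_cpp(NumericVector ax, NumericVector ay,
                        NumericVector bx, NumericVector by) {
  const int na = ax.size() - 1, nb = bx.size() - 1;
  // bounding boxes of the reference segments for cheap rejection
  std::vector<double> bminx(nb), bmaxx(nb), bminy(nb), bmaxy(nb);
  for (int j = 0; j < nb; ++j) {
    bminx[j] = std::min(bx[j], bx[j + 1]); bmaxx[j] = std::max(bx[j], bx[j + 1]);
    bminy[j] = std::min(by[j], by[j + 1]); bmaxy[j] = std::max(by[j], by[j + 1]);
  }
  int count = 0;
  bool any_degenerate = false;
  for (int i = 0; i < na; ++i) {
    const double aminx = std::min(ax[i], ax[i + 1]),
                 amaxx = std::max(ax[i], ax[i + 1]),
                 aminy = std::min(ay[i], ay[i + 1]),
                 amaxy = std::max(ay[i], ay[i + 1]);
    for (int j = 0; j < nb; ++j) {
      if (bminx[j] > amaxx || bmaxx[j] < aminx ||
          bminy[j] > amaxy || bmaxy[j] < aminy) continue;
      const double d1 = cross2(bx[j], by[j], bx[j + 1], by[j + 1],
                               ax[i], ay[i]);
      const double d2 = cross2(bx[j], by[j], bx[j + 1], by[j + 1],
                               ax[i + 1], ay[i + 1]);
      const double d3 = cross2(ax[i], ay[i], ax[i + 1], ay[i + 1],
                               bx[j], by[j]);
      const double d4 = cross2(ax[i], ay[i], ax[i + 1], ay[i + 1],
                               bx[j + 1], by[j + 1]);
      if (d1 == 0 || d2 == 0 || d3 == 0 || d4 == 0) {
        any_degenerate = true;
        continue; // handled by the vertex-event analysis
      }
      if ((d1 < 0) != (d2 < 0) && (d3 < 0) != (d4 < 0)) ++count;
    }
  }
  if (any_degenerate) {
    count += vertex_events(ax, ay, bx, by, false);
    count += vertex_events(bx, by, ax, ay, true);
  }
  return count;
}
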