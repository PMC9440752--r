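#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// All randomness (turning angles, initial headings) is drawn in R and passed
// in, so simulations are governed entirely by R's RNG state.

static inline double wrap_angle(double a) {
  // wrap to [-pi, pi)
  return a - 2.0 * M_PI * std::floor((a + M_PI) / (2.0 * M_PI));
}

static inline bool in_return_region_c(double x, double y,
                                      double dish_half, double return_radius) {
  double dx = std::fabs(x) - dish_half; if (dx < 0) dx = 0;
  double dy = std::fabs(y) - dish_half; if (dy < 0) dy = 0;
  return std::sqrt(dx * dx + dy * dy) <= return_radius;
}

// Advance one step with the given boundary policy.  Returns false when the
// walker is absorbed at a wall (policy 2).
static inline bool apply_step(double &x, double &y, double &heading,
                              double step,
                              double xmin, double xmax,
                              double ymin, double ymax,
                              int boundary) {
  double nx = x + step * std::cos(heading);
  double ny = y + step * std::sin(heading);
  if (boundary == 0) { // specular reflection
    for (int it = 0; it < 8; ++it) {
      bool moved = false;
      if (nx < xmin) { nx = 2 * xmin - nx; heading = M_PI - heading; moved = true; }
      else if (nx > xmax) { nx = 2 * xmax - nx; heading = M_PI - heading; moved = true; }
      if (ny < ymin) { ny = 2 * ymin - ny; heading = -heading; moved = true; }
      else if (ny > ymax) { ny = 2 * ymax - ny; heading = -heading; moved = true; }
      if (!moved) break;
    }
  } else if (boundary == 1) { // clip to walls
    if (nx < xmin) nx = xmin; else if (nx > xmax) nx = xmax;
    if (ny < ymin) ny = ymin; else if (ny > ymax) ny = ymax;
  } else { // absorb
    if (nx < xmin || nx > xmax || ny < ymin || ny > ymax) return false;
  }
  x = nx; y = ny;
  return true;
}

//' @noRd
// [[Rcpp::export]]
List walk_path_cpp(NumericVector turn_angles, double heading0,
                   double x0, double y0, double step,
                   double homing_weight, double goal_x, double goal_y,
                   bool has_goal, double step_rate,
                   double xmin, double xmax, double ymin, double ymax,
                   int boundary, bool stop_at_return,
                   double dish_half, double return_radius) {
  const int max_steps = turn_angles.size();
  NumericVector xs(max_steps + 1), ys(max_steps + 1), ts(max_steps + 1);
  double x = x0, y = y0, heading = heading0;
  xs[0] = x; ys[0] = y; ts[0] = 0.0;
  bool returned = stop_at_return &&
    in_return_region_c(x, y, dish_half, return_radius);
  bool absorbed = false;
  int k = 0;
  while (k < max_steps && !returned) {
    heading += turn_angles[k];
    if (has_goal && homing_weight > 0) {
      double bearing = std::atan2(goal_y - y, goal_x - x);
      heading += homing_weight * wrap_angle(bearing - heading);
    }
    heading = wrap_angle(heading);
    if (!apply_step(x, y, heading, step, xmin, xmax, ymin, ymax, boundary)) {
      absorbed = true;
      break;
    }
    ++k;
    xs[k] = x; ys[k] = y; ts[k] = k / step_rate;
    if (stop_at_return && in_return_region_c(x, y, dish_half, return_radius))
      returned = true;
  }
  return List::create(
    _["t"] = ts[Range(0, k)],
    _["x"] = xs[Range(0, k)],
    _["y"] = ys[Range(0, k)],
    _["steps"] = k,
    _["returned"] = returned,
    _["absorbed"] = absorbed);
}

// Batch walker returning per-replicate summaries only (no stored paths).
// turn_angles is n x max_steps; headings0 length n.
//' @noRd
// [[Rcpp::export]]
NumericMatrix walk_batch_cpp(NumericMatrix turn_angles, NumericVector headings0,
                             double x0, double y0, double step,
                             double homing_weight, double goal_x, double goal_y,
                             bool has_goal, double step_rate,
                             double xmin, double xmax, double ymin, double ymax,
                             int boundary, bool stop_at_return,
                             double dish_half, double return_radius) {
  const int n = turn_angles.nrow();
  const int max_steps = turn_angles.ncol();
  NumericMatrix out(n, 4); // returned, steps, net_sq_displacement, path_length
  colnames(out) = CharacterVector::create("returned", "steps", "net_r2",
                                          "path_length");
  for (int i = 0; i < n; ++i) {
    double x = x0, y = y0, heading = headings0[i];
    bool returned = stop_at_return &&
      in_return_region_c(x, y, dish_half, return_radius);
    int k = 0;
    while (k < max_steps && !returned) {
      heading += turn_angles(i, k);
      if (has_goal && homing_weight > 0) {
        double bearing = std::atan2(goal_y - y, goal_x - x);
        heading += homing_weight * wrap_angle(bearing - heading);
      }
      heading = wrap_angle(heading);
      if (!apply_step(x, y, heading, step, xmin, xmax, ymin, ymax, boundary))
        break;
      ++k;
      if (stop_at_return && in_return_region_c(x, y, dish_half, return_radius))
        returned = true;
    }
    const double dx = x - x0, dy = y - y0;
    out(i, 0) = returned ? 1.0 : 0.0;
    out(i, 1) = k;
    out(i, 2) = dx * dx + dy * dy;
    out(i, 3) = k * step;
  }
  return out;
}
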