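#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Model codes: 0 baseline, 1..4 the four decision-action architectures.
//
// Time is discretised in intervals of length dt. Interval n covers
// (t_{n-1}, t_n]. The action focus used for movement during an interval is
// computed from the evidence state at the start of that interval, so the
// accumulator value reached at t_n steers the movement over (t_n, t_{n+1}].
// The evidence increment for the interval is added at its end. Trajectory
// samples are therefore consistent state snapshots (t, x, y, z, z_eff).
//
// Arrival: when the focus sits exactly on a target and the remaining
// distance is <= v*dt, the terminal step is shortened and contributes
// distance/v to the response time, so straight-line travel time is
// |target - start|/v exactly rather than a multiple of dt.

static inline double dist2d(double ax, double ay, double bx, double by) {
  return std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
}

// [[Rcpp::export]]
List sim_trial_cpp(int model, double mu, double sigma, double dt,
                   double b, double g, double v,
                   double sx, double sy,
                   double t1x, double t1y, double t2x, double t2y,
                   int max_steps, bool record,
                   Nullable<NumericVector> increments) {
  if (b <= 0) stop("decision bound must be positive");
  if (dt <= 0) stop("dt must be positive");

  bool scripted = increments.isNotNull();
  NumericVector script;
  if (scripted) script = increments.get();

  double z = 0.0, t = 0.0, x = sx, y = sy;
  bool has_focus = false, decided = false, tdec_set = false;
  double fx = 0.0, fy = 0.0, tdec = NA_REAL;
  int prev_sign = 0, n_switches = 0, choice = 0;
  double rt = NA_REAL;
  double mid_x = 0.5 * (t1x + t2x);  // arena midline for switch counting

  std::vector<double> rec_t, rec_x, rec_y, rec_z, rec_ze;
  if (record) {
    rec_t.reserve(64); rec_x.reserve(64); rec_y.reserve(64);
    rec_z.reserve(64); rec_ze.reserve(64);
  }

  double zeff = z;  // commitment term is zero when equidistant at start
  if (model == 4) {
    double d1 = dist2d(x, y, t1x, t1y), d2 = dist2d(x, y, t2x, t2y);
    zeff = z + g * (d2 - d1) / (d1 + d2);
  }
  if (record) {
    rec_t.push_back(0.0); rec_x.push_back(x); rec_y.push_back(y);
    rec_z.push_back(z); rec_ze.push_back(zeff);
  }

  bool finished = false;
  int step;
  for (step = 1; step <= max_steps && !finished; ++step) {
    // --- start of interval: effective evidence and focus from current state
    zeff = z;
    if (model == 4) {
      double d1 = dist2d(x, y, t1x, t1y), d2 = dist2d(x, y, t2x, t2y);
      zeff = z + g * (d2 - d1) / (d1 + d2);
    }

    if (model == 1) {
      if (!decided && std::fabs(z) >= b) {
        decided = true;
        tdec = t; tdec_set = true;
        if (z >= b) { fx = t1x; fy = t1y; } else { fx = t2x; fy = t2y; }
        has_focus = true;
      }
    } else if (model == 2) {
      if (z >= b) {
        fx = t1x; fy = t1y; has_focus = true;
        if (!tdec_set) { tdec = t; tdec_set = true; }
      } else if (z <= -b) {
        fx = t2x; fy = t2y; has_focus = true;
        if (!tdec_set) { tdec = t; tdec_set = true; }
      }
      // between bounds: focus (if any) held at its last value
    } else if (model == 3 || model == 4) {
      if (zeff >= b) {
        fx = t1x; fy = t1y;
      } else if (zeff <= -b) {
        fx = t2x; fy = t2y;
      } else {
        // parameterised from target 2 so the focus sits exactly on the
        // segment (w1*t1 + w2*t2 with w1+w2 != 1 by an ulp would not)
        double w1 = (b + zeff) / (2.0 * b);
        fx = t2x + w1 * (t1x - t2x);
        fy = t2y + w1 * (t1y - t2y);
      }
      has_focus = true;
      if (!tdec_set && std::fabs(zeff) >= b) { tdec = t; tdec_set = true; }
    }

    if (has_focus && model != 0) {
      int sign = (fx < mid_x) ? -1 : (fx > mid_x ? 1 : 0);
      if (sign != 0) {
        if (prev_sign != 0 && sign != prev_sign) ++n_switches;
        prev_sign = sign;
      }
    }

    // --- move toward the focus for this interval
    if (has_focus && model != 0) {
      double d = dist2d(x, y, fx, fy);
      bool focus_is_target =
        (fx == t1x && fy == t1y) || (fx == t2x && fy == t2y);
      if (focus_is_target && d <= v * dt) {
        rt = t + d / v;
        x = fx; y = fy;
        choice = (fx == t1x && fy == t1y) ? 1 : 2;
        if (record) {
          rec_t.push_back(rt); rec_x.push_back(x); rec_y.push_back(y);
          rec_z.push_back(z); rec_ze.push_back(zeff);
        }
        finished = true;
        break;
      }
      if (d > 0) {
        if (d <= v * dt) {
          x = fx; y = fy;  // shortened step lands exactly on the focus
        } else {
          // each coordinate moves monotonically toward the focus; clamp
          // away 1-ulp overshoot so y stays exactly on the target line
          double nx = x + (fx - x) / d * (v * dt);
          double ny = y + (fy - y) / d * (v * dt);
          x = (fx >= x) ? std::min(nx, fx) : std::max(nx, fx);
          y = (fy >= y) ? std::min(ny, fy) : std::max(ny, fy);
        }
      }
    }

    // --- evidence increment at end of interval
    double dz;
    if (scripted) {
      if (step - 1 >= script.size())
        stop("noise script exhausted before the trial terminated");
      dz = script[step - 1];
    } else {
      dz = R::rnorm(mu, sigma);
    }
    if (!(model == 1 && decided)) z += dz;
    t += dt;

    double zeff_end = z;
    if (model == 4) {
      double d1 = dist2d(x, y, t1x, t1y), d2 = dist2d(x, y, t2x, t2y);
      zeff_end = z + g * (d2 - d1) / (d1 + d2);
    }
    if (record) {
      rec_t.push_back(t); rec_x.push_back(x); rec_y.push_back(y);
      rec_z.push_back(z); rec_ze.push_back(zeff_end);
    }

    if (model == 0) {
      if (z >= b) { choice = 1; rt = t; finished = true; }
      else if (z <= -b) { choice = 2; rt = t; finished = true; }
    }
  }

  if (!finished)
    stop("step cap (%d) exhausted: non-terminating configuration", max_steps);

  List out = List::create(
    _["choice"] = choice,
    _["rt"] = rt,
    _["t_dec"] = tdec_set ? tdec : NA_REAL,
    _["n_focus_switches"] = n_switches);
  if (record) {
    int n = rec_t.size();
    NumericMatrix traj(n, 5);
    for (int i = 0; i < n; ++i) {
      traj(i, 0) = rec_t[i]; traj(i, 1) = rec_x[i]; traj(i, 2) = rec_y[i];
      traj(i, 3) = rec_z[i]; traj(i, 4) = rec_ze[i];
    }
    colnames(traj) = CharacterVector::create("t", "x", "y", "z", "z_eff");
    out["trajectory"] = traj;
  } else {
    out["trajectory"] = R_NilValue;
  }
  return out;
}
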