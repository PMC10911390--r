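#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double slip(double r, double x0) {
  return r * r / (x0 * x0 + r * r);
}

// slip-inhibited exponential repulsion magnitude
static inline double force_mag(double amp, double r, double x0, double lam) {
  return amp * slip(r, x0) * std::exp(-r / lam);
}

// Overdamped Euler integration of n point asters in a disk.
// Wall interaction acts through the mirror charge at the nearest boundary
// point: magnitude evaluated at the perpendicular separation b (default) or
// with the pair law at the image distance 2b (wall_image_mode).
// Noise is a force delta_f along a fresh random unit vector per aster per
// step (optionally sqrt(dt)-scaled displacement).
// [[Rcpp::export]]
List sim2d_engine(NumericMatrix init, double cx, double cy, double R,
                  double f0, double f1, double lambda_wall,
                  double lambda_aster, double x0_wall, double x0_aster,
                  double delta_f, double gamma, double dt,
                  int max_steps, int record_every,
                  double steady_tol, int steady_window,
                  bool wall_image_mode, bool noise_sqrt_dt) {
  const int n = init.nrow();
  std::vector<double> x(n), y(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) { x[i] = init(i, 0); y[i] = init(i, 1); }

  const int nrec_max = max_steps / record_every + 2;
  std::vector<double> rec_x, rec_y; rec_x.reserve(nrec_max * n); rec_y.reserve(nrec_max * n);
  std::vector<int> rec_step; rec_step.reserve(nrec_max);
  // circular buffer of the last steady_window positions for plateau detection
  std::vector<double> buf(2 * n * steady_window);
  const double noise_disp = noise_sqrt_dt ? gamma * delta_f * std::sqrt(dt)
                                          : gamma * delta_f * dt;
  int steady_step = -1, n_clamped = 0, step = 0;

  rec_step.push_back(0);
  for (int i = 0; i < n; ++i) { rec_x.push_back(x[i]); rec_y.push_back(y[i]); }

  RNGScope scope;
  for (step = 1; step <= max_steps; ++step) {
    for (int i = 0; i < n; ++i) { fx[i] = 0.0; fy[i] = 0.0; }
    // wall repulsion, inward along the radial through the nearest boundary point
    for (int i = 0; i < n; ++i) {
      double rx = x[i] - cx, ry = y[i] - cy;
      double r = std::sqrt(rx * rx + ry * ry);
      if (r > 1e-12) {
        double b = R - r;
        double mag = wall_image_mode
          ? force_mag(f0, 2.0 * b, x0_wall, lambda_wall)
          : force_mag(f0, b, x0_wall, lambda_wall);
        fx[i] -= mag * rx / r; // inward: -r_hat
        fy[i] -= mag * ry / r;
      }
    }
    // pair repulsion along each inter-aster axis (Newton's third law)
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = x[i] - x[j], dy = y[i] - y[j];
        double d = std::sqrt(dx * dx + dy * dy);
        if (d > 1e-12) {
          double mag = force_mag(f1, d, x0_aster, lambda_aster);
          double ux = dx / d, uy = dy / d;
          fx[i] += mag * ux; fy[i] += mag * uy;
          fx[j] -= mag * ux; fy[j] -= mag * uy;
        }
      }
    }
    // step
    for (int i = 0; i < n; ++i) {
      double nx = x[i] + gamma * fx[i] * dt;
      double ny = y[i] + gamma * fy[i] * dt;
      if (delta_f > 0.0) {
        double th = unif_rand() * 2.0 * M_PI;
        nx += noise_disp * std::cos(th);
        ny += noise_disp * std::sin(th);
      }
      double rx = nx - cx, ry = ny - cy;
      double r = std::sqrt(rx * rx + ry * ry);
      if (r >= R) { // clamp 0.5 um inside along the radial
        double s = (R - 0.5) / r;
        nx = cx + rx * s; ny = cy + ry * s;
        ++n_clamped;
      }
      x[i] = nx; y[i] = ny;
    }
    // steady-state check over the trailing window
    int slot = (step - 1) % steady_window;
    for (int i = 0; i < n; ++i) {
      buf[2 * (slot * n + i)] = x[i];
      buf[2 * (slot * n + i) + 1] = y[i];
    }
    if (step % record_every == 0 || step == max_steps) {
      rec_step.push_back(step);
      for (int i = 0; i < n; ++i) { rec_x.push_back(x[i]); rec_y.push_back(y[i]); }
    }
    if (step >= steady_window && step % steady_window == 0) {
      bool steady = true;
      for (int s = 0; s < steady_window && steady; ++s) {
        for (int i = 0; i < n; ++i) {
          double dx = x[i] - buf[2 * (s * n + i)];
          double dy = y[i] - buf[2 * (s * n + i) + 1];
          if (dx * dx + dy * dy >= steady_tol * steady_tol) { steady = false; break; }
        }
      }
      if (steady) {
        steady_step = step;
        if (rec_step.back() != step) {
          rec_step.push_back(step);
          for (int i = 0; i < n; ++i) { rec_x.push_back(x[i]); rec_y.push_back(y[i]); }
        }
        break;
      }
    }
  }

  const int nrec = rec_step.size();
  NumericMatrix traj(nrec * n, 4); // step, aster, x, y
  for (int k = 0; k < nrec; ++k) {
    for (int i = 0; i < n; ++i) {
      int row = k * n + i;
      traj(row, 0) = rec_step[k];
      traj(row, 1) = i + 1;
      traj(row, 2) = rec_x[k * n + i];
      traj(row, 3) = rec_y[k * n + i];
    }
  }
  NumericMatrix fin(n, 2);
  for (int i = 0; i < n; ++i) { fin(i, 0) = x[i]; fin(i, 1) = y[i]; }
  return List::create(_["traj"] = traj, _["final"] = fin,
                      _["steady_step"] = steady_step,
                      _["n_clamped"] = n_clamped);
}

// 1D stochastic ensembles on [0, 2R]: Euler-Maruyama with the full
// slip-inhibited force law. Each aster feels its nearest endpoint (the 1D
// analogue of the single mirror charge) plus, for pairs, mutual repulsion.
// Noise delta_f * xi per step (xi standard normal, or +/-1 Bernoulli),
// reflecting boundaries at 0 and 2R.
// [[Rcpp::export]]
NumericMatrix sim1d_engine(int n_asters, double R,
                           double f0, double f1, double lambda_wall,
                           double lambda_aster, double x0_wall, double x0_aster,
                           double delta_f, double gamma, double dt,
                           int n_runs, int n_steps,
                           NumericVector start, bool bernoulli,
                           bool wall_image_mode) {
  NumericMatrix out(n_runs, n_asters);
  const double L = 2.0 * R;
  RNGScope scope;
  for (int run = 0; run < n_runs; ++run) {
    double x1 = start[0];
    double x2 = (n_asters == 2) ? start[1] : 0.0;
    for (int s = 0; s < n_steps; ++s) {
      double F1, F2 = 0.0;
      // nearest-endpoint wall force, directed away from that endpoint
      double b1 = (x1 <= R) ? x1 : L - x1;
      if (wall_image_mode) b1 *= 2.0;
      double w1 = force_mag(f0, b1, x0_wall, lambda_wall);
      F1 = (x1 <= R) ? w1 : -w1;
      if (n_asters == 2) {
        double b2 = (x2 <= R) ? x2 : L - x2;
        if (wall_image_mode) b2 *= 2.0;
        double w2 = force_mag(f0, b2, x0_wall, lambda_wall);
        F2 = (x2 <= R) ? w2 : -w2;
        double d = x2 - x1;
        double ad = std::fabs(d);
        if (ad > 1e-12) {
          double p = force_mag(f1, ad, x0_aster, lambda_aster);
          if (d > 0) { F1 -= p; F2 += p; } else { F1 += p; F2 -= p; }
        }
      }
      if (delta_f > 0.0) {
        F1 += delta_f * (bernoulli ? (unif_rand() < 0.5 ? -1.0 : 1.0) : norm_rand());
        if (n_asters == 2)
          F2 += delta_f * (bernoulli ? (unif_rand() < 0.5 ? -1.0 : 1.0) : norm_rand());
      }
      x1 += gamma * F1 * dt;
      if (x1 < 0) x1 = -x1; else if (x1 > L) x1 = 2.0 * L - x1;
      if (n_asters == 2) {
        x2 += gamma * F2 * dt;
        if (x2 < 0) x2 = -x2; else if (x2 > L) x2 = 2.0 * L - x2;
      }
    }
    out(run, 0) = x1;
    if (n_asters == 2) out(run, 1) = x2;
  }
  return out;
}
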