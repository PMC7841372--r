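#include <Rcpp.h>
using namespace Rcpp;

// Wrap an angle into (-pi, pi]. Same floating-point expression as the R
// reference (wrap_angle) so compiled and scalar runs agree bitwise.
static inline double wrap_pi(double a) {
  const double TWOPI = 2.0 * M_PI;
  double y = a - TWOPI * std::floor((a + M_PI) / TWOPI);
  if (y <= -M_PI) y = M_PI;
  if (y > M_PI) y = M_PI;
  return y;
}

// Wrap a coordinate into [0, L); mirrors the R reference expression.
static inline double wrap_box(double v, double L) {
  double m = v - L * std::floor(v / L);
  if (m < 0.0) m += L;
  if (m >= L) m -= L;
  return m;
}

// Minimum-image Euclidean distance on the L-periodic square.
static inline double min_image_dist(double x1, double y1, double x2, double y2,
                                    double L) {
  double dx = std::fabs(x1 - x2);
  if (dx > L - dx) dx = L - dx;
  double dy = std::fabs(y1 - y2);
  if (dy > L - dy) dy = L - dy;
  return std::sqrt(dx * dx + dy * dy);
}

// Simulate n_steps synchronous updates of the skill-modulated agent model.
//
// Noise is supplied, not drawn here: `draws` holds uniform(-xi, xi) variates
// ordered by time step, then agent, then (xi2, xi3, xi1x, xi1y), so a scalar
// R implementation fed the same vector reproduces the run draw-for-draw.
//
// Heading rule per agent i at step t (snapshot-synchronous):
//   base  = circular mean of headings within radius r (incl. self) if social,
//           otherwise own heading
//   self  = wrap(base + xi2 / p_i)
//   envir = wrap(theta_g(x_i(t)) + xi3 / p_i)  (theta_g falls back to the
//           current heading when the field gradient is degenerate)
//   theta' = wrap(alpha * self + beta * envir)         [mix = 0, literal sum]
//          = atan2 of the weighted unit vectors        [mix = 1, circular]
// Position rule: x' = (x + xi1 / p_i + kappa * (cos theta', sin theta')) mod L.
// [[Rcpp::export]]
List sim_core_cpp(NumericVector x0, NumericVector y0, NumericVector theta0,
                  NumericVector p, NumericVector draws, int n_steps, double L,
                  double kappa, double alpha, double beta, double r,
                  bool env_on, bool social_on, int mix) {
  const int n = x0.size();
  if (theta0.size() != n || y0.size() != n || p.size() != n)
    stop("state vectors must share one length");
  if ((int)draws.size() != n_steps * n * 4)
    stop("draws must have length n_steps * n_agents * 4");

  NumericMatrix X(n_steps + 1, n), Y(n_steps + 1, n), TH(n_steps + 1, n);
  std::vector<double> cx(n), cy(n), cth(n), nth(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = x0[i];
    cy[i] = y0[i];
    cth[i] = theta0[i];
    X(0, i) = cx[i];
    Y(0, i) = cy[i];
    TH(0, i) = cth[i];
  }
  const double c0 = L / 2.0;

  for (int t = 0; t < n_steps; ++t) {
    // headings first, all from the time-t snapshot
    for (int i = 0; i < n; ++i) {
      const double *d = &draws[((t * n) + i) * 4];
      double base;
      if (social_on) {
        double ssum = 0.0, csum = 0.0;
        int cnt = 0;
        for (int j = 0; j < n; ++j) {
          if (j == i || min_image_dist(cx[i], cy[i], cx[j], cy[j], L) <= r) {
            ssum += std::sin(cth[j]);
            csum += std::cos(cth[j]);
            ++cnt;
          }
        }
        base = (cnt > 1) ? std::atan2(ssum / cnt, csum / cnt) : cth[i];
      } else {
        base = cth[i];
      }
      double self_term = wrap_pi(base + d[0] / p[i]);
      double env_term = 0.0;
      if (env_on) {
        double gx = c0 - cx[i], gy = c0 - cy[i];
        double dist = std::sqrt(gx * gx + gy * gy);
        double gnorm =
            dist * std::exp(-dist * dist / 2.0) / (2.0 * M_PI);
        double tg = (gnorm <= 1e-12) ? cth[i] : std::atan2(gy, gx);
        env_term = wrap_pi(tg + d[1] / p[i]);
      }
      if (mix == 0) {
        nth[i] = wrap_pi(alpha * self_term + beta * env_term);
      } else {
        nth[i] = std::atan2(alpha * std::sin(self_term) + beta * std::sin(env_term),
                            alpha * std::cos(self_term) + beta * std::cos(env_term));
      }
    }
    // then all positions, using the new headings
    for (int i = 0; i < n; ++i) {
      const double *d = &draws[((t * n) + i) * 4];
      cx[i] = wrap_box(cx[i] + d[2] / p[i] + kappa * std::cos(nth[i]), L);
      cy[i] = wrap_box(cy[i] + d[3] / p[i] + kappa * std::sin(nth[i]), L);
      cth[i] = nth[i];
      X(t + 1, i) = cx[i];
      Y(t + 1, i) = cy[i];
      TH(t + 1, i) = cth[i];
    }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["theta"] = TH);
}
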