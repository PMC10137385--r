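#include <Rcpp.h>
using namespace Rcpp;

// Explicit Euler stepping of the delayed-feedback inverted pendulum
//
//   theta''(t) = -(gamma/m) theta'(t) + (g/L) sin theta(t)
//                - (R0 + xi_n) theta(t - tau)
//
// with xi_n ~ N(0, noise_sd^2) drawn once per step (R's RNG, so the
// trajectory is reproducible under set.seed), the delayed angle read from
// the stored trajectory (method of steps), and a constant pre-history
// theta == theta0, theta' == 0 on [-tau, 0].
//
// Integration stops at the first sample with |theta| >= fall_angle (that
// sample is recorded) or after t_max_steps steps.  A non-finite state is
// flagged as overflow and treated as a fall at the offending step.
// [[Rcpp::export]]
List sdde_integrate_cpp(double theta0, double gamma_m, double g_over_L,
                        double R0, double noise_sd, int tau_steps,
                        double dt, int t_max_steps, double fall_angle) {
  NumericVector theta(t_max_steps + 1), omega(t_max_steps + 1);
  theta[0] = theta0;
  omega[0] = 0.0;

  bool fell = false, overflow = false;
  int last = 0;
  int fall_step = NA_INTEGER;

  // initial sample may already violate the bound
  if (std::abs(theta0) >= fall_angle) {
    fell = true;
    fall_step = 0;
  } else {
    for (int n = 0; n < t_max_steps; ++n) {
      double xi = (noise_sd > 0.0) ? R::rnorm(0.0, noise_sd) : 0.0;
      double delayed = (n >= tau_steps) ? theta[n - tau_steps] : theta0;
      double acc = -gamma_m * omega[n] + g_over_L * std::sin(theta[n])
                   - (R0 + xi) * delayed;
      theta[n + 1] = theta[n] + dt * omega[n];
      omega[n + 1] = omega[n] + dt * acc;
      last = n + 1;
      if (!std::isfinite(theta[n + 1]) || !std::isfinite(omega[n + 1])) {
        overflow = true;
        fell = true;
        fall_step = n + 1;
        break;
      }
      if (std::abs(theta[n + 1]) >= fall_angle) {
        fell = true;
        fall_step = n + 1;
        break;
      }
    }
  }

  Range keep(0, last);
  return List::create(_["theta"] = theta[keep],
                      _["omega"] = omega[keep],
                      _["fell"] = fell,
                      _["fall_step"] = fall_step,
                      _["overflow"] = overflow);
}
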