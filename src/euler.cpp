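#include <Rcpp.h>
using namespace Rcpp;

// Euler-forward integration of the three-equation ecocultural model.
// xi holds one pre-drawn Weibull innovation per step; K0_step holds the
// forcing baseline evaluated at each step's start time. All right-hand
// sides are evaluated at the current state (fully explicit, simultaneous
// update). Negative Euler overshoots of rho or c are clipped to zero and
// counted; K is never clipped.
//
// barren_decline: policy for steps where the population is positive but
// the effective carrying capacity K(1+c) is not (resources exhausted).
// The raw logistic term is explosive there (it rewards a negative
// capacity), so either the step errors out (false) or the population
// declines at its intrinsic rate, drho = -alpha*rho (true); such steps
// are counted in n_barren.
// [[Rcpp::export]]
List euler_simulate_cpp(double rho0, double c0, double K_init,
                        double alpha, double lam, double mu, double eta,
                        double sigma, NumericVector xi,
                        NumericVector K0_step, double dt,
                        bool barren_decline = true) {
  const int n = xi.size();
  if (K0_step.size() != n)
    stop("xi and K0_step must have one value per step");
  NumericVector rho(n + 1), cc(n + 1), K(n + 1);
  int n_clipped = 0, n_barren = 0;
  rho[0] = rho0;
  cc[0] = c0;
  K[0] = K_init;
  for (int i = 0; i < n; ++i) {
    const double r = rho[i], c = cc[i], k = K[i];
    double drho;
    if (r == 0.0) {
      drho = 0.0;  // extinction is absorbing
    } else {
      const double keff = k * (1.0 + c);
      if (keff <= 0.0) {
        if (!barren_decline)
          stop("degenerate state at step %d: effective carrying capacity "
               "K(1+c) = %g is not positive", i, keff);
        drho = -alpha * r;
        ++n_barren;
      } else {
        drho = alpha * r * (1.0 - r / keff);
      }
    }
    const double dc = -lam * c + sigma * xi[i] * r;
    const double dK = -eta * (k - K0_step[i]) - mu * r;
    double rn = r + dt * drho;
    double cn = c + dt * dc;
    const double Kn = k + dt * dK;
    if (rn <= 0.0 && r > 0.0) {
      // Euler overshoot through zero: land softly on the positive side
      // with the multiplicative update r*exp(dt*drho/r), the exact decay
      // the relative drift implies. A hard clip to zero would make a
      // single overshoot step an absorbing extinction, which the
      // continuous equations do not have.
      double g = dt * (drho / r);
      if (g < -600.0) g = -600.0;
      rn = r * std::exp(g);
      ++n_clipped;
    }
    if (cn < 0.0) { cn = 0.0; ++n_clipped; }
    if (!std::isfinite(rn) || !std::isfinite(cn) || !std::isfinite(Kn))
      stop("integration failure: non-finite state at step %d", i + 1);
    rho[i + 1] = rn;
    cc[i + 1] = cn;
    K[i + 1] = Kn;
  }
  return List::create(_["rho"] = rho, _["c"] = cc, _["K"] = K,
                      _["n_clipped"] = n_clipped, _["n_barren"] = n_barren);
}
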