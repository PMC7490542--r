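#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Euler-Maruyama integration of the dimensionless HPA cascade.
//
// Hormones (CRH x1, ACTH x2, cortisol x3) and, in the gland-mass variant,
// the functional masses of the pituitary corticotrophs (P) and adrenal
// cortex (A) are integrated on a log scale, which preserves positivity:
//   d ln x1 = a1 (u/(x3 x1) - 1) dt
//   d ln x2 = a2 (P x1/(x3 x2) - 1) dt
//   d ln x3 = a3 (A x2/x3    - 1) dt
//   d ln P  = bP (x1 - 1) dt,   d ln A = bA (x2 - 1) dt
// (P = A = 1 fixed in the classic variant). The stress input u is an
// Ornstein-Uhlenbeck process with mean u_mean, stationary sd sigma and
// correlation time tau, clipped below at u_floor. Uses R's RNG so that
// set.seed() in the caller makes trajectories reproducible.

// [[Rcpp::export]]
List hpa_sim_cpp(bool gland_mass,
                 double a1, double a2, double a3,
                 double bP, double bA,
                 double sigma, double tau, double u_mean, double u_floor,
                 double dt, double t_total, double burn_in,
                 int record_every) {
  const long n_steps = (long)std::llround((t_total + burn_in) / dt);
  const long n_burn  = (long)std::llround(burn_in / dt);
  const long n_rec   = (n_steps - n_burn) / record_every + 1;

  NumericVector times(n_rec), u_out(n_rec), x1_out(n_rec), x2_out(n_rec),
      x3_out(n_rec), P_out(n_rec), A_out(n_rec);

  double u = u_mean, l1 = 0.0, l2 = 0.0, l3 = 0.0, lP = 0.0, lA = 0.0;
  const double noise = sigma * std::sqrt(2.0 * dt / tau);
  long j = 0;

  for (long i = 0; i <= n_steps; ++i) {
    const double x1 = std::exp(l1), x2 = std::exp(l2), x3 = std::exp(l3);
    const double P = gland_mass ? std::exp(lP) : 1.0;
    const double A = gland_mass ? std::exp(lA) : 1.0;

    if (i >= n_burn && (i - n_burn) % record_every == 0 && j < n_rec) {
      times[j] = (i - n_burn) * dt;
      u_out[j] = u; x1_out[j] = x1; x2_out[j] = x2; x3_out[j] = x3;
      P_out[j] = P; A_out[j] = A;
      ++j;
    }
    if (i == n_steps) break;

    l1 += a1 * (u / (x3 * x1) - 1.0) * dt;
    l2 += a2 * (P * x1 / (x3 * x2) - 1.0) * dt;
    l3 += a3 * (A * x2 / x3 - 1.0) * dt;
    if (gland_mass) {
      lP += bP * (x1 - 1.0) * dt;
      lA += bA * (x2 - 1.0) * dt;
    }
    u += (u_mean - u) / tau * dt;
    if (sigma > 0.0) u += noise * norm_rand();
    if (u < u_floor) u = u_floor;

    if (!std::isfinite(l1) || !std::isfinite(l2) || !std::isfinite(l3) ||
        !std::isfinite(lP) || !std::isfinite(lA))
      stop("integration failure (non-finite state) at t = %f days", i * dt);
  }

  List out = List::create(
      Named("time_days") = times, Named("u") = u_out,
      Named("x1") = x1_out, Named("x2") = x2_out, Named("x3") = x3_out);
  if (gland_mass) {
    out.push_back(P_out, "P");
    out.push_back(A_out, "A");
  }
  return out;
}
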