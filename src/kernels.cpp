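#include <Rcpp.h>
using namespace Rcpp;

// Metropolis random-walk kernels for the shipped model families.  The walk
// uses R's RNG (so per-replica streams managed at the R level via
// .Random.seed swapping are honoured) and records (step, dU/dlambda, U) every
// `record_interval` steps.  Energies are in reduced units (kT at beta = 1).

static inline double wrap_angle(double a) {
  // wrap to (-pi, pi]
  const double twopi = 2.0 * M_PI;
  double r = a - twopi * std::floor((a + M_PI) / twopi);
  if (r <= -M_PI) r += twopi;
  return r;
}

// Quadratic family: U(x, lam) = 0.5 * k(lam) * x^2 + lam * c * x,
// k(lam) = (1 - lam) k0 + lam k1.  dU/dlam = 0.5 (k1 - k0) x^2 + c x.
// [[Rcpp::export]]
List mc_propagate_quad(double x, double lam, double k0, double k1, double cc,
                       int n_steps, double beta, double step_size,
                       int record_interval) {
  RNGScope scope;
  const double k = (1.0 - lam) * k0 + lam * k1;
  const double dk2 = 0.5 * (k1 - k0);
  int n_rec = (record_interval > 0) ? n_steps / record_interval : 0;
  NumericVector rec_dudl(n_rec), rec_u(n_rec), rec_coord(n_rec);
  IntegerVector rec_step(n_rec);
  double u = 0.5 * k * x * x + lam * cc * x;
  int n_acc = 0, ir = 0;
  for (int i = 1; i <= n_steps; ++i) {
    double xp = x + (unif_rand() * 2.0 - 1.0) * step_size;
    double up = 0.5 * k * xp * xp + lam * cc * xp;
    double du = up - u;
    if (du <= 0.0 || unif_rand() < std::exp(-beta * du)) {
      x = xp; u = up; ++n_acc;
    }
    if (record_interval > 0 && (i % record_interval) == 0) {
      rec_step[ir] = i;
      rec_dudl[ir] = dk2 * x * x + cc * x;
      rec_u[ir] = u;
      rec_coord[ir] = x;
      ++ir;
    }
  }
  return List::create(_["x"] = x, _["step"] = rec_step, _["dudl"] = rec_dudl,
                      _["u"] = rec_u, _["coord"] = rec_coord,
                      _["n_accept"] = n_acc);
}

static inline double torsion_energy(const NumericVector& th,
                                    const NumericVector& v,
                                    const NumericVector& nf,
                                    const NumericVector& ph,
                                    const LogicalVector& scaled,
                                    double gamma) {
  double e = 0.0;
  for (int j = 0; j < th.size(); ++j) {
    double g = scaled[j] ? gamma : 1.0;
    e += g * v[j] * (1.0 + std::cos(nf[j] * th[j] - ph[j]));
  }
  return e;
}

static inline double torsion_scaled_part(const NumericVector& th,
                                         const NumericVector& v,
                                         const NumericVector& nf,
                                         const NumericVector& ph,
                                         const LogicalVector& scaled) {
  double e = 0.0;
  for (int j = 0; j < th.size(); ++j)
    if (scaled[j]) e += v[j] * (1.0 + std::cos(nf[j] * th[j] - ph[j]));
  return e;
}

// Torsion chain: d periodic angles with (optionally gamma-scaled) cosine
// barriers plus a lambda-coupled harmonic well on the collective coordinate
// s = mean(sin(theta_j)).  One randomly chosen angle is updated per step.
// dudl_direct = 1 adds the scaled torsion term's derivative (direct mapping
// gamma(lambda) = lambda); 0 holds gamma fixed (two-state scheme).
// [[Rcpp::export]]
List mc_propagate_torsion(NumericVector theta, double lam, double gamma,
                          NumericVector v, NumericVector nf, NumericVector ph,
                          LogicalVector scaled, double k0, double k1,
                          int n_steps, double beta, double step_size,
                          int record_interval, int dudl_direct) {
  RNGScope scope;
  NumericVector th = clone(theta);
  const int d = th.size();
  const double k = (1.0 - lam) * k0 + lam * k1;
  const double dk2 = 0.5 * (k1 - k0);
  int n_rec = (record_interval > 0) ? n_steps / record_interval : 0;
  NumericVector rec_dudl(n_rec), rec_u(n_rec), rec_coord(n_rec);
  IntegerVector rec_step(n_rec);
  double ssum = 0.0;
  for (int j = 0; j < d; ++j) ssum += std::sin(th[j]);
  double etors = torsion_energy(th, v, nf, ph, scaled, gamma);
  int n_acc = 0, ir = 0;
  for (int i = 1; i <= n_steps; ++i) {
    int j = (int)(unif_rand() * d);
    if (j == d) j = d - 1;
    double old = th[j];
    double gj = scaled[j] ? gamma : 1.0;
    double e_old = gj * v[j] * (1.0 + std::cos(nf[j] * old - ph[j]));
    double s_old = ssum;
    double prop = wrap_angle(old + (unif_rand() * 2.0 - 1.0) * step_size);
    double e_new = gj * v[j] * (1.0 + std::cos(nf[j] * prop - ph[j]));
    double s_new = ssum - std::sin(old) + std::sin(prop);
    double sm_old = s_old / d, sm_new = s_new / d;
    double du = (e_new - e_old) + 0.5 * k * (sm_new * sm_new - sm_old * sm_old);
    if (du <= 0.0 || unif_rand() < std::exp(-beta * du)) {
      th[j] = prop;
      ssum = s_new;
      etors += e_new - e_old;
      ++n_acc;
    }
    if (record_interval > 0 && (i % record_interval) == 0) {
      double sm = ssum / d;
      double dudl = dk2 * sm * sm;
      if (dudl_direct)
        dudl += torsion_scaled_part(th, v, nf, ph, scaled);
      rec_step[ir] = i;
      rec_dudl[ir] = dudl;
      rec_u[ir] = etors + 0.5 * k * sm * sm;
      rec_coord[ir] = sm;
      ++ir;
    }
  }
  return List::create(_["theta"] = th, _["step"] = rec_step,
                      _["dudl"] = rec_dudl, _["u"] = rec_u,
                      _["coord"] = rec_coord, _["n_accept"] = n_acc);
}
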