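#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Three-element microtissue model, strain-driven integration.
//
// State vector: (eps_a, eps_pl)
//   eps_a   active-element strain (Hill element)
//   eps_pl  accumulated plastic strain of the parallel (matrix) element
// Branch stresses, for total strain eps:
//   sigma_a = E_s * (eps - eps_a)          (series spring = active branch)
//   sigma_p = E_p * (eps - eps_pl)         (parallel matrix spring)
// Rates:
//   deps_a/dt  = (sigma_a - sigma_max) / eta_a        (linearized Hill)
//   deps_pl/dt = Bingham-Norton overstress flow rule
// Variant codes: 1 = full, 2 = ecm_only (active branch frozen),
// 3 = cell_only (parallel branch absent).

struct ModelP {
  double Es, eta_a, sigma_max, Ep, eta_p, sYt, sYc;
  bool active, parallel;
};

static inline double plastic_rate(double sigma_p, const ModelP& p) {
  // |sigma_p| exactly at yield counts as elastic (continuous rule)
  if (sigma_p > p.sYt)  return (sigma_p - p.sYt) / p.eta_p;
  if (sigma_p < -p.sYc) return (sigma_p + p.sYc) / p.eta_p;
  return 0.0;
}

static inline void rhs(double eps, double eps_a, double eps_pl,
                       const ModelP& p, double& da, double& dpl) {
  da = p.active ? (p.Es * (eps - eps_a) - p.sigma_max) / p.eta_a : 0.0;
  dpl = p.parallel ? plastic_rate(p.Ep * (eps - eps_pl), p) : 0.0;
}

// One RK4 step of size h; total strain is linear in time over the step,
// from eps0 (at step start) to eps1 (at step end).
static inline void rk4_step(double h, double eps0, double eps1,
                            const ModelP& p, double& eps_a, double& eps_pl) {
  double epsm = 0.5 * (eps0 + eps1);
  double k1a, k1p, k2a, k2p, k3a, k3p, k4a, k4p;
  rhs(eps0, eps_a, eps_pl, p, k1a, k1p);
  rhs(epsm, eps_a + 0.5 * h * k1a, eps_pl + 0.5 * h * k1p, p, k2a, k2p);
  rhs(epsm, eps_a + 0.5 * h * k2a, eps_pl + 0.5 * h * k2p, p, k3a, k3p);
  rhs(eps1, eps_a + h * k3a, eps_pl + h * k3p, p, k4a, k4p);
  eps_a  += h / 6.0 * (k1a + 2.0 * k2a + 2.0 * k3a + k4a);
  eps_pl += h / 6.0 * (k1p + 2.0 * k2p + 2.0 * k3p + k4p);
}

static ModelP unpack(List params, int variant) {
  ModelP p;
  p.Es = params["E_s"]; p.eta_a = params["eta_a"];
  p.sigma_max = params["sigma_max"];
  p.Ep = params["E_p"]; p.eta_p = params["eta_p"];
  p.sYt = params["sigma_Y_t"]; p.sYc = params["sigma_Y_c"];
  p.active = (variant != 2);
  p.parallel = (variant != 3);
  return p;
}

// Advance the state across one output interval [t0, t1], with total strain
// linear from e0 to e1, using fixed substeps of nominal size dt.
static inline void advance_interval(double t0, double t1, double e0, double e1,
                                    double dt, const ModelP& p,
                                    double& eps_a, double& eps_pl) {
  double span = t1 - t0;
  int n = (int)std::ceil(span / dt - 1e-12);
  if (n < 1) n = 1;
  double h = span / n;
  for (int j = 0; j < n; ++j) {
    double ea = e0 + (e1 - e0) * (double)j / n;
    double eb = e0 + (e1 - e0) * (double)(j + 1) / n;
    rk4_step(h, ea, eb, p, eps_a, eps_pl);
  }
}

// [[Rcpp::export]]
NumericMatrix sim_strain_driven(NumericVector times, NumericVector strain,
                                List params, int variant, double dt,
                                double eps_a0, double eps_pl0) {
  int n = times.size();
  ModelP p = unpack(params, variant);
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("t", "eps_total", "eps_a",
                                          "eps_pl", "sigma_a", "sigma_p");
  double eps_a = eps_a0, eps_pl = eps_pl0;
  for (int i = 0; i < n; ++i) {
    if (i > 0)
      advance_interval(times[i - 1], times[i], strain[i - 1], strain[i],
                       dt, p, eps_a, eps_pl);
    out(i, 0) = times[i];
    out(i, 1) = strain[i];
    out(i, 2) = eps_a;
    out(i, 3) = eps_pl;
    out(i, 4) = p.active ? p.Es * (strain[i] - eps_a) : 0.0;
    out(i, 5) = p.parallel ? p.Ep * (strain[i] - eps_pl) : 0.0;
  }
  return out;
}

// Force-controlled stretch: at every output time the applied incremental
// load (uN) must balance the pillar restoring force plus the tissue stress
// increment, kL * eps + A * (sigma - sigma0) = F_applied(t), solved for the
// end-of-interval strain by bisection (the tissue's instantaneous stiffness
// is positive, so the balance residual is monotone in strain).
// kL_uN: pillar spring constant times effective tissue length, uN per unit
// strain; A_uN_per_kPa: cross-section area converted so sigma [kPa] * A
// gives uN; sigma0_kPa: baseline (pre-actuation) total stress.
// [[Rcpp::export]]
NumericMatrix sim_force_controlled(NumericVector times, NumericVector force_uN,
                                   List params, int variant, double dt,
                                   double eps_a0, double eps_pl0,
                                   double kL_uN, double A_uN_per_kPa,
                                   double sigma0_kPa, double tol_uN) {
  int n = times.size();
  ModelP p = unpack(params, variant);
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("t", "eps_total", "eps_a",
                                          "eps_pl", "sigma_a", "sigma_p");
  double eps_a = eps_a0, eps_pl = eps_pl0, eps = 0.0;
  out(0, 0) = times[0]; out(0, 1) = 0.0;
  out(0, 2) = eps_a; out(0, 3) = eps_pl;
  out(0, 4) = p.active ? p.Es * (0.0 - eps_a) : 0.0;
  out(0, 5) = p.parallel ? p.Ep * (0.0 - eps_pl) : 0.0;

  for (int i = 1; i < n; ++i) {
    double t0 = times[i - 1], t1 = times[i];
    double target = force_uN[i];

    // residual of the force balance for a trial end-of-interval strain
    auto residual = [&](double e_end, double& ea_out, double& epl_out) {
      double ea = eps_a, epl = eps_pl;
      advance_interval(t0, t1, eps, e_end, dt, p, ea, epl);
      double sa = p.active ? p.Es * (e_end - ea) : 0.0;
      double sp = p.parallel ? p.Ep * (e_end - epl) : 0.0;
      ea_out = ea; epl_out = epl;
      return kL_uN * e_end + A_uN_per_kPa * (sa + sp - sigma0_kPa) - target;
    };

    double ea_tmp, epl_tmp;
    double lo = eps - 0.2, hi = eps + 0.2;
    int guard = 0;
    while (residual(lo, ea_tmp, epl_tmp) > 0 && guard++ < 50) lo -= 0.2;
    guard = 0;
    while (residual(hi, ea_tmp, epl_tmp) < 0 && guard++ < 50) hi += 0.2;
    if (residual(lo, ea_tmp, epl_tmp) > 0 || residual(hi, ea_tmp, epl_tmp) < 0)
      stop("force balance could not be bracketed at t = %f", t1);

    double mid = 0.5 * (lo + hi), r = 0.0;
    for (int it = 0; it < 200; ++it) {
      mid = 0.5 * (lo + hi);
      r = residual(mid, ea_tmp, epl_tmp);
      if (std::fabs(r) < tol_uN) break;
      if (r > 0) hi = mid; else lo = mid;
    }
    if (std::fabs(r) >= tol_uN)
      stop("force balance did not converge at t = %f (residual %g uN)", t1, r);

    eps = mid; eps_a = ea_tmp; eps_pl = epl_tmp;
    out(i, 0) = t1; out(i, 1) = eps;
    out(i, 2) = eps_a; out(i, 3) = eps_pl;
    out(i, 4) = p.active ? p.Es * (eps - eps_a) : 0.0;
    out(i, 5) = p.parallel ? p.Ep * (eps - eps_pl) : 0.0;
  }
  return out;
}
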