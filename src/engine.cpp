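#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Core recurrences for the proportions of senescent (S) and damaged (D)
// cells in a well-mixed tissue.  Per step t:
//   alpha_t = min(1, alpha * t)
//   delta_t = min((1 - S - D) * alpha_t * (1 + S^rDamageToCS), 1 - S - D)
//   D'      = (D + delta)(1 - gamma)(1 - sigma) + gamma (D + delta) D / (1 - S)
//   S'      = S + (D + delta)(1 - gamma) sigma
// delta is clamped to the healthy pool so proportions stay in the simplex;
// the replacement term is guarded at S = 1 (frozen tissue, no division).

namespace {

inline double pow0(double base, double expo) {
  // 0^0 := 0 here: an organism with no damaged (senescent) cells cannot
  // die of cancer (ageing) whatever the resilience exponent.
  if (base <= 0.0) return 0.0;
  return std::pow(base, expo);
}

struct Tissue {
  double S, D;
  double alpha, gamma, sigma, rD;
  Tissue(double alpha_, double gamma_, double sigma_, double rD_,
         double S0, double D0)
    : S(S0), D(D0), alpha(alpha_), gamma(gamma_), sigma(sigma_), rD(rD_) {}

  double delta_at(int t) const {
    double pool = 1.0 - S - D;
    if (pool <= 0.0) return 0.0;
    double at = alpha * t;
    if (at > 1.0) at = 1.0;
    double d = pool * at * (1.0 + pow0(S, rD));
    return d > pool ? pool : d;
  }

  // advance one step using delta computed at time t
  void step(int t) {
    double delta = delta_at(t);
    double Dtot = D + delta;
    double repl = 0.0;
    if (1.0 - S > 0.0) repl = gamma * Dtot * D / (1.0 - S);
    double Dn = Dtot * (1.0 - gamma) * (1.0 - sigma) + repl;
    double Sn = S + Dtot * (1.0 - gamma) * sigma;
    D = Dn;
    S = Sn;
  }
};

} // namespace

// Tissue trajectory alone: rows t0..end with columns (t, S, D, delta).
// Stops when the healthy pool falls below stop_eps or at the horizon.
// [[Rcpp::export(name = ".tissue_path_cpp")]]
NumericMatrix tissue_path_cpp(double alpha, double gamma, double sigma,
                              double r_damage_to_cs,
                              int t0, double S0, double D0,
                              int horizon, double stop_eps) {
  Tissue tis(alpha, gamma, sigma, r_damage_to_cs, S0, D0);
  std::vector<double> tv, Sv, Dv, dv;
  tv.reserve(1024); Sv.reserve(1024); Dv.reserve(1024); dv.reserve(1024);
  for (int t = t0; t <= horizon; ++t) {
    double delta = tis.delta_at(t);
    tv.push_back(t); Sv.push_back(tis.S); Dv.push_back(tis.D);
    dv.push_back(delta);
    if (1.0 - tis.S - tis.D < stop_eps) break;
    tis.step(t);
  }
  int n = tv.size();
  NumericMatrix out(n, 4);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = tv[i]; out(i, 1) = Sv[i]; out(i, 2) = Dv[i]; out(i, 3) = dv[i];
  }
  colnames(out) = CharacterVector::create("t", "S", "D", "delta");
  return out;
}

// Full demographic path: per-age tissue state plus survival components and
// survivorship l_x (product of p_C * p_S * p_E up to, not including, age t).
// Stops when l_x < tail_eps or at the horizon; the last kept row still has
// l_x >= tail_eps.  Pass ext_m = 0 for the captive / intrinsic-only setting.
// [[Rcpp::export(name = ".demographic_path_cpp")]]
NumericMatrix demographic_path_cpp(double alpha, double gamma, double sigma,
                                   double r_damage_to_cs,
                                   double r_cancer_to_dc,
                                   double r_senesc_to_cs,
                                   double ext_m,
                                   int t0, double S0, double D0,
                                   int horizon, double tail_eps) {
  Tissue tis(alpha, gamma, sigma, r_damage_to_cs, S0, D0);
  double pE = 1.0 - ext_m;
  double lx = 1.0;
  std::vector<double> tv, Sv, Dv, dv, pCv, pSv, lv;
  for (int t = t0; t <= horizon; ++t) {
    double pC = 1.0 - pow0(tis.D, r_cancer_to_dc);
    double pS = 1.0 - pow0(tis.S, r_senesc_to_cs);
    double delta = tis.delta_at(t);
    tv.push_back(t); Sv.push_back(tis.S); Dv.push_back(tis.D);
    dv.push_back(delta); pCv.push_back(pC); pSv.push_back(pS);
    lv.push_back(lx);
    lx *= pC * pS * pE;
    if (lx < tail_eps) break;
    tis.step(t);
  }
  int n = tv.size();
  NumericMatrix out(n, 7);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = tv[i]; out(i, 1) = Sv[i]; out(i, 2) = Dv[i]; out(i, 3) = dv[i];
    out(i, 4) = pCv[i]; out(i, 5) = pSv[i]; out(i, 6) = lv[i];
  }
  colnames(out) = CharacterVector::create("t", "S", "D", "delta",
                                          "p_cancer", "p_ageing", "lx");
  return out;
}

// Lifetime reproductive success LRS = sum_x l_x B_x with
// B_x = max(0, 1 - senesc_repro * x), evaluated for a whole grid of sigma
// values.  This is the hot loop of the sigma* search.
// [[Rcpp::export(name = ".lrs_grid_cpp")]]
NumericVector lrs_grid_cpp(double alpha, double gamma,
                           double r_damage_to_cs,
                           double r_cancer_to_dc,
                           double r_senesc_to_cs,
                           double ext_m, double senesc_repro,
                           NumericVector sigma_grid,
                           int horizon, double tail_eps) {
  int ns = sigma_grid.size();
  NumericVector lrs(ns);
  double pE = 1.0 - ext_m;
  for (int k = 0; k < ns; ++k) {
    Tissue tis(alpha, gamma, sigma_grid[k], r_damage_to_cs, 0.0, 0.0);
    double lx = 1.0, acc = 0.0;
    for (int t = 0; t <= horizon; ++t) {
      double Bx = 1.0 - senesc_repro * t;
      if (Bx <= 0.0) break;  // no further reproduction: LRS complete
      acc += lx * Bx;
      double pC = 1.0 - pow0(tis.D, r_cancer_to_dc);
      double pS = 1.0 - pow0(tis.S, r_senesc_to_cs);
      lx *= pC * pS * pE;
      if (lx < tail_eps) break;
      tis.step(t);
    }
    lrs[k] = acc;
  }
  return lrs;
}
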