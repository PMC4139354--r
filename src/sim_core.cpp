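#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Law codes must stay in sync with .law_code() on the R side:
// 0 verhulst, 1 oc, 2 cc_i, 3 cc_ii, 4 cc_iii, 5 cc_iv, 6 cc_m.
//
// One annual step:
//   dP_t = r * P_t * (K_t - P_t)            (non-normalised logistic form)
//   dK_t = law-specific, evaluated at the pre-step state by default
//          (post_update = true substitutes P_{t+1} in the elasticity term).
// All cost laws reduce bit-for-bit to the OC law at a = 0 because the cost
// term is an exact additive/subtractive zero there.

static inline double dk_for(int law, double p, double k, double dp,
                            double L, double a, double b) {
  switch (law) {
  case 0: return 0.0;                                             // static K
  case 1: return (L / p) * dp;                                    // oc
  case 2: return (L / p - a * std::pow(p, b)) * dp;               // cc_i
  case 3: return ((L - a * std::pow(p, b)) / p) * dp;             // cc_ii
  case 4: return (L / p) * dp - a * std::pow(p, b);               // cc_iii
  case 5: return (L / p) * dp - a * std::pow(k, b);               // cc_iv
  case 6:                                                         // cc_m
    return (L / p - a * std::pow(1e6, 1.0 - b) * std::pow(p, b)) * dp;
  default:
    stop("unknown law code %d", law);
  }
  return NA_REAL; // not reached
}

// [[Rcpp::export]]
List sim_core(int law, double P0, double K0, double r,
              double L, double a, double b,
              int t0, int t_end, bool post_update) {
  const int n = t_end - t0 + 1;
  NumericVector P(n), K(n), dP(n), dK(n);
  double p = P0, k = K0;
  int n_valid = 0;
  int collapse_year = NA_INTEGER;
  std::string collapse_reason = "";

  for (int i = 0; i < n; ++i) {
    P[i] = p;
    K[i] = k;
    double dp = r * p * (k - p);
    double pc = post_update ? (p + dp) : p;
    double dk = dk_for(law, pc, k, dp, L, a, b);
    dP[i] = dp;
    dK[i] = dk;
    n_valid = i + 1;
    if (i == n - 1) break;
    double pn = p + dp;
    double kn = (law == 0) ? k : k + dk;
    if (!(pn > 0.0) || !(kn > 0.0) ||
        !std::isfinite(pn) || !std::isfinite(kn)) {
      collapse_year = t0 + i + 1;
      if (!std::isfinite(pn) || !std::isfinite(kn))
        collapse_reason = "non-finite state";
      else if (!(pn > 0.0))
        collapse_reason = "population fell to or below zero";
      else
        collapse_reason = "carrying capacity fell to or below zero";
      break;
    }
    p = pn;
    k = kn;
  }

  return List::create(
    _["P"] = P, _["K"] = K, _["dP"] = dP, _["dK"] = dK,
    _["n_valid"] = n_valid,
    _["collapse_year"] = collapse_year,
    _["collapse_reason"] = collapse_reason);
}

// Population at a single target year, used heavily inside K0 calibration and
// grid scans. Returns NA_REAL if the trajectory collapses before `year`.
// [[Rcpp::export]]
double sim_p_at(int law, double P0, double K0, double r,
                double L, double a, double b,
                int t0, int year, bool post_update) {
  double p = P0, k = K0;
  for (int t = t0; t < year; ++t) {
    double dp = r * p * (k - p);
    double pc = post_update ? (p + dp) : p;
    double dk = dk_for(law, pc, k, dp, L, a, b);
    p += dp;
    if (law != 0) k += dk;
    if (!(p > 0.0) || !(k > 0.0) || !std::isfinite(p) || !std::isfinite(k))
      return NA_REAL;
  }
  return p;
}

// Populations at several target years in one pass (years must be sorted
// ascending and >= t0). NA where the trajectory has collapsed.
// [[Rcpp::export]]
NumericVector sim_p_at_years(int law, double P0, double K0, double r,
                             double L, double a, double b,
                             int t0, IntegerVector years, bool post_update) {
  const int m = years.size();
  NumericVector out(m, NA_REAL);
  double p = P0, k = K0;
  int j = 0;
  int t_max = years[m - 1];
  for (int t = t0; t <= t_max; ++t) {
    while (j < m && years[j] == t) out[j++] = p;
    if (t == t_max) break;
    double dp = r * p * (k - p);
    double pc = post_update ? (p + dp) : p;
    double dk = dk_for(law, pc, k, dp, L, a, b);
    p += dp;
    if (law != 0) k += dk;
    if (!(p > 0.0) || !(k > 0.0) || !std::isfinite(p) || !std::isfinite(k))
      break;
  }
  return out;
}
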