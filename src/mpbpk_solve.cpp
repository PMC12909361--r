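// Batched exact solver for the linear mPBPK system.
//
// The model is dC/dt = M C + g with g a constant infusion input on
// [0, T_inf] and zero afterwards, so the solution is available through the
// eigendecomposition of M per subject. Used by the virtual-cohort
// generator, the Monte Carlo prediction intervals and the MCMC benchmark,
// where many subjects/draws are solved per call.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

//' @keywords internal
// [[Rcpp::export(name = ".mpbpk_plasma_batch")]]
arma::mat mpbpk_plasma_batch(const arma::vec& times, const arma::vec& weights,
                             const arma::vec& clp, double sigma1,
                             double sigma2, const Rcpp::List& phys_ref,
                             double dose_per_kg, double T_inf) {
  const int n = weights.n_elem, nt = times.n_elem;
  const double Vp_r = Rcpp::as<double>(phys_ref["V_plasma"]);
  const double Vt_r = Rcpp::as<double>(phys_ref["V_tight"]);
  const double Vl_r = Rcpp::as<double>(phys_ref["V_leaky"]);
  const double Vly_r = Rcpp::as<double>(phys_ref["V_lymph"]);
  const double L_r = Rcpp::as<double>(phys_ref["L"]);
  const double L1_r = Rcpp::as<double>(phys_ref["L1"]);
  const double L2_r = Rcpp::as<double>(phys_ref["L2"]);
  const double sigL = Rcpp::as<double>(phys_ref["sigma_L"]);
  const double ref_w = Rcpp::as<double>(phys_ref["ref_weight"]);

  mat out(n, nt);
  for (int k = 0; k < n; ++k) {
    double s = weights(k) / ref_w;
    double Vp = Vp_r * s, Vt = Vt_r * s, Vl = Vl_r * s, Vly = Vly_r * s;
    double L = L_r * s, L1 = L1_r * s, L2 = L2_r * s;
    double k1 = L1 * (1.0 - sigma1), k2 = L2 * (1.0 - sigma2);
    double kL1 = L1 * (1.0 - sigL), kL2 = L2 * (1.0 - sigL);
    mat M(4, 4, fill::zeros);
    M(0, 0) = -(k1 + k2 + clp(k)) / Vp;
    M(0, 3) = L / Vp;
    M(1, 0) = k1 / Vt;  M(1, 1) = -kL1 / Vt;
    M(2, 0) = k2 / Vl;  M(2, 2) = -kL2 / Vl;
    M(3, 1) = kL1 / Vly; M(3, 2) = kL2 / Vly; M(3, 3) = -L / Vly;
    vec g(4, fill::zeros);
    g(0) = dose_per_kg * weights(k) / T_inf / Vp;

    cx_vec lam;
    cx_mat P;
    if (!eig_gen(lam, P, M)) Rcpp::stop("eigendecomposition failed");
    cx_mat Pinv = inv(P);
    cx_vec Mg = Pinv * cx_vec(solve(M, g), vec(4, fill::zeros));
    // during infusion: C(t) = P (exp(lam t) - 1) Pinv M^-1 g
    // eigenbasis coordinates of the state at the end of infusion
    cx_vec w0(4);
    for (int q = 0; q < 4; ++q)
      w0(q) = (std::exp(lam(q) * T_inf) - 1.0) * Mg(q);
    for (int j = 0; j < nt; ++j) {
      double t = times(j);
      cx_double val(0, 0);
      if (t <= T_inf) {
        for (int q = 0; q < 4; ++q)
          val += P(0, q) * (std::exp(lam(q) * t) - 1.0) * Mg(q);
      } else {
        double dt = t - T_inf;
        for (int q = 0; q < 4; ++q)
          val += P(0, q) * std::exp(lam(q) * dt) * w0(q);
      }
      out(k, j) = val.real();
    }
  }
  return out;
}
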