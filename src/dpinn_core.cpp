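// Training core for the distributional PINN estimator.
//
// The loss couples a small tanh network (outputting concentration moments
// over time) with a sampling-based ODE residual: per collocation time,
// draws from a joint log-normal over (concentration, ODE parameters) are
// denoised, pushed through the model RHS, and summarised into estimates of
// the observed-moment time derivatives, which the network's AD time
// derivatives must match. Gradients with respect to every trainable
// (network weights, log-scale population parameters, cross-correlations,
// residual SD, point parameters) are accumulated by a hand-written reverse
// pass mirroring the forward computation; correctness is enforced by
// finite-difference tests on the R side.
//
// Model ids: 1 = one-compartment IV bolus (eta = (Vd, ke), IC loss active),
// 2 = minimal PBPK mAb (eta = (CLp), point params (sigma1_raw, sigma2_raw),
// unobserved tight/leaky/lymph states carried as extra mean channels).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

inline double softplus(double x) { return x > 30.0 ? x : std::log1p(std::exp(x)); }
inline double sigmoid_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Config {
  int model_id, n_eta, n_point, n_unobs, n_out, n_samples, n_ic;
  ivec layer_sizes;
  bool spread_is_sd, ic_enabled, literal_sd;
  vec tc, obs_t, obs_mean, obs_spread, lambda, x_min, x_max;
  double t0, dose, t_min, t_max, spread_bias, var_floor, sd_floor, sigma_fixed;
  // mPBPK reference coefficients (weight-invariant ratios precomputed)
  double Vp_r, Vt_r, Vl_r, Vly_r, L_r, L1_r, L2_r, sigmaL, ref_w;
  double Tinf, dose_per_kg, bw_min, bw_max;
  double jitter;
  bool denoise_stochastic, input_log_time, relative_ode;
};

Config parse_config(const Rcpp::List& cfg) {
  Config c;
  c.model_id = Rcpp::as<int>(cfg["model_id"]);
  c.n_eta = Rcpp::as<int>(cfg["n_eta"]);
  c.n_point = Rcpp::as<int>(cfg["n_point"]);
  c.n_unobs = Rcpp::as<int>(cfg["n_unobs"]);
  c.layer_sizes = Rcpp::as<ivec>(cfg["layer_sizes"]);
  c.n_out = c.layer_sizes(c.layer_sizes.n_elem - 1);
  c.spread_is_sd = Rcpp::as<bool>(cfg["spread_is_sd"]);
  c.ic_enabled = Rcpp::as<bool>(cfg["ic_enabled"]);
  c.literal_sd = Rcpp::as<bool>(cfg["literal_sd_scaling"]);
  c.tc = Rcpp::as<vec>(cfg["tc"]);
  c.obs_t = Rcpp::as<vec>(cfg["obs_t"]);
  c.obs_mean = Rcpp::as<vec>(cfg["obs_mean"]);
  c.obs_spread = Rcpp::as<vec>(cfg["obs_spread"]);
  c.lambda = Rcpp::as<vec>(cfg["lambda"]);
  c.x_min = Rcpp::as<vec>(cfg["x_min"]);
  c.x_max = Rcpp::as<vec>(cfg["x_max"]);
  c.t0 = Rcpp::as<double>(cfg["t0"]);
  c.dose = Rcpp::as<double>(cfg["dose"]);
  c.t_min = Rcpp::as<double>(cfg["t_min"]);
  c.t_max = Rcpp::as<double>(cfg["t_max"]);
  c.n_samples = Rcpp::as<int>(cfg["n_samples"]);
  c.n_ic = Rcpp::as<int>(cfg["n_ic_samples"]);
  c.spread_bias = Rcpp::as<double>(cfg["spread_bias"]);
  c.var_floor = Rcpp::as<double>(cfg["var_floor"]);
  c.sd_floor = Rcpp::as<double>(cfg["sd_floor"]);
  c.sigma_fixed = Rcpp::as<double>(cfg["sigma_fixed"]);
  c.denoise_stochastic = Rcpp::as<bool>(cfg["denoise_stochastic"]);
  c.input_log_time = Rcpp::as<bool>(cfg["input_log_time"]);
  c.relative_ode = Rcpp::as<bool>(cfg["relative_ode_residuals"]);
  c.jitter = 1e-6;
  if (c.model_id == 2) {
    Rcpp::List ph = cfg["phys"];
    c.Vp_r = Rcpp::as<double>(ph["V_plasma"]);
    c.Vt_r = Rcpp::as<double>(ph["V_tight"]);
    c.Vl_r = Rcpp::as<double>(ph["V_leaky"]);
    c.Vly_r = Rcpp::as<double>(ph["V_lymph"]);
    c.L_r = Rcpp::as<double>(ph["L"]);
    c.L1_r = Rcpp::as<double>(ph["L1"]);
    c.L2_r = Rcpp::as<double>(ph["L2"]);
    c.sigmaL = Rcpp::as<double>(ph["sigma_L"]);
    c.ref_w = Rcpp::as<double>(ph["ref_weight"]);
    c.Tinf = Rcpp::as<double>(cfg["T_inf"]);
    c.dose_per_kg = Rcpp::as<double>(cfg["dose_per_kg"]);
    c.bw_min = Rcpp::as<double>(cfg["bw_min"]);
    c.bw_max = Rcpp::as<double>(cfg["bw_max"]);
  } else {
    c.Vp_r = c.Vt_r = c.Vl_r = c.Vly_r = 1.0;
    c.L_r = c.L1_r = c.L2_r = c.sigmaL = c.ref_w = 1.0;
    c.Tinf = c.dose_per_kg = c.bw_min = c.bw_max = 0.0;
  }
  return c;
}

int n_weight_par(const Config& c) {
  int n = 0;
  for (uword l = 0; l + 1 < c.layer_sizes.n_elem; ++l)
    n += c.layer_sizes(l) * c.layer_sizes(l + 1) + c.layer_sizes(l + 1);
  return n;
}

// Parameter vector layout:
//   [weights | mu_eta | sd_eta_raw | rho_raw | cross_raw | sigma_raw | point_raw]
struct ParLayout {
  int nw, n_eta, n_rho, n_point, total;
  int off_mu, off_sd, off_rho, off_cross, off_sigma, off_point;
};

ParLayout layout_of(const Config& c) {
  ParLayout L;
  L.nw = n_weight_par(c);
  L.n_eta = c.n_eta;
  L.n_rho = c.n_eta * (c.n_eta - 1) / 2;
  L.n_point = c.n_point;
  L.off_mu = L.nw;
  L.off_sd = L.off_mu + c.n_eta;
  L.off_rho = L.off_sd + c.n_eta;
  L.off_cross = L.off_rho + L.n_rho;
  L.off_sigma = L.off_cross + c.n_eta;
  L.off_point = L.off_sigma + 1;
  L.total = L.off_point + c.n_point;
  return L;
}

struct Losses {
  double ode_mean = 0, ode_var = 0, ic_mean = 0, ic_var = 0,
         data_mean = 0, data_var = 0;
  double total(const vec& lam) const {
    return lam(0) * ode_mean + lam(1) * ode_var + lam(2) * ic_mean +
           lam(3) * ic_var + lam(4) * data_mean + lam(5) * data_var;
  }
};

// Full forward + reverse evaluation with externally supplied draws.
// draws_z: d * Ns * Ncp standard normals, index [l + d*(i + Ns*j)];
// draws_u: Ns * Ncp; draws_bw: Ns * Ncp uniforms in [0,1] (model 2);
// draws_zeta/draws_om: n_ic normals (model 1 IC).
Losses eval_core(const Config& c, const ParLayout& lay, const vec& par,
                 const vec& draws_z, const vec& draws_u, const vec& draws_bw,
                 const vec& draws_zeta, const vec& draws_om,
                 vec& grad, bool want_grad) {
  const int Ncp = c.tc.n_elem, Nobs = c.obs_t.n_elem, Ns = c.n_samples;
  const int d = 1 + c.n_eta;
  const int nL = c.layer_sizes.n_elem - 1;  // number of weight layers
  const int nt = Ncp + Nobs + 1;            // last column = t0

  // --- unpack weights ---
  std::vector<mat> W(nL);
  std::vector<vec> B(nL);
  {
    int pos = 0;
    for (int l = 0; l < nL; ++l) {
      int ni = c.layer_sizes(l), no = c.layer_sizes(l + 1);
      W[l] = mat(&par[pos], no, ni);
      pos += no * ni;
      B[l] = vec(&par[pos], no);
      pos += no;
    }
  }
  vec mu_eta = par.subvec(lay.off_mu, lay.off_mu + c.n_eta - 1);
  vec sd_raw = par.subvec(lay.off_sd, lay.off_sd + c.n_eta - 1);
  vec s_eta(c.n_eta);
  for (int k = 0; k < c.n_eta; ++k) s_eta(k) = softplus(sd_raw(k)) + 1e-8;
  double rho = 0, rho_raw = 0;
  if (lay.n_rho == 1) { rho_raw = par(lay.off_rho); rho = std::tanh(rho_raw); }
  vec cross_raw = par.subvec(lay.off_cross, lay.off_cross + c.n_eta - 1);
  vec cr(c.n_eta);
  for (int k = 0; k < c.n_eta; ++k) cr(k) = std::tanh(cross_raw(k));
  double sigma, sig_chain = 0;
  bool sigma_trainable = c.sigma_fixed < 0;
  if (sigma_trainable) {
    sigma = softplus(par(lay.off_sigma)) + 1e-8;
    sig_chain = sigmoid_(par(lay.off_sigma));
  } else sigma = c.sigma_fixed;
  double s1 = 0, s2 = 0, g2 = 0;  // reflection coefficients (model 2)
  if (c.n_point == 2) {
    double r1 = par(lay.off_point), r2 = par(lay.off_point + 1);
    s1 = sigmoid_(r1);
    g2 = sigmoid_(r2);
    s2 = s1 * g2;
  }

  // --- joint correlation Cholesky (closed form, d <= 3) ---
  // rows: 0 = concentration (unit), 1..n_eta = parameters
  mat Lr(d, d, fill::zeros);
  Lr(0, 0) = 1.0;
  bool clamp11 = false, clamp22 = false;
  double L11 = 1, L21 = 0;
  if (d >= 2) {
    Lr(1, 0) = cr(0);
    double a11 = 1.0 - cr(0) * cr(0);
    if (a11 < c.jitter) { a11 = c.jitter; clamp11 = true; }
    L11 = std::sqrt(a11);
    Lr(1, 1) = L11;
  }
  if (d == 3) {
    Lr(2, 0) = cr(1);
    L21 = (rho - cr(0) * cr(1)) / L11;
    Lr(2, 1) = L21;
    double a22 = 1.0 - cr(1) * cr(1) - L21 * L21;
    if (a22 < c.jitter) { a22 = c.jitter; clamp22 = true; }
    Lr(2, 2) = std::sqrt(a22);
  }

  // --- doubled network forward over all times ---
  vec tall(nt);
  for (int j = 0; j < Ncp; ++j) tall(j) = c.tc(j);
  for (int j = 0; j < Nobs; ++j) tall(Ncp + j) = c.obs_t(j);
  tall(nt - 1) = c.t0;
  double span_t = c.t_max - c.t_min;
  bool log_time = c.input_log_time;
  double log_span = std::log1p(c.t_max - c.t_min);
  std::vector<mat> A(nL + 1), Adot(nL + 1), Zdot(nL);
  A[0] = mat(1, nt);
  Adot[0] = mat(1, nt);
  for (int j = 0; j < nt; ++j) {
    if (log_time) {
      // log-warped input: uniform network resolution across time decades
      A[0](0, j) = std::log1p(tall(j) - c.t_min) / log_span;
      Adot[0](0, j) = 1.0 / ((1.0 + tall(j) - c.t_min) * log_span);
    } else {
      A[0](0, j) = (tall(j) - c.t_min) / span_t;
      Adot[0](0, j) = 1.0 / span_t;
    }
  }
  for (int l = 0; l < nL - 1; ++l) {
    mat z = W[l] * A[l];
    z.each_col() += B[l];
    Zdot[l] = W[l] * Adot[l];
    A[l + 1] = tanh(z);
    Adot[l + 1] = (1.0 - square(A[l + 1])) % Zdot[l];
  }
  mat zL = W[nL - 1] * A[nL - 1];
  zL.each_col() += B[nL - 1];
  mat zLdot = W[nL - 1] * Adot[nL - 1];
  // output transform + unscale
  mat Y(c.n_out, nt), Ydot(c.n_out, nt), Sig(c.n_out, nt);
  for (int o = 0; o < c.n_out; ++o) {
    double dx = c.x_max(o) - c.x_min(o);
    bool spread_ch = (o == 1);
    double fac = dx;
    if (c.literal_sd && c.spread_is_sd && spread_ch) fac = dx * dx;
    for (int j = 0; j < nt; ++j) {
      double s = sigmoid_(zL(o, j));
      Sig(o, j) = s;
      double y = softplus(zL(o, j)) + (spread_ch ? c.spread_bias : 0.0);
      Y(o, j) = c.x_min(o) + dx * y;
      Ydot(o, j) = fac * s * zLdot(o, j);
    }
  }

  Losses L;
  mat Ybar(c.n_out, nt, fill::zeros), Ydotbar(c.n_out, nt, fill::zeros);
  double mu_bar_acc[3] = {0, 0, 0};     // mu_eta adjoints
  double s_bar_acc[3] = {0, 0, 0};      // s_eta adjoints (pre-softplus-chain)
  double sig_bar = 0;                   // sigma adjoint (pre-chain)
  mat Lr_bar(d, d, fill::zeros);
  double s1_bar = 0, s2_bar = 0;

  // --- data loss ---
  for (int j = 0; j < Nobs; ++j) {
    int g = Ncp + j;
    double rm = Y(0, g) - c.obs_mean(j);
    double rv = Y(1, g) - c.obs_spread(j);
    L.data_mean += rm * rm / Nobs;
    L.data_var += rv * rv / Nobs;
    if (want_grad) {
      Ybar(0, g) += c.lambda(4) * 2.0 * rm / Nobs;
      Ybar(1, g) += c.lambda(5) * 2.0 * rv / Nobs;
    }
  }

  // --- initial-condition loss (model 1) ---
  if (c.ic_enabled && c.n_ic >= 2) {
    int n = c.n_ic;
    vec C0(n);
    double M0 = 0;
    for (int i = 0; i < n; ++i) {
      C0(i) = c.dose * std::exp(-mu_eta(0) - s_eta(0) * draws_zeta(i) +
                                sigma * draws_om(i));
      M0 += C0(i);
    }
    M0 /= n;
    double V0 = 0;
    for (int i = 0; i < n; ++i) V0 += (C0(i) - M0) * (C0(i) - M0);
    V0 /= (n - 1);
    int g0 = nt - 1;
    double rm = Y(0, g0) - M0, rv = Y(1, g0) - V0;
    L.ic_mean += rm * rm;
    L.ic_var += rv * rv;
    if (want_grad) {
      Ybar(0, g0) += c.lambda(2) * 2.0 * rm;
      Ybar(1, g0) += c.lambda(3) * 2.0 * rv;
      double M0bar = -c.lambda(2) * 2.0 * rm;
      double V0bar = -c.lambda(3) * 2.0 * rv;
      for (int i = 0; i < n; ++i) {
        double cb = M0bar / n + V0bar * 2.0 * (C0(i) - M0) / (n - 1);
        mu_bar_acc[0] += cb * (-C0(i));
        s_bar_acc[0] += cb * (-draws_zeta(i) * C0(i));
        if (sigma_trainable) sig_bar += cb * draws_om(i) * C0(i);
      }
    }
  }

  // --- ODE losses over collocation points ---
  const double Aexp = std::exp(sigma * sigma / 2.0);
  const double Bexp = std::exp(sigma * sigma);
  // mPBPK weight-invariant ratios
  double aL = 0, a1c = 0, a2c = 0, a0base = 0;
  double b1t = 0, b2t = 0, b1l = 0, b2l = 0, b3 = 0, b4 = 0, b5 = 0;
  if (c.model_id == 2) {
    aL = c.L_r / c.Vp_r;
    a1c = c.L1_r * (1.0 - s1) / c.Vp_r;
    a2c = c.L2_r * (1.0 - s2) / c.Vp_r;
    a0base = c.dose_per_kg * c.ref_w / (c.Tinf * c.Vp_r);
    b1t = c.L1_r * (1.0 - s1) / c.Vt_r;
    b2t = c.L1_r * (1.0 - c.sigmaL) / c.Vt_r;
    b1l = c.L2_r * (1.0 - s2) / c.Vl_r;
    b2l = c.L2_r * (1.0 - c.sigmaL) / c.Vl_r;
    b3 = c.L1_r * (1.0 - c.sigmaL) / c.Vly_r;
    b4 = c.L2_r * (1.0 - c.sigmaL) / c.Vly_r;
    b5 = c.L_r / c.Vly_r;
  }

  vec Ci(Ns), dCi(Ns), eta_rhs(Ns), mloc(Ns), w0v(Ns), uv(Ns), sloc(Ns);
  vec etaV(Ns), mlocV(Ns);  // Vd draws (model 1) kept for completeness

  for (int j = 0; j < Ncp; ++j) {
    double m = Y(0, j);
    double sp = Y(1, j);
    double v, sd_hat = 0;
    bool sd_clamped = false;
    if (c.spread_is_sd) {
      sd_hat = sp;
      if (sd_hat < c.sd_floor) { sd_hat = c.sd_floor; sd_clamped = true; }
      v = sd_hat * sd_hat;
    } else {
      v = std::max(sp, c.var_floor);
    }
    double q = std::log1p(v / (m * m));
    double muC = std::log(m) - q / 2.0;
    // concentration block actually sampled: observed (noisy) scale when
    // denoising stochastically, true (denoised) scale otherwise
    double vT = q;
    bool vT_clamped = false;
    if (!c.denoise_stochastic) {
      vT = q - sigma * sigma;
      if (vT < 1e-10) { vT = 1e-10; vT_clamped = true; }
    }
    double sT = std::sqrt(vT);

    double Cbar = 0, Dbar = 0;
    double mbar_u[3] = {0, 0, 0};  // unobserved mean RHS accumulators
    for (int i = 0; i < Ns; ++i) {
      const double* zz = &draws_z[(size_t)d * (i + (size_t)Ns * j)];
      double w0 = zz[0];
      double u = draws_u[(size_t)i + (size_t)Ns * j];
      double lC = muC + sT * w0;
      if (c.denoise_stochastic) lC -= sigma * u;
      double C = std::exp(lC);
      Ci(i) = C;
      w0v(i) = w0;
      uv(i) = u;
      double dC;
      if (c.model_id == 1) {
        // eta = (Vd, ke); RHS uses ke only
        double m1 = Lr(1, 0) * zz[0] + Lr(1, 1) * zz[1];
        double m2 = Lr(2, 0) * zz[0] + Lr(2, 1) * zz[1] + Lr(2, 2) * zz[2];
        double ke = std::exp(mu_eta(1) + s_eta(1) * m2);
        etaV(i) = std::exp(mu_eta(0) + s_eta(0) * m1);
        mlocV(i) = m1;
        eta_rhs(i) = ke;
        mloc(i) = m2;
        dC = -ke * C;
      } else {
        double m1 = Lr(1, 0) * zz[0] + Lr(1, 1) * zz[1];
        double CLp = std::exp(mu_eta(0) + s_eta(0) * m1);
        eta_rhs(i) = CLp;
        mloc(i) = m1;
        double bw = c.bw_min + (c.bw_max - c.bw_min) *
                    draws_bw[(size_t)i + (size_t)Ns * j];
        double scl = bw / c.ref_w;
        sloc(i) = scl;
        double a0 = (c.tc(j) <= c.Tinf) ? a0base : 0.0;
        double Cly = Y(4, j);
        dC = a0 + aL * Cly - C * (a1c + a2c + CLp / (c.Vp_r * scl));
        // unobserved-state mean residual pieces (tight depends on C)
        mbar_u[0] += b1t * C;
      }
      dCi(i) = dC;
      Cbar += C;
      Dbar += dC;
    }
    Cbar /= Ns;
    Dbar /= Ns;
    double Vh = 0;
    for (int i = 0; i < Ns; ++i)
      Vh += (Ci(i) - Cbar) * (dCi(i) - Dbar);
    Vh *= 2.0 / (Ns - 1);

    double rE = Aexp * Dbar;
    double rV = Bexp * (2.0 * Cbar * Dbar * (Bexp - 1.0) + Bexp * Vh);

    // optional per-point relative weighting: concentrations span several
    // decades over a long horizon, so absolute residuals at late times
    // (where the kinetic information lives) would be numerically invisible
    double wE = 1.0, wV = 1.0, wE_scale = 0, wV_scale = 0;
    if (c.relative_ode) {
      wE_scale = std::max(m, 1e-3);
      wV_scale = std::max(c.spread_is_sd ? sd_hat : v, 1e-3);
      wE = 1.0 / (wE_scale * wE_scale);
      wV = 1.0 / (wV_scale * wV_scale);
    }
    double residE = Ydot(0, j) - rE;
    L.ode_mean += wE * residE * residE / Ncp;

    double residV, rS = 0;
    if (c.spread_is_sd) {
      rS = rV / (2.0 * sd_hat);
      residV = Ydot(1, j) - rS;
    } else {
      residV = Ydot(1, j) - rV;
    }
    L.ode_var += wV * residV * residV / Ncp;

    // unobserved-state mean residuals (model 2), each normalised by its
    // own concentration scale in relative mode (the lymph return feeds
    // back into the plasma balance, so a loosely pinned lymph curve can
    // mask clearance)
    double fbt = 0, fbl = 0, fblym = 0, residT = 0, residLk = 0, residLy = 0;
    double wU[3] = {1.0, 1.0, 1.0}, wU_scale[3] = {0, 0, 0};
    if (c.model_id == 2) {
      double Ct = Y(2, j), Cl = Y(3, j), Cly = Y(4, j);
      fbt = mbar_u[0] / Ns - b2t * Ct;
      fbl = b1l * Cbar - b2l * Cl;
      fblym = b3 * Ct + b4 * Cl - b5 * Cly;
      residT = Ydot(2, j) - fbt;
      residLk = Ydot(3, j) - fbl;
      residLy = Ydot(4, j) - fblym;
      if (c.relative_ode) {
        for (int s = 0; s < 3; ++s) {
          wU_scale[s] = std::max(Y(2 + s, j), 1e-3);
          wU[s] = 1.0 / (wU_scale[s] * wU_scale[s]);
        }
      }
      L.ode_mean += (wU[0] * residT * residT + wU[1] * residLk * residLk +
                     wU[2] * residLy * residLy) / Ncp;
    }

    if (!want_grad) continue;

    // --- reverse through this collocation point ---
    double gE = c.lambda(0) * 2.0 * wE * residE / Ncp;
    Ydotbar(0, j) += gE;
    double rEbar = -gE;
    double gV = c.lambda(1) * 2.0 * wV * residV / Ncp;
    Ydotbar(1, j) += gV;
    double rVbar, sd_bar_direct = 0;
    if (c.spread_is_sd) {
      double rSbar = -gV;
      rVbar = rSbar / (2.0 * sd_hat);
      if (!sd_clamped) sd_bar_direct = -rSbar * rV / (2.0 * sd_hat * sd_hat);
    } else {
      rVbar = -gV;
    }

    double Dbar_bar = rEbar * Aexp;
    double Cbar_bar = 0, Vh_bar = 0;
    Cbar_bar += rVbar * Bexp * 2.0 * Dbar * (Bexp - 1.0);
    Dbar_bar += rVbar * Bexp * 2.0 * Cbar * (Bexp - 1.0);
    Vh_bar = rVbar * Bexp * Bexp;
    if (sigma_trainable) {
      double dA = sigma * Aexp, dB = 2.0 * sigma * Bexp;
      sig_bar += rEbar * Dbar * dA;
      sig_bar += rVbar * (dB * (2.0 * Cbar * Dbar * (Bexp - 1.0) + Bexp * Vh) +
                          Bexp * (2.0 * Cbar * Dbar * dB + dB * Vh));
    }

    double gUt = 0, gUl = 0, gUly = 0, fbt_bar = 0, fbl_bar = 0, fbly_bar = 0;
    if (c.model_id == 2) {
      gUt = c.lambda(0) * 2.0 * wU[0] * residT / Ncp;
      gUl = c.lambda(0) * 2.0 * wU[1] * residLk / Ncp;
      gUly = c.lambda(0) * 2.0 * wU[2] * residLy / Ncp;
      Ydotbar(2, j) += gUt;
      Ydotbar(3, j) += gUl;
      Ydotbar(4, j) += gUly;
      fbt_bar = -gUt;
      fbl_bar = -gUl;
      fbly_bar = -gUly;
      // deterministic pieces of the unobserved residuals
      Ybar(2, j) += fbt_bar * (-b2t) + fbly_bar * b3;
      Ybar(3, j) += fbl_bar * (-b2l) + fbly_bar * b4;
      Ybar(4, j) += fbly_bar * (-b5);
      Cbar_bar += fbl_bar * b1l;  // fbl depends on Cbar
      // sigma2 via b1l = L2(1-s2)/Vl
      s2_bar += fbl_bar * (-c.L2_r / c.Vl_r) * Cbar;
    }

    // gradient of the relative weights themselves (they are functions of
    // the surrogate outputs)
    if (c.relative_ode) {
      if (m > 1e-3)
        Ybar(0, j) += c.lambda(0) * residE * residE / Ncp *
                      (-2.0 * wE / wE_scale);
      bool spread_free = c.spread_is_sd ? !sd_clamped : (sp >= c.var_floor);
      if (wV_scale > 1e-3 && spread_free)
        Ybar(1, j) += c.lambda(1) * residV * residV / Ncp *
                      (-2.0 * wV / wV_scale);
      if (c.model_id == 2) {
        double sq[3] = {residT * residT, residLk * residLk, residLy * residLy};
        for (int s = 0; s < 3; ++s) {
          if (wU_scale[s] > 1e-3)
            Ybar(2 + s, j) += c.lambda(0) * sq[s] / Ncp *
                              (-2.0 * wU[s] / wU_scale[s]);
        }
      }
    }

    double muC_bar = 0, sC_bar = 0;
    for (int i = 0; i < Ns; ++i) {
      double C_bar_i = Vh_bar * 2.0 / (Ns - 1) * (dCi(i) - Dbar) +
                       Cbar_bar / Ns;
      double dC_bar_i = Vh_bar * 2.0 / (Ns - 1) * (Ci(i) - Cbar) +
                        Dbar_bar / Ns;
      double eta_bar_i;
      if (c.model_id == 1) {
        C_bar_i += dC_bar_i * (-eta_rhs(i));
        eta_bar_i = dC_bar_i * (-Ci(i));
      } else {
        double coef = a1c + a2c + eta_rhs(i) / (c.Vp_r * sloc(i));
        C_bar_i += dC_bar_i * (-coef);
        eta_bar_i = dC_bar_i * (-Ci(i) / (c.Vp_r * sloc(i)));
        Ybar(4, j) += dC_bar_i * aL;
        s1_bar += dC_bar_i * Ci(i) * c.L1_r / c.Vp_r;
        s2_bar += dC_bar_i * Ci(i) * c.L2_r / c.Vp_r;
        // tight residual also touches C_i
        C_bar_i += fbt_bar * b1t / Ns;
        s1_bar += fbt_bar * (-c.L1_r / c.Vt_r) * Ci(i) / Ns;
      }
      // C_i = exp(muC + sT w0 [- sigma u])
      double cc = C_bar_i * Ci(i);
      muC_bar += cc;
      sC_bar += cc * w0v(i);
      if (sigma_trainable && c.denoise_stochastic) sig_bar += cc * (-uv(i));
      // eta_rhs = exp(mu_k + s_k * mloc)
      int k = (c.model_id == 1) ? 1 : 0;  // index of the RHS parameter
      double ee = eta_bar_i * eta_rhs(i);
      mu_bar_acc[k] += ee;
      s_bar_acc[k] += ee * mloc(i);
      const double* zz = &draws_z[(size_t)d * (i + (size_t)Ns * j)];
      int row = k + 1;
      for (int l = 0; l <= row; ++l) Lr_bar(row, l) += ee * s_eta(k) * zz[l];
    }

    // moments backward: q = log1p(v/m^2), muC = log m - q/2,
    // sT = sqrt(vT), vT = q [- sigma^2]
    double vT_bar = sC_bar / (2.0 * sT);
    double q_bar = -muC_bar / 2.0;
    if (!vT_clamped) {
      q_bar += vT_bar;
      if (!c.denoise_stochastic && sigma_trainable)
        sig_bar += vT_bar * (-2.0 * sigma);
    }
    double denom = m * m + v;
    double m_bar = muC_bar / m + q_bar * (-2.0 * v / (m * denom));
    double v_bar = q_bar / denom;
    Ybar(0, j) += m_bar;
    if (c.spread_is_sd) {
      if (!sd_clamped) Ybar(1, j) += v_bar * 2.0 * sd_hat + sd_bar_direct;
    } else {
      if (sp >= c.var_floor) Ybar(1, j) += v_bar;
    }
  }

  if (want_grad) {
    grad.zeros(lay.total);

    // --- correlation Cholesky backward ---
    double c_bar[2] = {0, 0}, rho_bar = 0;
    if (d == 2) {
      c_bar[0] += Lr_bar(1, 0);
      if (!clamp11) c_bar[0] += Lr_bar(1, 1) * (-cr(0) / L11);
    } else if (d == 3) {
      double L22 = Lr(2, 2);
      double L21_bar = 0, L11_bar = 0;
      // L22 = sqrt(1 - c2^2 - L21^2)
      if (!clamp22) {
        L21_bar += Lr_bar(2, 2) * (-L21 / L22);
        c_bar[1] += Lr_bar(2, 2) * (-cr(1) / L22);
      }
      L21_bar += Lr_bar(2, 1);
      // L21 = (rho - c1 c2) / L11
      rho_bar += L21_bar / L11;
      c_bar[0] += L21_bar * (-cr(1) / L11);
      c_bar[1] += L21_bar * (-cr(0) / L11);
      L11_bar += L21_bar * (-L21 / L11);
      L11_bar += Lr_bar(1, 1);
      if (!clamp11) c_bar[0] += L11_bar * (-cr(0) / L11);
      c_bar[0] += Lr_bar(1, 0);
      c_bar[1] += Lr_bar(2, 0);
    }
    for (int k = 0; k < c.n_eta; ++k)
      grad(lay.off_cross + k) = c_bar[k] * (1.0 - cr(k) * cr(k));
    if (lay.n_rho == 1)
      grad(lay.off_rho) = rho_bar * (1.0 - rho * rho);

    for (int k = 0; k < c.n_eta; ++k) {
      grad(lay.off_mu + k) = mu_bar_acc[k];
      grad(lay.off_sd + k) = s_bar_acc[k] * sigmoid_(sd_raw(k));
    }
    grad(lay.off_sigma) = sigma_trainable ? sig_bar * sig_chain : 0.0;

    if (c.n_point == 2) {
      // s1 = invlogit(r1); s2 = s1 * invlogit(r2)
      double ds1 = s1 * (1.0 - s1);
      grad(lay.off_point) = s1_bar * ds1 + s2_bar * g2 * ds1;
      grad(lay.off_point + 1) = s2_bar * s1 * g2 * (1.0 - g2);
    }

    // --- network backward (value + tangent adjoints) ---
    mat zbar(c.n_out, nt), zdotbar(c.n_out, nt);
    for (int o = 0; o < c.n_out; ++o) {
      double dx = c.x_max(o) - c.x_min(o);
      bool spread_ch = (o == 1);
      double fac = dx;
      if (c.literal_sd && c.spread_is_sd && spread_ch) fac = dx * dx;
      for (int j = 0; j < nt; ++j) {
        double s = Sig(o, j);
        zbar(o, j) = Ybar(o, j) * dx * s +
                     Ydotbar(o, j) * fac * s * (1.0 - s) * zLdot(o, j);
        zdotbar(o, j) = Ydotbar(o, j) * fac * s;
      }
    }
    std::vector<mat> Wbar(nL);
    std::vector<vec> Bbar(nL);
    Wbar[nL - 1] = zbar * A[nL - 1].t() + zdotbar * Adot[nL - 1].t();
    Bbar[nL - 1] = sum(zbar, 1);
    mat abar = W[nL - 1].t() * zbar;
    mat adotbar = W[nL - 1].t() * zdotbar;
    for (int l = nL - 2; l >= 0; --l) {
      mat one_m = 1.0 - square(A[l + 1]);
      mat zb = abar % one_m +
               adotbar % (-2.0 * A[l + 1] % one_m) % Zdot[l];
      mat zdb = adotbar % one_m;
      Wbar[l] = zb * A[l].t() + zdb * Adot[l].t();
      Bbar[l] = sum(zb, 1);
      if (l > 0) {
        abar = W[l].t() * zb;
        adotbar = W[l].t() * zdb;
      }
    }
    int pos = 0;
    for (int l = 0; l < nL; ++l) {
      int ni = c.layer_sizes(l), no = c.layer_sizes(l + 1);
      std::memcpy(&grad[pos], Wbar[l].memptr(), sizeof(double) * no * ni);
      pos += no * ni;
      std::memcpy(&grad[pos], Bbar[l].memptr(), sizeof(double) * no);
      pos += no;
    }
  }
  return L;
}

void fill_normals(vec& v) { for (uword i = 0; i < v.n_elem; ++i) v(i) = R::norm_rand(); }
void fill_uniforms(vec& v) { for (uword i = 0; i < v.n_elem; ++i) v(i) = R::unif_rand(); }

}  // namespace

//' @keywords internal
// [[Rcpp::export(name = ".dpinn_loss_grad")]]
Rcpp::List dpinn_loss_grad(const arma::vec& par, const Rcpp::List& cfg,
                           const arma::vec& draws_z, const arma::vec& draws_u,
                           const arma::vec& draws_bw,
                           const arma::vec& draws_zeta,
                           const arma::vec& draws_om, bool want_grad = true) {
  Config c = parse_config(cfg);
  ParLayout lay = layout_of(c);
  if ((int)par.n_elem != lay.total)
    Rcpp::stop("parameter vector has %d entries, expected %d",
               (int)par.n_elem, lay.total);
  vec grad;
  Losses L = eval_core(c, lay, par, draws_z, draws_u, draws_bw, draws_zeta,
                       draws_om, grad, want_grad);
  return Rcpp::List::create(
      Rcpp::Named("ode_mean") = L.ode_mean, Rcpp::Named("ode_var") = L.ode_var,
      Rcpp::Named("ic_mean") = L.ic_mean, Rcpp::Named("ic_var") = L.ic_var,
      Rcpp::Named("data_mean") = L.data_mean,
      Rcpp::Named("data_var") = L.data_var,
      Rcpp::Named("total") = L.total(c.lambda),
      Rcpp::Named("grad") = want_grad ? Rcpp::wrap(grad) : R_NilValue);
}

//' @keywords internal
// [[Rcpp::export(name = ".dpinn_train")]]
Rcpp::List dpinn_train(const arma::vec& par0, const Rcpp::List& cfg,
                       int iterations, double lr, double lr_decay_factor,
                       int lr_decay_every, double clip_norm, int log_every,
                       bool frozen_draws = false) {
  Config c = parse_config(cfg);
  ParLayout lay = layout_of(c);
  if ((int)par0.n_elem != lay.total)
    Rcpp::stop("parameter vector has %d entries, expected %d",
               (int)par0.n_elem, lay.total);
  const int Ncp = c.tc.n_elem, Ns = c.n_samples, d = 1 + c.n_eta;
  vec par = par0, grad(lay.total, fill::zeros);
  vec m_adam(lay.total, fill::zeros), v_adam(lay.total, fill::zeros);
  const double b1 = 0.9, b2 = 0.999, eps_adam = 1e-8;

  vec dz((size_t)d * Ns * Ncp), du((size_t)Ns * Ncp);
  vec dbw(c.model_id == 2 ? (size_t)Ns * Ncp : (size_t)0);
  vec dzeta(c.ic_enabled ? c.n_ic : 0), dom(c.ic_enabled ? c.n_ic : 0);
  if (frozen_draws) {
    fill_normals(dz);
    fill_normals(du);
    if (dbw.n_elem) fill_uniforms(dbw);
    if (dzeta.n_elem) { fill_normals(dzeta); fill_normals(dom); }
  }

  int n_log = (iterations + log_every - 1) / log_every;
  mat history(std::max(n_log, 1), 8, fill::zeros);
  int hrow = 0;

  for (int it = 0; it < iterations; ++it) {
    if (!frozen_draws) {
      fill_normals(dz);
      fill_normals(du);
      if (dbw.n_elem) fill_uniforms(dbw);
      if (dzeta.n_elem) { fill_normals(dzeta); fill_normals(dom); }
    }
    Losses L = eval_core(c, lay, par, dz, du, dbw, dzeta, dom, grad, true);
    double total = L.total(c.lambda);
    if (!std::isfinite(total))
      Rcpp::stop("non-finite loss at iteration %d (total=%g); "
                 "inspect initialisation / learning rate", it, total);
    if (it % log_every == 0 && hrow < (int)history.n_rows) {
      history(hrow, 0) = it;
      history(hrow, 1) = L.ode_mean; history(hrow, 2) = L.ode_var;
      history(hrow, 3) = L.ic_mean;  history(hrow, 4) = L.ic_var;
      history(hrow, 5) = L.data_mean; history(hrow, 6) = L.data_var;
      history(hrow, 7) = total;
      ++hrow;
    }
    double gn = norm(grad, 2);
    if (gn > clip_norm && gn > 0) grad *= clip_norm / gn;
    double lr_t = lr * std::pow(lr_decay_factor, it / lr_decay_every);
    double bc1 = 1.0 - std::pow(b1, it + 1);
    double bc2 = 1.0 - std::pow(b2, it + 1);
    for (int p = 0; p < lay.total; ++p) {
      m_adam(p) = b1 * m_adam(p) + (1.0 - b1) * grad(p);
      v_adam(p) = b2 * v_adam(p) + (1.0 - b2) * grad(p) * grad(p);
      par(p) -= lr_t * (m_adam(p) / bc1) /
                (std::sqrt(v_adam(p) / bc2) + eps_adam);
    }
    if (it % 512 == 0) Rcpp::checkUserInterrupt();
  }
  history.resize(hrow, 8);
  return Rcpp::List::create(Rcpp::Named("par") = par,
                            Rcpp::Named("history") = history);
}
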