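// Core numerics: fixed-step RK4 integration of the coupled growth system,
// SAD(1) longitudinal covariance, and the multivariate-normal negative
// log-likelihood evaluated from per-genotype sufficient statistics.
// These sit in the inner loop of the Nelder-Mead estimator, hence C++.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double OVERFLOW_GUARD = 1e12;

// Right-hand side of the coupled system: logistic self-growth plus a
// Holling type II (saturating) interaction term.
//   dE/dt = r_e E (1 - E/K_e) + r_e E (a_es / (1 + E)) S
//   dS/dt = r_s S (1 - S/K_s) + r_s S (a_se / (1 + S)) E
static inline void hlv_deriv(const double E, const double S,
                             const double r_e, const double K_e, const double a_es,
                             const double r_s, const double K_s, const double a_se,
                             double &dE, double &dS) {
  dE = r_e * E * (1.0 - E / K_e) + r_e * E * (a_es / (1.0 + E)) * S;
  dS = r_s * S * (1.0 - S / K_s) + r_s * S * (a_se / (1.0 + S)) * E;
}

// One classical fourth-order Runge-Kutta step of size h.
static inline bool rk4_step(double &E, double &S, const double h,
                            const double r_e, const double K_e, const double a_es,
                            const double r_s, const double K_s, const double a_se) {
  double k1E, k1S, k2E, k2S, k3E, k3S, k4E, k4S;
  hlv_deriv(E, S, r_e, K_e, a_es, r_s, K_s, a_se, k1E, k1S);
  hlv_deriv(E + 0.5 * h * k1E, S + 0.5 * h * k1S, r_e, K_e, a_es, r_s, K_s, a_se, k2E, k2S);
  hlv_deriv(E + 0.5 * h * k2E, S + 0.5 * h * k2S, r_e, K_e, a_es, r_s, K_s, a_se, k3E, k3S);
  hlv_deriv(E + h * k3E, S + h * k3S, r_e, K_e, a_es, r_s, K_s, a_se, k4E, k4S);
  E += h / 6.0 * (k1E + 2.0 * k2E + 2.0 * k3E + k4E);
  S += h / 6.0 * (k1S + 2.0 * k2S + 2.0 * k3S + k4S);
  return std::isfinite(E) && std::isfinite(S) &&
         std::fabs(E) < OVERFLOW_GUARD && std::fabs(S) < OVERFLOW_GUARD;
}

// Integrate from the first observation time and record the state at every
// requested time.  Each inter-observation interval is split into equal
// sub-steps no longer than `step`, so the RK4 grid lands exactly on the
// requested times.  Returns false (and the divergence time) on blow-up.
static bool solve_hlv_core(const arma::vec &par6, const double E0, const double S0,
                           const arma::vec &times, const double step,
                           arma::vec &Eout, arma::vec &Sout, double &t_div) {
  const double r_e = par6[0], K_e = par6[1], a_es = par6[2];
  const double r_s = par6[3], K_s = par6[4], a_se = par6[5];
  const int T = times.n_elem;
  double E = E0, S = S0, t = times[0];
  Eout[0] = E; Sout[0] = S;
  for (int k = 1; k < T; ++k) {
    const double dt = times[k] - times[k - 1];
    const int nsub = std::max(1, (int)std::ceil(dt / step - 1e-9));
    const double h = dt / nsub;
    for (int m = 0; m < nsub; ++m) {
      if (!rk4_step(E, S, h, r_e, K_e, a_es, r_s, K_s, a_se)) {
        t_div = t;
        return false;
      }
      t += h;
    }
    Eout[k] = E; Sout[k] = S;
  }
  return true;
}

// [[Rcpp::export]]
arma::mat cpp_solve_hlv(const arma::vec &par6, const double E0, const double S0,
                        const arma::vec &times, const double step) {
  const int T = times.n_elem;
  arma::vec E(T), S(T);
  double t_div = NA_REAL;
  if (!solve_hlv_core(par6, E0, S0, times, step, E, S, t_div))
    stop("trajectory diverged (|state| exceeded 1e12) near t = %f", t_div);
  arma::mat out(T, 2);
  out.col(0) = E; out.col(1) = S;
  return out;
}

// Bivariate SAD(1) covariance over T time indices, ordered (E block, S block).
// e_k(t) = phi_k e_k(t-1) + eps_k(t), e_k(1) = eps_k(1); innovations have SD
// nu_k and cross-species correlation rho at equal times, zero otherwise.
// The stacked residual vector is (P_e eps_E, P_s eps_S) with P_k the
// lower-triangular matrix of phi powers, so the blocks are triangular
// outer products: Cov_EE = nu_e^2 P_e P_e', Cov_ES = rho nu_e nu_s P_e P_s'.
// [[Rcpp::export]]
arma::mat cpp_sad1_cov(const double phi_e, const double phi_s,
                       const double nu_e, const double nu_s,
                       const double rho, const int T) {
  arma::vec pe(T), ps(T);
  for (int i = 0; i < T; ++i) {
    pe[i] = (i == 0) ? 1.0 : pe[i - 1] * phi_e;
    ps[i] = (i == 0) ? 1.0 : ps[i - 1] * phi_s;
  }
  arma::mat Pe(T, T, arma::fill::zeros), Ps(T, T, arma::fill::zeros);
  for (int j = 0; j < T; ++j)
    for (int m = 0; m <= j; ++m) {
      Pe(j, m) = pe[j - m];
      Ps(j, m) = ps[j - m];
    }
  arma::mat Sig(2 * T, 2 * T);
  Sig.submat(0, 0, T - 1, T - 1) = (nu_e * nu_e) * (Pe * Pe.t());
  Sig.submat(T, T, 2 * T - 1, 2 * T - 1) = (nu_s * nu_s) * (Ps * Ps.t());
  arma::mat C = (rho * nu_e * nu_s) * (Pe * Ps.t());
  Sig.submat(0, T, T - 1, 2 * T - 1) = C;
  Sig.submat(T, 0, 2 * T - 1, T - 1) = C.t();
  return Sig;
}

// Univariate SAD(1) covariance (monoculture residuals).
// [[Rcpp::export]]
arma::mat cpp_sad1_cov_uni(const double phi, const double nu, const int T) {
  arma::mat Sig(T, T);
  arma::vec p(T);
  for (int i = 0; i < T; ++i) p[i] = (i == 0) ? 1.0 : p[i - 1] * phi;
  for (int j = 0; j < T; ++j)
    for (int k = 0; k < T; ++k) {
      const int mn = std::min(j, k);
      double c = 0.0;
      for (int m = 0; m <= mn; ++m) c += p[j - m] * p[k - m];
      Sig(j, k) = nu * nu * c;
    }
  return Sig;
}

static const double BIG_NLL = 1e10;

// Cache of the covariance factorization keyed on the SAD parameters and a
// checksum of the scatter matrix.  During the numerical-gradient polish
// the optimizer perturbs one coordinate at a time, so most evaluations
// reuse the factor, the log-determinant and the trace term.
struct SigmaCache {
  arma::vec key;       // sad parameters
  double s_check = std::numeric_limits<double>::quiet_NaN();
  int d = -1;
  arma::mat Ut;        // lower-triangular transpose of the Cholesky factor
  double logdet = 0.0, trace_term = 0.0;
  bool valid = false;
};

static double scatter_checksum(const arma::mat &S) {
  return arma::accu(S) + 3.0 * S(0, 0) + 7.0 * S(S.n_rows - 1, S.n_cols - 1);
}

// Shared Gaussian core: given genotype-class mean curves mu (d x J), class
// means ybar (d x J), class sizes nj, pooled within-class scatter S and the
// covariance Sigma, return the negative log-likelihood.
static double gauss_nll(const arma::mat &mu, const arma::mat &ybar,
                        const arma::vec &nj, const arma::mat &S,
                        const arma::vec &sad, SigmaCache &cache,
                        arma::mat (*sigma_builder)(const arma::vec &, int),
                        const int T) {
  const int d = S.n_rows;
  const double s_check = scatter_checksum(S);
  if (!(cache.valid && cache.d == d && cache.key.n_elem == sad.n_elem &&
        arma::all(cache.key == sad) && cache.s_check == s_check)) {
    arma::mat Sigma = sigma_builder(sad, T);
    arma::mat U;
    if (!arma::chol(U, Sigma)) return BIG_NLL;
    cache.Ut = U.t();
    cache.logdet = 2.0 * arma::accu(arma::log(U.diag()));
    arma::mat W = arma::solve(arma::trimatl(cache.Ut), S);
    arma::mat X = arma::solve(arma::trimatu(cache.Ut.t()), W);
    cache.trace_term = arma::trace(X);   // tr(Sigma^-1 S)
    cache.key = sad;
    cache.s_check = s_check;
    cache.d = d;
    cache.valid = true;
  }
  const double ntot = arma::accu(nj);
  double quad = 0.0;
  for (arma::uword j = 0; j < nj.n_elem; ++j) {
    arma::vec z = arma::solve(arma::trimatl(cache.Ut), ybar.col(j) - mu.col(j));
    quad += nj[j] * arma::dot(z, z);
  }
  const double nll = 0.5 * (ntot * d * std::log(2.0 * M_PI) + ntot * cache.logdet +
                            quad + cache.trace_term);
  return std::isfinite(nll) ? nll : BIG_NLL;
}

// Negative log-likelihood for co-culture data.
// theta: J x 6 (r_e, K_e, a_es, r_s, K_s, a_se) per genotype combination;
// sad: (phi_e, phi_s, nu_e, nu_s, rho); ybar: 2T x J class mean vectors;
// S: pooled within-class scatter; init: 2 x J initial states at times[0].
static arma::mat sigma_cc(const arma::vec &sad, int T) {
  return cpp_sad1_cov(sad[0], sad[1], sad[2], sad[3], sad[4], T);
}
static arma::mat sigma_mono(const arma::vec &sad, int T) {
  return cpp_sad1_cov_uni(sad[0], sad[1], T);
}
static SigmaCache cache_cc, cache_mono;

// [[Rcpp::export]]
double cpp_nll_cc(const arma::mat &theta, const arma::vec &sad,
                  const arma::mat &ybar, const arma::vec &nj,
                  const arma::mat &S, const arma::vec &times,
                  const arma::mat &init, const double step) {
  const int T = times.n_elem;
  const int J = theta.n_rows;
  arma::mat mu(2 * T, J);
  arma::vec E(T), Sv(T);
  double t_div;
  for (int j = 0; j < J; ++j) {
    if (!solve_hlv_core(theta.row(j).t(), init(0, j), init(1, j), times, step, E, Sv, t_div))
      return BIG_NLL;
    mu.col(j) = arma::join_cols(E, Sv);
  }
  return gauss_nll(mu, ybar, nj, S, sad, cache_cc, sigma_cc, T);
}

double cpp_nll_mono(const arma::mat &theta, const arma::vec &sad,
                    const arma::mat &ybar, const arma::vec &nj,
                    const arma::mat &S, const arma::vec &times,
                    const arma::vec &init, const double step);

// Negative log-likelihood evaluated directly from the packed transformed
// optimizer vector (the optimizer's hot path).  Layout metadata mirrors
// the R-side packer: per-entry block offsets (0-based), shared flags and
// log-transform flags for the growth parameters, followed by the SAD
// block and (optionally) log initial states.
// kind: 1 = co-culture (6 growth parameters, 5 SAD), 2 = monoculture
// (2 growth parameters, 2 SAD).  init_mode: 0 = use obs_init as passed,
// 1 = shared free init, 2 = per-combination free init.
// [[Rcpp::export]]
double cpp_nll_packed(const arma::vec &par, const int kind, const int J,
                      const arma::ivec &theta_off, const arma::ivec &theta_shared,
                      const arma::ivec &theta_log, const int sad_off,
                      const int init_mode, const int init_off,
                      const arma::mat &ybar, const arma::vec &nj,
                      const arma::mat &S, const arma::vec &times,
                      const arma::mat &obs_init, const double step) {
  const int k_theta = theta_off.n_elem;
  const int T = times.n_elem;
  const int n_species = (kind == 1) ? 2 : 1;
  arma::mat theta(J, k_theta);
  for (int e = 0; e < k_theta; ++e)
    for (int j = 0; j < J; ++j) {
      double v = par[theta_off[e] + (theta_shared[e] ? 0 : j)];
      theta(j, e) = theta_log[e] ? std::exp(v) : v;
    }
  arma::vec sad;
  if (kind == 1) {
    sad = {3.0 * std::tanh(par[sad_off]), 3.0 * std::tanh(par[sad_off + 1]),
           std::exp(par[sad_off + 2]), std::exp(par[sad_off + 3]),
           std::tanh(par[sad_off + 4])};
  } else {
    sad = {3.0 * std::tanh(par[sad_off]), std::exp(par[sad_off + 1])};
  }
  arma::mat init(n_species, J);
  if (init_mode == 0) {
    init = obs_init;
  } else if (init_mode == 1) {
    for (int s = 0; s < n_species; ++s)
      init.row(s).fill(std::exp(par[init_off + s]));
  } else {
    for (int j = 0; j < J; ++j)
      for (int s = 0; s < n_species; ++s)
        init(s, j) = std::exp(par[init_off + j * n_species + s]);
  }
  if (kind == 1)
    return cpp_nll_cc(theta, sad, ybar, nj, S, times, init, step);
  return cpp_nll_mono(theta, sad, ybar, nj, S, times, init.row(0).t(), step);
}

// Negative log-likelihood for one species in monoculture (pure logistic
// mean curves, univariate SAD(1) residuals).
// theta: J x 2 (r, K); sad: (phi, nu); init: length-J initial abundances.
// [[Rcpp::export]]
double cpp_nll_mono(const arma::mat &theta, const arma::vec &sad,
                    const arma::mat &ybar, const arma::vec &nj,
                    const arma::mat &S, const arma::vec &times,
                    const arma::vec &init, const double step) {
  const int T = times.n_elem;
  const int J = theta.n_rows;
  arma::mat mu(T, J);
  arma::vec E(T), Sv(T);
  double t_div;
  for (int j = 0; j < J; ++j) {
    arma::vec par6 = {theta(j, 0), theta(j, 1), 0.0, 1.0, 1.0, 0.0};
    if (!solve_hlv_core(par6, init[j], 0.0, times, step, E, Sv, t_div))
      return BIG_NLL;
    mu.col(j) = E;
  }
  return gauss_nll(mu, ybar, nj, S, sad, cache_mono, sigma_mono, T);
}
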