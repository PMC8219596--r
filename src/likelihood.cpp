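// Fast log-likelihood kernels for the shifted-Wald model and its
// drift-variability mixtures.  These are the inner loop of the MCMC sampler;
// the user-facing R densities (dsw, dswtn, dswgam) are implemented in R and
// the C++ routes are tested against them.
#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

// log SW(t; alpha, theta, xi) for a single observation, s = t - theta > 0
static inline double sw_logpdf_1(double s, double alpha, double xi) {
  double d = alpha - xi * s;
  return std::log(alpha) - 0.5 * (LOG_2PI + 3.0 * std::log(s)) -
         d * d / (2.0 * s);
}

// [[Rcpp::export(name = ".sw_loglik_cpp")]]
double sw_loglik_cpp(NumericVector t, double alpha, double theta, double xi) {
  double ll = 0.0;
  for (R_xlen_t i = 0; i < t.size(); ++i) {
    double s = t[i] - theta;
    if (!(s > 0.0)) return R_NegInf;
    ll += sw_logpdf_1(s, alpha, xi);
  }
  return ll;
}

// Closed-form marginal when trial-level drift is zero-truncated normal:
// log f(t) = log alpha - 0.5 log(2 pi s^3 v) - log Phi(mu/sigma)
//            - (mu s - alpha)^2 / (2 s v) + log Phi((alpha sig2 + mu)/sqrt(sig2 v))
// with s = t - theta, v = s sig2 + 1.
// [[Rcpp::export(name = ".swtn_loglik_cpp")]]
double swtn_loglik_cpp(NumericVector t, double alpha, double theta,
                       double mu, double sigma) {
  double sig2 = sigma * sigma;
  double log_phi_norm = R::pnorm(mu / sigma, 0.0, 1.0, 1, 1);
  double ll = 0.0;
  for (R_xlen_t i = 0; i < t.size(); ++i) {
    double s = t[i] - theta;
    if (!(s > 0.0)) return R_NegInf;
    double v = s * sig2 + 1.0;
    double d = mu * s - alpha;
    double tail = R::pnorm((alpha * sig2 + mu) / std::sqrt(sig2 * v),
                           0.0, 1.0, 1, 1);
    ll += std::log(alpha) - 0.5 * (LOG_2PI + 3.0 * std::log(s) + std::log(v)) -
          log_phi_norm - d * d / (2.0 * s * v) + tail;
  }
  return ll;
}

// 15-point Gauss-Legendre rule on [-1, 1]
static const int GL_N = 15;
static const double GL_X[GL_N] = {
  -0.9879925180204854, -0.9372733924007059, -0.8482065834104272,
  -0.7244177313601700, -0.5709721726085388, -0.3941513470775634,
  -0.2011940939974345,  0.0,
   0.2011940939974345,  0.3941513470775634,  0.5709721726085388,
   0.7244177313601700,  0.8482065834104272,  0.9372733924007059,
   0.9879925180204854
};
static const double GL_W[GL_N] = {
  0.0307532419961173, 0.0703660474881081, 0.1071592204671719,
  0.1395706779261543, 0.1662692058169939, 0.1861610000155622,
  0.1984314853271116, 0.2025782419255613,
  0.1984314853271116, 0.1861610000155622, 0.1662692058169939,
  0.1395706779261543, 0.1071592204671719, 0.0703660474881081,
  0.0307532419961173
};

// log integrand of the gamma-mixture marginal in u = log(xi):
// L(u) = log SW(s; alpha, e^u) + log GAM(e^u; kappa, tau) + u
//      = log alpha - .5 log(2 pi s^3) - (alpha - s e^u)^2/(2s)
//        + kappa log tau - lgamma(kappa) + kappa u - tau e^u
struct GamIntegrand {
  double s, alpha, kappa, tau, c0;
  GamIntegrand(double s_, double a_, double k_, double t_) :
    s(s_), alpha(a_), kappa(k_), tau(t_) {
    c0 = std::log(a_) - 0.5 * (LOG_2PI + 3.0 * std::log(s_)) +
         k_ * std::log(t_) - std::lgamma(k_);
  }
  double operator()(double u) const {
    double x = std::exp(u);
    double d = alpha - s * x;
    return c0 - d * d / (2.0 * s) + kappa * u - tau * x;
  }
};

// integrate exp(L(u) - M) over [a, b] split into np equal Gauss-Legendre
// panels; skipped when the integrand is provably negligible on the panel
// (both endpoints far below the running maximum and no interior mode).
static double panels_exp(const GamIntegrand &L, double a, double b, int np,
                         double M, double ustar) {
  double acc = 0.0;
  double h = (b - a) / np;
  for (int p = 0; p < np; ++p) {
    double lo = a + p * h, hi = lo + h;
    bool has_mode = (ustar > lo && ustar < hi);
    if (!has_mode && L(lo) - M < -45.0 && L(hi) - M < -45.0) continue;
    double c = 0.5 * (lo + hi), r = 0.5 * h;
    double sum = 0.0;
    for (int k = 0; k < GL_N; ++k) {
      double v = L(c + r * GL_X[k]) - M;
      if (v > -700.0) sum += GL_W[k] * std::exp(v);
    }
    acc += r * sum;
  }
  return acc;
}

// log of the SW-GAM marginal density at a single s = t - theta, via fixed
// composite Gauss-Legendre quadrature in log-drift space centred on the
// Laplace point of the integrand.  ql/qr are the log 1e-14 lower/upper
// quantiles of the gamma (precomputed once per parameter point: they do not
// depend on the trial).
static double swgam_logpdf_1(double s, double alpha, double kappa,
                             double tau, double ql, double qr) {
  // mode of the integrand in xi: -s x^2 + (alpha - tau) x + kappa = 0
  double am = alpha - tau;
  double xs = (am + std::sqrt(am * am + 4.0 * s * kappa)) / (2.0 * s);
  double H = s * xs * xs + kappa;       // -d2L/du2 at the mode
  double su = 1.0 / std::sqrt(H);
  double ustar = std::log(xs);
  GamIntegrand L(s, alpha, kappa, tau);
  double M = L(ustar);

  double l0 = ustar - 10.0 * su, r0 = ustar + 10.0 * su;
  // make sure the gamma's own mass is covered (matters for small kappa)
  double lo = std::min(l0, ql), hi = std::max(r0, qr);

  double acc = panels_exp(L, l0, r0, 6, M, ustar);
  if (lo < l0) acc += panels_exp(L, lo, l0, 6, M, ustar);
  if (hi > r0) acc += panels_exp(L, r0, hi, 3, M, ustar);
  if (!(acc > 0.0)) return R_NegInf;
  return M + std::log(acc);
}

// [[Rcpp::export(name = ".swgam_loglik_cpp")]]
double swgam_loglik_cpp(NumericVector t, double alpha, double theta,
                        double kappa, double tau) {
  if (kappa / (tau * tau) < 1e-12)            // degenerate: fixed drift
    return sw_loglik_cpp(t, alpha, theta, kappa / tau);
  double ql = std::log(R::qgamma(1e-14, kappa, 1.0 / tau, 1, 0));
  double qr = std::log(R::qgamma(1e-14, kappa, 1.0 / tau, 0, 0));
  double ll = 0.0;
  for (R_xlen_t i = 0; i < t.size(); ++i) {
    double s = t[i] - theta;
    if (!(s > 0.0)) return R_NegInf;
    ll += swgam_logpdf_1(s, alpha, kappa, tau, ql, qr);
  }
  return ll;
}

// [[Rcpp::export(name = ".swgam_logpdf_cpp")]]
NumericVector swgam_logpdf_cpp(NumericVector t, double alpha, double theta,
                               double kappa, double tau) {
  NumericVector out(t.size());
  bool degen = kappa / (tau * tau) < 1e-12;
  double ql = 0.0, qr = 0.0;
  if (!degen) {
    ql = std::log(R::qgamma(1e-14, kappa, 1.0 / tau, 1, 0));
    qr = std::log(R::qgamma(1e-14, kappa, 1.0 / tau, 0, 0));
  }
  for (R_xlen_t i = 0; i < t.size(); ++i) {
    double s = t[i] - theta;
    if (!(s > 0.0)) { out[i] = R_NegInf; continue; }
    out[i] = degen ? sw_logpdf_1(s, alpha, kappa / tau)
                   : swgam_logpdf_1(s, alpha, kappa, tau, ql, qr);
  }
  return out;
}
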