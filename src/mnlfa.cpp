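#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Numerically stable log(plogis(a)).
static inline double log_sigmoid(double a) {
  if (a > 0.0) return -std::log1p(std::exp(-a));
  return a - std::log1p(std::exp(a));
}

static inline double sigmoid(double a) {
  if (a > 0.0) return 1.0 / (1.0 + std::exp(-a));
  double e = std::exp(a);
  return e / (1.0 + e);
}

// Marginal log-likelihood (and analytic score) of a one-factor moderated
// binary factor model.  For row i with covariates x_i the latent variable is
// eta ~ N(alpha_i, psi_i) with alpha_i = gamma'x_i, psi_i = exp(omega'x_i),
// and item j is Bernoulli with logit nu0_j + kappa_j'x_i + (lambda0_j +
// delta_j'x_i) * eta.  The integral over eta uses the supplied quadrature
// rule (z, w), already normalized so that sum(w) = 1 and sum(w z^2) = 1.
//
// The per-node Bernoulli product is accumulated directly (one exp per
// item-node); rows whose product underflows are redone in log space.
// Element access goes through raw column-major pointers: the Rcpp
// accessors dominate the profile otherwise.
//
// Y is n x J in {0, 1, NA}; X is n x K; kappa/delta are J x K.
// [[Rcpp::export]]
List mnlfa_ll_cpp(const NumericMatrix& Ym, const NumericMatrix& Xm,
                  const NumericVector& nu0v, const NumericVector& lambda0v,
                  const NumericMatrix& kappam, const NumericMatrix& deltam,
                  const NumericVector& gammav, const NumericVector& omegav,
                  const NumericVector& zv, const NumericVector& wv,
                  const bool want_grad) {
  const int n = Ym.nrow(), J = Ym.ncol(), K = Xm.ncol(), Q = zv.size();
  const double *Y = REAL(Ym), *X = REAL(Xm);
  const double *nu0 = REAL(nu0v), *lambda0 = REAL(lambda0v);
  const double *kap = REAL(kappam), *del = REAL(deltam);
  const double *gam = REAL(gammav), *ome = REAL(omegav);
  const double *z = REAL(zv), *w = REAL(wv);

  NumericVector row_llv(n);
  double *row_ll = REAL(row_llv);
  std::vector<double> gnu(J, 0.0), glam(J, 0.0), gg(K, 0.0), go(K, 0.0);
  std::vector<double> gk((size_t)J * K, 0.0), gd((size_t)J * K, 0.0);
  std::vector<double> nux(J), lam(J), f(Q), etas(Q), lf(Q),
      pbuf((size_t)Q * J), yi(J), xi(K);
  double ll = 0.0;

  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < K; ++k) xi[k] = X[(size_t)k * n + i];
    for (int j = 0; j < J; ++j) yi[j] = Y[(size_t)j * n + i];

    double alpha = 0.0, logpsi = 0.0;
    for (int k = 0; k < K; ++k) {
      alpha  += gam[k] * xi[k];
      logpsi += ome[k] * xi[k];
    }
    const double sg = std::exp(0.5 * logpsi);

    for (int j = 0; j < J; ++j) {
      double a = 0.0, b = 0.0;
      for (int k = 0; k < K; ++k) {
        a += kap[(size_t)k * J + j] * xi[k];
        b += del[(size_t)k * J + j] * xi[k];
      }
      nux[j] = nu0[j] + a;
      lam[j] = lambda0[j] + b;
    }

    double L = 0.0;
    bool under = false;
    for (int q = 0; q < Q; ++q) {
      const double eta = alpha + sg * z[q];
      etas[q] = eta;
      double fq = 1.0;
      for (int j = 0; j < J; ++j) {
        const double y = yi[j];
        if (ISNAN(y)) { pbuf[(size_t)q * J + j] = NA_REAL; continue; }
        const double p = sigmoid(nux[j] + lam[j] * eta);
        pbuf[(size_t)q * J + j] = p;
        fq *= (y > 0.5) ? p : (1.0 - p);
      }
      if (fq < 1e-290) under = true;
      f[q] = fq;
      L += w[q] * fq;
    }

    if (under || L <= 0.0 || !R_finite(L)) {
      // slow path: log space with max shift
      double m = -INFINITY;
      for (int q = 0; q < Q; ++q) {
        double s = 0.0;
        const double eta = etas[q];
        for (int j = 0; j < J; ++j) {
          const double y = yi[j];
          if (ISNAN(y)) continue;
          const double a = nux[j] + lam[j] * eta;
          s += (y > 0.5) ? log_sigmoid(a) : log_sigmoid(-a);
        }
        lf[q] = s;
        if (s > m) m = s;
      }
      L = 0.0;
      for (int q = 0; q < Q; ++q) {
        f[q] = std::exp(lf[q] - m);
        L += w[q] * f[q];
      }
      row_ll[i] = m + std::log(L);
    } else {
      row_ll[i] = std::log(L);
    }
    ll += row_ll[i];

    if (want_grad && L > 0.0 && R_finite(row_ll[i])) {
      for (int q = 0; q < Q; ++q) {
        const double u = w[q] * f[q] / L;
        if (u <= 0.0) continue;
        const double eta = etas[q];
        double s = 0.0;
        for (int j = 0; j < J; ++j) {
          const double y = yi[j];
          if (ISNAN(y)) continue;
          const double r = y - pbuf[(size_t)q * J + j];
          const double ur = u * r, ure = ur * eta;
          gnu[j]  += ur;
          glam[j] += ure;
          for (int k = 0; k < K; ++k) {
            gk[(size_t)k * J + j] += ur * xi[k];
            gd[(size_t)k * J + j] += ure * xi[k];
          }
          s += r * lam[j];
        }
        const double us = u * s, ds = us * sg * z[q] * 0.5;
        for (int k = 0; k < K; ++k) {
          gg[k] += us * xi[k];
          go[k] += ds * xi[k];
        }
      }
    }
  }

  NumericMatrix g_kappa(J, K), g_delta(J, K);
  std::copy(gk.begin(), gk.end(), REAL(g_kappa));
  std::copy(gd.begin(), gd.end(), REAL(g_delta));
  return List::create(
    _["loglik"] = ll, _["row_loglik"] = row_llv,
    _["g_nu0"] = NumericVector(gnu.begin(), gnu.end()),
    _["g_lambda0"] = NumericVector(glam.begin(), glam.end()),
    _["g_kappa"] = g_kappa, _["g_delta"] = g_delta,
    _["g_gamma"] = NumericVector(gg.begin(), gg.end()),
    _["g_omega"] = NumericVector(go.begin(), go.end()));
}

// Marginal log-likelihood (and score) of an unmoderated two-factor binary
// model: items with fac = 0 load on eta1, fac = 1 on eta2, where
// (eta1, eta2) is standard bivariate normal with correlation phi.  The
// integral uses a tensor-product rule: za, zb, w all have length Q^2 and
// eta1 = za, eta2 = phi*za + sqrt(1-phi^2)*zb.
// [[Rcpp::export]]
List twofactor_ll_cpp(const NumericMatrix& Ym, const IntegerVector& facv,
                      const NumericVector& nu0v, const NumericVector& lambda0v,
                      const double phi,
                      const NumericVector& zav, const NumericVector& zbv,
                      const NumericVector& wv, const bool want_grad) {
  const int n = Ym.nrow(), J = Ym.ncol(), Q = zav.size();
  const double c = std::sqrt(1.0 - phi * phi);
  const double *Y = REAL(Ym), *za = REAL(zav), *zb = REAL(zbv), *w = REAL(wv);
  const double *nu0 = REAL(nu0v), *lambda0 = REAL(lambda0v);
  const int *fac = INTEGER(facv);

  std::vector<double> gnu(J, 0.0), glam(J, 0.0);
  double g_phi = 0.0, ll = 0.0;
  NumericVector row_llv(n);
  double *row_ll = REAL(row_llv);
  std::vector<double> eta2(Q), deta2(Q), f(Q), lf(Q), pbuf((size_t)Q * J),
      yi(J);

  for (int q = 0; q < Q; ++q) {
    eta2[q]  = phi * za[q] + c * zb[q];
    deta2[q] = za[q] - (phi / c) * zb[q];
  }

  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < J; ++j) yi[j] = Y[(size_t)j * n + i];
    double L = 0.0;
    bool under = false;
    for (int q = 0; q < Q; ++q) {
      double fq = 1.0;
      for (int j = 0; j < J; ++j) {
        const double y = yi[j];
        if (ISNAN(y)) { pbuf[(size_t)q * J + j] = NA_REAL; continue; }
        const double eta = (fac[j] == 0) ? za[q] : eta2[q];
        const double p = sigmoid(nu0[j] + lambda0[j] * eta);
        pbuf[(size_t)q * J + j] = p;
        fq *= (y > 0.5) ? p : (1.0 - p);
      }
      if (fq < 1e-290) under = true;
      f[q] = fq;
      L += w[q] * fq;
    }

    if (under || L <= 0.0 || !R_finite(L)) {
      double m = -INFINITY;
      for (int q = 0; q < Q; ++q) {
        double s = 0.0;
        for (int j = 0; j < J; ++j) {
          const double y = yi[j];
          if (ISNAN(y)) continue;
          const double eta = (fac[j] == 0) ? za[q] : eta2[q];
          const double a = nu0[j] + lambda0[j] * eta;
          s += (y > 0.5) ? log_sigmoid(a) : log_sigmoid(-a);
        }
        lf[q] = s;
        if (s > m) m = s;
      }
      L = 0.0;
      for (int q = 0; q < Q; ++q) {
        f[q] = std::exp(lf[q] - m);
        L += w[q] * f[q];
      }
      row_ll[i] = m + std::log(L);
    } else {
      row_ll[i] = std::log(L);
    }
    ll += row_ll[i];

    if (want_grad && L > 0.0 && R_finite(row_ll[i])) {
      for (int q = 0; q < Q; ++q) {
        const double u = w[q] * f[q] / L;
        if (u <= 0.0) continue;
        for (int j = 0; j < J; ++j) {
          const double y = yi[j];
          if (ISNAN(y)) continue;
          const double r = y - pbuf[(size_t)q * J + j];
          const double eta = (fac[j] == 0) ? za[q] : eta2[q];
          gnu[j]  += u * r;
          glam[j] += u * r * eta;
          if (fac[j] == 1) g_phi += u * r * lambda0[j] * deta2[q];
        }
      }
    }
  }

  return List::create(
    _["loglik"] = ll, _["row_loglik"] = row_llv,
    _["g_nu0"] = NumericVector(gnu.begin(), gnu.end()),
    _["g_lambda0"] = NumericVector(glam.begin(), glam.end()),
    _["g_phi"] = g_phi);
}
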