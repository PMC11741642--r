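// Coordinate-ascent variational inner loops for the multivariate
// summary-statistics regression.  All heavy per-variant work lives here;
// orchestration, empirical-Bayes housekeeping and validation stay in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = 1.8378770664093454836;

// Mixture posterior for one variant given bhat ~ N(b, V/d), b ~ sum_k w0k
// N(0, S0k).  Uses the S0 (S0 + V/d)^{-1} factorization so rank-deficient
// components (null, singletons, rank-1) need no inversion of S0 itself.
// Fills gamma (K), bbar (r), M2 (r x r); returns the log marginal
// log sum_k w0k N(bhat; 0, S0k + V/d).  Optionally fills mu1 (r x K) and
// Sigma1 (r x r x K).
static double mix_update(const vec &bhat, double d, const mat &V,
                         const vec &w0, const cube &S0,
                         vec &gamma, vec &bbar, mat &M2,
                         mat *mu1_out, cube *sig1_out) {
  const uword K = S0.n_slices, r = bhat.n_elem;
  mat Vj = V / d;
  vec logp(K);
  logp.fill(-datum::inf);
  mat mu1(r, K, fill::zeros);
  cube sig1(r, r, K, fill::zeros);
  for (uword k = 0; k < K; k++) {
    if (w0(k) <= 0.0 && !(mu1_out || sig1_out)) continue;
    mat Ck = S0.slice(k) + Vj;
    mat L;
    if (!chol(L, Ck, "lower"))
      Rcpp::stop("singular (S0_k + V/d) for component %d", (int)(k + 1));
    vec z = solve(trimatl(L), bhat);
    double ldet = 2.0 * accu(log(L.diag()));
    logp(k) = -0.5 * (r * LOG2PI + ldet + dot(z, z));
    mat CinvS0 = solve(Ck, S0.slice(k));        // Ck^{-1} S0k
    mu1.col(k) = CinvS0.t() * bhat;             // S0k Ck^{-1} bhat
    mat S1 = CinvS0.t() * Vj;                   // S0k Ck^{-1} (V/d)
    sig1.slice(k) = 0.5 * (S1 + S1.t());
  }
  vec lg(K);
  for (uword k = 0; k < K; k++)
    lg(k) = (w0(k) > 0.0) ? std::log(w0(k)) + logp(k) : -datum::inf;
  double m = lg.max();
  if (!std::isfinite(m))
    Rcpp::stop("non-finite mixture log-likelihood for a variant");
  double lse = m + std::log(accu(exp(lg - m)));
  gamma = exp(lg - lse);
  bbar = mu1 * gamma;
  M2.zeros(r, r);
  for (uword k = 0; k < K; k++)
    if (gamma(k) > 0.0)
      M2 += gamma(k) * (sig1.slice(k) + mu1.col(k) * mu1.col(k).t());
  M2 = 0.5 * (M2 + M2.t());
  if (mu1_out) *mu1_out = mu1;
  if (sig1_out) *sig1_out = sig1;
  return lse;
}

// [[Rcpp::export]]
Rcpp::List mix_posterior_cpp(const arma::vec &bhat, double d,
                             const arma::mat &V, const arma::vec &w0,
                             const arma::cube &S0) {
  vec gamma;
  vec bbar;
  mat M2;
  mat mu1;
  cube sig1;
  double logp = mix_update(bhat, d, V, w0, S0, gamma, bbar, M2, &mu1, &sig1);
  return Rcpp::List::create(Rcpp::Named("gamma") = gamma,
                            Rcpp::Named("mu1") = mu1,
                            Rcpp::Named("Sigma1") = sig1,
                            Rcpp::Named("b_bar") = bbar,
                            Rcpp::Named("M2") = M2,
                            Rcpp::Named("log_marginal") = logp);
}

// Per-sweep precomputation in the whitened residual basis: with V = L L'
// and S0k whitened to L^{-1} S0k L^{-T} = Q diag(lam) Q', every
// per-variant, per-component posterior quantity becomes diagonal in
// lam + 1/d, so the inner loop needs only r x r matrix-vector products and
// no factorizations.
struct MixPre {
  mat lam;              // r x K eigenvalues (clamped >= 0)
  std::vector<mat> A;   // K of r x r: Q' L^{-1}
  std::vector<mat> W;   // K of r x r: L Q
  mat Vinv;
  double ldetV;
};

static MixPre precompute_mix(const mat &V, const cube &S0) {
  const uword r = V.n_rows, K = S0.n_slices;
  MixPre pre;
  mat Lv;
  if (!chol(Lv, V, "lower"))
    Rcpp::stop("residual covariance V is not positive definite");
  mat Linv = inv(trimatl(Lv));
  pre.lam.set_size(r, K);
  pre.A.resize(K);
  pre.W.resize(K);
  for (uword k = 0; k < K; k++) {
    mat St = Linv * S0.slice(k) * Linv.t();
    St = 0.5 * (St + St.t());
    vec lam;
    mat Q;
    eig_sym(lam, Q, St);
    pre.lam.col(k) = clamp(lam, 0.0, datum::inf);
    pre.A[k] = Q.t() * Linv;
    pre.W[k] = Lv * Q;
  }
  pre.Vinv = Linv.t() * Linv;
  double sign;
  log_det(pre.ldetV, sign, V);
  return pre;
}

// Full coordinate-ascent fit on sufficient statistics.
//
// Per sweep, for each variant j in the given order: form the residualized
// single-variant estimate bhat_j = (T_j + d_j * Bbar_j) / d_j with
// T = XtY - XtX * Bbar maintained incrementally, run the mixture posterior
// update, and write back.  The evidence lower bound is accumulated during
// the sweep via the local-evidence identity
//   -KL_j = log p(bhat_j) - E_q[log N(bhat_j; b_j, V/d_j)],
// exact because KL_j depends only on q_j, which the update makes the exact
// local posterior at that bhat_j.  Mixture weights (M-step: column means of
// the responsibilities) and the residual covariance V (M-step: ERSS / n,
// eigenvalue-floored) are updated after each sweep's ELBO; both are closed
// -form ascent steps, so the trace is nondecreasing.
//
// orders: (n_orders x p) 0-based variant orders; row min(iter, n_orders) is
// used, so one row gives a fixed order and max_iter rows a per-iteration
// shuffle.
// [[Rcpp::export]]
Rcpp::List mrmash_rss_core(const arma::mat &XtX, const arma::mat &XtY,
                           const arma::vec &d, const arma::cube &S0,
                           arma::vec w0, arma::mat V,
                           const arma::mat &YtY, bool has_yty, double n,
                           arma::mat B, const arma::imat &orders,
                           double tol, int max_iter, bool update_w0,
                           int w0_max_updates, bool update_v,
                           double v_eig_floor) {
  const uword p = XtX.n_rows, r = XtY.n_cols, K = S0.n_slices;
  mat T = XtY - XtX * B;
  mat gamma(p, K, fill::zeros);
  vec elbo(max_iter, fill::zeros);
  mat var_part_out(r, r, fill::zeros);
  bool converged = false;
  int iter = 0;
  std::string bad = "";

  MixPre pre = precompute_mix(V, S0);
  vec logw0(K);
  mat mu1(r, K);
  vec logp(K), lg(K), g(K), bbar(r), y(r), u(r), denom(r), resid(r);
  mat M2(r, r), Cov(r, r), Ck(r, r);

  for (iter = 1; iter <= max_iter; iter++) {
    double neg_kl = 0.0;
    mat var_part(r, r, fill::zeros); // sum_j d_j (M2_j - bbar_j bbar_j')
    for (uword k = 0; k < K; k++)
      logw0(k) = (w0(k) > 0.0) ? std::log(w0(k)) : -datum::inf;
    const uword orow = std::min((uword)(iter - 1), orders.n_rows - 1);
    for (uword jj = 0; jj < p; jj++) {
      uword j = (uword)orders(orow, jj);
      const double vj = 1.0 / d(j);
      vec bhat = (T.row(j).t() + d(j) * B.row(j).t()) / d(j);
      // mixture posterior in the whitened eigenbasis
      for (uword k = 0; k < K; k++) {
        if (!std::isfinite(logw0(k))) { logp(k) = 0.0; continue; }
        y = pre.A[k] * bhat;
        denom = pre.lam.col(k) + vj;
        u = pre.lam.col(k) % y / denom;
        mu1.col(k) = pre.W[k] * u;
        logp(k) = -0.5 * (r * LOG2PI + pre.ldetV + accu(log(denom)) +
                          accu(square(y) / denom));
      }
      lg = logw0 + logp;
      double mx = lg.max();
      if (!std::isfinite(mx)) { bad = "non-finite mixture likelihood"; break; }
      double lse = mx + std::log(accu(exp(lg - mx)));
      g = exp(lg - lse);
      bbar.zeros();
      M2.zeros();
      for (uword k = 0; k < K; k++) {
        if (g(k) <= 1e-15) continue;
        bbar += g(k) * mu1.col(k);
        y = pre.A[k] * bhat;
        denom = pre.lam.col(k) + vj;
        u = pre.lam.col(k) % y / denom;
        // C = diag(lam * vj / denom) + u u'
        Ck = diagmat(pre.lam.col(k) * vj / denom) + u * u.t();
        M2 += g(k) * (pre.W[k] * Ck * pre.W[k].t());
      }
      M2 = 0.5 * (M2 + M2.t());
      Cov = M2 - bbar * bbar.t();
      var_part += d(j) * Cov;
      resid = bhat - bbar;
      neg_kl += lse +
        0.5 * (r * LOG2PI + pre.ldetV - r * std::log(d(j))) +
        0.5 * d(j) * (as_scalar(resid.t() * pre.Vinv * resid) +
                      accu(pre.Vinv % Cov));
      vec delta = bbar - B.row(j).t();
      if (accu(abs(delta)) > 0.0)
        T -= XtX.col(j) * delta.t();
      B.row(j) = bbar.t();
      gamma.row(j) = g.t();
    }
    if (!bad.empty()) break;
    // Expected residual sum of squares in sufficient statistics
    mat XtYtB = XtY.t() * B;                        // r x r
    var_part_out = var_part;
    mat ERSS = -XtYtB - XtYtB.t() + B.t() * (XtX * B) + var_part;
    if (has_yty) ERSS += YtY;
    ERSS = 0.5 * (ERSS + ERSS.t());
    elbo(iter - 1) = -0.5 * n * r * LOG2PI - 0.5 * n * pre.ldetV -
      0.5 * accu(pre.Vinv % ERSS) + neg_kl;
    if (!std::isfinite(elbo(iter - 1))) {
      bad = "non-finite ELBO";
      break;
    }
    if (iter > 1) {
      double prev = elbo(iter - 2), cur = elbo(iter - 1);
      if (cur < prev - 1e-8 * std::abs(prev)) {
        bad = "ELBO decreased";
        break;
      }
      if (std::abs(cur - prev) < tol * std::abs(cur)) {
        converged = true;
      }
    }
    if (update_w0 && iter <= w0_max_updates) {
      w0 = mean(gamma, 0).t();
      w0 /= accu(w0);
    }
    if (update_v) {
      mat Vnew = ERSS / n;
      vec ev;
      mat evec;
      eig_sym(ev, evec, 0.5 * (Vnew + Vnew.t()));
      ev = clamp(ev, v_eig_floor, ev.max() > v_eig_floor ? ev.max()
                                                         : v_eig_floor);
      V = evec * diagmat(ev) * evec.t();
      V = 0.5 * (V + V.t());
      pre = precompute_mix(V, S0);
    }
    if (converged) break;
  }
  int used = std::min(iter, max_iter);
  return Rcpp::List::create(
      Rcpp::Named("B_bar") = B, Rcpp::Named("gamma") = gamma,
      Rcpp::Named("w0") = w0, Rcpp::Named("V") = V,
      Rcpp::Named("elbo") = elbo.head(used),
      Rcpp::Named("converged") = converged, Rcpp::Named("n_iter") = used,
      Rcpp::Named("var_part") = var_part_out, Rcpp::Named("error") = bad);
}

// Log-likelihood matrix for the (LD-free) mixture weight fit on
// approximately independent strong signals: L(j, k) = log N(bhat_j; 0,
// S0_k + diag(se_j^2)).
// [[Rcpp::export]]
arma::mat mix_loglik_cpp(const arma::mat &Bhat, const arma::mat &SE,
                         const arma::cube &S0) {
  const uword m = Bhat.n_rows, r = Bhat.n_cols, K = S0.n_slices;
  mat L(m, K);
  for (uword j = 0; j < m; j++) {
    mat Shat = diagmat(square(SE.row(j).t()));
    vec b = Bhat.row(j).t();
    for (uword k = 0; k < K; k++) {
      mat C = S0.slice(k) + Shat;
      mat Lc;
      if (!chol(Lc, C, "lower"))
        Rcpp::stop("singular covariance in weight fit (component %d)",
                   (int)(k + 1));
      vec z = solve(trimatl(Lc), b);
      L(j, k) = -0.5 * (r * LOG2PI + 2.0 * accu(log(Lc.diag())) + dot(z, z));
    }
  }
  return L;
}
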