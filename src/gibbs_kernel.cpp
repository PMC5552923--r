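// Blocked Gibbs sweep for y = X*beta + Z_f*u_f + Z_m*u_m + e with
// u_role ~ N(0, sigma2_role * A_role) and scaled inverse-gamma variance
// priors. Z matrices enter as 0-based row->taxon index vectors (each cross
// has exactly one parent per role), so Z'Z is diagonal and Z'v is an
// indexed accumulation. All randomness comes from R's RNG so that
// set.seed() gives bit-identical chains.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double VAR_FLOOR = 1e-12;

// Draw from N(P^{-1} h, P^{-1}) via the upper Cholesky factor of P.
static arma::vec draw_mvn_canonical(const arma::mat& P, const arma::vec& h) {
  arma::mat R;
  if (!arma::chol(R, P)) {
    stop("precision matrix not positive definite");
  }
  arma::vec w = arma::solve(arma::trimatl(R.t()), h);
  arma::vec mu = arma::solve(arma::trimatu(R), w);
  int d = P.n_rows;
  arma::vec z(d);
  for (int i = 0; i < d; ++i) z(i) = R::norm_rand();
  return mu + arma::solve(arma::trimatu(R), z);
}

// Scaled inverse-gamma draw: shape a, scale b (density ~ x^{-(a+1)} e^{-b/x}).
static double draw_invgamma(double a, double b) {
  double g = R::rgamma(a, 1.0 / b);
  double out = 1.0 / g;
  return out < VAR_FLOOR ? VAR_FLOOR : out;
}

// [[Rcpp::export]]
List gibbs_chain_cpp(const arma::vec& y, const arma::mat& X,
                     const arma::ivec& zf, const arma::ivec& zm,
                     const arma::mat& Af_inv, const arma::mat& Am_inv,
                     const arma::mat& B0_inv, const arma::vec& B0_inv_b0,
                     double Vf, double nuf, double Vm, double num,
                     double Ve, double nue,
                     int n_iter, int burnin, int thin,
                     arma::vec beta, arma::vec uf, arma::vec um,
                     double s2f, double s2m, double s2e,
                     bool fix_variances, bool keep_u) {
  const int n = y.n_elem, p = X.n_cols;
  const int qf = Af_inv.n_rows, qm = Am_inv.n_rows;

  arma::vec nf(qf, arma::fill::zeros), nm(qm, arma::fill::zeros);
  for (int i = 0; i < n; ++i) { nf(zf(i)) += 1.0; nm(zm(i)) += 1.0; }

  const arma::mat XtX = X.t() * X;
  const int n_keep = (n_iter - burnin) / thin;
  arma::mat draws(n_keep, p + 3);
  arma::mat u_draws;
  if (keep_u) u_draws.set_size(n_keep, qf + qm);

  arma::vec rf(n), rm(n);
  int row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    for (int i = 0; i < n; ++i) { rf(i) = uf(zf(i)); rm(i) = um(zm(i)); }

    // beta | rest
    {
      arma::mat P = XtX / s2e + B0_inv;
      arma::vec h = X.t() * (y - rf - rm) / s2e + B0_inv_b0;
      beta = draw_mvn_canonical(P, h);
    }
    arma::vec resid = y - X * beta;

    // u_f | rest
    {
      arma::mat P = Af_inv / s2f;
      P.diag() += nf / s2e;
      arma::vec h(qf, arma::fill::zeros);
      for (int i = 0; i < n; ++i) h(zf(i)) += (resid(i) - rm(i)) / s2e;
      uf = draw_mvn_canonical(P, h);
      for (int i = 0; i < n; ++i) rf(i) = uf(zf(i));
    }

    // u_m | rest
    {
      arma::mat P = Am_inv / s2m;
      P.diag() += nm / s2e;
      arma::vec h(qm, arma::fill::zeros);
      for (int i = 0; i < n; ++i) h(zm(i)) += (resid(i) - rf(i)) / s2e;
      um = draw_mvn_canonical(P, h);
      for (int i = 0; i < n; ++i) rm(i) = um(zm(i));
    }

    if (!fix_variances) {
      double quad_f = arma::dot(uf, Af_inv * uf);
      s2f = draw_invgamma((nuf + qf) / 2.0, (nuf * Vf + quad_f) / 2.0);
      double quad_m = arma::dot(um, Am_inv * um);
      s2m = draw_invgamma((num + qm) / 2.0, (num * Vm + quad_m) / 2.0);
      arma::vec e = resid - rf - rm;
      s2e = draw_invgamma((nue + n) / 2.0, (nue * Ve + arma::dot(e, e)) / 2.0);
    }

    if (!beta.is_finite() || !uf.is_finite() || !um.is_finite() ||
        !std::isfinite(s2f) || !std::isfinite(s2m) || !std::isfinite(s2e)) {
      stop("non-finite draw at sweep %d", it);
    }

    if (it > burnin && (it - burnin) % thin == 0) {
      for (int j = 0; j < p; ++j) draws(row, j) = beta(j);
      draws(row, p) = s2f;
      draws(row, p + 1) = s2m;
      draws(row, p + 2) = s2e;
      if (keep_u) {
        for (int j = 0; j < qf; ++j) u_draws(row, j) = uf(j);
        for (int j = 0; j < qm; ++j) u_draws(row, qf + j) = um(j);
      }
      ++row;
    }
  }

  List out = List::create(Named("draws") = draws);
  if (keep_u) out["u_draws"] = u_draws;
  return out;
}
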