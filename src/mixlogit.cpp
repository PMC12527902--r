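// Panel mixed logit simulated log-likelihood with analytic score.
//
// Data layout contract (enforced by the R wrapper): rows sorted by
// respondent, task, alternative; a fixed number of alternatives per task;
// tasks of a respondent contiguous. The simulated likelihood for
// respondent i averages, over draws r, the product over the respondent's
// tasks of the MNL probability of the chosen alternative under
// beta_ir = mu + sd (.) z_ir on the random design columns.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List mixl_loglik_cpp(const arma::vec& mu,        // K fixed part-worth means
                     double asc,                 // opt-out constant
                     const arma::vec& sd,        // n_rand sds (may be negative)
                     const arma::mat& X,         // n_rows x K design matrix
                     const arma::vec& optout,    // n_rows opt-out indicator
                     const arma::uvec& resp0,    // 0-based respondent per row
                     const arma::uvec& chosen_row0, // 0-based chosen row per task
                     int n_alt,
                     int n_resp,
                     const arma::cube& Z,        // n_resp x n_draws x n_rand
                     const arma::uvec& rand_col0, // 0-based random X columns
                     bool want_grad) {
  const int n_rows = X.n_rows;
  const int K = X.n_cols;
  const int n_task = n_rows / n_alt;
  const int R = Z.n_slices > 0 ? (int)Z.n_cols : 1;
  const int n_rand = rand_col0.n_elem;

  // random-part columns pre-extracted for cache friendliness
  arma::mat Xr(n_rows, n_rand);
  for (int k = 0; k < n_rand; ++k) Xr.col(k) = X.col(rand_col0[k]);

  arma::vec Vfix = X * mu + asc * optout;          // fixed utility part

  arma::mat lP(n_resp, R, arma::fill::zeros);       // log panel prob per draw
  arma::mat P;                                      // row probabilities
  if (want_grad) P.set_size(n_rows, R);

  arma::vec U(n_alt);
  for (int r = 0; r < R; ++r) {
    for (int t = 0; t < n_task; ++t) {
      const int row0 = t * n_alt;
      const int i = resp0[row0];
      double umax = -arma::datum::inf;
      for (int j = 0; j < n_alt; ++j) {
        const int row = row0 + j;
        double u = Vfix[row];
        for (int k = 0; k < n_rand; ++k) {
          const double x = Xr(row, k);
          if (x != 0.0) u += x * sd[k] * Z(i, r, k);
        }
        U[j] = u;
        if (u > umax) umax = u;
      }
      double den = 0.0;
      for (int j = 0; j < n_alt; ++j) { U[j] = std::exp(U[j] - umax); den += U[j]; }
      const int ch = chosen_row0[t] - row0;
      lP(i, r) += std::log(U[ch] / den);
      if (want_grad) {
        for (int j = 0; j < n_alt; ++j) P(row0 + j, r) = U[j] / den;
      }
    }
  }

  // log-sum-exp over draws per respondent
  double ll = 0.0;
  arma::mat W;
  if (want_grad) W.set_size(n_resp, R);
  for (int i = 0; i < n_resp; ++i) {
    double m = lP.row(i).max();
    double s = 0.0;
    for (int r = 0; r < R; ++r) s += std::exp(lP(i, r) - m);
    ll += m + std::log(s / R);
    if (want_grad) {
      for (int r = 0; r < R; ++r) W(i, r) = std::exp(lP(i, r) - m) / s;
    }
  }

  if (!want_grad) return List::create(_["loglik"] = ll);

  // score: d ll / d mu_k = sum_{i,r} W_ir sum_rows (chosen - p) x_k,
  // sd_k picks up the extra factor z_irk, asc the opt-out indicator
  arma::vec g_mu(K, arma::fill::zeros);
  double g_asc = 0.0;
  arma::vec g_sd(n_rand, arma::fill::zeros);
  for (int r = 0; r < R; ++r) {
    for (int t = 0; t < n_task; ++t) {
      const int row0 = t * n_alt;
      const int i = resp0[row0];
      const double w = W(i, r);
      for (int j = 0; j < n_alt; ++j) {
        const int row = row0 + j;
        double res = -P(row, r);
        if ((int)chosen_row0[t] == row) res += 1.0;
        const double c = w * res;
        if (c == 0.0) continue;
        for (int k = 0; k < K; ++k) {
          const double x = X(row, k);
          if (x != 0.0) g_mu[k] += c * x;
        }
        if (optout[row] != 0.0) g_asc += c * optout[row];
        for (int k = 0; k < n_rand; ++k) {
          const double x = Xr(row, k);
          if (x != 0.0) g_sd[k] += c * x * Z(i, r, k);
        }
      }
    }
  }
  arma::vec grad(K + 1 + n_rand);
  grad.subvec(0, K - 1) = g_mu;
  grad[K] = g_asc;
  if (n_rand > 0) grad.subvec(K + 1, K + n_rand) = g_sd;
  return List::create(_["loglik"] = ll, _["gradient"] = grad);
}
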