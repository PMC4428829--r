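// Batch engine for the studentized rank statistics.
//
// All inputs arrive as pooled mid-rank matrices (N x d): pooled ranks are
// invariant under permutation of the unit labels, so per permutation only
// the within-pseudo-group mid-ranks have to be recomputed.  Ties in the
// raw data are preserved exactly by the pooled mid-ranks (x_i == x_j iff
// equal mid-rank), hence ranking the ranks is ranking the data.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// mid-ranks of v (ties averaged), written into out
static void midranks_vec(const arma::vec& v, arma::vec& out) {
  const arma::uword n = v.n_elem;
  arma::uvec ord = arma::stable_sort_index(v);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && v(ord(j + 1)) == v(ord(i))) ++j;
    double mr = 0.5 * (double)(i + j) + 1.0;   // average of ranks i+1..j+1
    for (arma::uword k = i; k <= j; ++k) out(ord(k)) = mr;
    i = j + 1;
  }
}

// placements and relative effects for one pseudo-grouping.
// PR: pooled midranks (N x d); rowsA/rowsB: 0-based unit indices.
static void group_stats(const arma::mat& PR, const arma::uvec& rowsA,
                        const arma::uvec& rowsB, arma::vec& p_hat,
                        arma::mat& V, arma::mat& YA, arma::mat& YB,
                        arma::vec& wrk_a, arma::vec& wrk_b) {
  const arma::uword nA = rowsA.n_elem, nB = rowsB.n_elem, d = PR.n_cols;
  const double N = (double)(nA + nB);
  for (arma::uword l = 0; l < d; ++l) {
    arma::vec vA(nA), vB(nB);
    for (arma::uword k = 0; k < nA; ++k) vA(k) = PR(rowsA(k), l);
    for (arma::uword k = 0; k < nB; ++k) vB(k) = PR(rowsB(k), l);
    midranks_vec(vA, wrk_a);
    midranks_vec(vB, wrk_b);
    for (arma::uword k = 0; k < nA; ++k)
      YA(k, l) = (vA(k) - wrk_a(k)) / (double)nB;
    for (arma::uword k = 0; k < nB; ++k)
      YB(k, l) = (vB(k) - wrk_b(k)) / (double)nA;
  }
  p_hat = arma::mean(YB, 0).t();
  V = (N / (double)nA) * arma::cov(YA) + (N / (double)nB) * arma::cov(YB);
  V = 0.5 * (V + V.t());
}

// quadratic form N * diff' pinv(Vs) diff with spectral pseudoinverse;
// eigenvalues below tol_rel * max eigenvalue are treated as zero.
static void quad_form(const arma::vec& diff, const arma::mat& Vs, double N,
                      double tol_rel, double& stat, int& df) {
  arma::vec ev;
  arma::mat Q;
  arma::eig_sym(ev, Q, Vs);
  double mx = ev.max();
  stat = 0.0;
  df = 0;
  if (!(mx > 0.0)) return;           // rank 0: undefined statistic
  const double tol = tol_rel * mx;
  for (arma::uword j = 0; j < ev.n_elem; ++j) {
    if (ev(j) > tol) {
      double proj = arma::dot(Q.col(j), diff);
      stat += proj * proj / ev(j);
      ++df;
    }
  }
  stat *= N;
  if (stat < 0.0) stat = 0.0;
}

// [[Rcpp::export]]
List cpp_sample_stats(const arma::mat& PR, int nA, int nB) {
  arma::uvec rowsA = arma::regspace<arma::uvec>(0, nA - 1);
  arma::uvec rowsB = arma::regspace<arma::uvec>(nA, nA + nB - 1);
  const arma::uword d = PR.n_cols;
  arma::vec p_hat(d);
  arma::mat V(d, d), YA(nA, d), YB(nB, d);
  arma::vec wa(nA), wb(nB);
  group_stats(PR, rowsA, rowsB, p_hat, V, YA, YB, wa, wb);
  return List::create(_["p_hat"] = p_hat, _["v_hat"] = V);
}

// [[Rcpp::export]]
List cpp_wald_subsets(const arma::vec& p_hat, const arma::mat& V,
                      const List& subsets, double N, double tol_rel) {
  const int S = subsets.size();
  NumericVector stats(S);
  IntegerVector dfs(S);
  arma::vec centered = p_hat - 0.5;
  for (int s = 0; s < S; ++s) {
    arma::uvec idx = as<arma::uvec>(subsets[s]) - 1;
    arma::vec diff = centered.elem(idx);
    arma::mat Vs = V.submat(idx, idx);
    double st; int df;
    quad_form(diff, Vs, N, tol_rel, st, df);
    stats[s] = st;
    dfs[s] = df;
  }
  return List::create(_["statistic"] = stats, _["df"] = dfs);
}

// Permutation null for every subset over a shared plan.
// perms: N x P matrix of 1-based permutations (columns); canonical unit
// order has group A in rows 1..nA.  Centering follows the tau-dependent
// mixture around the observed p_hat.
// [[Rcpp::export]]
List cpp_perm_null(const arma::mat& PR, const IntegerMatrix& perms,
                   int nA, int nB, const arma::vec& p_obs,
                   const List& subsets, double tol_rel) {
  const int N = nA + nB, P = perms.ncol(), S = subsets.size();
  if (perms.nrow() != N) stop("permutation length != N");
  std::vector<arma::uvec> idx(S);
  for (int s = 0; s < S; ++s) idx[s] = as<arma::uvec>(subsets[s]) - 1;
  const arma::uword d = PR.n_cols;
  arma::mat W(P, S), V(d, d), YA(nA, d), YB(nB, d);
  arma::vec tau(P), p_hat(d), wa(nA), wb(nB);
  arma::uvec rowsA(nA), rowsB(nB);
  const double ratio = 1.0 + (double)nA / (double)nB;
  for (int p = 0; p < P; ++p) {
    int nbFront = 0;
    for (int k = 0; k < nA; ++k) {
      rowsA(k) = perms(k, p) - 1;
      if ((int)rowsA(k) >= nA) ++nbFront;
    }
    for (int k = 0; k < nB; ++k) rowsB(k) = perms(nA + k, p) - 1;
    const double t = (double)nbFront / (double)nA;
    tau(p) = t;
    group_stats(PR, rowsA, rowsB, p_hat, V, YA, YB, wa, wb);
    const double a = t * ratio;
    arma::vec ctr = a * 0.5 + (1.0 - a) * p_obs;
    arma::vec centered = p_hat - ctr;
    for (int s = 0; s < S; ++s) {
      arma::vec diff = centered.elem(idx[s]);
      arma::mat Vs = V.submat(idx[s], idx[s]);
      double st; int df;
      quad_form(diff, Vs, (double)N, tol_rel, st, df);
      W(p, s) = st;
    }
    if (p % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["w"] = W, _["tau"] = tau);
}
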