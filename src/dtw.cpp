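// Weighted DTW over feature contours and the Metropolis-Hastings weight
// calibration chain. Contour matrices are frames x features; point cost is
// the weighted Euclidean distance between frames, and the dissimilarity is
// the optimal monotone alignment's total cost divided by its path length.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double dtw_pair(const arma::mat& A, const arma::mat& B,
                       const arma::vec& w) {
  const arma::uword n = A.n_rows, m = B.n_rows, F = A.n_cols;
  arma::mat G(n, m);
  // cumulative cost
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < m; ++j) {
      double c = 0.0;
      for (arma::uword f = 0; f < F; ++f) {
        const double d = A(i, f) - B(j, f);
        c += w(f) * d * d;
      }
      c = std::sqrt(c);
      double best;
      if (i == 0 && j == 0) best = 0.0;
      else if (i == 0) best = G(0, j - 1);
      else if (j == 0) best = G(i - 1, 0);
      else best = std::min(G(i - 1, j - 1),
                           std::min(G(i - 1, j), G(i, j - 1)));
      G(i, j) = c + best;
    }
  }
  // backtrack to measure path length (diagonal preferred on exact ties)
  arma::uword i = n - 1, j = m - 1, len = 1;
  while (i > 0 || j > 0) {
    if (i == 0) { --j; }
    else if (j == 0) { --i; }
    else {
      const double dg = G(i - 1, j - 1), up = G(i - 1, j), lf = G(i, j - 1);
      if (dg <= up && dg <= lf) { --i; --j; }
      else if (up <= lf) { --i; }
      else { --j; }
    }
    ++len;
  }
  return G(n - 1, m - 1) / static_cast<double>(len);
}

// [[Rcpp::export]]
double dtw_cost_cpp(const arma::mat& A, const arma::mat& B,
                    const arma::vec& w) {
  return dtw_pair(A, B, w);
}

// [[Rcpp::export]]
arma::mat dtw_matrix_cpp(const List& contours, const arma::vec& w) {
  const int n = contours.size();
  std::vector<arma::mat> C(n);
  for (int i = 0; i < n; ++i) C[i] = as<arma::mat>(contours[i]);
  arma::mat D(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      D(i, j) = D(j, i) = dtw_pair(C[i], C[j], w);
  return D;
}

// Summed decision log-likelihood over triplets for one weight vector.
// Pairs are unique (probe, stimulus) contour pairs; each triplet points at
// the pair indices of its chosen (positive) and unchosen (negative) side.
// Xp is oriented so the chosen side is A: ll = sum log(1/(1+exp(4*Xp))).
static double triplet_loglik(const arma::vec& dist,
                             const std::vector<std::vector<int>>& pos,
                             const std::vector<std::vector<int>>& neg) {
  double ll = 0.0;
  for (size_t t = 0; t < pos.size(); ++t) {
    double dp = 0.0, dn = 0.0;
    for (int k : pos[t]) dp += dist(k);
    for (int k : neg[t]) dn += dist(k);
    dp /= pos[t].size();
    dn /= neg[t].size();
    const double denom = dp + dn;
    const double xp = denom > 0 ? (dp - dn) / denom : 0.0;
    // log(1/(1+exp(4 xp))) computed stably
    ll += -R::log1pexp(4.0 * xp);
  }
  return ll;
}

static void recompute_dists(const std::vector<arma::mat>& C,
                            const IntegerVector& pair_i,
                            const IntegerVector& pair_j,
                            const arma::vec& w, arma::vec& out) {
  const int P = pair_i.size();
  for (int p = 0; p < P; ++p)
    out(p) = dtw_pair(C[pair_i[p]], C[pair_j[p]], w);
}

// [[Rcpp::export]]
List mcmc_tune_cpp(const List& contours, const IntegerVector& pair_i,
                   const IntegerVector& pair_j, const List& pos_pairs,
                   const List& neg_pairs, const arma::vec& w_init,
                   const int n_iter, const double proposal_sd,
                   const bool jacobian) {
  const int n = contours.size();
  std::vector<arma::mat> C(n);
  for (int i = 0; i < n; ++i) C[i] = as<arma::mat>(contours[i]);
  const int T = pos_pairs.size();
  std::vector<std::vector<int>> pos(T), neg(T);
  for (int t = 0; t < T; ++t) {
    pos[t] = as<std::vector<int>>(pos_pairs[t]);
    neg[t] = as<std::vector<int>>(neg_pairs[t]);
  }
  const int F = w_init.n_elem;
  arma::vec w = w_init / arma::accu(w_init);
  arma::vec dist(pair_i.size()), dist_prop(pair_i.size());
  recompute_dists(C, pair_i, pair_j, w, dist);
  double ll = triplet_loglik(dist, pos, neg);
  if (!std::isfinite(ll)) stop("non-finite likelihood at initial weights");

  arma::mat samples(n_iter, F);
  arma::vec ll_trace(n_iter);
  LogicalVector accepted(n_iter);
  RNGScope scope;
  for (int it = 0; it < n_iter; ++it) {
    arma::vec wp(F);
    for (int f = 0; f < F; ++f)
      wp(f) = w(f) * std::exp(norm_rand() * proposal_sd);
    wp /= arma::accu(wp);
    recompute_dists(C, pair_i, pair_j, wp, dist_prop);
    const double llp = triplet_loglik(dist_prop, pos, neg);
    if (!std::isfinite(llp)) stop("non-finite likelihood in proposal");
    double log_alpha = llp - ll;
    if (jacobian)
      log_alpha += arma::accu(arma::log(wp)) - arma::accu(arma::log(w));
    const bool acc = std::log(unif_rand()) < log_alpha;
    if (acc) {
      w = wp;
      ll = llp;
      dist = dist_prop;
    }
    samples.row(it) = w.t();
    ll_trace(it) = ll;
    accepted[it] = acc;
  }
  return List::create(_["samples"] = samples, _["log_likelihood"] = ll_trace,
                      _["accepted"] = accepted);
}
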