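// Sequential inner recursions of the Gaussian-observation HMM: scaled
// forward-backward (E-step sufficient statistics) and Viterbi decoding.
// Emission log-densities are computed in R with BLAS; only the O(T K^2)
// recursions live here.
#include <RcppArmadillo.h>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Forward-backward over one or more independent segments.
// logB: T x K emission log-densities; segments: 2-col 1-based (start, end)
// inclusive rows of logB; each segment restarts the chain at pi.
// Returns gamma (T x K posteriors), xi (K x K summed expected transition
// counts), and the total log-likelihood.
// [[Rcpp::export(name = ".fb_cpp")]]
List fb_cpp(const arma::mat& logB, const arma::vec& pi, const arma::mat& A,
            const arma::imat& segments) {
  const int T = logB.n_rows, K = logB.n_cols;
  arma::mat gamma(T, K, arma::fill::zeros);
  arma::mat xi(K, K, arma::fill::zeros);
  double loglik = 0.0;

  arma::mat At = A.t();
  for (arma::uword s = 0; s < segments.n_rows; ++s) {
    const int t0 = segments(s, 0) - 1, t1 = segments(s, 1) - 1;
    const int n = t1 - t0 + 1;
    arma::mat alpha(n, K), beta(n, K);
    arma::vec scale(n);
    // stabilise emissions per sample
    arma::mat B(n, K);
    for (int t = 0; t < n; ++t) {
      arma::rowvec lb = logB.row(t0 + t);
      double m = lb.max();
      B.row(t) = arma::exp(lb - m);
      scale(t) = m;  // reuse: log of the subtracted max
    }
    arma::vec c(n);
    arma::rowvec a = pi.t() % B.row(0);
    c(0) = arma::accu(a);
    alpha.row(0) = a / c(0);
    for (int t = 1; t < n; ++t) {
      a = (alpha.row(t - 1) * A) % B.row(t);
      c(t) = arma::accu(a);
      alpha.row(t) = a / c(t);
    }
    beta.row(n - 1).ones();
    for (int t = n - 2; t >= 0; --t) {
      arma::rowvec b = (beta.row(t + 1) % B.row(t + 1)) * At;
      beta.row(t) = b / c(t + 1);
    }
    for (int t = 0; t < n; ++t) {
      arma::rowvec g = alpha.row(t) % beta.row(t);
      gamma.row(t0 + t) = g / arma::accu(g);
    }
    for (int t = 0; t < n - 1; ++t) {
      arma::mat x = (alpha.row(t).t() * (beta.row(t + 1) % B.row(t + 1))) % A / c(t + 1);
      xi += x;
    }
    loglik += arma::accu(arma::log(c)) + arma::accu(scale);
  }
  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = loglik);
}

// Viterbi decoding over independent segments; ties broken toward the lower
// state index (strict improvement required to switch candidate).
// [[Rcpp::export(name = ".viterbi_cpp")]]
IntegerVector viterbi_cpp(const arma::mat& logB, const arma::vec& logpi,
                          const arma::mat& logA, const arma::imat& segments) {
  const int T = logB.n_rows, K = logB.n_cols;
  IntegerVector path(T);
  for (arma::uword s = 0; s < segments.n_rows; ++s) {
    const int t0 = segments(s, 0) - 1, t1 = segments(s, 1) - 1;
    const int n = t1 - t0 + 1;
    arma::mat delta(n, K);
    arma::imat psi(n, K, arma::fill::zeros);
    delta.row(0) = logpi.t() + logB.row(t0);
    for (int t = 1; t < n; ++t) {
      for (int k = 0; k < K; ++k) {
        double best = delta(t - 1, 0) + logA(0, k);
        int arg = 0;
        for (int j = 1; j < K; ++j) {
          double v = delta(t - 1, j) + logA(j, k);
          if (v > best) { best = v; arg = j; }
        }
        delta(t, k) = best + logB(t0 + t, k);
        psi(t, k) = arg;
      }
    }
    int k = 0;
    for (int j = 1; j < K; ++j) if (delta(n - 1, j) > delta(n - 1, k)) k = j;
    path[t0 + n - 1] = k + 1;
    for (int t = n - 1; t > 0; --t) {
      k = psi(t, k);
      path[t0 + t - 1] = k + 1;
    }
  }
  return path;
}

// Per-permutation maximum component size: stats is E x P (edge statistics
// for P permutations, aligned with `edges` rows); returns for each column
// the maximum connected-component edge count among edges whose statistic
// exceeds thr (direction +1) or falls below -thr (direction -1). NaNs are
// excluded.
// [[Rcpp::export(name = ".nbs_maxcomp_cpp")]]
IntegerVector nbs_maxcomp_cpp(const arma::mat& stats, const IntegerMatrix& edges,
                              int n_nodes, double thr, int direction) {
  const int E = stats.n_rows, P = stats.n_cols;
  IntegerVector out(P);
  std::vector<int> parent(n_nodes + 1), esz(n_nodes + 1);
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int p = 0; p < P; ++p) {
    bool any = false;
    for (int e = 0; e < E; ++e) {
      double v = stats(e, p);
      if (std::isnan(v)) continue;
      if ((direction > 0 && v > thr) || (direction < 0 && v < -thr)) {
        if (!any) {  // lazy reset of the union-find
          for (int i = 0; i <= n_nodes; ++i) { parent[i] = i; esz[i] = 0; }
          any = true;
        }
        int a = find(edges(e, 0)), b = find(edges(e, 1));
        if (a != b) { parent[a] = b; esz[b] += esz[a] + 1; }
        else esz[a] += 1;
      }
    }
    int best = 0;
    if (any)
      for (int i = 1; i <= n_nodes; ++i)
        if (parent[i] == i && esz[i] > best) best = esz[i];
    out[p] = best;
  }
  return out;
}

// Maximum connected-component edge count over the suprathreshold graph.
// edges: 2-col 1-based node pairs already above threshold. Union-find.
// [[Rcpp::export(name = ".max_component_cpp")]]
int max_component_cpp(const IntegerMatrix& edges, int n_nodes) {
  if (edges.nrow() == 0) return 0;
  std::vector<int> parent(n_nodes + 1), esz(n_nodes + 1, 0);
  for (int i = 0; i <= n_nodes; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = find(edges(e, 0)), b = find(edges(e, 1));
    if (a != b) { parent[a] = b; esz[b] += esz[a] + 1; }
    else esz[a] += 1;
  }
  int best = 0;
  for (int i = 1; i <= n_nodes; ++i)
    if (parent[i] == i && esz[i] > best) best = esz[i];
  return best;
}
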