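// Multiplicative-update NMF under the Kullback-Leibler divergence
// (Brunet formulation).  Initial factors are generated on the R side so
// that all randomness flows through R's seeded RNG; the update loop here
// is fully deterministic.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double EPS = 1e-16;

// D(V || WH) = sum( V * log(V / WH) - V + WH ), terms with V == 0
// contribute WH only.  The V-only part (sum V log V - sum V) is constant
// over iterations, so the loop evaluates only -sum_{V>0} V log(WH) + sum WH
// against precomputed positive-entry indices.
struct KLParts {
  uvec pos;        // indices of V > 0
  vec v_pos;       // V at those indices
  double const_term;  // sum(V log V) - sum(V)
};

static KLParts kl_prepare(const mat& V) {
  KLParts p;
  p.pos = find(V > 0.0);
  p.v_pos = V.elem(p.pos);
  p.const_term = accu(p.v_pos % log(p.v_pos)) - accu(V);
  return p;
}

static double kl_divergence(const KLParts& p, const mat& WH) {
  vec wh = WH.elem(p.pos);
  wh.transform([](double x) { return std::max(x, EPS); });
  return p.const_term - accu(p.v_pos % log(wh)) + accu(WH);
}

// [[Rcpp::export(name = ".nmf_brunet_cpp")]]
Rcpp::List nmf_brunet_cpp(const arma::mat& V,
                          arma::mat W,
                          arma::mat H,
                          int max_iter,
                          double tol,
                          int window) {
  const uword n = V.n_rows;
  const uword m = V.n_cols;
  std::vector<double> trace;
  trace.reserve(static_cast<size_t>(max_iter) + 1);

  const KLParts parts = kl_prepare(V);
  mat WH = W * H;
  trace.push_back(kl_divergence(parts, WH));
  bool converged = false;
  int iter = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    // H update: H <- H % (W' (V / WH)) / (W' 1)
    mat Q = V / (WH + EPS);              // n x m
    vec wsum = sum(W, 0).t();            // k
    H = H % (W.t() * Q);
    H.each_col() /= (wsum + EPS);

    // W update with refreshed WH
    WH = W * H;
    Q = V / (WH + EPS);
    rowvec hsum = sum(H, 1).t();         // k
    W = W % (Q * H.t());
    W.each_row() /= (hsum + EPS);

    WH = W * H;
    trace.push_back(kl_divergence(parts, WH));

    if (iter >= window) {
      const double prev = trace[iter - window];
      const double cur = trace[iter];
      const double rel = (prev - cur) / std::max(std::abs(prev), EPS);
      if (rel < tol) { converged = true; break; }
    }
  }
  (void)n; (void)m;

  return Rcpp::List::create(
    Rcpp::Named("W") = W,
    Rcpp::Named("H") = H,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("n_iter") = std::min(iter, max_iter),
    Rcpp::Named("converged") = converged);
}
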