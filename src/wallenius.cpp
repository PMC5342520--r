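#include <Rcpp.h>
using namespace Rcpp;

// Exact pmf of the Wallenius noncentral hypergeometric distribution by
// forward recursion over draw states. The urn holds n balls, m1 of them
// "red" with odds weight w and n - m1 "white" with weight 1; x balls are
// drawn sequentially without replacement, each removal probability
// proportional to the remaining weight of its colour. Because the remaining
// urn depends only on how many of each colour have been drawn, the draw
// count pair is a Markov state and the pmf follows exactly from
//   P(red | j drawn, k red) = w (m1 - k) / (w (m1 - k) + (n - m1 - (j - k))).
// Returns P(X = k) for k = 0..x (entries outside the feasible support are 0).
// [[Rcpp::export]]
NumericVector wallenius_pmf_cpp(int n, int m1, int x, double w) {
  if (n < 0 || m1 < 0 || m1 > n || x < 0 || x > n)
    stop("infeasible urn: need 0 <= m1 <= n and 0 <= x <= n");
  if (!(w > 0) || !R_finite(w))
    stop("weight w must be positive and finite");
  std::vector<double> f(x + 1, 0.0), g(x + 1, 0.0);
  f[0] = 1.0;
  int m2max = std::min(x, m1);
  for (int j = 0; j < x; ++j) {
    std::fill(g.begin(), g.end(), 0.0);
    int kmax = std::min(j, m2max);
    for (int k = 0; k <= kmax; ++k) {
      double fk = f[k];
      if (fk == 0.0) continue;
      double redW = w * (double)(m1 - k);
      double whiteW = (double)(n - m1 - (j - k));
      double denom = redW + whiteW;
      // denom > 0 is guaranteed while j < x <= n
      double pRed = redW / denom;
      if (pRed > 0.0) g[k + 1] += fk * pRed;
      if (pRed < 1.0) g[k] += fk * (1.0 - pRed);
    }
    std::swap(f, g);
  }
  NumericVector out(x + 1);
  for (int k = 0; k <= x; ++k) out[k] = f[k];
  return out;
}
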