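#include <Rcpp.h>
using namespace Rcpp;

// Expected tree output under a feature coalition S: features in S follow the
// query point x, features outside S are marginalized with path-dependent
// weights (training cover counts of the child nodes).
static double tree_expect(const IntegerVector& feat,
                          const NumericVector& thresh,
                          const IntegerVector& left,
                          const IntegerVector& right,
                          const NumericVector& cover,
                          const NumericVector& value,
                          const NumericVector& x,
                          unsigned int mask, int node) {
  int f = feat[node];
  if (f < 0) return value[node];
  int l = left[node], r = right[node];
  if (mask & (1u << f)) {
    int nxt = (x[f] < thresh[node]) ? l : r;
    return tree_expect(feat, thresh, left, right, cover, value, x, mask, nxt);
  }
  double cl = cover[l], cr = cover[r], ct = cl + cr;
  if (ct <= 0) return value[node];
  return (cl * tree_expect(feat, thresh, left, right, cover, value, x, mask, l)
        + cr * tree_expect(feat, thresh, left, right, cover, value, x, mask, r))
         / ct;
}

// Exact Shapley attributions for an ensemble of binary trees by full
// coalition enumeration (2^p subsets; p capped by the R caller). Each tree
// is a list with integer vectors feat (0-based, -1 = leaf), left, right,
// numeric thresh, cover (training sample count per node) and value (leaf
// prediction). The ensemble output is the mean over trees.
// [[Rcpp::export]]
List shap_enumerate(List trees, NumericVector x, int p) {
  if (p > 20) stop("coalition enumeration limited to 20 features");
  unsigned int nmask = 1u << p;
  int nt = trees.size();

  // Shapley kernel weights w[s] = s! (p-1-s)! / p!
  std::vector<double> w(p);
  for (int s = 0; s < p; ++s) {
    double lw = 0.0;
    for (int i = 2; i <= s; ++i) lw += std::log((double)i);
    for (int i = 2; i <= p - 1 - s; ++i) lw += std::log((double)i);
    for (int i = 2; i <= p; ++i) lw -= std::log((double)i);
    w[s] = std::exp(lw);
  }

  NumericVector phi(p);
  double base = 0.0, fx = 0.0;
  std::vector<double> v(nmask);
  std::vector<int> popcnt(nmask, 0);
  for (unsigned int m = 1; m < nmask; ++m)
    popcnt[m] = popcnt[m >> 1] + (m & 1u);

  for (int t = 0; t < nt; ++t) {
    List tr = trees[t];
    IntegerVector feat = tr["feat"];
    NumericVector thresh = tr["thresh"];
    IntegerVector left = tr["left"];
    IntegerVector right = tr["right"];
    NumericVector cover = tr["cover"];
    NumericVector value = tr["value"];
    for (unsigned int m = 0; m < nmask; ++m)
      v[m] = tree_expect(feat, thresh, left, right, cover, value, x, m, 0);
    base += v[0];
    fx += v[nmask - 1];
    for (int j = 0; j < p; ++j) {
      unsigned int bit = 1u << j;
      double ph = 0.0;
      for (unsigned int m = 0; m < nmask; ++m) {
        if (m & bit) continue;
        ph += w[popcnt[m]] * (v[m | bit] - v[m]);
      }
      phi[j] += ph;
    }
  }
  for (int j = 0; j < p; ++j) phi[j] /= nt;
  return List::create(_["phi"] = phi, _["base_value"] = base / nt,
                      _["fx"] = fx / nt);
}
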