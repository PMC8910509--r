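#include <Rcpp.h>
using namespace Rcpp;

// Flat tree-ensemble representation shared with the R side:
//   feature[k]  0-based split feature, or -1 for a leaf
//   threshold[k] split point (left branch taken when x < threshold)
//   yes[k]/no[k] 0-based global node indices of the children
//   value[k]    leaf value (margin contribution, excludes base score)
//   roots       0-based index of each tree's root node

static double fact_tab[64];
static void init_fact() {
  fact_tab[0] = 1.0;
  for (int i = 1; i < 64; ++i) fact_tab[i] = fact_tab[i - 1] * i;
}

static double tree_value(const IntegerVector& feature,
                         const NumericVector& threshold,
                         const IntegerVector& yes, const IntegerVector& no,
                         const NumericVector& value, int node,
                         const double* x) {
  while (feature[node] >= 0) {
    node = (x[feature[node]] < threshold[node]) ? yes[node] : no[node];
  }
  return value[node];
}

// [[Rcpp::export]]
NumericVector predict_trees_cpp(NumericMatrix X, IntegerVector feature,
                                NumericVector threshold, IntegerVector yes,
                                IntegerVector no, NumericVector value,
                                IntegerVector roots, double base_score) {
  int n = X.nrow(), p = X.ncol();
  NumericVector out(n, base_score);
  std::vector<double> x(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    for (int t = 0; t < roots.size(); ++t) {
      out[i] += tree_value(feature, threshold, yes, no, value, roots[t],
                           x.data());
    }
  }
  return out;
}

// Exact interventional Shapley values for one foreground/background pair and
// one tree. Descend tracking the features forced present (maskX, follow x)
// and forced absent (maskB, follow b). Each leaf then corresponds to the
// indicator game u(S) = [X subset of S][B disjoint from S], whose Shapley
// values have the closed form (a-1)! b! / (a+b)! for members of X and
// -a! (b-1)! / (a+b)! for members of B (a = |X|, b = |B|).
struct ShapCtx {
  const IntegerVector* feature;
  const NumericVector* threshold;
  const IntegerVector* yes;
  const IntegerVector* no;
  const NumericVector* value;
  const double* x;
  const double* b;
  double* phi;  // length p accumulator
};

static void shap_recurse(const ShapCtx& c, int node, unsigned int maskX,
                         unsigned int maskB) {
  int f = (*c.feature)[node];
  if (f < 0) {
    double val = (*c.value)[node];
    int a = __builtin_popcount(maskX), bb = __builtin_popcount(maskB);
    if (a + bb == 0) return;  // reached by both x and b: no attribution
    double denom = fact_tab[a + bb];
    if (a > 0) {
      double w = fact_tab[a - 1] * fact_tab[bb] / denom * val;
      for (int j = 0; maskX; ++j, maskX >>= 1)
        if (maskX & 1u) c.phi[j] += w;
    }
    if (bb > 0) {
      double w = fact_tab[a] * fact_tab[bb - 1] / denom * val;
      for (int j = 0; maskB; ++j, maskB >>= 1)
        if (maskB & 1u) c.phi[j] -= w;
    }
    return;
  }
  int cx = (c.x[f] < (*c.threshold)[node]) ? (*c.yes)[node] : (*c.no)[node];
  int cb = (c.b[f] < (*c.threshold)[node]) ? (*c.yes)[node] : (*c.no)[node];
  unsigned int bit = 1u << f;
  if (cx == cb) {
    shap_recurse(c, cx, maskX, maskB);
  } else if (maskX & bit) {
    shap_recurse(c, cx, maskX, maskB);
  } else if (maskB & bit) {
    shap_recurse(c, cb, maskX, maskB);
  } else {
    shap_recurse(c, cx, maskX | bit, maskB);
    shap_recurse(c, cb, maskX, maskB | bit);
  }
}

// [[Rcpp::export]]
NumericMatrix shap_interventional_cpp(NumericMatrix X, NumericMatrix B,
                                      IntegerVector feature,
                                      NumericVector threshold,
                                      IntegerVector yes, IntegerVector no,
                                      NumericVector value,
                                      IntegerVector roots) {
  init_fact();
  int n = X.nrow(), p = X.ncol(), nb = B.nrow(), nt = roots.size();
  if (p > 31) stop("more than 31 features not supported");
  NumericMatrix phi(n, p);
  std::vector<double> x(p), b(p), acc(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) x[j] = X(i, j);
    std::fill(acc.begin(), acc.end(), 0.0);
    ShapCtx c;
    c.feature = &feature; c.threshold = &threshold; c.yes = &yes;
    c.no = &no; c.value = &value; c.x = x.data(); c.phi = acc.data();
    for (int k = 0; k < nb; ++k) {
      for (int j = 0; j < p; ++j) b[j] = B(k, j);
      c.b = b.data();
      for (int t = 0; t < nt; ++t) shap_recurse(c, roots[t], 0u, 0u);
    }
    for (int j = 0; j < p; ++j) phi(i, j) = acc[j] / nb;
  }
  return phi;
}
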