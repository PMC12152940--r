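#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Regression forest engine shared by all forest families.
//
// One code path covers every variant so that setting a knob to its neutral
// value reproduces the plain random forest exactly (same RNG draw order):
//   - bootstrap indices drawn with per-sample probabilities `prob`
//     (uniform prob == ordinary bootstrap)
//   - split criterion is weighted variance reduction with per-sample case
//     weights `casew` (all-ones == unweighted CART criterion)
//   - per-tree Gaussian target noise with per-sample sd `smear_sd`
//     (length 0 == no smearing; draws happen before the bootstrap draw so the
//     RNG stream is identical across smearing variants)
//   - `mtry` features sampled without replacement at every node
// Uses R's RNG (RNGScope) so results are reproducible from set.seed().

struct TreeNodes {
  std::vector<int> feature;      // -1 for leaf
  std::vector<double> threshold;
  std::vector<int> left, right;  // 0-based node ids
  std::vector<double> value;     // weighted mean of node targets
};

struct GrowCtx {
  const double* X; int n; int p;
  const unsigned char* Xb;        // byte-packed copy of binary columns
  std::vector<double> y;          // per-tree (possibly smeared) targets
  std::vector<int> idx;           // bootstrap instance -> row of X
  std::vector<double> w;          // case weight per bootstrap instance
  std::vector<double> wy;         // w * y per bootstrap instance
  int mtry, min_split;
  std::vector<char> binary;       // column has only {0,1} values?
  std::vector<int> perm;          // scratch for feature subsampling
  TreeNodes* tree;
};

// partial Fisher-Yates draw of mtry feature indices using R's RNG
static void sample_features(GrowCtx& c) {
  int p = c.p;
  for (int j = 0; j < c.mtry; ++j) {
    int k = j + (int)(unif_rand() * (p - j));
    if (k >= p) k = p - 1;
    std::swap(c.perm[j], c.perm[k]);
  }
}

static int new_node(TreeNodes& t) {
  t.feature.push_back(-1); t.threshold.push_back(0.0);
  t.left.push_back(-1); t.right.push_back(-1); t.value.push_back(0.0);
  return (int)t.feature.size() - 1;
}

// Grow node over instances items[lo..hi); returns node id.
static int grow(GrowCtx& c, std::vector<int>& items, int lo, int hi) {
  TreeNodes& t = *c.tree;
  int id = new_node(t);
  int m = hi - lo;
  double W = 0.0, S = 0.0, Q = 0.0;
  for (int k = lo; k < hi; ++k) {
    int ins = items[k];
    double wi = c.w[ins], yi = c.y[c.idx[ins]];
    W += wi; S += wi * yi; Q += wi * yi * yi;
  }
  t.value[id] = S / W;
  double ss_parent = Q - S * S / W;
  if (m < c.min_split || ss_parent <= 1e-12 * (Q + 1.0)) return id;

  // candidate features, sampled without replacement via R's RNG
  sample_features(c);
  double best_gain = 1e-12 * (ss_parent + 1.0);
  int best_f = -1; double best_thr = 0.0;
  for (int fi = 0; fi < c.mtry; ++fi) {
    int f = c.perm[fi];
    const double* col = c.X + (size_t)f * c.n;
    if (c.binary[f]) {
      // byte-packed column + cached w*y keep this scan cache-resident
      const unsigned char* colb = c.Xb + (size_t)f * c.n;
      double W1 = 0.0, S1 = 0.0; int n1 = 0;
      for (int k = lo; k < hi; ++k) {
        int ins = items[k];
        if (colb[c.idx[ins]]) {
          W1 += c.w[ins]; S1 += c.wy[ins]; ++n1;
        }
      }
      if (n1 == 0 || n1 == m) continue;
      double W0 = W - W1, S0 = S - S1;
      double gain = S0 * S0 / W0 + S1 * S1 / W1 - S * S / W;
      if (gain > best_gain) { best_gain = gain; best_f = f; best_thr = 0.5; }
    } else {
      std::vector<int> ord(m);
      for (int k = 0; k < m; ++k) ord[k] = items[lo + k];
      std::sort(ord.begin(), ord.end(), [&](int a, int b) {
        return col[c.idx[a]] < col[c.idx[b]];
      });
      double WL = 0.0, SL = 0.0;
      for (int k = 0; k + 1 < m; ++k) {
        int ins = ord[k];
        double wi = c.w[ins];
        WL += wi; SL += wi * c.y[c.idx[ins]];
        double xk = col[c.idx[ord[k]]], xk1 = col[c.idx[ord[k + 1]]];
        if (xk1 <= xk) continue;
        double WR = W - WL, SR = S - SL;
        double gain = SL * SL / WL + SR * SR / WR - S * S / W;
        if (gain > best_gain) {
          best_gain = gain; best_f = f; best_thr = 0.5 * (xk + xk1);
        }
      }
    }
  }
  if (best_f < 0) return id;

  const double* col = c.X + (size_t)best_f * c.n;
  int mid = lo;
  for (int k = lo; k < hi; ++k)
    if (col[c.idx[items[k]]] <= best_thr) std::swap(items[k], items[mid++]);
  if (mid == lo || mid == hi) return id; // numerical guard, should not happen

  t.feature[id] = best_f; t.threshold[id] = best_thr;
  int l = grow(c, items, lo, mid);
  int r = grow(c, items, mid, hi);
  t.left[id] = l; t.right[id] = r;
  return id;
}

// [[Rcpp::export(name = ".grow_forest_cpp")]]
List grow_forest_cpp(NumericMatrix X, NumericVector y, NumericVector prob,
                     NumericVector casew, NumericVector smear_sd,
                     int ntrees, int mtry, int min_split, bool keep_inbag) {
  int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("length(y) must equal nrow(X)");
  RNGScope rng;

  std::vector<char> binary(p, 1);
  for (int f = 0; f < p; ++f) {
    const double* col = &X(0, f);
    for (int i = 0; i < n; ++i)
      if (col[i] != 0.0 && col[i] != 1.0) { binary[f] = 0; break; }
  }
  std::vector<unsigned char> Xb((size_t)n * p, 0);
  for (int f = 0; f < p; ++f) {
    if (!binary[f]) continue;
    const double* col = &X(0, f);
    unsigned char* dst = &Xb[(size_t)f * n];
    for (int i = 0; i < n; ++i) dst[i] = col[i] != 0.0;
  }

  bool smear = smear_sd.size() > 0;
  List trees(ntrees);
  IntegerMatrix inbag;
  if (keep_inbag) inbag = IntegerMatrix(n, ntrees);

  GrowCtx ctx;
  ctx.X = X.begin(); ctx.n = n; ctx.p = p;
  ctx.Xb = Xb.data();
  ctx.mtry = std::min(std::max(mtry, 1), p);
  ctx.min_split = std::max(min_split, 2);
  ctx.binary = binary;
  ctx.perm.resize(p);
  for (int f = 0; f < p; ++f) ctx.perm[f] = f;

  for (int b = 0; b < ntrees; ++b) {
    ctx.y.assign(y.begin(), y.end());
    if (smear) {
      for (int i = 0; i < n; ++i)
        if (smear_sd[i] > 0) ctx.y[i] += R::rnorm(0.0, smear_sd[i]);
    }
    // prob of length 0 disables the bootstrap (identity sample; used by
    // diagnostics and oracle tests)
    IntegerVector boot = (prob.size() == 0)
      ? seq(1, n) : IntegerVector(sample(n, n, true, prob)); // 1-based
    ctx.idx.resize(n); ctx.w.resize(n); ctx.wy.resize(n);
    for (int i = 0; i < n; ++i) {
      int row = boot[i] - 1;
      ctx.idx[i] = row;
      ctx.w[i] = casew[row];
      ctx.wy[i] = casew[row] * ctx.y[row];
      if (keep_inbag) inbag(row, b) += 1;
    }
    TreeNodes t;
    ctx.tree = &t;
    std::vector<int> items(n);
    for (int i = 0; i < n; ++i) items[i] = i;
    grow(ctx, items, 0, n);
    int nn = (int)t.feature.size();
    IntegerMatrix nodes(nn, 3);
    NumericMatrix vals(nn, 2);
    for (int k = 0; k < nn; ++k) {
      nodes(k, 0) = t.feature[k]; nodes(k, 1) = t.left[k]; nodes(k, 2) = t.right[k];
      vals(k, 0) = t.threshold[k]; vals(k, 1) = t.value[k];
    }
    trees[b] = List::create(_["nodes"] = nodes, _["vals"] = vals);
  }
  List out = List::create(_["trees"] = trees);
  if (keep_inbag) out["inbag"] = inbag;
  return out;
}

// [[Rcpp::export(name = ".predict_forest_cpp")]]
NumericMatrix predict_forest_cpp(List trees, NumericMatrix X) {
  int n = X.nrow(), ntrees = trees.size();
  NumericMatrix out(n, ntrees);
  for (int b = 0; b < ntrees; ++b) {
    List tr = trees[b];
    IntegerMatrix nodes = tr["nodes"];
    NumericMatrix vals = tr["vals"];
    for (int i = 0; i < n; ++i) {
      int k = 0;
      while (nodes(k, 0) >= 0) {
        int f = nodes(k, 0);
        k = (X(i, f) <= vals(k, 0)) ? nodes(k, 1) : nodes(k, 2);
      }
      out(i, b) = vals(k, 1);
    }
  }
  return out;
}
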