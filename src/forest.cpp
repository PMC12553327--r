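// Probability-machine random forest over 3-level categorical SNP features
// (minor-allele counts 0/1/2) plus numeric covariates.
//
// SNP splits are one-category-vs-rest binary partitions (3 candidates per
// SNP), numeric features split at midpoints between distinct sorted values.
// Split criterion: Gini impurity decrease. Candidate features at each node
// are sampled without replacement, uniformly or proportional to
// split_weights (weight-0 features are never sampled). Terminal nodes store
// the in-bag disease proportion; prediction averages terminal proportions
// across trees. Uses R's RNG, so results are reproducible via set.seed().
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct TreeBuf {
  std::vector<int> feature;     // -1 for terminal
  std::vector<int> cat_left;    // category routed left (categorical splits)
  std::vector<double> threshold; // x <= threshold goes left (numeric splits)
  std::vector<int> left, right;
  std::vector<double> prop;     // terminal disease proportion
  std::vector<int> n_node;      // in-bag samples in node
};

inline double gini(double n1, double n) {
  const double p = n1 / n;
  return 1.0 - p * p - (1.0 - p) * (1.0 - p);
}

// mtry draws without replacement; uniform or weight-proportional with
// sequential renormalization. Candidates returned sorted ascending so that
// ties in impurity decrease resolve to the lowest feature index.
void sampleCandidates(int M, int mtry, const std::vector<double>& w,
                      bool weighted, std::vector<int>& out) {
  out.clear();
  if (!weighted) {
    static thread_local std::vector<int> pool;
    pool.resize(M);
    for (int i = 0; i < M; ++i) pool[i] = i;
    const int k = std::min(mtry, M);
    for (int i = 0; i < k; ++i) {
      int j = i + (int)((M - i) * unif_rand());
      if (j >= M) j = M - 1;
      std::swap(pool[i], pool[j]);
      out.push_back(pool[i]);
    }
  } else {
    std::vector<int> ids;
    std::vector<double> ws;
    double total = 0.0;
    for (int i = 0; i < M; ++i) {
      if (w[i] > 0.0) { ids.push_back(i); ws.push_back(w[i]); total += w[i]; }
    }
    const int k = std::min<int>(mtry, (int)ids.size());
    for (int d = 0; d < k; ++d) {
      double u = unif_rand() * total, cum = 0.0;
      size_t pick = ids.size() - 1;
      for (size_t i = 0; i < ids.size(); ++i) {
        cum += ws[i];
        if (u <= cum) { pick = i; break; }
      }
      out.push_back(ids[pick]);
      total -= ws[pick];
      ids.erase(ids.begin() + pick);
      ws.erase(ws.begin() + pick);
    }
  }
  std::sort(out.begin(), out.end());
}

struct Grower {
  const NumericMatrix& X;
  const IntegerVector& y;
  const LogicalVector& is_cat;
  int mtry, min_node;
  bool weighted;
  std::vector<double> w;
  TreeBuf& tb;

  Grower(const NumericMatrix& X_, const IntegerVector& y_,
         const LogicalVector& cat_, int mtry_, int min_node_,
         const NumericVector& sw, TreeBuf& tb_)
      : X(X_), y(y_), is_cat(cat_), mtry(mtry_), min_node(min_node_),
        weighted(sw.size() > 0), tb(tb_) {
    if (weighted) w.assign(sw.begin(), sw.end());
  }

  int makeTerminal(const std::vector<int>& idx, int n1) {
    tb.feature.push_back(-1);
    tb.cat_left.push_back(-1);
    tb.threshold.push_back(NA_REAL);
    tb.left.push_back(-1);
    tb.right.push_back(-1);
    tb.prop.push_back((double)n1 / (double)idx.size());
    tb.n_node.push_back((int)idx.size());
    return (int)tb.feature.size() - 1;
  }

  int grow(const std::vector<int>& idx) {
    const int n = (int)idx.size();
    int n1 = 0;
    for (int i : idx) n1 += y[i];
    if (n1 == 0 || n1 == n || n < 2 || n < min_node)
      return makeTerminal(idx, n1);

    static thread_local std::vector<int> cand;
    sampleCandidates(X.ncol(), mtry, w, weighted, cand);

    const double g_par = gini(n1, n);
    double best_dec = 1e-12;
    int best_f = -1, best_cat = -1;
    double best_thr = NA_REAL;

    for (int f : cand) {
      if (is_cat[f]) {
        int nc[3] = {0, 0, 0}, nc1[3] = {0, 0, 0};
        for (int i : idx) {
          const int v = (int)X(i, f);
          ++nc[v];
          nc1[v] += y[i];
        }
        for (int v = 0; v < 3; ++v) {  // partition index order = category
          const int nl = nc[v];
          if (nl == 0 || nl == n) continue;
          const int nr = n - nl;
          const double dec = g_par - (nl * gini(nc1[v], nl) +
                                      nr * gini(n1 - nc1[v], nr)) / n;
          if (dec > best_dec) {
            best_dec = dec; best_f = f; best_cat = v; best_thr = NA_REAL;
          }
        }
      } else {
        static thread_local std::vector<std::pair<double, int> > vals;
        vals.clear();
        for (int i : idx) vals.push_back(std::make_pair(X(i, f), y[i]));
        std::sort(vals.begin(), vals.end());
        int nl = 0, nl1 = 0;
        for (int k = 0; k < n - 1; ++k) {
          ++nl;
          nl1 += vals[k].second;
          if (vals[k].first == vals[k + 1].first) continue;
          const int nr = n - nl;
          const double dec = g_par - (nl * gini(nl1, nl) +
                                      nr * gini(n1 - nl1, nr)) / n;
          if (dec > best_dec) {  // ascending thresholds: ties keep lowest
            best_dec = dec; best_f = f; best_cat = -1;
            best_thr = (vals[k].first + vals[k + 1].first) / 2.0;
          }
        }
      }
    }

    if (best_f < 0) return makeTerminal(idx, n1);

    std::vector<int> li, ri;
    if (best_cat >= 0) {
      for (int i : idx)
        ((int)X(i, best_f) == best_cat ? li : ri).push_back(i);
    } else {
      for (int i : idx)
        (X(i, best_f) <= best_thr ? li : ri).push_back(i);
    }

    const int me = (int)tb.feature.size();
    tb.feature.push_back(best_f);
    tb.cat_left.push_back(best_cat);
    tb.threshold.push_back(best_thr);
    tb.left.push_back(-2);
    tb.right.push_back(-2);
    tb.prop.push_back(NA_REAL);
    tb.n_node.push_back(n);
    const int l = grow(li);
    const int r = grow(ri);
    tb.left[me] = l;
    tb.right[me] = r;
    return me;
  }
};

inline int routeSample(const List& tree, const NumericMatrix& X, int s) {
  IntegerVector feature = tree["feature"];
  IntegerVector cat_left = tree["cat_left"];
  NumericVector threshold = tree["threshold"];
  IntegerVector left = tree["left"], right = tree["right"];
  int node = 0;
  while (feature[node] >= 0) {
    const int f = feature[node];
    bool goLeft;
    if (cat_left[node] >= 0)
      goLeft = ((int)X(s, f) == cat_left[node]);
    else
      goLeft = (X(s, f) <= threshold[node]);
    node = goLeft ? left[node] : right[node];
  }
  return node;
}

}  // namespace

// [[Rcpp::export(name = ".growForestCpp")]]
List growForestCpp(NumericMatrix X, IntegerVector y, LogicalVector is_cat,
                   int ntree, int mtry, int min_node,
                   NumericVector split_weights, bool bootstrap) {
  const int n = X.nrow();
  List trees(ntree);
  List inbag(ntree);
  for (int t = 0; t < ntree; ++t) {
    std::vector<int> idx;
    IntegerVector counts(n);
    if (bootstrap) {
      for (int d = 0; d < n; ++d) {
        int j = (int)(n * unif_rand());
        if (j >= n) j = n - 1;
        ++counts[j];
      }
      for (int i = 0; i < n; ++i)
        for (int c = 0; c < counts[i]; ++c) idx.push_back(i);
    } else {
      for (int i = 0; i < n; ++i) { idx.push_back(i); counts[i] = 1; }
    }
    TreeBuf tb;
    Grower g(X, y, is_cat, mtry, min_node, split_weights, tb);
    g.grow(idx);
    trees[t] = List::create(
        _["feature"] = wrap(tb.feature), _["cat_left"] = wrap(tb.cat_left),
        _["threshold"] = wrap(tb.threshold), _["left"] = wrap(tb.left),
        _["right"] = wrap(tb.right), _["prop"] = wrap(tb.prop),
        _["n_node"] = wrap(tb.n_node));
    inbag[t] = counts;
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".predictForestCpp")]]
NumericVector predictForestCpp(List trees, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector out(n);
  for (int t = 0; t < ntree; ++t) {
    List tree = trees[t];
    NumericVector prop = tree["prop"];
    for (int s = 0; s < n; ++s) out[s] += prop[routeSample(tree, X, s)];
  }
  for (int s = 0; s < n; ++s) out[s] /= ntree;
  return out;
}

// [[Rcpp::export(name = ".oobForestCpp")]]
NumericVector oobForestCpp(List trees, List inbag, NumericMatrix X) {
  const int n = X.nrow(), ntree = trees.size();
  NumericVector acc(n);
  IntegerVector cnt(n);
  for (int t = 0; t < ntree; ++t) {
    List tree = trees[t];
    NumericVector prop = tree["prop"];
    IntegerVector counts = inbag[t];
    for (int s = 0; s < n; ++s) {
      if (counts[s] == 0) {
        acc[s] += prop[routeSample(tree, X, s)];
        ++cnt[s];
      }
    }
  }
  NumericVector out(n);
  for (int s = 0; s < n; ++s)
    out[s] = (cnt[s] > 0) ? acc[s] / cnt[s] : NA_REAL;
  return out;
}
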