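// Random forest regression: CART trees grown greedily on bootstrap samples,
// best variance-reduction split among k randomly drawn candidate variables
// per node, plus out-of-bag permutation importance.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

inline int sampleInt(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

struct RTree {
  std::vector<int> left, right, var;   // var -1 for leaf
  std::vector<double> cut, val;
  int addNode() {
    left.push_back(-1); right.push_back(-1); var.push_back(-1);
    cut.push_back(0.0); val.push_back(0.0);
    return (int)left.size() - 1;
  }
  double predictOne(const NumericMatrix& X, int i, int overrideVar = -1,
                    double overrideVal = 0.0) const {
    int u = 0;
    while (var[u] >= 0) {
      const double x = (var[u] == overrideVar) ? overrideVal : X(i, var[u]);
      u = (x <= cut[u]) ? left[u] : right[u];
    }
    return val[u];
  }
};

struct SplitResult {
  int var = -1;
  double cut = 0.0, gain = 0.0;
};

// best SSE-reduction split at a node over k random candidate variables
SplitResult bestSplit(const NumericMatrix& X, const NumericVector& y,
                      const std::vector<int>& rows, int k,
                      std::vector<int>& varPerm) {
  const int p = X.ncol();
  const int m = (int)rows.size();
  // partial Fisher-Yates for k candidates, undone afterwards
  std::vector<std::pair<int, int>> swaps;
  for (int t = 0; t < k; ++t) {
    const int u = t + sampleInt(p - t);
    std::swap(varPerm[t], varPerm[u]);
    swaps.push_back({t, u});
  }
  SplitResult best;
  double sAll = 0.0;
  for (int i : rows) sAll += y[i];
  std::vector<std::pair<double, double>> xy(m);
  for (int t = 0; t < k; ++t) {
    const int j = varPerm[t];
    for (int q = 0; q < m; ++q) xy[q] = {X(rows[q], j), y[rows[q]]};
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue;
    double sL = 0.0;
    for (int q = 0; q < m - 1; ++q) {
      sL += xy[q].second;
      if (xy[q].first == xy[q + 1].first) continue;
      const int nL = q + 1, nR = m - nL;
      const double gain = sL * sL / nL + (sAll - sL) * (sAll - sL) / nR
                          - sAll * sAll / m;
      if (gain > best.gain + 1e-12) {
        best.gain = gain;
        best.var = j;
        best.cut = 0.5 * (xy[q].first + xy[q + 1].first);
      }
    }
  }
  for (auto it = swaps.rbegin(); it != swaps.rend(); ++it)
    std::swap(varPerm[it->first], varPerm[it->second]);
  return best;
}

void growTree(RTree& tr, const NumericMatrix& X, const NumericVector& y,
              std::vector<int>& bootRows, int k, int nodesize,
              std::vector<int>& varPerm) {
  struct Item { int node; std::vector<int> rows; };
  std::vector<Item> stack;
  const int root = tr.addNode();
  stack.push_back({root, bootRows});
  while (!stack.empty()) {
    Item it = std::move(stack.back());
    stack.pop_back();
    double s = 0.0;
    for (int i : it.rows) s += y[i];
    tr.val[it.node] = s / it.rows.size();
    if ((int)it.rows.size() <= nodesize) continue;
    SplitResult sp = bestSplit(X, y, it.rows, k, varPerm);
    if (sp.var < 0) continue;
    std::vector<int> lrows, rrows;
    for (int i : it.rows)
      (X(i, sp.var) <= sp.cut ? lrows : rrows).push_back(i);
    tr.var[it.node] = sp.var;
    tr.cut[it.node] = sp.cut;
    const int L = tr.addNode(), R_ = tr.addNode();
    tr.left[it.node] = L;
    tr.right[it.node] = R_;
    stack.push_back({L, std::move(lrows)});
    stack.push_back({R_, std::move(rrows)});
  }
}

NumericMatrix serialize(const RTree& tr) {
  const int s = (int)tr.left.size();
  NumericMatrix nm(s, 5);
  for (int i = 0; i < s; ++i) {
    nm(i, 0) = tr.left[i] + 1;   // 0 marks leaf
    nm(i, 1) = tr.right[i] + 1;
    nm(i, 2) = tr.var[i] + 1;
    nm(i, 3) = tr.cut[i];
    nm(i, 4) = tr.val[i];
  }
  return nm;
}

RTree deserialize(const NumericMatrix& nm) {
  RTree tr;
  const int s = nm.nrow();
  tr.left.resize(s); tr.right.resize(s); tr.var.resize(s);
  tr.cut.resize(s); tr.val.resize(s);
  for (int i = 0; i < s; ++i) {
    tr.left[i] = (int)nm(i, 0) - 1;
    tr.right[i] = (int)nm(i, 1) - 1;
    tr.var[i] = (int)nm(i, 2) - 1;
    tr.cut[i] = nm(i, 3);
    tr.val[i] = nm(i, 4);
  }
  return tr;
}

}  // namespace

// [[Rcpp::export(name = ".rf_fit_cpp")]]
List rf_fit_cpp(const NumericMatrix& X, const NumericVector& y, int B, int k,
                int nodesize) {
  const int n = X.nrow(), p = X.ncol();
  List trees(B);
  IntegerMatrix inbag(n, B);
  std::vector<int> varPerm(p);
  for (int j = 0; j < p; ++j) varPerm[j] = j;
  for (int b = 0; b < B; ++b) {
    Rcpp::checkUserInterrupt();
    std::vector<int> rows(n);
    for (int i = 0; i < n; ++i) {
      rows[i] = sampleInt(n);
      inbag(rows[i], b) += 1;
    }
    RTree tr;
    growTree(tr, X, y, rows, k, nodesize, varPerm);
    trees[b] = serialize(tr);
  }
  return List::create(_["trees"] = trees, _["inbag"] = inbag);
}

// [[Rcpp::export(name = ".rf_predict_cpp")]]
NumericMatrix rf_predict_cpp(const List& trees, const NumericMatrix& X) {
  const int B = trees.size(), n = X.nrow();
  NumericMatrix out(B, n);
  for (int b = 0; b < B; ++b) {
    RTree tr = deserialize(trees[b]);
    for (int i = 0; i < n; ++i) out(b, i) = tr.predictOne(X, i);
  }
  return out;
}

// Mean over all trees of (permuted-OOB MSPE - OOB MSPE) per variable,
// normalized by the SD over trees of those differences; variables a tree
// never splits on contribute an exact zero for that tree.
// [[Rcpp::export(name = ".rf_oob_vimp_cpp")]]
List rf_oob_vimp_cpp(const List& trees, const IntegerMatrix& inbag,
                     const NumericMatrix& X, const NumericVector& y) {
  const int B = trees.size(), n = X.nrow(), p = X.ncol();
  NumericMatrix diffs(B, p);
  NumericVector oobErr(B, NA_REAL);
  IntegerVector oobCount(n);
  for (int b = 0; b < B; ++b) {
    Rcpp::checkUserInterrupt();
    RTree tr = deserialize(trees[b]);
    std::vector<int> oob;
    for (int i = 0; i < n; ++i)
      if (inbag(i, b) == 0) { oob.push_back(i); oobCount[i] += 1; }
    if (oob.empty()) continue;
    const int m = (int)oob.size();
    double e0 = 0.0;
    for (int i : oob) {
      const double d = tr.predictOne(X, i) - y[i];
      e0 += d * d;
    }
    e0 /= m;
    oobErr[b] = e0;
    std::vector<bool> used(p, false);
    for (size_t u = 0; u < tr.var.size(); ++u)
      if (tr.var[u] >= 0) used[tr.var[u]] = true;
    std::vector<double> xv(m);
    for (int j = 0; j < p; ++j) {
      if (!used[j]) continue;
      for (int q = 0; q < m; ++q) xv[q] = X(oob[q], j);
      for (int q = m - 1; q > 0; --q)
        std::swap(xv[q], xv[sampleInt(q + 1)]);
      double e1 = 0.0;
      for (int q = 0; q < m; ++q) {
        const double d = tr.predictOne(X, oob[q], j, xv[q]) - y[oob[q]];
        e1 += d * d;
      }
      diffs(b, j) = e1 / m - e0;
    }
  }
  NumericVector imp(p);
  for (int j = 0; j < p; ++j) {
    double s = 0.0, s2 = 0.0;
    for (int b = 0; b < B; ++b) { s += diffs(b, j); s2 += diffs(b, j) * diffs(b, j); }
    const double mean = s / B;
    const double sd = (B > 1) ? std::sqrt(std::max(0.0, (s2 - B * mean * mean) / (B - 1)))
                              : 0.0;
    imp[j] = (sd > 0.0) ? mean / sd : 0.0;
  }
  return List::create(_["importance"] = imp, _["meanDiff"] = colMeans(diffs),
                      _["oobErr"] = oobErr, _["oobCount"] = oobCount);
}
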