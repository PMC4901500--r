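// Backfitting MCMC engine for the sum-of-trees model.
//
// One binary regression tree per slot; each sweep updates tree m against the
// partial residuals of the other M-1 trees via a Metropolis-Hastings move
// (grow / prune / change / swap), then redraws its leaf means from the
// conjugate normal conditional, and finally redraws the residual variance
// from its scaled inverse chi-square conditional.  All randomness comes from
// R's RNG so that set.seed() in R makes runs bit-reproducible.
//
// The rule-assignment prior (uniform over splittable variables, then uniform
// over that variable's candidate cutpoints, conditional on the rows reaching
// the node) is the expensive quantity at large p: its per-node counts depend
// only on the design matrix and the tree's row partition, so they are cached
// on every node and refreshed only when an accepted move changes the row
// sets below it.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Node {
  int parent, left, right, depth;
  int var;      // 0-based split variable; -1 for a leaf
  double cut;
  double mu;
  int nValid;   // cached: splittable vars among this node's rows
  int nCut;     // cached: candidate cutpoints of `var` among this node's rows
};

struct Tree {
  std::vector<Node> nodes;   // slot 0 is always the root
  std::vector<int> freeSlots;
  Tree() { nodes.push_back(Node{-1, -1, -1, 0, -1, 0.0, 0.0, 0, 0}); }
  bool isLeaf(int i) const { return nodes[i].left < 0; }
  int newNode() {
    if (!freeSlots.empty()) {
      int s = freeSlots.back(); freeSlots.pop_back();
      nodes[s] = Node{-1, -1, -1, 0, -1, 0.0, 0.0, 0, 0};
      return s;
    }
    nodes.push_back(Node{-1, -1, -1, 0, -1, 0.0, 0.0, 0, 0});
    return (int)nodes.size() - 1;
  }
  void freeNode(int i) { freeSlots.push_back(i); }
  void collectLeaves(int from, std::vector<int>& out) const {
    if (isLeaf(from)) { out.push_back(from); return; }
    collectLeaves(nodes[from].left, out);
    collectLeaves(nodes[from].right, out);
  }
  void collectInternals(int from, std::vector<int>& out) const {
    if (isLeaf(from)) return;
    out.push_back(from);
    collectInternals(nodes[from].left, out);
    collectInternals(nodes[from].right, out);
  }
  int countPrunable() const {
    std::vector<int> ints;
    collectInternals(0, ints);
    int k = 0;
    for (int i : ints)
      if (isLeaf(nodes[i].left) && isLeaf(nodes[i].right)) ++k;
    return k;
  }
};

inline int sampleInt(int m) {
  int k = (int)(unif_rand() * m);
  return k >= m ? m - 1 : k;
}

inline bool hasTwoDistinct(const double* col, const std::vector<int>& rows) {
  const double first = col[rows[0]];
  for (size_t k = 1; k < rows.size(); ++k)
    if (col[rows[k]] != first) return true;
  return false;
}

// splittable variables among `rows` (early-exit scan over all p columns)
void validVars(const NumericMatrix& X, const std::vector<int>& rows,
               std::vector<int>& out) {
  out.clear();
  const int p = X.ncol(), n = X.nrow();
  const double* base = REAL(X);
  for (int j = 0; j < p; ++j)
    if (hasTwoDistinct(base + (size_t)j * n, rows)) out.push_back(j);
}

// draw uniformly among splittable variables given their cached count
int drawValidVar(const NumericMatrix& X, const std::vector<int>& rows,
                 int nValidCached) {
  const int p = X.ncol(), n = X.nrow();
  const double* base = REAL(X);
  if (nValidCached * 3 > p) {           // dense case: rejection is fast
    for (int tries = 0; tries < 60; ++tries) {
      const int j = sampleInt(p);
      if (hasTwoDistinct(base + (size_t)j * n, rows)) return j;
    }
  }
  std::vector<int> vv;
  validVars(X, rows, vv);
  if (vv.empty()) return -1;
  return vv[sampleInt((int)vv.size())];
}

// candidate cutpoints: midpoints of sorted unique observed values in the node
void cutpointsAt(const NumericMatrix& X, const std::vector<int>& rows, int j,
                 std::vector<double>& cuts) {
  std::vector<double> v;
  v.reserve(rows.size());
  for (int i : rows) v.push_back(X(i, j));
  std::sort(v.begin(), v.end());
  v.erase(std::unique(v.begin(), v.end()), v.end());
  cuts.clear();
  for (size_t k = 1; k < v.size(); ++k) cuts.push_back(0.5 * (v[k - 1] + v[k]));
}

// log marginal likelihood of one leaf: N(mu, sig2) likelihood, N(muMu, sMu2)
// prior on mu, mu integrated out; (n, s, s2) = count, sum, sum of squares.
inline double leafML(double n, double s, double s2, double sig2, double sMu2,
                     double muMu) {
  const double denom = sig2 + n * sMu2;
  return -0.5 * n * std::log(2.0 * M_PI * sig2)
         + 0.5 * std::log(sig2 / denom)
         - s2 / (2.0 * sig2)
         + (sMu2 * s * s + 2.0 * muMu * sig2 * s - n * muMu * muMu * sig2)
           / (2.0 * sig2 * denom);
}

inline double leafMLRows(const std::vector<int>& rows,
                         const std::vector<double>& r, double sig2,
                         double sMu2, double muMu) {
  double s = 0.0, s2 = 0.0;
  for (int i : rows) { s += r[i]; s2 += r[i] * r[i]; }
  return leafML((double)rows.size(), s, s2, sig2, sMu2, muMu);
}

inline double pSplit(double alpha, double beta, int depth) {
  return alpha * std::pow(1.0 + depth, -beta);
}

// rows routed to `node` (walk each observation's leaf up the ancestor chain)
void nodeRows(const Tree& tr, int node, const std::vector<int>& leafidx,
              std::vector<int>& rows) {
  rows.clear();
  for (int i = 0; i < (int)leafidx.size(); ++i) {
    int u = leafidx[i];
    while (u >= 0 && u != node) u = tr.nodes[u].parent;
    if (u == node) rows.push_back(i);
  }
}

int routeFrom(const Tree& tr, int node, const NumericMatrix& X, int i) {
  int u = node;
  while (!tr.isLeaf(u))
    u = (X(i, tr.nodes[u].var) <= tr.nodes[u].cut) ? tr.nodes[u].left
                                                   : tr.nodes[u].right;
  return u;
}

// marginal log-likelihood + rule-assignment log prior over the subtree at
// `node`, using the cached per-node counts (valid while row sets unchanged)
bool subtreeEvalCached(const Tree& tr, int node,
                       const NumericMatrix& X, const std::vector<int>& rows,
                       const std::vector<double>& r, double sig2, double sMu2,
                       double muMu, double& logML, double& rulePrior) {
  if (rows.empty()) return false;
  if (tr.isLeaf(node)) {
    logML += leafMLRows(rows, r, sig2, sMu2, muMu);
    return true;
  }
  const Node& nd = tr.nodes[node];
  rulePrior += -std::log((double)nd.nValid) - std::log((double)nd.nCut);
  std::vector<int> lrows, rrows;
  for (int i : rows) (X(i, nd.var) <= nd.cut ? lrows : rrows).push_back(i);
  if (lrows.empty() || rrows.empty()) return false;
  return subtreeEvalCached(tr, nd.left, X, lrows, r, sig2, sMu2, muMu, logML,
                           rulePrior) &&
         subtreeEvalCached(tr, nd.right, X, rrows, r, sig2, sMu2, muMu, logML,
                           rulePrior);
}

// as above but recomputing the counts from scratch (for proposed routings);
// records them as (slot, nValid, nCut) so acceptance can install them
struct CountRec { int slot, nValid, nCut; };

bool subtreeEvalScan(const Tree& tr, int node, const NumericMatrix& X,
                     const std::vector<int>& rows,
                     const std::vector<double>& r, double sig2, double sMu2,
                     double muMu, double& logML, double& rulePrior,
                     std::vector<CountRec>& rec, int rootNValid = -1) {
  if (rows.empty()) return false;
  if (tr.isLeaf(node)) {
    logML += leafMLRows(rows, r, sig2, sMu2, muMu);
    return true;
  }
  const Node& nd = tr.nodes[node];
  int nv;
  if (rootNValid >= 0) {
    nv = rootNValid;  // row set of this node unchanged: count still valid
  } else {
    std::vector<int> vv;
    validVars(X, rows, vv);
    nv = (int)vv.size();
  }
  if (nv == 0) return false;
  std::vector<double> cc;
  cutpointsAt(X, rows, nd.var, cc);
  if (cc.empty()) return false;
  rulePrior += -std::log((double)nv) - std::log((double)cc.size());
  rec.push_back(CountRec{node, nv, (int)cc.size()});
  std::vector<int> lrows, rrows;
  for (int i : rows) (X(i, nd.var) <= nd.cut ? lrows : rrows).push_back(i);
  if (lrows.empty() || rrows.empty()) return false;
  return subtreeEvalScan(tr, nd.left, X, lrows, r, sig2, sMu2, muMu, logML,
                         rulePrior, rec) &&
         subtreeEvalScan(tr, nd.right, X, rrows, r, sig2, sMu2, muMu, logML,
                         rulePrior, rec);
}

// move codes: 0 grow, 1 prune, 2 change, 3 swap
int drawMove(const NumericVector& probs) {
  double u = unif_rand(), c = 0.0;
  for (int k = 0; k < 4; ++k) { c += probs[k]; if (u <= c) return k; }
  return 3;
}

// One MH structural update of a single tree against residuals r.
// Returns true if the proposal was accepted.  `leafidx` is kept in sync.
bool mhUpdate(Tree& tr, std::vector<int>& leafidx, const NumericMatrix& X,
              const std::vector<double>& r, double sig2, double sMu2,
              double muMu, double alpha, double beta,
              const NumericVector& moveProbs, int maxDepth, int& moveOut) {
  const int move = drawMove(moveProbs);
  moveOut = move;

  std::vector<int> leaves, internals, rows;
  std::vector<double> cuts;
  std::vector<CountRec> rec;
  tr.collectLeaves(0, leaves);
  tr.collectInternals(0, internals);
  const int nleaf = (int)leaves.size();

  if (move == 0) {  // ---- grow
    const int L = leaves[sampleInt(nleaf)];
    const int d = tr.nodes[L].depth;
    if (d >= maxDepth) return false;
    nodeRows(tr, L, leafidx, rows);
    std::vector<int> vv;
    validVars(X, rows, vv);
    if (vv.empty()) return false;
    const int j = vv[sampleInt((int)vv.size())];
    cutpointsAt(X, rows, j, cuts);
    const double cut = cuts[sampleInt((int)cuts.size())];
    std::vector<int> lrows, rrows;
    for (int i : rows) (X(i, j) <= cut ? lrows : rrows).push_back(i);
    // both children non-empty by construction of the cutpoint set
    const double dML = leafMLRows(lrows, r, sig2, sMu2, muMu)
                     + leafMLRows(rrows, r, sig2, sMu2, muMu)
                     - leafMLRows(rows, r, sig2, sMu2, muMu);
    const double ps = pSplit(alpha, beta, d);
    const double ps1 = pSplit(alpha, beta, d + 1);
    const double logRule = -std::log((double)vv.size())
                           - std::log((double)cuts.size());
    bool parentWasPrunable = false;
    if (tr.nodes[L].parent >= 0) {
      const Node& par = tr.nodes[tr.nodes[L].parent];
      const int sib = (par.left == L) ? par.right : par.left;
      parentWasPrunable = tr.isLeaf(sib);
    }
    const int nprNew = tr.countPrunable() + 1 - (parentWasPrunable ? 1 : 0);
    const double logPrior = std::log(ps) - std::log(1.0 - ps)
                            + 2.0 * std::log(1.0 - ps1) + logRule;
    const double logProp = (std::log(moveProbs[1]) - std::log((double)nprNew))
                         - (std::log(moveProbs[0]) - std::log((double)nleaf)
                            + logRule);
    if (std::log(unif_rand()) >= dML + logPrior + logProp) return false;
    const int cl = tr.newNode(), cr = tr.newNode();
    tr.nodes[cl].parent = L; tr.nodes[cl].depth = d + 1;
    tr.nodes[cr].parent = L; tr.nodes[cr].depth = d + 1;
    tr.nodes[L].left = cl; tr.nodes[L].right = cr;
    tr.nodes[L].var = j; tr.nodes[L].cut = cut;
    tr.nodes[L].nValid = (int)vv.size(); tr.nodes[L].nCut = (int)cuts.size();
    for (int i : lrows) leafidx[i] = cl;
    for (int i : rrows) leafidx[i] = cr;
    return true;
  }

  if (move == 1) {  // ---- prune
    std::vector<int> prunable;
    for (int i : internals)
      if (tr.isLeaf(tr.nodes[i].left) && tr.isLeaf(tr.nodes[i].right))
        prunable.push_back(i);
    if (prunable.empty()) return false;
    const int P = prunable[sampleInt((int)prunable.size())];
    nodeRows(tr, P, leafidx, rows);
    std::vector<int> lrows, rrows;
    for (int i : rows)
      (X(i, tr.nodes[P].var) <= tr.nodes[P].cut ? lrows : rrows).push_back(i);
    const double dML = leafMLRows(rows, r, sig2, sMu2, muMu)
                     - leafMLRows(lrows, r, sig2, sMu2, muMu)
                     - leafMLRows(rrows, r, sig2, sMu2, muMu);
    const double logRule = -std::log((double)tr.nodes[P].nValid)
                           - std::log((double)tr.nodes[P].nCut);
    const int d = tr.nodes[P].depth;
    const double ps = pSplit(alpha, beta, d);
    const double ps1 = pSplit(alpha, beta, d + 1);
    const double logPrior = -(std::log(ps) - std::log(1.0 - ps)
                              + 2.0 * std::log(1.0 - ps1) + logRule);
    const double logProp =
        (std::log(moveProbs[0]) - std::log((double)(nleaf - 1)) + logRule)
      - (std::log(moveProbs[1]) - std::log((double)prunable.size()));
    if (std::log(unif_rand()) >= dML + logPrior + logProp) return false;
    tr.freeNode(tr.nodes[P].left);
    tr.freeNode(tr.nodes[P].right);
    tr.nodes[P].left = tr.nodes[P].right = -1;
    tr.nodes[P].var = -1;
    for (int i : rows) leafidx[i] = P;
    return true;
  }

  if (move == 2) {  // ---- change
    if (internals.empty()) return false;
    const int C = internals[sampleInt((int)internals.size())];
    nodeRows(tr, C, leafidx, rows);
    double mlOld = 0.0, rpOld = 0.0;
    if (!subtreeEvalCached(tr, C, X, rows, r, sig2, sMu2, muMu, mlOld, rpOld))
      return false;  // current subtree degenerate (should not happen)
    const int oldVar = tr.nodes[C].var;
    const double oldCut = tr.nodes[C].cut;
    const int oldNCut = tr.nodes[C].nCut;
    const int nValid = tr.nodes[C].nValid;
    const int j = drawValidVar(X, rows, nValid);
    if (j < 0) return false;
    cutpointsAt(X, rows, j, cuts);
    const double cut = cuts[sampleInt((int)cuts.size())];
    tr.nodes[C].var = j; tr.nodes[C].cut = cut;
    double mlNew = 0.0, rpNew = 0.0;
    const bool ok = subtreeEvalScan(tr, C, X, rows, r, sig2, sMu2, muMu,
                                    mlNew, rpNew, rec, nValid);
    // proposal: uniform internal node, uniform valid var, uniform cutpoint
    const double logQf = -std::log((double)nValid)
                         - std::log((double)cuts.size());
    const double logQr = -std::log((double)nValid)
                         - std::log((double)oldNCut);
    if (!ok || std::log(unif_rand()) >=
                   (mlNew - mlOld) + (rpNew - rpOld) + (logQr - logQf)) {
      tr.nodes[C].var = oldVar; tr.nodes[C].cut = oldCut;
      return false;
    }
    for (const CountRec& cr2 : rec) {
      tr.nodes[cr2.slot].nValid = cr2.nValid;
      tr.nodes[cr2.slot].nCut = cr2.nCut;
    }
    for (int i : rows) leafidx[i] = routeFrom(tr, C, X, i);
    return true;
  }

  // ---- swap
  std::vector<int> cand;
  for (int i : internals) {
    if (!tr.isLeaf(tr.nodes[i].left) || !tr.isLeaf(tr.nodes[i].right))
      cand.push_back(i);
  }
  if (cand.empty()) return false;
  const int P = cand[sampleInt((int)cand.size())];
  std::vector<int> ic;
  if (!tr.isLeaf(tr.nodes[P].left)) ic.push_back(tr.nodes[P].left);
  if (!tr.isLeaf(tr.nodes[P].right)) ic.push_back(tr.nodes[P].right);
  const int C = ic[sampleInt((int)ic.size())];
  nodeRows(tr, P, leafidx, rows);
  double mlOld = 0.0, rpOld = 0.0;
  if (!subtreeEvalCached(tr, P, X, rows, r, sig2, sMu2, muMu, mlOld, rpOld))
    return false;
  std::swap(tr.nodes[P].var, tr.nodes[C].var);
  std::swap(tr.nodes[P].cut, tr.nodes[C].cut);
  double mlNew = 0.0, rpNew = 0.0;
  const bool ok = subtreeEvalScan(tr, P, X, rows, r, sig2, sMu2, muMu, mlNew,
                                  rpNew, rec, tr.nodes[P].nValid);
  // structure is unchanged, so the node/child choice probabilities cancel
  if (!ok || std::log(unif_rand()) >= (mlNew - mlOld) + (rpNew - rpOld)) {
    std::swap(tr.nodes[P].var, tr.nodes[C].var);
    std::swap(tr.nodes[P].cut, tr.nodes[C].cut);
    return false;
  }
  for (const CountRec& cr2 : rec) {
    tr.nodes[cr2.slot].nValid = cr2.nValid;
    tr.nodes[cr2.slot].nCut = cr2.nCut;
  }
  for (int i : rows) leafidx[i] = routeFrom(tr, P, X, i);
  return true;
}

// conjugate draw of every leaf mean; refreshes fit for this tree
void drawLeafMeansTree(Tree& tr, const std::vector<int>& leafidx,
                       const std::vector<double>& r, double sig2, double sMu2,
                       double muMu, std::vector<double>& fit) {
  const size_t S = tr.nodes.size();
  std::vector<double> sum(S, 0.0);
  std::vector<int> cnt(S, 0);
  for (size_t i = 0; i < leafidx.size(); ++i) {
    sum[leafidx[i]] += r[i];
    cnt[leafidx[i]] += 1;
  }
  std::vector<int> leaves;
  tr.collectLeaves(0, leaves);
  for (int L : leaves) {
    const double postVar = 1.0 / (cnt[L] / sig2 + 1.0 / sMu2);
    const double postMean = postVar * (sum[L] / sig2 + muMu / sMu2);
    tr.nodes[L].mu = postMean + std::sqrt(postVar) * norm_rand();
  }
  for (size_t i = 0; i < leafidx.size(); ++i) fit[i] = tr.nodes[leafidx[i]].mu;
}

}  // namespace

// [[Rcpp::export(name = ".bart_mcmc_cpp")]]
List bart_mcmc_cpp(const NumericMatrix& X, const NumericVector& y,
                   const NumericMatrix& Xtest, int ntree, int niter, int burn,
                   int thin, double alpha, double beta, double sigmaMu,
                   double muMu, double nu, double lambda, double sigma2Init,
                   NumericVector moveProbs, int maxDepth, double fixSigma2,
                   bool keepTrees, bool keepTrainDraws) {
  const int n = X.nrow(), p = X.ncol(), ntest = Xtest.nrow();
  const double sMu2 = sigmaMu * sigmaMu;
  const int nkeep = (niter - burn) / thin;

  std::vector<Tree> trees((size_t)ntree);
  std::vector<std::vector<int>> leafidx((size_t)ntree,
                                        std::vector<int>(n, 0));
  std::vector<std::vector<double>> fits((size_t)ntree,
                                        std::vector<double>(n, 0.0));
  std::vector<double> allfit(n, 0.0), resid(n, 0.0);
  double sigma2 = (fixSigma2 > 0.0) ? fixSigma2 : sigma2Init;

  NumericVector sigma2Draws(nkeep);
  IntegerMatrix varcount(nkeep, p);
  NumericMatrix yhatTrain(keepTrainDraws ? nkeep : 0, keepTrainDraws ? n : 0);
  NumericVector yhatTrainMean(n);
  NumericVector yhatTestMean(ntest);
  List treeDraws(keepTrees ? nkeep : 0);
  IntegerVector proposed(4), accepted(4);

  int keep = 0;
  for (int it = 1; it <= niter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
    for (int m = 0; m < ntree; ++m) {
      for (int i = 0; i < n; ++i) resid[i] = y[i] - (allfit[i] - fits[m][i]);
      int mv = 0;
      const bool acc = mhUpdate(trees[m], leafidx[m], X, resid, sigma2, sMu2,
                                muMu, alpha, beta, moveProbs, maxDepth, mv);
      proposed[mv] += 1;
      if (acc) accepted[mv] += 1;
      for (int i = 0; i < n; ++i) allfit[i] -= fits[m][i];
      drawLeafMeansTree(trees[m], leafidx[m], resid, sigma2, sMu2, muMu,
                        fits[m]);
      for (int i = 0; i < n; ++i) allfit[i] += fits[m][i];
    }
    if (fixSigma2 <= 0.0) {
      double sse = 0.0;
      for (int i = 0; i < n; ++i) {
        const double e = y[i] - allfit[i];
        sse += e * e;
      }
      sigma2 = (nu * lambda + sse) / R::rchisq(nu + n);
    }
    if (it > burn && (it - burn) % thin == 0) {
      sigma2Draws[keep] = sigma2;
      for (int m = 0; m < ntree; ++m) {
        std::vector<int> ints;
        trees[m].collectInternals(0, ints);
        for (int u : ints) varcount(keep, trees[m].nodes[u].var) += 1;
      }
      for (int i = 0; i < n; ++i) {
        if (keepTrainDraws) yhatTrain(keep, i) = allfit[i];
        yhatTrainMean[i] += allfit[i] / nkeep;
      }
      if (ntest > 0) {
        for (int i = 0; i < ntest; ++i) {
          double s = 0.0;
          for (int m = 0; m < ntree; ++m) {
            int u = 0;
            const Tree& tr = trees[m];
            while (!tr.isLeaf(u))
              u = (Xtest(i, tr.nodes[u].var) <= tr.nodes[u].cut)
                      ? tr.nodes[u].left : tr.nodes[u].right;
            s += tr.nodes[u].mu;
          }
          yhatTestMean[i] += s / nkeep;
        }
      }
      if (keepTrees) {
        // serialize all trees of this draw into one matrix; left/right are
        // 1-based global row indices, 0 marks a leaf child pointer
        int tot = 0;
        std::vector<std::vector<int>> dfs((size_t)ntree);
        for (int m = 0; m < ntree; ++m) {
          std::vector<int> stack{0}, order;
          while (!stack.empty()) {
            int u = stack.back(); stack.pop_back();
            order.push_back(u);
            if (!trees[m].isLeaf(u)) {
              stack.push_back(trees[m].nodes[u].right);
              stack.push_back(trees[m].nodes[u].left);
            }
          }
          dfs[m] = order;
          tot += (int)order.size();
        }
        NumericMatrix nm(tot, 7);
        IntegerVector starts(ntree);
        int row = 0;
        for (int m = 0; m < ntree; ++m) {
          starts[m] = row + 1;
          std::vector<int> slot2row(trees[m].nodes.size(), -1);
          for (size_t k = 0; k < dfs[m].size(); ++k)
            slot2row[dfs[m][k]] = row + (int)k;
          for (size_t k = 0; k < dfs[m].size(); ++k) {
            const Node& nd = trees[m].nodes[dfs[m][k]];
            const int rr = row + (int)k;
            nm(rr, 0) = m + 1;
            nm(rr, 1) = nd.left < 0 ? 0 : slot2row[nd.left] + 1;
            nm(rr, 2) = nd.right < 0 ? 0 : slot2row[nd.right] + 1;
            nm(rr, 3) = nd.var < 0 ? 0 : nd.var + 1;
            nm(rr, 4) = nd.cut;
            nm(rr, 5) = nd.mu;
            nm(rr, 6) = nd.depth;
          }
          row += (int)dfs[m].size();
        }
        treeDraws[keep] = List::create(_["nodes"] = nm, _["starts"] = starts);
      }
      ++keep;
    }
  }

  return List::create(
      _["sigma2"] = sigma2Draws, _["varcount"] = varcount,
      _["yhat_train"] = yhatTrain, _["yhat_train_mean"] = yhatTrainMean,
      _["yhat_test_mean"] = yhatTestMean, _["trees"] = treeDraws,
      _["proposed"] = proposed, _["accepted"] = accepted);
}

// per-draw sum-of-trees evaluation at new rows, from serialized tree draws
// [[Rcpp::export(name = ".bart_predict_cpp")]]
NumericMatrix bart_predict_cpp(const List& treeDraws, const NumericMatrix& X) {
  const int T = treeDraws.size(), n = X.nrow();
  NumericMatrix out(T, n);
  for (int t = 0; t < T; ++t) {
    List d = treeDraws[t];
    NumericMatrix nm = d["nodes"];
    IntegerVector starts = d["starts"];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int m = 0; m < starts.size(); ++m) {
        int u = starts[m] - 1;
        while (nm(u, 1) > 0)
          u = (X(i, (int)nm(u, 3) - 1) <= nm(u, 4)) ? (int)nm(u, 1) - 1
                                                    : (int)nm(u, 2) - 1;
        s += nm(u, 5);
      }
      out(t, i) = s;
    }
  }
  return out;
}

// closed-form leaf marginal log-likelihood (exposed for cross-checks)
// [[Rcpp::export(name = ".leaf_ml_cpp")]]
double leaf_ml_cpp(const NumericVector& r, double sigma2, double sigmaMu2,
                   double muMu) {
  double s = 0.0, s2 = 0.0;
  for (double v : r) { s += v; s2 += v * v; }
  return leafML((double)r.size(), s, s2, sigma2, sigmaMu2, muMu);
}
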