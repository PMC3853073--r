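// Tree growth for multivariate random-forest regression.
//
// Each tree is grown on a bootstrap multiset of the N samples.  At every
// node a fresh random subset of Mtry candidate SNPs is drawn and every
// allowable ordinal threshold split (genotype <= 0 | >= 1, genotype <= 1 |
// == 2, de-duplicated when they induce the same partition) is scored by the
// reduction in the node sum of squares.  Two criteria are available:
//
//  * standard:  SS(j) = sum_i (y_i - ybar)' V^-1 (y_i - ybar), with V either
//    the identity or the diagonal of per-trait variances estimated at the
//    node (children are scored with the parent's V).
//  * distance:  SS(j) = (1/2N(j)) sum_{i,l} d2(y_i, y_l), evaluated from a
//    precomputed matrix of squared pairwise phenotype distances, so the
//    per-split cost is independent of the number of traits.
//
// The split search is vectorised over candidates: class-indicator matrices
// are multiplied against the node phenotypes (standard) or the node
// distance submatrix (distance), so the inner work is BLAS GEMMs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

// splitmix64: tiny, high-quality, platform-independent stream; keyed per
// tree so results do not depend on how trees are batched over workers.
struct SplitMix {
  uint64_t s;
  explicit SplitMix(uint64_t seed) : s(seed) {}
  uint64_t nxt() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (nxt() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int k = static_cast<int>(unif() * n);
    return k >= n ? n - 1 : k;
  }
};

SplitMix tree_rng(int master_seed, int tree_id) {
  SplitMix r(static_cast<uint64_t>(master_seed) * 0x9E3779B97F4A7C15ULL +
             static_cast<uint64_t>(tree_id) + 0x632BE59BD9B4E019ULL);
  r.nxt();
  r.nxt();
  return r;
}

struct TreeBuf {
  std::vector<int> snp, thr, left, right, size, leaf_id;
  std::vector<double> gain;
  std::vector<arma::rowvec> leaf_means;
  std::vector<std::vector<int> > leaf_bag;  // in-bag multiset per leaf
};

struct Grower {
  const arma::imat& X;   // N x P genotypes (0/1/2)
  const arma::mat& Y;    // N x Q phenotypes
  const arma::mat& D2;   // N x N squared distances (distance criterion)
  int criterion;         // 0 standard, 1 distance
  int covariance;        // 0 identity, 1 diagonal (standard only)
  int mtry, min_node;
  double var_floor;
  SplitMix rng;
  TreeBuf out;
  std::vector<int> cand;

  Grower(const arma::imat& X_, const arma::mat& Y_, const arma::mat& D2_,
         int crit, int cov, int mtry_, int min_node_, double floor_,
         SplitMix rng_)
      : X(X_), Y(Y_), D2(D2_), criterion(crit), covariance(cov),
        mtry(mtry_), min_node(min_node_), var_floor(floor_), rng(rng_) {}

  void draw_candidates() {
    const int P = X.n_cols;
    std::vector<int> perm(P);
    for (int j = 0; j < P; ++j) perm[j] = j;
    cand.resize(mtry);
    for (int k = 0; k < mtry; ++k) {
      int j = k + rng.below(P - k);
      std::swap(perm[k], perm[j]);
      cand[k] = perm[k];
    }
    std::sort(cand.begin(), cand.end());
  }

  int make_leaf(const std::vector<int>& idx) {
    const int n = idx.size();
    arma::rowvec m(Y.n_cols, arma::fill::zeros);
    for (int i = 0; i < n; ++i) m += Y.row(idx[i]);
    m /= n;
    int node = new_node(n);
    out.leaf_id[node] = out.leaf_means.size();
    out.leaf_means.push_back(m);
    out.leaf_bag.push_back(idx);
    return node;
  }

  int new_node(int n) {
    out.snp.push_back(-1);
    out.thr.push_back(-1);
    out.left.push_back(-1);
    out.right.push_back(-1);
    out.size.push_back(n);
    out.leaf_id.push_back(-1);
    out.gain.push_back(0.0);
    return out.snp.size() - 1;
  }

  // Split search under the standard (covariance-weighted) criterion.
  bool best_split_standard(const std::vector<int>& idx, int& bsnp, int& bthr,
                           double& bgain) {
    const int n = idx.size(), m = cand.size(), Q = Y.n_cols;
    arma::mat Ysub(n, Q);
    for (int i = 0; i < n; ++i) Ysub.row(i) = Y.row(idx[i]);
    arma::rowvec tot = arma::sum(Ysub, 0);
    arma::rowvec w(Q, arma::fill::ones);
    if (covariance == 1) {
      arma::rowvec mu = tot / n;
      arma::rowvec v(Q, arma::fill::zeros);
      for (int i = 0; i < n; ++i) {
        arma::rowvec d = Ysub.row(i) - mu;
        v += d % d;
      }
      v /= (n - 1);
      for (int q = 0; q < Q; ++q)
        w[q] = 1.0 / std::max(v[q], var_floor);
    }
    arma::mat Z1(n, m, arma::fill::zeros), Z2(n, m, arma::fill::zeros);
    std::vector<int> c1(m, 0), c2(m, 0);
    for (int s = 0; s < m; ++s) {
      const int j = cand[s];
      for (int i = 0; i < n; ++i) {
        const int g = X(idx[i], j);
        if (g == 1) { Z1(i, s) = 1.0; ++c1[s]; }
        else if (g == 2) { Z2(i, s) = 1.0; ++c2[s]; }
      }
    }
    arma::mat S1 = Z1.t() * Ysub;  // m x Q class sums
    arma::mat S2 = Z2.t() * Ysub;
    double base = 0.0;
    for (int q = 0; q < Q; ++q) base += w[q] * tot[q] * tot[q] / n;
    // gains tied within ~fp error of the node SS (e.g. two SNPs inducing
    // the same partition) must resolve to the lowest (snp, threshold) in
    // every criterion, so "better" means beating the incumbent by a
    // tolerance scaled to the node SS
    const double ss_node =
        std::max(arma::dot(w, arma::sum(arma::square(Ysub), 0)) - base, 0.0);
    const double tol = 1e-9 * ss_node;
    bgain = 0.0; bsnp = -1; bthr = -1;
    for (int s = 0; s < m; ++s) {
      const int n1 = c1[s], n2 = c2[s], n0 = n - n1 - n2;
      if (n0 >= 1 && n0 < n) {  // threshold 0: {0} | {1,2}
        double g = -base;
        for (int q = 0; q < Q; ++q) {
          const double sl = tot[q] - S1(s, q) - S2(s, q);
          const double sr = tot[q] - sl;
          g += w[q] * (sl * sl / n0 + sr * sr / (n - n0));
        }
        if (g > bgain + tol) { bgain = g; bsnp = s; bthr = 0; }
      }
      // threshold 1: {0,1} | {2}; same partition as t=0 when n1 == 0
      if (n2 >= 1 && n2 < n && n1 > 0) {
        double g = -base;
        for (int q = 0; q < Q; ++q) {
          const double sr = S2(s, q);
          const double sl = tot[q] - sr;
          g += w[q] * (sl * sl / (n - n2) + sr * sr / n2);
        }
        if (g > bgain + tol) { bgain = g; bsnp = s; bthr = 1; }
      }
    }
    return bsnp >= 0 && bgain > tol;
  }

  // Split search under the distance-based criterion (Q never enters).
  bool best_split_distance(const std::vector<int>& idx, int& bsnp, int& bthr,
                           double& bgain) {
    const int n = idx.size(), m = cand.size();
    arma::mat Dsub(n, n);
    for (int i = 0; i < n; ++i)
      for (int l = 0; l < n; ++l) Dsub(i, l) = D2(idx[i], idx[l]);
    arma::vec rs = arma::sum(Dsub, 1);
    const double T = arma::accu(rs);
    arma::mat Z0(n, m, arma::fill::zeros), Z2(n, m, arma::fill::zeros);
    std::vector<int> c0(m, 0), c2(m, 0);
    for (int s = 0; s < m; ++s) {
      const int j = cand[s];
      for (int i = 0; i < n; ++i) {
        const int g = X(idx[i], j);
        if (g == 0) { Z0(i, s) = 1.0; ++c0[s]; }
        else if (g == 2) { Z2(i, s) = 1.0; ++c2[s]; }
      }
    }
    arma::mat W0 = Dsub * Z0, W2 = Dsub * Z2;
    arma::rowvec S00 = arma::sum(Z0 % W0, 0);  // sum of d2 within class 0
    arma::rowvec S22 = arma::sum(Z2 % W2, 0);
    arma::rowvec R0 = rs.t() * Z0;  // row-sum mass of class 0
    arma::rowvec R2 = rs.t() * Z2;
    const double ss_node = T / (2.0 * n);
    const double tol = 1e-9 * ss_node;  // same tie rule as the standard path
    bgain = 0.0; bsnp = -1; bthr = -1;
    for (int s = 0; s < m; ++s) {
      const int n0 = c0[s], n2 = c2[s], n1 = n - n0 - n2;
      if (n0 >= 1 && n0 < n) {
        const double ss_l = S00[s] / (2.0 * n0);
        const double srr = T - 2.0 * R0[s] + S00[s];
        const double ss_r = srr / (2.0 * (n - n0));
        const double g = ss_node - ss_l - ss_r;
        if (g > bgain + tol) { bgain = g; bsnp = s; bthr = 0; }
      }
      if (n2 >= 1 && n2 < n && n1 > 0) {
        const double ss_r = S22[s] / (2.0 * n2);
        const double sll = T - 2.0 * R2[s] + S22[s];
        const double ss_l = sll / (2.0 * (n - n2));
        const double g = ss_node - ss_l - ss_r;
        if (g > bgain + tol) { bgain = g; bsnp = s; bthr = 1; }
      }
    }
    return bsnp >= 0 && bgain > tol;
  }

  int grow(const std::vector<int>& idx) {
    const int n = idx.size();
    if (n < min_node) return make_leaf(idx);
    draw_candidates();
    int bsnp, bthr;
    double bgain;
    bool ok = (criterion == 0)
                  ? best_split_standard(idx, bsnp, bthr, bgain)
                  : best_split_distance(idx, bsnp, bthr, bgain);
    if (!ok) return make_leaf(idx);
    const int j = cand[bsnp];
    std::vector<int> li, ri;
    li.reserve(n); ri.reserve(n);
    for (int i = 0; i < n; ++i) {
      if (X(idx[i], j) <= bthr) li.push_back(idx[i]);
      else ri.push_back(idx[i]);
    }
    int node = new_node(n);
    out.snp[node] = j;
    out.thr[node] = bthr;
    out.gain[node] = bgain;
    const int l = grow(li);
    const int r = grow(ri);
    out.left[node] = l;
    out.right[node] = r;
    return node;
  }
};

}  // namespace

// Grow one or more trees; returns one list per tree id.
// [[Rcpp::export(name = ".grow_trees_cpp")]]
List grow_trees_cpp(const arma::imat& X, const arma::mat& Y,
                    const arma::mat& D2, IntegerVector tree_ids,
                    int master_seed, int criterion, int covariance,
                    int mtry, int min_node, double var_floor) {
  const int N = X.n_rows;
  List res(tree_ids.size());
  for (int t = 0; t < tree_ids.size(); ++t) {
    const int id = tree_ids[t];
    SplitMix rng = tree_rng(master_seed, id);
    std::vector<int> bag(N);
    std::vector<int> inbag(N, 0);
    for (int i = 0; i < N; ++i) {
      bag[i] = rng.below(N);
      ++inbag[bag[i]];
    }
    Grower g(X, Y, D2, criterion, covariance, mtry, min_node, var_floor, rng);
    int root = g.grow(bag);
    (void)root;  // preorder: root is node 0
    const int n_nodes = g.out.snp.size();
    const int n_leaves = g.out.leaf_means.size();
    // route every sample to its leaf
    IntegerVector leaf_assign(N);
    for (int i = 0; i < N; ++i) {
      int node = 0;
      while (g.out.leaf_id[node] < 0) {
        node = (X(i, g.out.snp[node]) <= g.out.thr[node]) ? g.out.left[node]
                                                          : g.out.right[node];
      }
      leaf_assign[i] = g.out.leaf_id[node] + 1;
    }
    NumericMatrix lm(n_leaves, Y.n_cols);
    List lbag(n_leaves);
    for (int k = 0; k < n_leaves; ++k) {
      for (unsigned q = 0; q < Y.n_cols; ++q) lm(k, q) = g.out.leaf_means[k][q];
      IntegerVector b(g.out.leaf_bag[k].size());
      for (size_t i = 0; i < g.out.leaf_bag[k].size(); ++i)
        b[i] = g.out.leaf_bag[k][i] + 1;
      lbag[k] = b;
    }
    std::vector<int> oob;
    for (int i = 0; i < N; ++i)
      if (inbag[i] == 0) oob.push_back(i + 1);
    IntegerMatrix nodes(n_nodes, 6);
    NumericVector gains(n_nodes);
    for (int k = 0; k < n_nodes; ++k) {
      nodes(k, 0) = g.out.snp[k] + 1;  // 0 marks a leaf
      nodes(k, 1) = g.out.thr[k];
      nodes(k, 2) = g.out.left[k] + 1;
      nodes(k, 3) = g.out.right[k] + 1;
      nodes(k, 4) = g.out.size[k];
      nodes(k, 5) = g.out.leaf_id[k] + 1;
      gains[k] = g.out.gain[k];
    }
    colnames(nodes) = CharacterVector::create("snp", "threshold", "left",
                                              "right", "size", "leaf");
    res[t] = List::create(
        _["tree_id"] = id, _["nodes"] = nodes, _["gain"] = gains,
        _["leaf_means"] = lm, _["leaf_bag"] = lbag,
        _["leaf_assign"] = leaf_assign, _["oob"] = wrap(oob),
        _["inbag_count"] = wrap(inbag));
  }
  return res;
}
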