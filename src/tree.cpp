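// Exact greedy least-squares regression tree.
//
// This is the shared base learner for the boosted stage models and the
// random-forest imputer. No CRAN tree package is assumed; the tree is a
// flat node table so fitted models serialise as plain numeric vectors.
//
// Split search: at each node every candidate feature is scanned in sorted
// order and the SSE-optimal midpoint threshold is kept. Ties are broken
// toward the lower feature index / smaller threshold, so fits are fully
// deterministic for a given (X, y, seed).

#include <Rcpp.h>
#include <random>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  int feature;      // -1 for leaf
  double threshold;
  double value;     // mean response (leaves); mean also kept for internals
  int left, right;
  int n;
};

struct Task {
  int node;
  std::vector<int> rows;
  int depth;
};

// Best split for one node. Returns gain over the no-split score, or -1.
bool best_split(const NumericMatrix& X, const NumericVector& y,
                const std::vector<int>& rows, const std::vector<int>& feats,
                int min_leaf, int& bf, double& bt, double& bgain) {
  const int m = (int)rows.size();
  double tot = 0.0;
  for (int i : rows) tot += y[i];
  const double base = tot * tot / m;
  bf = -1; bt = 0.0; bgain = 1e-12;

  std::vector<std::pair<double, double> > xy(m); // (x, y)
  for (int f : feats) {
    for (int k = 0; k < m; ++k)
      xy[k] = std::make_pair(X(rows[k], f), y[rows[k]]);
    std::sort(xy.begin(), xy.end());
    if (xy.front().first == xy.back().first) continue; // constant feature
    double sl = 0.0;
    for (int k = 0; k < m - 1; ++k) {
      sl += xy[k].second;
      if (xy[k].first == xy[k + 1].first) continue;
      const int nl = k + 1, nr = m - nl;
      if (nl < min_leaf || nr < min_leaf) continue;
      const double sr = tot - sl;
      const double gain = sl * sl / nl + sr * sr / nr - base;
      if (gain > bgain) {
        bgain = gain;
        bf = f;
        bt = xy[k].first + 0.5 * (xy[k + 1].first - xy[k].first);
      }
    }
  }
  return bf >= 0;
}

// Level-wise presorted builder used when every feature is a candidate at
// every node (the boosting case): features are sorted once, then each
// level costs one linear scan per feature. Semantics (tie-breaks, gain
// threshold, midpoint thresholds) match the generic builder exactly.
List fit_tree_presort(const NumericMatrix& X, const NumericVector& y,
                      int max_depth, int min_split, int min_leaf) {
  const int n = X.nrow(), p = X.ncol();
  std::vector<std::vector<int> > order(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<int>& o = order[f];
    for (int i = 0; i < n; ++i) o[i] = i;
    const int ff = f;
    std::stable_sort(o.begin(), o.end(), [&X, ff](int a, int b) {
      return X(a, ff) < X(b, ff);
    });
  }

  std::vector<Node> nodes(1);
  std::vector<int> node_of(n, 0), depth_of(1, 0);
  {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += y[i];
    nodes[0].feature = -1; nodes[0].threshold = 0.0;
    nodes[0].value = s / n; nodes[0].left = nodes[0].right = -1;
    nodes[0].n = n;
  }
  std::vector<int> active(1, 0);

  // per-node scan state, indexed by node id
  std::vector<double> tot_sum(1, nodes[0].value * n);
  while (!active.empty()) {
    const size_t m = nodes.size();
    std::vector<char> is_active(m, 0);
    for (int id : active)
      if (depth_of[id] < max_depth && nodes[id].n >= min_split &&
          nodes[id].n >= 2 * min_leaf)
        is_active[id] = 1;
    std::vector<int> scan;
    for (int id : active) if (is_active[id]) scan.push_back(id);
    if (scan.empty()) break;

    std::vector<double> best_gain(m, 1e-12), best_thr(m, 0.0);
    std::vector<int> best_feat(m, -1);
    std::vector<int> cnt(m); std::vector<double> sl(m), lastv(m);

    for (int f = 0; f < p; ++f) {
      for (int id : scan) { cnt[id] = 0; sl[id] = 0.0; }
      const std::vector<int>& o = order[f];
      for (int k = 0; k < n; ++k) {
        const int i = o[k];
        const int nd = node_of[i];
        if (nd < 0 || (size_t)nd >= m || !is_active[nd]) continue;
        const double xv = X(i, f);
        if (cnt[nd] > 0 && xv > lastv[nd]) {
          const int nl = cnt[nd], nr = nodes[nd].n - nl;
          if (nl >= min_leaf && nr >= min_leaf) {
            const double s_l = sl[nd], s_r = tot_sum[nd] - s_l;
            const double base = tot_sum[nd] * tot_sum[nd] / nodes[nd].n;
            const double gain = s_l * s_l / nl + s_r * s_r / nr - base;
            if (gain > best_gain[nd]) {
              best_gain[nd] = gain;
              best_feat[nd] = f;
              best_thr[nd] = lastv[nd] + 0.5 * (xv - lastv[nd]);
            }
          }
        }
        cnt[nd] += 1; sl[nd] += y[i]; lastv[nd] = xv;
      }
    }

    std::vector<int> next;
    const size_t old_size = nodes.size();
    for (int id : scan) {
      if (best_feat[id] < 0) continue;
      const int li = (int)nodes.size(), ri = li + 1;
      nodes[id].feature = best_feat[id];
      nodes[id].threshold = best_thr[id];
      nodes[id].left = li; nodes[id].right = ri;
      nodes.push_back(Node()); nodes.push_back(Node());
      depth_of.push_back(depth_of[id] + 1);
      depth_of.push_back(depth_of[id] + 1);
      nodes[li].feature = nodes[ri].feature = -1;
      nodes[li].left = nodes[li].right = -1;
      nodes[ri].left = nodes[ri].right = -1;
      nodes[li].n = nodes[ri].n = 0;
      nodes[li].value = nodes[ri].value = 0.0;
      next.push_back(li); next.push_back(ri);
    }
    tot_sum.assign(nodes.size(), 0.0);
    for (int i = 0; i < n; ++i) {
      int nd = node_of[i];
      if (nd >= 0 && nodes[nd].feature >= 0) {
        nd = (X(i, nodes[nd].feature) <= nodes[nd].threshold)
               ? nodes[nd].left : nodes[nd].right;
        node_of[i] = nd;
      }
      // accumulate stats only for the children created this level;
      // pre-existing leaves already carry correct counts
      if (nd >= 0 && (size_t)nd >= old_size) {
        nodes[nd].n += 1;
        tot_sum[nd] += y[i];
      }
    }
    for (int id : next)
      if (nodes[id].n > 0) nodes[id].value = tot_sum[id] / nodes[id].n;
    active = next;
  }

  const int k = (int)nodes.size();
  IntegerVector feature(k), left(k), right(k), nn(k);
  NumericVector threshold(k), value(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    value[i] = nodes[i].value;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    nn[i] = nodes[i].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["value"] = value, _["left"] = left,
                      _["right"] = right, _["n"] = nn);
}

} // namespace

// [[Rcpp::export(name = ".fit_tree_cpp")]]
List fit_tree_cpp(NumericMatrix X, NumericVector y,
                  int max_depth, int min_split, int min_leaf,
                  int mtry, int seed) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("X and y sizes differ");
  if (mtry < 1) mtry = p;
  if (mtry > p) mtry = p;
  if (mtry == p)
    return fit_tree_presort(X, y, max_depth, min_split, min_leaf);
  std::mt19937 rng((unsigned)seed);

  std::vector<Node> nodes;
  std::vector<Task> stack;
  {
    std::vector<int> all(n);
    for (int i = 0; i < n; ++i) all[i] = i;
    nodes.push_back(Node());
    Task t0; t0.node = 0; t0.rows = all; t0.depth = 0;
    stack.push_back(t0);
  }

  std::vector<int> featbuf(p);
  for (int j = 0; j < p; ++j) featbuf[j] = j;

  while (!stack.empty()) {
    Task t = std::move(stack.back());
    stack.pop_back();
    const int m = (int)t.rows.size();
    double s = 0.0;
    for (int i : t.rows) s += y[i];
    Node& nd = nodes[t.node];
    nd.feature = -1; nd.threshold = 0.0; nd.value = s / m;
    nd.left = nd.right = -1; nd.n = m;

    if (t.depth >= max_depth || m < min_split || m < 2 * min_leaf) continue;

    std::vector<int> feats;
    if (mtry == p) {
      feats = featbuf;
    } else {
      std::vector<int> pool(featbuf);
      feats.reserve(mtry);
      for (int k = 0; k < mtry; ++k) {
        std::uniform_int_distribution<int> d(0, (int)pool.size() - 1);
        int j = d(rng);
        feats.push_back(pool[j]);
        pool.erase(pool.begin() + j);
      }
      std::sort(feats.begin(), feats.end());
    }

    int bf; double bt, bgain;
    if (!best_split(X, y, t.rows, feats, min_leaf, bf, bt, bgain)) continue;

    std::vector<int> lrows, rrows;
    lrows.reserve(m); rrows.reserve(m);
    for (int i : t.rows) {
      if (X(i, bf) <= bt) lrows.push_back(i); else rrows.push_back(i);
    }
    const int li = (int)nodes.size(), ri = li + 1;
    nodes[t.node].feature = bf;
    nodes[t.node].threshold = bt;
    nodes[t.node].left = li;
    nodes[t.node].right = ri;
    nodes.push_back(Node());
    nodes.push_back(Node());
    Task tl; tl.node = li; tl.rows = std::move(lrows); tl.depth = t.depth + 1;
    Task tr; tr.node = ri; tr.rows = std::move(rrows); tr.depth = t.depth + 1;
    stack.push_back(std::move(tl));
    stack.push_back(std::move(tr));
  }

  const int k = (int)nodes.size();
  IntegerVector feature(k), left(k), right(k), nn(k);
  NumericVector threshold(k), value(k);
  for (int i = 0; i < k; ++i) {
    feature[i] = nodes[i].feature;
    threshold[i] = nodes[i].threshold;
    value[i] = nodes[i].value;
    left[i] = nodes[i].left;
    right[i] = nodes[i].right;
    nn[i] = nodes[i].n;
  }
  return List::create(_["feature"] = feature, _["threshold"] = threshold,
                      _["value"] = value, _["left"] = left,
                      _["right"] = right, _["n"] = nn);
}

// [[Rcpp::export(name = ".predict_tree_cpp")]]
NumericVector predict_tree_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"], value = tree["value"];
  const int n = X.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (feature[nd] >= 0)
      nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
    out[i] = value[nd];
  }
  return out;
}

// [[Rcpp::export(name = ".predict_tree_leaf_cpp")]]
IntegerVector predict_tree_leaf_cpp(List tree, NumericMatrix X) {
  IntegerVector feature = tree["feature"], left = tree["left"],
                right = tree["right"];
  NumericVector threshold = tree["threshold"];
  const int n = X.nrow();
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int nd = 0;
    while (feature[nd] >= 0)
      nd = (X(i, feature[nd]) <= threshold[nd]) ? left[nd] : right[nd];
    out[i] = nd; // 0-based node index
  }
  return out;
}
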