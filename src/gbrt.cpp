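#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Deterministic exact-greedy gradient-boosted regression trees, squared loss.
//
// Follows the standard second-order boosting formulation: for squared loss the
// gradient of row i is (pred_i - y_i) and the hessian is 1, so a node's best
// leaf weight is -G/(H + lambda) and the split gain is
//   0.5 * [ GL^2/(HL+l) + GR^2/(HR+l) - G^2/(H+l) ].
// Trees are grown level-wise to max_depth with exact greedy splits over
// pre-sorted feature columns. No row/column subsampling, so the fit is a pure
// function of its inputs; ties are broken toward the lower feature index and
// the leftmost split point.

namespace {

struct Node {
  double G = 0.0, H = 0.0;
  double best_gain = 0.0;
  int best_feat = -1;
  double best_thr = 0.0;
  int left = -1, right = -1;
  bool finalized = false;
  double value = 0.0;
};

inline double node_score(double G, double H, double lambda) {
  return (G * G) / (H + lambda);
}

}  // namespace

// Fits a boosted ensemble on (X, y), monitoring RMSE on (Xval, yval) for
// early stopping, and returns the validation predictions at the best
// iteration. Validation rows are routed through each tree in lockstep with
// training rows so no explicit tree serialization is needed.
// [[Rcpp::export(name = ".gbrt_fit_cpp")]]
List gbrt_fit_cpp(NumericMatrix X, NumericVector y,
                  NumericMatrix Xval, NumericVector yval,
                  int n_trees, double eta, int max_depth,
                  int early_stopping_rounds, double lambda,
                  double min_gain) {
  const int n = X.nrow(), p = X.ncol();
  const int nv = Xval.nrow();
  if (n < 2) stop("need at least 2 training rows");
  if (p < 1) stop("need at least 1 feature");
  if (yval.size() != nv) stop("validation X/y size mismatch");

  // pre-sort each feature once (stable, so equal values keep row order)
  std::vector<std::vector<int>> order(p, std::vector<int>(n));
  for (int j = 0; j < p; ++j) {
    std::vector<int>& o = order[j];
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* col = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [col](int a, int b) { return col[a] < col[b]; });
  }

  double base = 0.0;
  for (int i = 0; i < n; ++i) base += y[i];
  base /= n;

  std::vector<double> pred(n, base), vpred(nv, base), grad(n);
  std::vector<int> node_of(n), vnode_of(nv);

  std::vector<double> best_vpred(vpred);
  double best_rmse = R_PosInf;
  int best_iter = -1, since_best = 0, trees_built = 0;

  // initial validation rmse of the constant model (iteration 0 = base score)
  {
    double s = 0.0;
    for (int i = 0; i < nv; ++i) { double d = yval[i] - base; s += d * d; }
    best_rmse = nv > 0 ? std::sqrt(s / nv) : R_PosInf;
  }

  std::vector<Node> nodes;
  std::vector<int> active;
  // per-feature scan buffers, indexed by node id
  std::vector<double> gl, hl, lastv;
  std::vector<char> has_last;

  for (int iter = 0; iter < n_trees; ++iter) {
    for (int i = 0; i < n; ++i) grad[i] = pred[i] - y[i];

    nodes.clear();
    nodes.push_back(Node());
    std::fill(node_of.begin(), node_of.end(), 0);
    std::fill(vnode_of.begin(), vnode_of.end(), 0);
    {
      Node& root = nodes[0];
      for (int i = 0; i < n; ++i) { root.G += grad[i]; root.H += 1.0; }
    }
    active.assign(1, 0);

    for (int depth = 0; depth < max_depth && !active.empty(); ++depth) {
      size_t nn = nodes.size();
      gl.assign(nn, 0.0);
      hl.assign(nn, 0.0);
      lastv.assign(nn, 0.0);
      has_last.assign(nn, 0);

      for (int j = 0; j < p; ++j) {
        for (int id : active) { gl[id] = 0.0; hl[id] = 0.0; has_last[id] = 0; }
        const std::vector<int>& o = order[j];
        for (int k = 0; k < n; ++k) {
          const int i = o[k];
          const int id = node_of[i];
          Node& nd = nodes[id];
          if (nd.finalized || nd.left >= 0) continue;  // not splittable here
          // only nodes created before this level are active; children created
          // this level have left/right unset but ids >= nn
          if ((size_t)id >= nn) continue;
          const double v = X(i, j);
          if (has_last[id] && v > lastv[id]) {
            const double GL = gl[id], HL = hl[id];
            const double GR = nd.G - GL, HR = nd.H - HL;
            if (HL >= 1.0 && HR >= 1.0) {
              const double gain = 0.5 * (node_score(GL, HL, lambda) +
                                         node_score(GR, HR, lambda) -
                                         node_score(nd.G, nd.H, lambda));
              if (gain > nd.best_gain + 1e-12) {
                nd.best_gain = gain;
                nd.best_feat = j;
                nd.best_thr = 0.5 * (lastv[id] + v);
              }
            }
          }
          gl[id] += grad[i];
          hl[id] += 1.0;
          lastv[id] = v;
          has_last[id] = 1;
        }
      }

      // finalize or split the active nodes
      std::vector<int> next_active;
      for (int id : active) {
        if (nodes[id].best_feat >= 0 && nodes[id].best_gain > min_gain) {
          const int l = (int)nodes.size(), r = l + 1;
          nodes.push_back(Node());  // may reallocate: index, don't hold refs
          nodes.push_back(Node());
          nodes[id].left = l;
          nodes[id].right = r;
          next_active.push_back(l);
          next_active.push_back(r);
        } else {
          nodes[id].finalized = true;
          nodes[id].value = -nodes[id].G / (nodes[id].H + lambda);
        }
      }

      // route rows to children and accumulate child stats
      if (!next_active.empty()) {
        for (int i = 0; i < n; ++i) {
          const int id = node_of[i];
          const Node& nd = nodes[id];
          if (nd.left < 0) continue;
          const int child = (X(i, nd.best_feat) < nd.best_thr) ? nd.left : nd.right;
          node_of[i] = child;
          nodes[child].G += grad[i];
          nodes[child].H += 1.0;
        }
        for (int i = 0; i < nv; ++i) {
          const int id = vnode_of[i];
          const Node& nd = nodes[id];
          if (nd.left < 0) continue;
          vnode_of[i] = (Xval(i, nd.best_feat) < nd.best_thr) ? nd.left : nd.right;
        }
      }
      active.swap(next_active);
    }
    // anything still unsplit at max depth becomes a leaf
    for (int id : active) {
      Node& nd = nodes[id];
      nd.finalized = true;
      nd.value = -nd.G / (nd.H + lambda);
    }

    for (int i = 0; i < n; ++i) pred[i] += eta * nodes[node_of[i]].value;
    for (int i = 0; i < nv; ++i) vpred[i] += eta * nodes[vnode_of[i]].value;
    ++trees_built;

    double s = 0.0;
    for (int i = 0; i < nv; ++i) { double d = yval[i] - vpred[i]; s += d * d; }
    const double rmse = nv > 0 ? std::sqrt(s / nv) : R_PosInf;
    if (rmse < best_rmse - 1e-12) {
      best_rmse = rmse;
      best_iter = iter;
      best_vpred = vpred;
      since_best = 0;
    } else if (++since_best >= early_stopping_rounds) {
      break;
    }
  }

  return List::create(
      _["val_pred"] = NumericVector(best_vpred.begin(), best_vpred.end()),
      _["val_rmse"] = best_rmse,
      _["best_iter"] = best_iter + 1,  // 0 = constant model won
      _["trees_built"] = trees_built,
      _["base_score"] = base);
}
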