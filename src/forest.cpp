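// Random forests used by the hub-gene selector (classification, Gini
// splitting) and the prognostic model (survival, log-rank splitting).
// Permutation importance throughout: mean OOB accuracy / concordance drop
// per tree after permuting one feature among that tree's OOB cases.
// All randomness comes from R's RNG so set.seed() governs reproducibility.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

inline int randi(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// sample m distinct ints from 0..n-1 (partial Fisher-Yates)
std::vector<int> sample_without_replacement(int n, int m) {
  std::vector<int> pool(n);
  for (int i = 0; i < n; ++i) pool[i] = i;
  std::vector<int> out(m);
  for (int j = 0; j < m; ++j) {
    int idx = j + randi(n - j);
    std::swap(pool[j], pool[idx]);
    out[j] = pool[j];
  }
  return out;
}

struct Node {
  int feature;      // -1 => leaf
  double threshold; // go left if x <= threshold
  int left, right;
  int cls;                      // classification leaf: majority class
  std::vector<double> chf;      // survival leaf: Nelson-Aalen CHF on grid
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> used_features;
};

int descend(const Tree& tr, const double* xrow, int n_feat_stride,
            const std::vector<double>& Xcol_major, int n, int i_override_feat,
            double override_val, int i) {
  // Xcol_major: column-major n x p matrix; sample i; if i_override_feat >= 0
  // that feature's value is replaced by override_val (permutation importance).
  int node = 0;
  (void)xrow; (void)n_feat_stride;
  while (tr.nodes[node].feature >= 0) {
    int f = tr.nodes[node].feature;
    double v = (f == i_override_feat) ? override_val
                                      : Xcol_major[(size_t)f * n + i];
    node = (v <= tr.nodes[node].threshold) ? tr.nodes[node].left
                                           : tr.nodes[node].right;
  }
  return node;
}

// ---------------- classification forest ----------------

struct ClassForestGrower {
  const std::vector<double>& X; // column-major n x p
  const IntegerVector& y;
  int n, p, n_class, mtry, min_node;

  ClassForestGrower(const std::vector<double>& X_, const IntegerVector& y_,
                    int n_, int p_, int n_class_, int mtry_, int min_node_)
      : X(X_), y(y_), n(n_), p(p_), n_class(n_class_), mtry(mtry_),
        min_node(min_node_) {}

  int grow(Tree& tr, std::vector<int>& idx, int lo, int hi) {
    int node_id = (int)tr.nodes.size();
    tr.nodes.push_back(Node{-1, 0.0, -1, -1, 0, {}});
    int m = hi - lo;
    std::vector<int> cnt(n_class, 0);
    for (int t = lo; t < hi; ++t) cnt[y[idx[t]]]++;
    int maj = 0;
    for (int c = 1; c < n_class; ++c) if (cnt[c] > cnt[maj]) maj = c;
    tr.nodes[node_id].cls = maj;
    bool pure = (cnt[maj] == m);
    if (pure || m < 2 * min_node) return node_id;

    double best_gain = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    double total_gini = 0.0;
    for (int c = 0; c < n_class; ++c)
      total_gini += (double)cnt[c] * cnt[c];
    total_gini = 1.0 - total_gini / ((double)m * m);

    std::vector<int> feats = sample_without_replacement(p, mtry);
    std::vector<std::pair<double,int>> vals(m);
    std::vector<int> lc(n_class);
    for (int f : feats) {
      for (int t = 0; t < m; ++t) {
        int i = idx[lo + t];
        vals[t] = {X[(size_t)f * n + i], y[i]};
      }
      std::sort(vals.begin(), vals.end());
      if (vals.front().first == vals.back().first) continue;
      std::fill(lc.begin(), lc.end(), 0);
      int nl = 0;
      double sl = 0.0, sr = 0.0; // sum of squared counts
      std::vector<int> rc(cnt);
      for (int c = 0; c < n_class; ++c) sr += (double)rc[c] * rc[c];
      for (int t = 0; t < m - 1; ++t) {
        int c = vals[t].second;
        sl += 2.0 * lc[c] + 1.0;
        sr -= 2.0 * rc[c] - 1.0;
        lc[c]++; rc[c]--; nl++;
        if (vals[t].first == vals[t + 1].first) continue;
        int nr = m - nl;
        double gini_l = 1.0 - sl / ((double)nl * nl);
        double gini_r = 1.0 - sr / ((double)nr * nr);
        double gain = total_gini -
          ((double)nl / m) * gini_l - ((double)nr / m) * gini_r;
        if (gain > best_gain) {
          best_gain = gain;
          best_f = f;
          best_thr = 0.5 * (vals[t].first + vals[t + 1].first);
        }
      }
    }
    if (best_f < 0) return node_id;

    int mid = lo;
    for (int t = lo; t < hi; ++t)
      if (X[(size_t)best_f * n + idx[t]] <= best_thr) std::swap(idx[mid++], idx[t]);
    if (mid == lo || mid == hi) return node_id;

    tr.nodes[node_id].feature = best_f;
    tr.nodes[node_id].threshold = best_thr;
    tr.used_features.push_back(best_f);
    int l = grow(tr, idx, lo, mid);
    tr.nodes[node_id].left = l;
    int r = grow(tr, idx, mid, hi);
    tr.nodes[node_id].right = r;
    return node_id;
  }
};

// ---------------- survival pieces ----------------

// Harrell C-index (ties in score count 1/2); returns NA if no usable pair.
double harrell_c(const std::vector<double>& score,
                 const std::vector<double>& time,
                 const std::vector<int>& event,
                 const std::vector<int>& which) {
  double conc = 0.0, usable = 0.0;
  int m = (int)which.size();
  for (int a = 0; a < m; ++a) {
    int i = which[a];
    for (int b = a + 1; b < m; ++b) {
      int j = which[b];
      int ii = i, jj = j;
      if (time[jj] < time[ii]) std::swap(ii, jj);
      else if (time[ii] == time[jj]) {
        // tied times: usable only when exactly one is an event
        if (event[i] + event[j] != 1) continue;
        ii = event[i] ? i : j; jj = event[i] ? j : i;
        if (score[ii] > score[jj]) conc += 1.0;
        else if (score[ii] == score[jj]) conc += 0.5;
        usable += 1.0;
        continue;
      }
      if (!event[ii]) continue; // earlier time censored -> not usable
      if (score[ii] > score[jj]) conc += 1.0;
      else if (score[ii] == score[jj]) conc += 0.5;
      usable += 1.0;
    }
  }
  if (usable == 0.0) return NA_REAL;
  return conc / usable;
}

// standardized log-rank statistic^2 (chisq, 1 df) for a 0/1 grouping over
// node samples; samples given by idx[lo,hi)
double logrank_chisq(const std::vector<double>& time,
                     const std::vector<int>& event,
                     const std::vector<int>& members,
                     const std::vector<int>& grp) {
  int m = (int)members.size();
  std::vector<int> ord(m);
  for (int t = 0; t < m; ++t) ord[t] = t;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return time[members[a]] < time[members[b]];
  });
  double Y = m, Y1 = 0.0;
  for (int t = 0; t < m; ++t) Y1 += grp[t];
  double U = 0.0, V = 0.0;
  int t = 0;
  while (t < m) {
    int s = t;
    double tt = time[members[ord[t]]];
    double d = 0.0, d1 = 0.0, atrisk_drop = 0.0, atrisk1_drop = 0.0;
    while (t < m && time[members[ord[t]]] == tt) {
      int loc = ord[t];
      if (event[members[loc]]) { d += 1.0; d1 += grp[loc]; }
      atrisk_drop += 1.0;
      atrisk1_drop += grp[loc];
      ++t;
    }
    (void)s;
    if (d > 0.0 && Y > 1.0) {
      U += d1 - d * Y1 / Y;
      V += d * (Y1 / Y) * (1.0 - Y1 / Y) * (Y - d) / (Y - 1.0);
    }
    Y -= atrisk_drop;
    Y1 -= atrisk1_drop;
  }
  if (V <= 0.0) return 0.0;
  return U * U / V;
}

struct SurvForestGrower {
  const std::vector<double>& X;
  const std::vector<double>& time;
  const std::vector<int>& event;
  const std::vector<double>& grid; // sorted unique event times (global)
  int n, p, mtry, min_node, nsplit;

  SurvForestGrower(const std::vector<double>& X_,
                   const std::vector<double>& time_,
                   const std::vector<int>& event_,
                   const std::vector<double>& grid_, int n_, int p_, int mtry_,
                   int min_node_, int nsplit_)
      : X(X_), time(time_), event(event_), grid(grid_), n(n_), p(p_),
        mtry(mtry_), min_node(min_node_), nsplit(nsplit_) {}

  void make_leaf(Tree& tr, int node_id, std::vector<int>& idx, int lo, int hi) {
    // Nelson-Aalen CHF of node members, evaluated on the global grid
    int m = hi - lo;
    std::vector<int> ord(idx.begin() + lo, idx.begin() + hi);
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      return time[a] < time[b];
    });
    std::vector<double>& chf = tr.nodes[node_id].chf;
    chf.assign(grid.size(), 0.0);
    double Y = m, cum = 0.0;
    size_t g = 0;
    int t = 0;
    while (t < m) {
      double tt = time[ord[t]];
      double d = 0.0, drop = 0.0;
      while (t < m && time[ord[t]] == tt) {
        if (event[ord[t]]) d += 1.0;
        drop += 1.0;
        ++t;
      }
      while (g < grid.size() && grid[g] < tt) { chf[g] = cum; ++g; }
      if (d > 0.0 && Y > 0.0) cum += d / Y;
      if (g < grid.size() && grid[g] == tt) { chf[g] = cum; ++g; }
      Y -= drop;
    }
    while (g < grid.size()) { chf[g] = cum; ++g; }
  }

  int grow(Tree& tr, std::vector<int>& idx, int lo, int hi) {
    int node_id = (int)tr.nodes.size();
    tr.nodes.push_back(Node{-1, 0.0, -1, -1, 0, {}});
    int m = hi - lo;
    int nev = 0;
    for (int t = lo; t < hi; ++t) nev += event[idx[t]];
    if (m < 2 * min_node || nev == 0) {
      make_leaf(tr, node_id, idx, lo, hi);
      return node_id;
    }

    std::vector<int> members(idx.begin() + lo, idx.begin() + hi);
    std::vector<int> feats = sample_without_replacement(p, mtry);
    double best_stat = 1e-12;
    int best_f = -1;
    double best_thr = 0.0;
    std::vector<double> vals(m);
    std::vector<int> grp(m);
    for (int f : feats) {
      for (int t = 0; t < m; ++t) vals[t] = X[(size_t)f * n + members[t]];
      std::vector<double> uq(vals);
      std::sort(uq.begin(), uq.end());
      uq.erase(std::unique(uq.begin(), uq.end()), uq.end());
      if (uq.size() < 2) continue;
      int ncand = (int)uq.size() - 1;
      int ntry = std::min(nsplit, ncand);
      std::vector<int> cand;
      if (ntry == ncand) {
        cand.resize(ncand);
        for (int c = 0; c < ncand; ++c) cand[c] = c;
      } else {
        cand = sample_without_replacement(ncand, ntry);
      }
      for (int c : cand) {
        double thr = 0.5 * (uq[c] + uq[c + 1]);
        int nl = 0;
        for (int t = 0; t < m; ++t) {
          grp[t] = (vals[t] <= thr) ? 1 : 0;
          nl += grp[t];
        }
        if (nl < min_node || m - nl < min_node) continue;
        double stat = logrank_chisq(time, event, members, grp);
        if (stat > best_stat) {
          best_stat = stat;
          best_f = f;
          best_thr = thr;
        }
      }
    }
    if (best_f < 0) {
      make_leaf(tr, node_id, idx, lo, hi);
      return node_id;
    }
    int mid = lo;
    for (int t = lo; t < hi; ++t)
      if (X[(size_t)best_f * n + idx[t]] <= best_thr) std::swap(idx[mid++], idx[t]);
    if (mid == lo || mid == hi) {
      tr.nodes[node_id].feature = -1;
      make_leaf(tr, node_id, idx, lo, hi);
      return node_id;
    }
    tr.nodes[node_id].feature = best_f;
    tr.nodes[node_id].threshold = best_thr;
    tr.used_features.push_back(best_f);
    tr.nodes[node_id].left = grow(tr, idx, lo, mid);
    tr.nodes[node_id].right = grow(tr, idx, mid, hi);
    return node_id;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_class_forest(NumericMatrix Xr, IntegerVector y, int n_class,
                      int n_trees, int mtry, int min_node) {
  int n = Xr.nrow(), p = Xr.ncol();
  std::vector<double> X(Xr.begin(), Xr.end()); // column-major
  ClassForestGrower grower(X, y, n, p, n_class, mtry, min_node);

  std::vector<double> importance(p, 0.0);
  std::vector<std::vector<int>> oob_votes(n, std::vector<int>(n_class, 0));
  std::vector<int> inbag(n);

  for (int b = 0; b < n_trees; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int s = randi(n);
      idx[i] = s;
      inbag[s]++;
    }
    Tree tr;
    grower.grow(tr, idx, 0, n);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (oob.empty()) continue;

    int correct = 0;
    for (int i : oob) {
      int leaf = descend(tr, nullptr, 0, X, n, -1, 0.0, i);
      int pred = tr.nodes[leaf].cls;
      oob_votes[i][pred]++;
      if (pred == y[i]) correct++;
    }
    double acc = (double)correct / oob.size();

    std::sort(tr.used_features.begin(), tr.used_features.end());
    tr.used_features.erase(
        std::unique(tr.used_features.begin(), tr.used_features.end()),
        tr.used_features.end());
    int nob = (int)oob.size();
    for (int f : tr.used_features) {
      // permute feature f among OOB cases
      std::vector<int> perm(oob);
      for (int t = nob - 1; t > 0; --t) std::swap(perm[t], perm[randi(t + 1)]);
      int corr_p = 0;
      for (int t = 0; t < nob; ++t) {
        int i = oob[t];
        double v = X[(size_t)f * n + perm[t]];
        int leaf = descend(tr, nullptr, 0, X, n, f, v, i);
        if (tr.nodes[leaf].cls == y[i]) corr_p++;
      }
      importance[f] += acc - (double)corr_p / nob;
    }
  }
  for (int f = 0; f < p; ++f) importance[f] /= n_trees;

  IntegerVector oob_pred(n, NA_INTEGER);
  for (int i = 0; i < n; ++i) {
    int best = -1, bc = 0, tot = 0;
    for (int c = 0; c < n_class; ++c) {
      tot += oob_votes[i][c];
      if (oob_votes[i][c] > bc) { bc = oob_votes[i][c]; best = c; }
    }
    if (tot > 0) oob_pred[i] = best;
  }
  return List::create(_["importance"] = NumericVector(importance.begin(), importance.end()),
                      _["oob_pred"] = oob_pred);
}

// [[Rcpp::export]]
List cpp_surv_forest(NumericMatrix Xr, NumericVector time_r,
                     IntegerVector event_r, int n_trees, int mtry,
                     int min_node, int nsplit, int checkpoint_every) {
  int n = Xr.nrow(), p = Xr.ncol();
  std::vector<double> X(Xr.begin(), Xr.end());
  std::vector<double> time(time_r.begin(), time_r.end());
  std::vector<int> event(event_r.begin(), event_r.end());

  std::vector<double> grid;
  for (int i = 0; i < n; ++i) if (event[i]) grid.push_back(time[i]);
  std::sort(grid.begin(), grid.end());
  grid.erase(std::unique(grid.begin(), grid.end()), grid.end());
  if (grid.empty()) stop("all samples censored: no event times to model");

  SurvForestGrower grower(X, time, event, grid, n, p, mtry, min_node, nsplit);

  std::vector<double> importance(p, 0.0);
  std::vector<double> oob_mort_sum(n, 0.0);
  std::vector<int> oob_count(n, 0);
  std::vector<int> inbag(n);
  std::vector<double> ckpt_trees, ckpt_err;
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;

  for (int b = 0; b < n_trees; ++b) {
    std::fill(inbag.begin(), inbag.end(), 0);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) {
      int s = randi(n);
      idx[i] = s;
      inbag[s]++;
    }
    Tree tr;
    grower.grow(tr, idx, 0, n);

    std::vector<int> oob;
    for (int i = 0; i < n; ++i) if (!inbag[i]) oob.push_back(i);
    if (!oob.empty()) {
      std::vector<double> mort(n, 0.0);
      for (int i : oob) {
        int leaf = descend(tr, nullptr, 0, X, n, -1, 0.0, i);
        const std::vector<double>& chf = tr.nodes[leaf].chf;
        double mm = 0.0;
        for (double v : chf) mm += v;
        mort[i] = mm;
        oob_mort_sum[i] += mm;
        oob_count[i]++;
      }
      double c_tree = harrell_c(mort, time, event, oob);
      if (!ISNA(c_tree)) {
        std::sort(tr.used_features.begin(), tr.used_features.end());
        tr.used_features.erase(
            std::unique(tr.used_features.begin(), tr.used_features.end()),
            tr.used_features.end());
        int nob = (int)oob.size();
        for (int f : tr.used_features) {
          std::vector<int> perm(oob);
          for (int t = nob - 1; t > 0; --t)
            std::swap(perm[t], perm[randi(t + 1)]);
          std::vector<double> mort_p(n, 0.0);
          for (int t = 0; t < nob; ++t) {
            int i = oob[t];
            double v = X[(size_t)f * n + perm[t]];
            int leaf = descend(tr, nullptr, 0, X, n, f, v, i);
            const std::vector<double>& chf = tr.nodes[leaf].chf;
            double mm = 0.0;
            for (double vv : chf) mm += vv;
            mort_p[i] = mm;
          }
          double c_perm = harrell_c(mort_p, time, event, oob);
          if (!ISNA(c_perm)) importance[f] += c_tree - c_perm;
        }
      }
    }

    if ((b + 1) % checkpoint_every == 0 || b + 1 == n_trees) {
      std::vector<double> ens(n, 0.0);
      std::vector<int> have;
      for (int i = 0; i < n; ++i)
        if (oob_count[i] > 0) {
          ens[i] = oob_mort_sum[i] / oob_count[i];
          have.push_back(i);
        }
      double cc = harrell_c(ens, time, event, have);
      if (!ISNA(cc)) {
        ckpt_trees.push_back(b + 1);
        ckpt_err.push_back(1.0 - cc);
      }
    }
  }
  for (int f = 0; f < p; ++f) importance[f] /= n_trees;

  NumericVector mort_out(n, NA_REAL);
  for (int i = 0; i < n; ++i)
    if (oob_count[i] > 0) mort_out[i] = oob_mort_sum[i] / oob_count[i];

  return List::create(
      _["importance"] = NumericVector(importance.begin(), importance.end()),
      _["oob_mortality"] = mort_out,
      _["oob_trees"] = NumericVector(ckpt_trees.begin(), ckpt_trees.end()),
      _["oob_error"] = NumericVector(ckpt_err.begin(), ckpt_err.end()));
}

// [[Rcpp::export]]
double cpp_harrell_c(NumericVector score, NumericVector time_r,
                     IntegerVector event_r) {
  int n = score.size();
  std::vector<double> s(score.begin(), score.end());
  std::vector<double> t(time_r.begin(), time_r.end());
  std::vector<int> e(event_r.begin(), event_r.end());
  std::vector<int> all(n);
  for (int i = 0; i < n; ++i) all[i] = i;
  double c = harrell_c(s, t, e, all);
  if (ISNA(c)) stop("no comparable pairs for concordance");
  return c;
}
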