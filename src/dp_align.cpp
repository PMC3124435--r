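// Dynamic-programming alignment of a short peptide query to simple paths in
// a small graph (<= 50 vertices, so a visited set fits a 64-bit mask).
//
// A state is (end vertex m, visited set S) at query position i, holding the
// best score of any alignment consuming the query prefix up to i whose path
// visits exactly S and ends at m.  Moves: start a new path at any vertex
// matching q_i (free leading ends), replacement (append neighbour, consume
// one query position), deletion gap (consume query, path unchanged),
// insertion gap (append neighbour, query unchanged).  Ends are free: the
// answer is the maximum over all states at all levels, floored at zero.
// Duplicate paths (same end vertex, same visited set, different permutation)
// collapse onto one state keeping the best score.
//
// Branch and bound: a state is expanded only if its admissible upper bound
// is not strictly below the best complete score found so far; pruning never
// changes the returned score.  The bound used is per-position: the state's
// score plus, for every unconsumed query position, the best matrix score
// that position can achieve against any amino acid present in the graph
// (insertions and deletions only subtract, so no completion can exceed it;
// it is never larger than remaining * max matrix entry).

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct StateRec {
  double score;
  uint64_t key;     // (S << 6) | m
  int parent;       // index into the global state vector, -1 for roots
  int8_t move;      // 0 init-match, 1 replacement, 2 deletion, 3 insertion
  int16_t level;    // query position (1-based) this state sits at
};

inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

struct Level {
  std::unordered_map<uint64_t, int> idx;              // key -> state index
  std::vector<std::vector<int> > buckets;             // by popcount(S)
  void reset(int n) {
    idx.clear();
    buckets.assign(n + 1, std::vector<int>());
  }
};

class Aligner {
public:
  Aligner(const std::vector<std::vector<int> >& adj,
          const std::vector<int>& vaa,
          const NumericMatrix& smat, double gap,
          bool use_bb, bool allow_ins, bool allow_del, bool want_path)
    : adj_(adj), vaa_(vaa), smat_(smat), gap_(gap), use_bb_(use_bb),
      allow_ins_(allow_ins), allow_del_(allow_del), want_path_(want_path),
      n_((int)adj.size()) {
    max_entry_ = R_NegInf;
    for (int i = 0; i < smat_.nrow(); ++i)
      for (int j = 0; j < smat_.ncol(); ++j)
        if (smat_(i, j) > max_entry_) max_entry_ = smat_(i, j);
  }

  // returns best score; fills qpos/vert alignment columns when requested
  double run(const std::vector<int>& query,
             std::vector<int>& out_qpos, std::vector<int>& out_vert,
             long long& expanded, long long& created) {
    const int k = (int)query.size();
    states_.clear();
    expanded = 0; created = 0;
    best_score_ = 0.0;               // empty alignment scores zero
    best_idx_ = -1;
    double lb = 0.0;
    // best achievable match per query position within this graph, and its
    // suffix sums (positive part only): admissible completion bound
    std::vector<double> suffix(k + 1, 0.0);
    {
      std::vector<double> rowbest(k, R_NegInf);
      for (int i = 0; i < k; ++i) {
        for (int v = 0; v < n_; ++v) {
          double h = smat_(query[i], vaa_[v]);
          if (h > rowbest[i]) rowbest[i] = h;
        }
        if (use_bb_ && rowbest[i] > lb) lb = rowbest[i];  // greedy pass
      }
      for (int i = k - 1; i >= 0; --i)
        suffix[i] = suffix[i + 1] + (rowbest[i] > 0.0 ? rowbest[i] : 0.0);
    }
    Level cur, nxt;
    cur.reset(n_);
    for (int i = 1; i <= k; ++i) {
      // seed: start a path at any vertex, matching q_i (free leading ends)
      for (int v = 0; v < n_; ++v) {
        uint64_t key = ((uint64_t(1) << v) << 6) | (uint64_t)v;
        relax(cur, key, smat_(query[i - 1], vaa_[v]), -1, 0, i, created);
      }
      nxt.reset(n_);
      const double future = suffix[i];
      for (int c = 1; c <= n_; ++c) {
        // bucket may grow while processing (insertions add popcount c+1 only)
        for (size_t bi = 0; bi < cur.buckets[c].size(); ++bi) {
          int si = cur.buckets[c][bi];
          const StateRec st = states_[si];
          std::unordered_map<uint64_t, int>::iterator it = cur.idx.find(st.key);
          if (it == cur.idx.end() || it->second != si) continue;  // stale
          double sc = st.score;
          if (sc > best_score_) { best_score_ = sc; best_idx_ = si; }
          if (use_bb_) {
            if (sc > lb) lb = sc;
            if (sc + future < lb) continue;            // prune expansion
          }
          ++expanded;
          int m = (int)(st.key & 63u);
          uint64_t S = st.key >> 6;
          const std::vector<int>& nb = adj_[m];
          if (allow_ins_) {
            for (size_t a = 0; a < nb.size(); ++a) {
              int j = nb[a];
              if (S & (uint64_t(1) << j)) continue;
              uint64_t nk = (((S | (uint64_t(1) << j))) << 6) | (uint64_t)j;
              relax(cur, nk, sc + gap_, si, 3, i, created);
            }
          }
          if (i < k) {
            if (allow_del_)
              relax(nxt, st.key, sc + gap_, si, 2, i + 1, created);
            for (size_t a = 0; a < nb.size(); ++a) {
              int j = nb[a];
              if (S & (uint64_t(1) << j)) continue;
              uint64_t nk = (((S | (uint64_t(1) << j))) << 6) | (uint64_t)j;
              relax(nxt, nk, sc + smat_(query[i] /*q_{i+1}*/, vaa_[j]),
                    si, 1, i + 1, created);
            }
          }
        }
      }
      std::swap(cur.idx, nxt.idx);
      std::swap(cur.buckets, nxt.buckets);
    }
    // states parked in the final swap (level k transitions landed in cur
    // before the swap) were already scanned for the best during expansion
    // of level k; but level-k states created by REP/DEL from level k-1 and
    // never expanded still carry candidate scores -- they were scanned in
    // the i == k iteration above, so nothing more to do.
    out_qpos.clear(); out_vert.clear();
    if (want_path_ && best_idx_ >= 0) {
      std::vector<int> chain;
      for (int i = best_idx_; i >= 0; i = states_[i].parent) chain.push_back(i);
      for (std::vector<int>::reverse_iterator it2 = chain.rbegin();
           it2 != chain.rend(); ++it2) {
        const StateRec& s = states_[*it2];
        int v = (int)(s.key & 63u);
        switch (s.move) {
        case 0: case 1:
          out_qpos.push_back(s.level); out_vert.push_back(v); break;
        case 2:
          out_qpos.push_back(s.level); out_vert.push_back(NA_INTEGER); break;
        case 3:
          out_qpos.push_back(NA_INTEGER); out_vert.push_back(v); break;
        }
      }
    }
    return best_score_;
  }

private:
  void relax(Level& lv, uint64_t key, double sc, int parent, int8_t move,
             int16_t level, long long& created) {
    std::unordered_map<uint64_t, int>::iterator it = lv.idx.find(key);
    if (it != lv.idx.end() && states_[it->second].score >= sc) return;
    StateRec r; r.score = sc; r.key = key; r.parent = parent;
    r.move = move; r.level = level;
    states_.push_back(r);
    int ni = (int)states_.size() - 1;
    int pc = popcount64(key >> 6);
    if (it != lv.idx.end()) it->second = ni; else lv.idx[key] = ni;
    lv.buckets[pc].push_back(ni);
    ++created;
  }

  const std::vector<std::vector<int> >& adj_;
  const std::vector<int>& vaa_;
  const NumericMatrix& smat_;
  double gap_, max_entry_;
  bool use_bb_, allow_ins_, allow_del_, want_path_;
  int n_;
  std::vector<StateRec> states_;
  double best_score_;
  int best_idx_;
};

std::vector<std::vector<int> > as_adj(List adj) {
  int n = adj.size();
  std::vector<std::vector<int> > out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    out[i].assign(nb.begin(), nb.end());
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List dp_align_cpp(List adj, IntegerVector vertex_aa, IntegerVector query,
                  NumericMatrix smat, double gap, bool use_bb,
                  bool allow_ins, bool allow_del, bool want_path) {
  int n = adj.size();
  if (n > 50) stop("graphs are limited to 50 vertices");
  std::vector<std::vector<int> > a = as_adj(adj);
  std::vector<int> vaa(vertex_aa.begin(), vertex_aa.end());
  std::vector<int> q(query.begin(), query.end());
  Aligner al(a, vaa, smat, gap, use_bb, allow_ins, allow_del, want_path);
  std::vector<int> qpos, vert;
  long long expanded = 0, created = 0;
  double sc = al.run(q, qpos, vert, expanded, created);
  return List::create(_["score"] = sc,
                      _["qpos"] = IntegerVector(qpos.begin(), qpos.end()),
                      _["vertex"] = IntegerVector(vert.begin(), vert.end()),
                      _["states_expanded"] = (double)expanded,
                      _["states_created"] = (double)created);
}

// [[Rcpp::export]]
NumericVector dp_align_batch_cpp(List adj, IntegerVector vertex_aa,
                                 List queries, NumericMatrix smat, double gap,
                                 bool use_bb, bool allow_ins, bool allow_del) {
  int n = adj.size();
  if (n > 50) stop("graphs are limited to 50 vertices");
  std::vector<std::vector<int> > a = as_adj(adj);
  std::vector<int> vaa(vertex_aa.begin(), vertex_aa.end());
  Aligner al(a, vaa, smat, gap, use_bb, allow_ins, allow_del, false);
  int nq = queries.size();
  NumericVector out(nq);
  std::vector<int> qpos, vert;
  for (int i = 0; i < nq; ++i) {
    IntegerVector qi = queries[i];
    std::vector<int> q(qi.begin(), qi.end());
    long long e = 0, c = 0;
    out[i] = al.run(q, qpos, vert, e, c);
  }
  return out;
}
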