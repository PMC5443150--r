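// Closed frequent itemset enumeration over a formal context: LCM-style
// depth-first search with prefix-preserving closure extension, occurrence
// deliver and conditional (projected) transaction sets. Items are 0-based
// attribute ids, transactions the per-window incidence sets. Returns every
// closed itemset with support >= min_support and size >= min_size together
// with its full extent.
//
// One counting pass per visited node yields the closure (items with full
// conditional support), the prefix-preservation test (a closure item below
// the extension item means this closed set was already enumerated on
// another path), and the extension candidates. Projection to conditionally
// frequent non-intent items is lossless for all descendants because any
// closure item of a sub-extent has full support there. A child node reads
// its transactions from the parent's projection through row positions, so
// the frequent leaf nodes never copy rows; scratch lives per recursion
// depth (bounded by the longest transaction) to avoid allocation churn.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Level {
  std::vector<int> tids;              // extent, original transaction ids
  std::vector<int> pos;               // rows: positions into parent's proj
  std::vector<int> items, off;        // root only: raw transaction rows
  std::vector<int> touched, cls, freq, intent;
  std::vector<int> occ_items, occ_off;  // per-candidate row positions
  std::vector<int> pitems, poff;        // projected rows for children
};

struct Miner {
  int n_items, min_support, min_size;
  std::vector<int> cnt, slot;
  std::vector<char> in_intent;
  std::vector<Level> lev;
  std::vector<std::vector<int>> out_intent, out_extent;

  Miner(int ni, int ms, int mz)
      : n_items(ni), min_support(ms), min_size(mz),
        cnt(ni, 0), slot(ni, 0), in_intent(ni, 0) {}

  // lev is pre-sized: the recursion depth is bounded by the longest
  // transaction (the intent gains at least one item per level), so
  // references into lev stay valid across recursive calls.
  void node(int d, int e_core) {
    Level& L = lev[d];
    Level* P = d ? &lev[d - 1] : nullptr;
    const int n = d ? (int)L.pos.size() : (int)L.tids.size();
    if (d) {
      L.tids.clear();
      for (int r : L.pos) L.tids.push_back(P->tids[r]);
    }
    // single counting pass over this node's transactions
    L.touched.clear();
    if (d) {
      for (int r : L.pos)
        for (int k = P->poff[r]; k < P->poff[r + 1]; ++k) {
          int it = P->pitems[k];
          if (!in_intent[it] && cnt[it]++ == 0) L.touched.push_back(it);
        }
    } else {
      for (int it : L.items)
        if (!in_intent[it] && cnt[it]++ == 0) L.touched.push_back(it);
    }
    // closure + prefix-preservation check
    L.cls.clear();
    bool ok = true;
    for (int it : L.touched)
      if (cnt[it] == n) {
        if (it < e_core) { ok = false; break; }
        L.cls.push_back(it);
      }
    if (!ok) {
      for (int it : L.touched) cnt[it] = 0;
      return;
    }
    std::sort(L.cls.begin(), L.cls.end());
    for (int it : L.cls) in_intent[it] = 1;
    L.intent.clear();
    if (d == 0) L.intent = L.cls;
    else
      std::merge(P->intent.begin(), P->intent.end(), L.cls.begin(),
                 L.cls.end(), std::back_inserter(L.intent));
    if ((int)L.intent.size() >= min_size) {
      out_intent.push_back(L.intent);
      out_extent.push_back(L.tids);
    }
    // extension candidates (> e_core) and projection alphabet (all frequent)
    L.freq.clear();
    int n_cand = 0;
    for (int it : L.touched)
      if (!in_intent[it] && cnt[it] >= min_support) {
        L.freq.push_back(it);
        if (it > e_core) ++n_cand;
      }
    if (!n_cand) {
      for (int it : L.touched) cnt[it] = 0;
      for (int it : L.cls) in_intent[it] = 0;
      return;
    }
    std::sort(L.freq.begin(), L.freq.end());
    const int nf = (int)L.freq.size();
    // candidate slots for occurrence deliver (candidates only)
    std::vector<int> cand;
    for (int it : L.freq)
      if (it > e_core) {
        slot[it] = (int)cand.size() + 1;
        cand.push_back(it);
      }
    const int nc = (int)cand.size();
    std::vector<int> occ_cnt(nc, 0);
    // projected rows (all frequent non-intent items) + candidate counts
    L.pitems.clear();
    L.poff.assign(1, 0);
    auto push_row = [&](int row_begin, int row_end, const std::vector<int>& src) {
      for (int k = row_begin; k < row_end; ++k) {
        int it = src[k];
        if (!in_intent[it] && cnt[it] >= min_support) {
          L.pitems.push_back(it);
          if (slot[it]) ++occ_cnt[slot[it] - 1];
        }
      }
      L.poff.push_back((int)L.pitems.size());
    };
    if (d)
      for (int r : L.pos) push_row(P->poff[r], P->poff[r + 1], P->pitems);
    else
      for (int r = 0; r < n; ++r) push_row(L.off[r], L.off[r + 1], L.items);
    for (int it : L.touched) cnt[it] = 0;
    // occurrence deliver: local row positions per candidate
    L.occ_off.assign(nc + 1, 0);
    for (int s = 0; s < nc; ++s) L.occ_off[s + 1] = L.occ_off[s] + occ_cnt[s];
    L.occ_items.assign(L.occ_off[nc], 0);
    std::vector<int> fill(L.occ_off.begin(), L.occ_off.end() - 1);
    for (int r = 0; r < n; ++r)
      for (int k = L.poff[r]; k < L.poff[r + 1]; ++k) {
        int it = L.pitems[k];
        if (slot[it]) L.occ_items[fill[slot[it] - 1]++] = r;
      }
    for (int it : cand) slot[it] = 0;
    (void)nf;
    for (int s = 0; s < nc; ++s) {
      Level& C = lev[d + 1];
      C.pos.assign(L.occ_items.begin() + L.occ_off[s],
                   L.occ_items.begin() + L.occ_off[s + 1]);
      node(d + 1, cand[s]);
    }
    for (int it : L.cls) in_intent[it] = 0;
  }
};

} // namespace

// [[Rcpp::export]]
List cpp_mine_closed(List incidence, int n_attrs, int min_support,
                     int min_size) {
  int n = incidence.size();
  Miner m(n_attrs, min_support, min_size);
  if (n >= min_support && n > 0) {
    int maxlen = 0;
    {
      Level R;
      R.tids.resize(n);
      R.off.assign(1, 0);
      for (int i = 0; i < n; ++i) {
        R.tids[i] = i;
        IntegerVector v = incidence[i];
        maxlen = std::max(maxlen, (int)v.size());
        R.items.insert(R.items.end(), v.begin(), v.end());
        R.off.push_back((int)R.items.size());
      }
      m.lev.resize(maxlen + 3);
      m.lev[0] = std::move(R);
    }
    m.node(0, -1);
  }
  int k = m.out_intent.size();
  List intents(k), extents(k);
  for (int i = 0; i < k; ++i) {
    intents[i] = IntegerVector(m.out_intent[i].begin(), m.out_intent[i].end());
    extents[i] = IntegerVector(m.out_extent[i].begin(), m.out_extent[i].end());
  }
  return List::create(_["intent"] = intents, _["extent"] = extents);
}
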