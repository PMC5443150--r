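// Conceptual stability of formal concepts: the fraction of subsets of the
// extent (intensional) or intent (extensional) whose derivation reproduces
// the concept's other side. Because the derived set of any subset always
// contains the target side, the equality test reduces to a size check,
// and the intersection can stop early once it reaches the target size.
// Subsets are either enumerated exhaustively (when 2^m <= Z, or in exact
// mode) or sampled uniformly from the power set by including each element
// independently with probability 1/2, using R's RNG.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

void intersect_into(std::vector<int>& a, const int* b, int nb) {
  size_t i = 0, k = 0;
  int j = 0;
  while (i < a.size() && j < nb) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else a[k++] = a[i], ++i, ++j;
  }
  a.resize(k);
}

// rows: the per-element sets of the base side; chosen: indices into rows
bool subset_succeeds(const std::vector<const int*>& ptr,
                     const std::vector<int>& len,
                     const std::vector<int>& chosen,
                     size_t target_len, int universe,
                     std::vector<int>& buf) {
  if (chosen.empty()) return target_len == (size_t)universe;
  buf.assign(ptr[chosen[0]], ptr[chosen[0]] + len[chosen[0]]);
  for (size_t i = 1; i < chosen.size(); ++i) {
    if (buf.size() == target_len) return true;
    intersect_into(buf, ptr[chosen[i]], len[chosen[i]]);
  }
  return buf.size() == target_len;
}

} // namespace

// [[Rcpp::export]]
List cpp_stability_batch(List incidence, List tidlists, List intents,
                         List extents, bool extensional, int Z, bool exact,
                         int n_attrs, int n_objects) {
  int nc = intents.size();
  NumericVector sigma(nc);
  IntegerVector enumerated(nc);
  std::vector<int> buf, chosen;
  for (int ci = 0; ci < nc; ++ci) {
    IntegerVector intent = intents[ci], extent = extents[ci];
    IntegerVector base = extensional ? intent : extent;
    size_t target_len = extensional ? extent.size() : intent.size();
    int universe = extensional ? n_objects : n_attrs;
    List& rows_src = extensional ? tidlists : incidence;
    int m = base.size();
    std::vector<const int*> ptr(m);
    std::vector<int> len(m);
    std::vector<IntegerVector> keep(m); // guard against GC of row vectors
    for (int i = 0; i < m; ++i) {
      keep[i] = rows_src[base[i]];
      ptr[i] = INTEGER(keep[i]);
      len[i] = keep[i].size();
    }
    bool enumerate = exact || (m <= 30 && (1LL << m) <= (long long)Z);
    if (enumerate && m > 30)
      stop("base set too large for exact enumeration (%d elements)", m);
    long long hits = 0;
    if (enumerate) {
      long long total = 1LL << m;
      for (long long mask = 0; mask < total; ++mask) {
        chosen.clear();
        for (int b = 0; b < m; ++b)
          if (mask & (1LL << b)) chosen.push_back(b);
        if (subset_succeeds(ptr, len, chosen, target_len, universe, buf))
          ++hits;
      }
      sigma[ci] = (double)hits / (double)total;
      enumerated[ci] = 1;
    } else {
      for (int z = 0; z < Z; ++z) {
        chosen.clear();
        for (int b = 0; b < m; ++b)
          if (unif_rand() < 0.5) chosen.push_back(b);
        if (subset_succeeds(ptr, len, chosen, target_len, universe, buf))
          ++hits;
      }
      sigma[ci] = (double)hits / (double)Z;
      enumerated[ci] = 0;
    }
  }
  return List::create(_["sigma"] = sigma, _["enumerated"] = enumerated);
}
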