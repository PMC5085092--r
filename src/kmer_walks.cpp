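#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Enumerate every gap-skipping k-character walk of the leveled PRG.
// Edge codes: A=0 C=1 G=2 T=3 N=4 '-'=5. '-' edges contribute no character;
// walks through 'N' edges are dropped (spacer isolation; an N-containing
// k-mer can never match a read k-mer textually).
//
// Partial walks are bit-packed (2 bits per base, k <= 31). Two distinct
// gap-free walks from the same start can never spell the same prefix (edge
// labels are distinct within a level), so deduplication is only required for
// walks that crossed a '-' edge.
//
// Returns the k-mer strings with their (start_level, end_level) walk spans,
// aborting if the number of simultaneously open walks exceeds max_frontier.

struct Walk {
  int start;
  uint8_t len;
  bool gapped;
  uint64_t seq;
};

// [[Rcpp::export]]
List cpp_enumerate_kmer_walks(IntegerVector ptr, IntegerVector lab,
                              int k, int max_frontier) {
  if (k < 2 || k > 31) stop("k must be between 2 and 31");
  const int n_levels = ptr.size() - 1;
  std::vector<Walk> frontier, next;
  std::vector<std::string> out_kmer;
  std::vector<int> out_start, out_end;
  std::unordered_set<uint64_t> seen;
  static const char BASES[4] = {'A', 'C', 'G', 'T'};
  std::string buf(k, 'A');

  for (int l = 1; l <= n_levels; ++l) {
    frontier.push_back(Walk{l, 0, false, 0});
    const int e0 = ptr[l - 1], e1 = ptr[l];
    bool has_gap = false;
    int bases[4]; int nb = 0;
    for (int e = e0; e < e1; ++e) {
      const int c = lab[e];
      if (c == 5) has_gap = true;
      else if (c != 4) bases[nb++] = c;   // 'N' branches are dropped
    }
    next.clear();
    seen.clear();
    for (size_t i = 0; i < frontier.size(); ++i) {
      const Walk &w = frontier[i];
      if (has_gap) {
        // '-' edge: walk advances a level without consuming a character
        Walk g = w; g.gapped = true;
        // dedupe gapped walks by (start, len, seq)
        uint64_t key = (uint64_t)g.start * 2097169ULL + g.len;
        key = key * 1000000007ULL ^ g.seq;
        if (seen.insert(key).second) next.push_back(g);
      }
      for (int b = 0; b < nb; ++b) {
        Walk x = w;
        x.seq = (x.seq << 2) | (uint64_t)bases[b];
        x.len += 1;
        if (x.gapped) {
          uint64_t key = (uint64_t)x.start * 2097169ULL + x.len;
          key = key * 1000000007ULL ^ x.seq;
          if (!seen.insert(key).second) continue;
        }
        if ((int)x.len == k) {
          for (int j = 0; j < k; ++j)
            buf[k - 1 - j] = BASES[(x.seq >> (2 * j)) & 3ULL];
          out_kmer.push_back(buf);
          out_start.push_back(x.start);
          out_end.push_back(l);
        } else {
          next.push_back(x);
        }
      }
    }
    if ((int)next.size() > max_frontier)
      stop("k-mer walk enumeration exceeds %d open walks in the window "
           "ending at level %d; the graph is too bushy for k = %d",
           max_frontier, l, k);
    frontier.swap(next);
  }
  return List::create(_["kmer"] = wrap(out_kmer),
                      _["start"] = wrap(out_start),
                      _["end"] = wrap(out_end));
}
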