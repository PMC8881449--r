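#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

// Canonical k-mer set Jaccard distances between DNA sequences.
// d(i,j) = 1 - |K_i n K_j| / |K_i u K_j|, K = set of canonical k-mers
// (lexicographic min of a k-mer and its reverse complement).

static inline int code2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static std::unordered_set<std::uint64_t> kmer_set(const std::string &s, int k) {
  std::unordered_set<std::uint64_t> out;
  std::uint64_t mask = ((std::uint64_t)1 << (std::uint64_t)(2 * k)) - 1ULL;
  std::uint64_t fwd = 0, rev = 0;
  int valid = 0;
  std::uint64_t shift = (std::uint64_t)(2 * (k - 1));
  for (size_t i = 0; i < s.size(); ++i) {
    int c = code2(s[i]);
    if (c < 0) { valid = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (std::uint64_t)c) & mask;
    rev = (rev >> 2) | ((std::uint64_t)(3 - c) << shift);
    if (++valid >= k) out.insert(fwd < rev ? fwd : rev);
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_kmer_jaccard_dist(CharacterVector seqs, int k) {
  if (2 * k > 62) stop("k too large for 64-bit packing");
  int n = seqs.size();
  std::vector<std::unordered_set<std::uint64_t> > sets(n);
  for (int i = 0; i < n; ++i)
    sets[i] = kmer_set(as<std::string>(seqs[i]), k);
  NumericMatrix d(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const std::unordered_set<std::uint64_t> &a =
        sets[i].size() <= sets[j].size() ? sets[i] : sets[j];
      const std::unordered_set<std::uint64_t> &b =
        sets[i].size() <= sets[j].size() ? sets[j] : sets[i];
      std::size_t inter = 0;
      for (std::unordered_set<std::uint64_t>::const_iterator it = a.begin();
           it != a.end(); ++it)
        if (b.count(*it)) ++inter;
      std::size_t uni = sets[i].size() + sets[j].size() - inter;
      double dij = (uni == 0) ? 0.0 : 1.0 - (double)inter / (double)uni;
      d(i, j) = dij; d(j, i) = dij;
    }
  }
  return d;
}
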