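#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// Desk-scale seed-and-extend aligner: exact k-mer seeding, ungapped
// extension along the seed diagonal with +1/-2 scoring, best local segment
// by Kadane's rule. Bit scores and E-values via Karlin-Altschul with fixed
// lambda/K. One hit (the best diagonal) per read x target x strand.

static inline int dna_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline int aa_code(char c) {
  if (c >= 'a' && c <= 'z') c = c - 'a' + 'A';
  if (c < 'A' || c > 'Z') return -1;  // '*' and other symbols break seeds
  return c - 'A';
}

static std::vector<int> encode(const std::string &s, bool dna) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i)
    v[i] = dna ? dna_code(s[i]) : aa_code(s[i]);
  return v;
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) {
    switch (c) {
    case 'A': case 'a': c = 'T'; break;
    case 'C': case 'c': c = 'G'; break;
    case 'G': case 'g': c = 'C'; break;
    case 'T': case 't': c = 'A'; break;
    default: c = 'N';
    }
  }
  return r;
}

struct Best {
  double score = -1e18;
  int matches = 0, seg_len = 0, read_start = 0, target_start = 0;
  int strand = 1;  // +1 forward, -1 reverse-complement read
};

// Extend along one diagonal; returns best local ungapped segment.
static void extend_diag(const std::vector<int> &r, const std::vector<int> &t,
                        int diag, double match, double mismatch, Best &out,
                        int strand) {
  int rlen = (int)r.size(), tlen = (int)t.size();
  int i0 = std::max(0, -diag);
  int i1 = std::min(rlen, tlen - diag);
  double run = 0, best = -1e18;
  int run_start = i0, run_matches = 0;
  int best_start = i0, best_end = i0, best_matches = 0;
  for (int i = i0; i < i1; ++i) {
    bool eq = (r[i] >= 0) && (r[i] == t[i + diag]);
    double s = eq ? match : mismatch;
    if (run <= 0) { run = s; run_start = i; run_matches = eq ? 1 : 0; }
    else { run += s; run_matches += eq ? 1 : 0; }
    if (run > best) {
      best = run; best_start = run_start; best_end = i + 1;
      best_matches = run_matches;
    }
  }
  if (best > out.score) {
    out.score = best;
    out.matches = best_matches;
    out.seg_len = best_end - best_start;
    out.read_start = best_start;
    out.target_start = best_start + diag;
    out.strand = strand;
  }
}

typedef std::unordered_map<std::uint64_t, std::vector<std::pair<int,int> > > SeedIndex;

static void index_targets(const std::vector<std::vector<int> > &tcodes,
                          int k, int bits, SeedIndex &index) {
  for (int t = 0; t < (int)tcodes.size(); ++t) {
    const std::vector<int> &v = tcodes[t];
    if ((int)v.size() < k) continue;
    std::uint64_t key = 0, mask = (bits * k >= 64) ? ~0ULL
      : ((1ULL << (std::uint64_t)(bits * k)) - 1ULL);
    int valid = 0;
    for (int i = 0; i < (int)v.size(); ++i) {
      if (v[i] < 0) { valid = 0; key = 0; continue; }
      key = ((key << bits) | (std::uint64_t)v[i]) & mask;
      if (++valid >= k) index[key].push_back(std::make_pair(t, i - k + 1));
    }
  }
}

// [[Rcpp::export]]
DataFrame cpp_align(CharacterVector reads, CharacterVector targets,
                    int k, bool dna, double match, double mismatch,
                    double lambda, double karlin_k, double db_len,
                    double min_bitscore, double max_evalue,
                    double min_identity, bool best_hit_only) {
  int bits = dna ? 2 : 5;
  if (k * bits > 62) stop("seed length too large for 64-bit packing");
  int nt = targets.size();
  std::vector<std::vector<int> > tcodes(nt);
  double total_tlen = 0;
  for (int i = 0; i < nt; ++i) {
    std::string s = as<std::string>(targets[i]);
    tcodes[i] = encode(s, dna);
    total_tlen += s.size();
  }
  if (db_len <= 0) db_len = total_tlen;
  SeedIndex index;
  index_targets(tcodes, k, bits, index);

  std::vector<int> out_read, out_target, out_strand;
  std::vector<double> out_score, out_bit, out_eval, out_ident;
  std::vector<int> out_len, out_rstart, out_tstart;
  const double ln2 = std::log(2.0);
  std::uint64_t mask = ((std::uint64_t)1 << (std::uint64_t)(bits * k)) - 1ULL;

  for (int rix = 0; rix < reads.size(); ++rix) {
    std::string fwd = as<std::string>(reads[rix]);
    std::unordered_map<int, Best> per_target;
    int n_orient = dna ? 2 : 1;
    for (int o = 0; o < n_orient; ++o) {
      std::string rs = (o == 0) ? fwd : revcomp(fwd);
      std::vector<int> rc = encode(rs, dna);
      int rlen = (int)rc.size();
      if (rlen < k) continue;
      std::unordered_map<long long, bool> diag_seen;
      std::uint64_t key = 0;
      int valid = 0;
      for (int i = 0; i < rlen; ++i) {
        if (rc[i] < 0) { valid = 0; key = 0; continue; }
        key = ((key << bits) | (std::uint64_t)rc[i]) & mask;
        if (++valid < k) continue;
        SeedIndex::const_iterator it = index.find(key);
        if (it == index.end()) continue;
        int rpos = i - k + 1;
        for (size_t h = 0; h < it->second.size(); ++h) {
          int tid = it->second[h].first, tpos = it->second[h].second;
          int diag = tpos - rpos;
          long long dk = ((long long)tid << 32) ^
            (long long)(diag + 1073741824LL) ^ ((long long)o << 62);
          if (diag_seen.count(dk)) continue;
          diag_seen[dk] = true;
          Best &b = per_target[tid];
          extend_diag(rc, tcodes[tid], diag, match, mismatch, b,
                      o == 0 ? 1 : -1);
        }
      }
    }
    // threshold + optional best-only
    int best_t = -1;
    double best_bit = -1e18;
    std::vector<std::pair<int, Best> > passed;
    for (std::unordered_map<int, Best>::iterator it = per_target.begin();
         it != per_target.end(); ++it) {
      Best &b = it->second;
      if (b.seg_len <= 0) continue;
      double bit = (lambda * b.score - std::log(karlin_k)) / ln2;
      double ev = karlin_k * (double)fwd.size() * db_len *
        std::exp(-lambda * b.score);
      double ident = b.seg_len > 0 ? (double)b.matches / b.seg_len : 0.0;
      if (!(bit > min_bitscore) || !(ev < max_evalue) ||
          !(ident >= min_identity)) continue;
      passed.push_back(*it);
      if (bit > best_bit) { best_bit = bit; best_t = it->first; }
      else if (bit == best_bit && best_t >= 0 && it->first < best_t)
        best_t = it->first;
    }
    std::sort(passed.begin(), passed.end(),
              [](const std::pair<int, Best> &a, const std::pair<int, Best> &b) {
                return a.first < b.first;
              });
    for (size_t p = 0; p < passed.size(); ++p) {
      int tid = passed[p].first;
      if (best_hit_only && tid != best_t) continue;
      Best &b = passed[p].second;
      double bit = (lambda * b.score - std::log(karlin_k)) / ln2;
      double ev = karlin_k * (double)fwd.size() * db_len *
        std::exp(-lambda * b.score);
      out_read.push_back(rix + 1);
      out_target.push_back(tid + 1);
      out_strand.push_back(b.strand);
      out_score.push_back(b.score);
      out_bit.push_back(bit);
      out_eval.push_back(ev);
      out_ident.push_back((double)b.matches / b.seg_len);
      out_len.push_back(b.seg_len);
      out_rstart.push_back(b.read_start + 1);
      out_tstart.push_back(b.target_start + 1);
    }
  }
  return DataFrame::create(
    _["read"] = out_read, _["target"] = out_target,
    _["strand"] = out_strand, _["raw_score"] = out_score,
    _["score"] = out_bit, _["evalue"] = out_eval,
    _["identity"] = out_ident, _["length"] = out_len,
    _["read_start"] = out_rstart, _["target_start"] = out_tstart);
}
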