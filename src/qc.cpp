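#include <Rcpp.h>
using namespace Rcpp;

// Per-read QC scan. Rule order is trim-first: the trailing run of bases
// below q_threshold (capped at max_trim) defines the trimmed read; ambiguous
// and low-quality base counts are then taken over the trimmed region only.

// [[Rcpp::export]]
DataFrame cpp_qc_stats(CharacterVector seqs, CharacterVector quals,
                       int q_threshold, int max_trim, int phred_offset) {
  int n = seqs.size();
  IntegerVector trim_len(n), n_ambig(n), n_lowq(n), kept_len(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    int len = (int)s.size();
    int run = 0;
    for (int j = len - 1; j >= 0; --j) {
      if ((int)q[j] - phred_offset < q_threshold) ++run; else break;
    }
    int tr = std::min(run, max_trim);
    int keep = len - tr;
    int na = 0, nl = 0;
    for (int j = 0; j < keep; ++j) {
      char c = s[j];
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T' &&
          c != 'a' && c != 'c' && c != 'g' && c != 't') ++na;
      if ((int)q[j] - phred_offset < q_threshold) ++nl;
    }
    trim_len[i] = tr; n_ambig[i] = na; n_lowq[i] = nl; kept_len[i] = keep;
  }
  return DataFrame::create(_["trim_len"] = trim_len, _["n_ambig"] = n_ambig,
                           _["n_lowq"] = n_lowq, _["kept_len"] = kept_len);
}

// Adapter read-through detection: after hard-clipping the first `clip_first`
// bases, a read is flagged when a suffix of length >= min_overlap matches a
// prefix of the adapter with at most floor(max_mismatch_frac * overlap)
// mismatches. Longest overlaps are tried first.

// [[Rcpp::export]]
LogicalVector cpp_adapter_match(CharacterVector seqs, std::string adapter,
                                int min_overlap, double max_mismatch_frac,
                                int clip_first) {
  int n = seqs.size();
  int alen = (int)adapter.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() > clip_first) s = s.substr(clip_first);
    int slen = (int)s.size();
    bool hit = false;
    int omax = std::min(slen, alen);
    for (int o = omax; o >= min_overlap && !hit; --o) {
      int allowed = (int)std::floor(max_mismatch_frac * o);
      int mm = 0;
      for (int j = 0; j < o; ++j) {
        if (s[slen - o + j] != adapter[j] && ++mm > allowed) break;
      }
      if (mm <= allowed) hit = true;
    }
    out[i] = hit;
  }
  return out;
}

// Apply point substitutions: read_idx (1-based into seqs), pos (1-based
// within read), base (single characters). Used by the read simulator.

// [[Rcpp::export]]
CharacterVector cpp_apply_subs(CharacterVector seqs, IntegerVector read_idx,
                               IntegerVector pos, CharacterVector base) {
  std::vector<std::string> s(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 0; i < read_idx.size(); ++i) {
    int r = read_idx[i] - 1, p = pos[i] - 1;
    if (r < 0 || r >= (int)s.size()) stop("read index out of range");
    if (p < 0 || p >= (int)s[r].size()) stop("position out of range");
    s[r][p] = as<std::string>(base[i])[0];
  }
  return wrap(s);
}
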