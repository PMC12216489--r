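#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Per-base substitution errors at rate `rate`, iid Bernoulli per base,
// implemented with geometric skipping so cost scales with the number
// of errors, not bases.  Uses R's RNG (deterministic under set.seed).
// [[Rcpp::export]]
CharacterVector cpp_add_read_errors(CharacterVector seqs, double rate) {
  if (rate <= 0.0) return seqs;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  const double log1m = std::log(1.0 - rate);
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    long len = (long)s.size();
    long pos = (long)std::floor(std::log(R::unif_rand()) / log1m);
    while (pos < len) {
      char sub;
      do {
        sub = bases[(int)(R::unif_rand() * 4.0) & 3];
      } while (sub == s[pos]);
      s[pos] = sub;
      pos += 1 + (long)std::floor(std::log(R::unif_rand()) / log1m);
    }
    out[i] = s;
  }
  return out;
}

// Strict-majority per-codon consensus over groups of reads.  `seqs`
// must be ordered by group; `group_sizes` gives the size of each
// group.  Within a group, reads whose length differs from the first
// read (indel-containing) are ignored.  Codons without a strict
// majority (> half of the group's used reads) are masked as "NNN".
// [[Rcpp::export]]
CharacterVector cpp_consensus_groups(CharacterVector seqs,
                                     IntegerVector group_sizes) {
  int ng = group_sizes.size();
  CharacterVector out(ng);
  long offset = 0;
  for (int g = 0; g < ng; ++g) {
    int m = group_sizes[g];
    std::string first = as<std::string>(seqs[offset]);
    int len = (int)first.size();
    bool allsame = true;
    std::vector<std::string> hold;
    hold.reserve(m);
    for (int j = 0; j < m; ++j) {
      std::string sj = as<std::string>(seqs[offset + j]);
      if (sj != first) allsame = false;
      if ((int)sj.size() == len) hold.push_back(sj);
    }
    offset += m;
    if (allsame) { out[g] = first; continue; }
    int nr = (int)hold.size();
    int ncod = len / 3;
    std::string cons(len, 'N');
    for (int c = 0; c < ncod; ++c) {
      int best = -1, bestcount = 0;
      for (int a = 0; a < nr; ++a) {
        bool dup = false;
        for (int b = 0; b < a; ++b)
          if (hold[b].compare(c * 3, 3, hold[a], c * 3, 3) == 0) {
            dup = true; break;
          }
        if (dup) continue;
        int count = 1;
        for (int b = a + 1; b < nr; ++b)
          if (hold[b].compare(c * 3, 3, hold[a], c * 3, 3) == 0) count++;
        if (count > bestcount) { bestcount = count; best = a; }
      }
      if (best >= 0 && 2 * bestcount > nr)
        cons.replace(c * 3, 3, hold[best], c * 3, 3);
    }
    out[g] = cons;
  }
  return out;
}

// Codon-level comparison of consensus sequences against a reference
// segment.  Returns mutant calls (1-based seq index, codon index
// within the segment, codon) and masked calls (codons containing N,
// or all codons of a length-mismatched sequence).
// [[Rcpp::export]]
List cpp_codon_mismatches(CharacterVector seqs, std::string ref) {
  std::vector<int> mi, mc, ki, kc;
  std::vector<std::string> mcod;
  int ncod = (int)ref.size() / 3;
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if (s.size() != ref.size()) {
      for (int c = 0; c < ncod; ++c) { ki.push_back(i + 1); kc.push_back(c + 1); }
      continue;
    }
    if (s == ref) continue;
    for (int c = 0; c < ncod; ++c) {
      if (s.compare(3 * c, 3, ref, 3 * c, 3) == 0) continue;
      std::string cod = s.substr(3 * c, 3);
      if (cod.find_first_not_of("ACGT") != std::string::npos) {
        ki.push_back(i + 1); kc.push_back(c + 1);
      } else {
        mi.push_back(i + 1); mc.push_back(c + 1); mcod.push_back(cod);
      }
    }
  }
  return List::create(_["seq"] = wrap(mi),
                      _["codon_idx"] = wrap(mc),
                      _["codon"] = wrap(mcod),
                      _["masked_seq"] = wrap(ki),
                      _["masked_codon_idx"] = wrap(kc));
}
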