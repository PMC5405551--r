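#include <Rcpp.h>
#include <map>
#include <string>
#include <vector>
using namespace Rcpp;

// Pileup engine: strand-resolved, quality-filtered per-position tallies.
//
// Semantics follow samtools mpileup: records below the mapping-quality cutoff
// contribute nothing; aligned bases below the base-quality cutoff are excluded
// from allele counts and qualified depth; deletion spans contribute to depth
// at every deleted position; insertions are anchored at the preceding aligned
// reference position and do not add depth; soft clips are skipped.

static inline int base_index(char b) {
  switch (b) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

struct IndelKey {
  int anchor;
  int type;  // 0 = insertion, 1 = deletion
  std::string seq;
  bool operator<(const IndelKey& o) const {
    if (anchor != o.anchor) return anchor < o.anchor;
    if (type != o.type) return type < o.type;
    return seq < o.seq;
  }
};

// [[Rcpp::export]]
List build_pileup_cpp(IntegerVector pos, IntegerVector mapq,
                      CharacterVector strand, CharacterVector cigar,
                      CharacterVector seq, CharacterVector qual,
                      std::string ref, int min_base_q, int min_map_q) {
  int L = (int)ref.size();
  int n = pos.size();
  IntegerMatrix counts(L, 8);  // A+,C+,G+,T+,A-,C-,G-,T-
  IntegerVector covmp(L), qdepth(L), delspan(L), ends_plus(L), ends_minus(L);
  std::map<IndelKey, std::pair<int, int> > indels;  // -> (plus, minus)

  for (int i = 0; i < n; ++i) {
    if (mapq[i] < min_map_q) continue;
    bool minus = (strand[i] == "-");
    const char* cg = CHAR(STRING_ELT(cigar, i));
    const char* sq = CHAR(STRING_ELT(seq, i));
    const char* ql = CHAR(STRING_ELT(qual, i));
    int r = pos[i];  // 1-based reference cursor
    int j = 0;       // 0-based read cursor
    int num = 0;
    int last_ref = 0;  // last reference position consumed by M/D
    for (const char* c = cg; *c; ++c) {
      if (*c >= '0' && *c <= '9') { num = num * 10 + (*c - '0'); continue; }
      char op = *c;
      int len = num;
      num = 0;
      if (len <= 0) stop("malformed CIGAR '%s' in record %d", cg, i + 1);
      if (op == 'M' || op == '=' || op == 'X') {
        if (r + len - 1 > L)
          stop("alignment at position %d extends past reference end (L=%d); align circular-origin reads against the other orientation", pos[i], L);
        for (int k = 0; k < len; ++k, ++r, ++j) {
          covmp[r - 1]++;
          last_ref = r;
          int q = (int)ql[j] - 33;
          if (q < min_base_q) continue;
          int b = base_index(sq[j]);
          if (b < 0) continue;  // N or ambiguous base: no allele count
          counts(r - 1, b + (minus ? 4 : 0))++;
          qdepth[r - 1]++;
        }
      } else if (op == 'I') {
        if (r > 1) {  // anchored at preceding aligned base; leading I is skipped
          IndelKey key;
          key.anchor = r - 1;
          key.type = 0;
          key.seq = std::string(sq + j, sq + j + len);
          std::pair<int, int>& v = indels[key];
          if (minus) v.second++; else v.first++;
        }
        j += len;
      } else if (op == 'D') {
        if (r + len - 1 > L)
          stop("deletion at position %d extends past reference end (L=%d)", r, L);
        if (r > 1) {
          IndelKey key;
          key.anchor = r - 1;
          key.type = 1;
          key.seq = ref.substr(r - 1, len);
          std::pair<int, int>& v = indels[key];
          if (minus) v.second++; else v.first++;
        }
        for (int k = 0; k < len; ++k, ++r) {
          covmp[r - 1]++;
          qdepth[r - 1]++;
          delspan[r - 1]++;
          last_ref = r;
        }
      } else if (op == 'S') {
        j += len;
      } else {
        stop("unsupported CIGAR op '%c' in record %d", op, i + 1);
      }
    }
    if (last_ref > 0) {
      if (minus) ends_minus[last_ref - 1]++; else ends_plus[last_ref - 1]++;
    }
  }

  int m = (int)indels.size();
  IntegerVector i_anchor(m), i_plus(m), i_minus(m);
  CharacterVector i_type(m), i_seq(m);
  int k = 0;
  for (std::map<IndelKey, std::pair<int, int> >::iterator it = indels.begin();
       it != indels.end(); ++it, ++k) {
    i_anchor[k] = it->first.anchor;
    i_type[k] = it->first.type == 0 ? "INS" : "DEL";
    i_seq[k] = it->first.seq;
    i_plus[k] = it->second.first;
    i_minus[k] = it->second.second;
  }

  return List::create(
    _["counts"] = counts, _["covmp"] = covmp, _["qdepth"] = qdepth,
    _["delspan"] = delspan, _["ends_plus"] = ends_plus,
    _["ends_minus"] = ends_minus,
    _["indel_anchor"] = i_anchor, _["indel_type"] = i_type,
    _["indel_seq"] = i_seq, _["indel_plus"] = i_plus,
    _["indel_minus"] = i_minus);
}
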