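#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Read simulation core for a two-haplotype circular mixture.
//
// Fragments are drawn uniformly on the haplotype circle; mate 1 covers the
// first read_len bases on the + strand, mate 2 the last read_len bases on the
// - strand (stored reference-oriented, as in SAM). Each read is projected onto
// the linear reference in BOTH orientations (original and origin-shifted); a
// read is emitted for an orientation only where its mapping is contiguous
// (does not wrap that orientation's origin).

static const char BASES[4] = {'A', 'C', 'G', 'T'};

static char random_other_base(char b) {
  // draw until different; at most a few iterations
  for (;;) {
    char c = BASES[(int)(unif_rand() * 4.0) % 4];
    if (c != b) return c;
  }
}

struct Encoded {
  bool ok;
  int pos;
  std::string cigar;
};

// refpos: reference position (1-based) of each read base in the target
// orientation, 0 for inserted bases. Contiguous iff mapped positions strictly
// increase with gaps only from deletions. Leading/trailing insertions are
// soft-clipped.
static Encoded encode_cigar(const std::vector<int>& refpos,
                            const std::vector<char>& /*bases*/) {
  Encoded out;
  out.ok = false;
  int n = (int)refpos.size();
  int first = -1, last = -1;
  for (int i = 0; i < n; ++i) {
    if (refpos[i] > 0) { if (first < 0) first = i; last = i; }
  }
  if (first < 0) return out;  // no aligned base
  // check monotone contiguity
  int prev = -1;
  for (int i = first; i <= last; ++i) {
    if (refpos[i] == 0) continue;
    if (prev >= 0 && refpos[i] <= prev) return out;  // wraps the origin
    prev = refpos[i];
  }
  // build ops
  std::vector<std::pair<char, int> > ops;
  if (first > 0) ops.push_back(std::make_pair('S', first));
  prev = -1;
  for (int i = first; i <= last; ++i) {
    if (refpos[i] == 0) {
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back(std::make_pair('I', 1));
    } else {
      if (prev > 0 && refpos[i] - prev > 1) {
        ops.push_back(std::make_pair('D', refpos[i] - prev - 1));
      }
      if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
      else ops.push_back(std::make_pair('M', 1));
      prev = refpos[i];
    }
  }
  if (last < n - 1) ops.push_back(std::make_pair('S', n - 1 - last));
  std::string cig;
  char buf[16];
  for (size_t k = 0; k < ops.size(); ++k) {
    snprintf(buf, sizeof(buf), "%d%c", ops[k].second, ops[k].first);
    cig += buf;
  }
  out.ok = true;
  out.pos = refpos[first];
  out.cigar = cig;
  return out;
}

// [[Rcpp::export]]
List sim_read_pairs_cpp(std::string hap_a, std::string hap_b,
                        IntegerVector map_b, int L, int n_pairs,
                        int read_len, int frag_len, double ratio_pct,
                        double sub_rate, double indel_rate, int shift) {
  if ((int)hap_a.size() != L) stop("haplotype A length must equal L");
  if (frag_len < 2 * read_len) stop("fragment length must be >= 2 * read length");
  if (frag_len > L / 2) stop("fragment length must be <= L/2 for the dual-orientation design");

  int n_reads = 2 * n_pairs;
  CharacterVector qname(n_reads), seq(n_reads), strand(n_reads);
  CharacterVector cigar_orig(n_reads), cigar_shift(n_reads);
  IntegerVector mate(n_reads), pos_orig(n_reads), pos_shift(n_reads);
  LogicalVector ok_orig(n_reads), ok_shift(n_reads), from_b(n_reads);

  double p_b = ratio_pct / 100.0;
  int Lb = (int)hap_b.size();

  std::vector<int> refpos;
  std::vector<char> bases;
  refpos.reserve(read_len + 8);
  bases.reserve(read_len + 8);

  for (int pair = 0; pair < n_pairs; ++pair) {
    bool is_b = unif_rand() < p_b;
    const std::string& hap = is_b ? hap_b : hap_a;
    int Lh = is_b ? Lb : L;
    int f = (int)(unif_rand() * Lh);  // 0-based fragment start on the haplotype circle
    if (f >= Lh) f = Lh - 1;

    for (int m = 0; m < 2; ++m) {
      int idx = 2 * pair + m;
      int start = (m == 0) ? f : f + frag_len - read_len;
      refpos.clear();
      bases.clear();
      int consumed = 0;  // haplotype bases consumed (for deletion extension)
      for (int j = 0; j < read_len; ++j) {
        int hp = (start + consumed) % Lh;  // 0-based
        ++consumed;
        bases.push_back(hap[hp]);
        refpos.push_back(is_b ? map_b[hp] : hp + 1);
      }
      // error injection: per-read event counts (binomial), then positions
      int n_indel = (indel_rate > 0.0)
        ? (int)R::rbinom((double)read_len, indel_rate) : 0;
      for (int ev = 0; ev < n_indel; ++ev) {
        int j = (int)(unif_rand() * read_len);
        if (j >= read_len) j = read_len - 1;
        if (unif_rand() < 0.5) {
          // 1-base insertion error before read base j; read length stays fixed
          bases.insert(bases.begin() + j, BASES[(int)(unif_rand() * 4.0) % 4]);
          refpos.insert(refpos.begin() + j, 0);
          bases.pop_back();
          refpos.pop_back();
        } else {
          // 1-base deletion error: drop read base j, extend at the read end
          bases.erase(bases.begin() + j);
          refpos.erase(refpos.begin() + j);
          int hp = (start + consumed) % Lh;
          ++consumed;
          bases.push_back(hap[hp]);
          refpos.push_back(is_b ? map_b[hp] : hp + 1);
        }
      }
      int n_sub = (sub_rate > 0.0)
        ? (int)R::rbinom((double)read_len, sub_rate) : 0;
      for (int ev = 0; ev < n_sub; ++ev) {
        int j = (int)(unif_rand() * read_len);
        if (j >= read_len) j = read_len - 1;
        bases[j] = random_other_base(bases[j]);
      }

      Encoded eo = encode_cigar(refpos, bases);
      // shifted orientation: recoordinate mapped positions
      std::vector<int> rs(refpos.size());
      for (size_t j = 0; j < refpos.size(); ++j) {
        rs[j] = refpos[j] == 0 ? 0 : ((refpos[j] - 1 - shift) % L + L) % L + 1;
      }
      Encoded es = encode_cigar(rs, bases);

      char nm[32];
      snprintf(nm, sizeof(nm), "sim%d", pair + 1);
      qname[idx] = nm;
      mate[idx] = m + 1;
      strand[idx] = (m == 0) ? "+" : "-";
      from_b[idx] = is_b;
      seq[idx] = std::string(bases.begin(), bases.end());
      ok_orig[idx] = eo.ok;
      pos_orig[idx] = eo.ok ? eo.pos : NA_INTEGER;
      if (eo.ok) cigar_orig[idx] = eo.cigar; else cigar_orig[idx] = NA_STRING;
      ok_shift[idx] = es.ok;
      pos_shift[idx] = es.ok ? es.pos : NA_INTEGER;
      if (es.ok) cigar_shift[idx] = es.cigar; else cigar_shift[idx] = NA_STRING;
    }
  }

  return List::create(
    _["qname"] = qname, _["mate"] = mate, _["strand"] = strand,
    _["from_b"] = from_b, _["seq"] = seq,
    _["ok_orig"] = ok_orig, _["pos_orig"] = pos_orig, _["cigar_orig"] = cigar_orig,
    _["ok_shift"] = ok_shift, _["pos_shift"] = pos_shift, _["cigar_shift"] = cigar_shift);
}
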