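#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 for anything outside ACGT (upper case expected).
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

struct KmerEntry {
  uint32_t count;   // saturates at 2; only count==1 k-mers anchor
  int32_t  chrom;
  int32_t  pos;
  uint8_t  orient;  // 0: stored occurrence reads as the canonical k-mer; 1: as its reverse complement
};

typedef std::unordered_map<uint64_t, KmerEntry> KmerMap;

// Scan one genome (list of chromosome strings) into a canonical k-mer map.
// A k-mer is "unique" when its canonical form occurs exactly once over all
// forward-strand positions, which counts the k-mer and its reverse
// complement together. k is odd, so no k-mer equals its own reverse
// complement and the orientation bit is well defined.
static void scan_genome(const CharacterVector& seqs, int k, KmerMap& map) {
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift = 2 * (k - 1);
  for (int c = 0; c < seqs.size(); ++c) {
    const char* s = CHAR(STRING_ELT(seqs, c));
    const int L = LENGTH(STRING_ELT(seqs, c));
    uint64_t f = 0, r = 0;
    int run = 0;
    for (int i = 0; i < L; ++i) {
      const int b = base_code(s[i]);
      if (b < 0) { run = 0; f = 0; r = 0; continue; }
      f = ((f << 2) | (uint64_t)b) & mask;
      r = (r >> 2) | ((uint64_t)(3 - b) << shift);
      if (++run >= k) {
        const bool fwd = (f <= r);
        const uint64_t key = fwd ? f : r;
        KmerEntry& e = map[key];
        if (e.count == 0) {
          e.chrom = c;
          e.pos = i - k + 1;
          e.orient = fwd ? 0 : 1;
        }
        if (e.count < 2) ++e.count;
      }
    }
  }
}

// [[Rcpp::export]]
DataFrame find_anchors_cpp(CharacterVector ref_seqs, CharacterVector qry_seqs, int k) {
  KmerMap ref_map, qry_map;
  {
    R_xlen_t tot = 0;
    for (R_xlen_t i = 0; i < ref_seqs.size(); ++i) tot += LENGTH(STRING_ELT(ref_seqs, i));
    ref_map.reserve((size_t)tot + 16);
    tot = 0;
    for (R_xlen_t i = 0; i < qry_seqs.size(); ++i) tot += LENGTH(STRING_ELT(qry_seqs, i));
    qry_map.reserve((size_t)tot + 16);
  }
  scan_genome(ref_seqs, k, ref_map);
  scan_genome(qry_seqs, k, qry_map);

  std::vector<int> rc, rp, qc, qp, st;
  for (KmerMap::const_iterator it = ref_map.begin(); it != ref_map.end(); ++it) {
    if (it->second.count != 1) continue;
    KmerMap::const_iterator jt = qry_map.find(it->first);
    if (jt == qry_map.end() || jt->second.count != 1) continue;
    rc.push_back(it->second.chrom + 1);
    rp.push_back(it->second.pos);
    qc.push_back(jt->second.chrom + 1);
    qp.push_back(jt->second.pos);
    st.push_back(it->second.orient == jt->second.orient ? 1 : -1);
  }
  return DataFrame::create(
    Named("ref_chrom_i") = wrap(rc),
    Named("ref_start") = wrap(rp),
    Named("qry_chrom_i") = wrap(qc),
    Named("qry_start") = wrap(qp),
    Named("strand_i") = wrap(st));
}

// Gap-bounded weighted chaining over collapsed anchors of one
// (ref chromosome, qry chromosome, strand) group. Inputs must be sorted by
// xs; y coordinates are strand-adjusted so that both axes increase along a
// chain. Successive anchors may overlap by up to `slack` bp on either axis
// (breakpoint ambiguity at indel junctions produces small overlaps); the
// block builder trims them. Returns best predecessor and score per anchor.
// [[Rcpp::export]]
List chain_dp_cpp(IntegerVector xs, IntegerVector xe,
                  IntegerVector ys, IntegerVector ye,
                  NumericVector w, double max_join, double penalty,
                  double slack) {
  const int n = xs.size();
  NumericVector dp(n);
  IntegerVector parent(n);
  int maxlen = 0;
  for (int i = 0; i < n; ++i) maxlen = std::max(maxlen, xe[i] - xs[i]);
  for (int i = 0; i < n; ++i) {
    double best = w[i];
    int par = 0; // 0 = no predecessor (1-based parents for R)
    const double lo = xs[i] - max_join - maxlen;
    for (int j = i - 1; j >= 0; --j) {
      if (xs[j] < lo) break;
      if (xe[j] - xs[i] > slack || ye[j] - ys[i] > slack) continue;
      if (xs[j] >= xs[i] || ys[j] >= ys[i]) continue;
      const double dx = std::max(0, xs[i] - xe[j]);
      const double dy = std::max(0, ys[i] - ye[j]);
      if (dx > max_join || dy > max_join) continue;
      const double cand = dp[j] + w[i] - penalty * (dx + dy);
      if (cand > best) { best = cand; par = j + 1; }
    }
    dp[i] = best;
    parent[i] = par;
  }
  return List::create(Named("score") = dp, Named("parent") = parent);
}

// Ungapped exact-match extension of block ends over one chromosome pair.
// Coordinates are 0-based half-open; strand -1 blocks map ascending ref to
// descending query (complemented).
// [[Rcpp::export]]
DataFrame extend_blocks_cpp(CharacterVector ref_seq, CharacterVector qry_seq,
                            IntegerVector rs, IntegerVector re,
                            IntegerVector qs, IntegerVector qe,
                            IntegerVector strand) {
  const char* R = CHAR(STRING_ELT(ref_seq, 0));
  const char* Q = CHAR(STRING_ELT(qry_seq, 0));
  const int Lr = LENGTH(STRING_ELT(ref_seq, 0));
  const int Lq = LENGTH(STRING_ELT(qry_seq, 0));
  const int n = rs.size();
  IntegerVector ors(n), ore(n), oqs(n), oqe(n), added(n);
  for (int i = 0; i < n; ++i) {
    int a = rs[i], b = re[i], c = qs[i], d = qe[i], m = 0;
    if (strand[i] > 0) {
      while (a > 0 && c > 0) {
        const int x = base_code(R[a - 1]);
        if (x < 0 || x != base_code(Q[c - 1])) break;
        --a; --c; ++m;
      }
      while (b < Lr && d < Lq) {
        const int x = base_code(R[b]);
        if (x < 0 || x != base_code(Q[d])) break;
        ++b; ++d; ++m;
      }
    } else {
      // ref left end pairs with qry right end
      while (a > 0 && d < Lq) {
        const int x = base_code(R[a - 1]);
        const int y = base_code(Q[d]);
        if (x < 0 || y < 0 || x != 3 - y) break;
        --a; ++d; ++m;
      }
      while (b < Lr && c > 0) {
        const int x = base_code(R[b]);
        const int y = base_code(Q[c - 1]);
        if (x < 0 || y < 0 || x != 3 - y) break;
        ++b; --c; ++m;
      }
    }
    ors[i] = a; ore[i] = b; oqs[i] = c; oqe[i] = d; added[i] = m;
  }
  return DataFrame::create(Named("ref_start") = ors, Named("ref_end") = ore,
                           Named("qry_start") = oqs, Named("qry_end") = oqe,
                           Named("added") = added);
}

// Positions (0-based, relative) where two equal-length strings differ.
// [[Rcpp::export]]
IntegerVector mismatch_positions_cpp(CharacterVector a, CharacterVector b) {
  const char* x = CHAR(STRING_ELT(a, 0));
  const char* y = CHAR(STRING_ELT(b, 0));
  const int L = LENGTH(STRING_ELT(a, 0));
  if (L != LENGTH(STRING_ELT(b, 0))) stop("strings must have equal length");
  std::vector<int> out;
  for (int i = 0; i < L; ++i) if (x[i] != y[i]) out.push_back(i);
  return wrap(out);
}
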