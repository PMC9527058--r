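#include "kenum.h"
#include <functional>
using namespace Rcpp;

// Enumerate every hamming-d neighbor of query index q for d = 1..maxD.
// Positions are chosen as increasing subsets; replacement 2-bit codes always
// differ from the query's code at that position, so each neighbor appears
// exactly once, at its exact distance. pos 0 = first (most significant) base.
static void visit_neighbors(uint64_t q, int k, int maxD,
                            std::vector<int> &changed,
                            int fromPos, int d, uint64_t cur,
                            const std::function<void(uint64_t, int,
                                                     const std::vector<int>&)> &f) {
  if (d >= maxD) return;
  for (int pos = fromPos; pos < k; ++pos) {
    int shift = 2 * (k - 1 - pos);
    uint64_t orig = (q >> shift) & 3ULL;
    uint64_t cleared = cur & ~(3ULL << shift);
    changed.push_back(pos);
    for (uint64_t code = 0; code < 4; ++code) {
      if (code == orig) continue;
      uint64_t mut = cleared | (code << shift);
      f(mut, d + 1, changed);
      visit_neighbors(q, k, maxD, changed, pos + 1, d + 1, mut, f);
    }
    changed.pop_back();
  }
}

// [[Rcpp::export]]
DataFrame cpp_gen_mask_pairs(std::string query, int maxD) {
  int k = (int)query.size();
  if (k < 1 || k > 26) stop("query length must be in 1..26");
  if (maxD < 0 || maxD > k) stop("maxD must be in 0..k");
  uint64_t q;
  if (!seq2_index(query, q)) stop("non-ACGT base in query");
  uint64_t full = (1ULL << (2 * k)) - 1ULL;
  std::vector<double> andm, orm;
  std::vector<int> dd;
  andm.push_back((double)full); orm.push_back(0.0); dd.push_back(0); // identity
  std::vector<int> changed;
  visit_neighbors(q, k, maxD, changed, 0, 0, q,
                  [&](uint64_t mut, int d, const std::vector<int> &chg) {
    if (d != (int)chg.size()) return; // record only leaf-complete subsets
    uint64_t am = full, om = 0;
    for (int pos : chg) {
      int shift = 2 * (k - 1 - pos);
      am &= ~(3ULL << shift);
      om |= mut & (3ULL << shift);
    }
    andm.push_back((double)am);
    orm.push_back((double)om);
    dd.push_back(d);
  });
  return DataFrame::create(_["and_mask"] = wrap(andm), _["or_mask"] = wrap(orm),
                           _["d"] = wrap(dd));
}

// [[Rcpp::export]]
IntegerVector cpp_count_seq_neighbors(RawVector bits, int k, std::string prefix,
                                      std::string query, int maxD) {
  if ((int)query.size() != k)
    stop("query length %d does not match space k=%d", (int)query.size(), k);
  if (maxD < 0 || maxD > k) stop("maxD must be in 0..k");
  uint64_t q;
  if (!seq2_index(query, q)) stop("non-ACGT base in query");
  int p = (int)prefix.size();
  int sw = 2 * (k - p);
  uint64_t pcode = 0;
  if (p > 0) seq2_index(prefix, pcode);
  uint64_t smask = (sw >= 64) ? ~0ULL : ((1ULL << sw) - 1ULL);
  IntegerVector counts(maxD + 1);
  auto probe = [&](uint64_t idx, int d) {
    if (p > 0 && (idx >> sw) != pcode) return;
    if (get_bit(bits, idx & smask)) counts[d] += 1;
  };
  probe(q, 0);
  std::vector<int> changed;
  visit_neighbors(q, k, maxD, changed, 0, 0, q,
                  [&](uint64_t mut, int d, const std::vector<int> &) {
    probe(mut, d);
  });
  return counts;
}

static double db_lookup(const RawVector &cells, int b, uint64_t idx,
                        const std::map<uint64_t, double> &overflow) {
  uint64_t sentinel = (1ULL << b) - 1ULL;
  uint64_t v = get_cell(cells, idx, b);
  if (v < sentinel) return (double)v;
  auto it = overflow.find(idx);
  if (it == overflow.end())
    stop("corrupt count database: saturated cell missing from overflow map");
  return it->second;
}

static std::map<uint64_t, double> build_overflow(const CharacterVector &ovK,
                                                 const NumericVector &ovC) {
  std::map<uint64_t, double> m;
  for (R_xlen_t i = 0; i < ovK.size(); ++i)
    m[parse_u64(as<std::string>(ovK[i]))] = ovC[i];
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_count_lookup(RawVector cells, int b, int k, std::string prefix,
                               CharacterVector overflowKeys,
                               NumericVector overflowCounts,
                               CharacterVector seqs) {
  std::map<uint64_t, double> overflow = build_overflow(overflowKeys, overflowCounts);
  int p = (int)prefix.size();
  int sw = 2 * (k - p);
  uint64_t pcode = 0;
  if (p > 0) seq2_index(prefix, pcode);
  uint64_t smask = (sw >= 64) ? ~0ULL : ((1ULL << sw) - 1ULL);
  R_xlen_t n = seqs.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() != k) stop("sequence length %d does not match k=%d",
        (int)s.size(), k);
    uint64_t idx;
    if (!seq2_index(s, idx)) stop("non-ACGT base in sequence");
    if (p > 0 && (idx >> sw) != pcode) { out[i] = NA_REAL; continue; }
    out[i] = db_lookup(cells, b, idx & smask, overflow);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_count_off_sites(RawVector cells, int b, int k, std::string prefix,
                         CharacterVector overflowKeys, NumericVector overflowCounts,
                         std::string query, int maxD, bool mark) {
  if ((int)query.size() != k)
    stop("query length %d does not match database k=%d", (int)query.size(), k);
  if (maxD < 0 || maxD > k) stop("maxD must be in 0..k");
  std::map<uint64_t, double> overflow = build_overflow(overflowKeys, overflowCounts);
  uint64_t q;
  if (!seq2_index(query, q)) stop("non-ACGT base in query");
  int p = (int)prefix.size();
  int sw = 2 * (k - p);
  uint64_t pcode = 0;
  if (p > 0) seq2_index(prefix, pcode);
  uint64_t smask = (sw >= 64) ? ~0ULL : ((1ULL << sw) - 1ULL);
  NumericVector profile(maxD + 1);
  std::vector<std::string> nseq;
  std::vector<int> ndist;
  std::vector<double> ncount;
  auto tally = [&](uint64_t idx, int d, const std::vector<int> *chg) {
    if (p > 0 && (idx >> sw) != pcode) return;
    double cnt = db_lookup(cells, b, idx & smask, overflow);
    profile[d] += cnt;
    if (mark && d > 0 && cnt > 0) {
      std::string s = index2_seq(idx, k);
      for (int pos : *chg) s[(size_t)pos] = (char)(s[(size_t)pos] + 32);
      nseq.push_back(s);
      ndist.push_back(d);
      ncount.push_back(cnt);
    }
  };
  tally(q, 0, nullptr);
  std::vector<int> changed;
  visit_neighbors(q, k, maxD, changed, 0, 0, q,
                  [&](uint64_t mut, int d, const std::vector<int> &chg) {
    tally(mut, d, &chg);
  });
  List out = List::create(
    _["profile"] = profile,
    _["neighbors"] = DataFrame::create(_["sequence"] = wrap(nseq),
                                       _["mismatches"] = wrap(ndist),
                                       _["count"] = wrap(ncount),
                                       _["stringsAsFactors"] = false));
  return out;
}

// Apply AND/OR mask pairs to a query: query_mut = (query & and) | or.
// [[Rcpp::export]]
CharacterVector cpp_apply_mask_pairs(std::string query, NumericVector andm,
                                     NumericVector orm) {
  int k = (int)query.size();
  uint64_t q;
  if (!seq2_index(query, q)) stop("non-ACGT base in query");
  R_xlen_t n = andm.size();
  if (orm.size() != n) stop("and/or mask vectors must have equal length");
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t mut = (q & (uint64_t)andm[i]) | (uint64_t)orm[i];
    out[i] = index2_seq(mut, k);
  }
  return out;
}

// Brute-force hamming scan of both strands of one sequence; used by the
// synthetic-genome simulator to enforce plant exclusivity.
// [[Rcpp::export]]
DataFrame cpp_hamming_scan(std::string seq, std::string query, int maxD) {
  int k = (int)query.size();
  long L = (long)seq.size();
  std::vector<int> poss, dists;
  std::vector<std::string> strands;
  for (long i = 0; i + k <= L; ++i) {
    int df = 0, dr = 0;
    for (int j = 0; j < k && (df <= maxD || dr <= maxD); ++j) {
      if (upcase(seq[(size_t)(i + j)]) != query[(size_t)j]) ++df;
      if (upcase(comp_base(seq[(size_t)(i + k - 1 - j)])) != query[(size_t)j]) ++dr;
    }
    if (df <= maxD) {
      poss.push_back((int)(i + 1)); strands.push_back("+"); dists.push_back(df);
    }
    if (dr <= maxD) {
      poss.push_back((int)(i + 1)); strands.push_back("-"); dists.push_back(dr);
    }
  }
  return DataFrame::create(_["pos"] = wrap(poss), _["strand"] = wrap(strands),
                           _["dist"] = wrap(dists),
                           _["stringsAsFactors"] = false);
}
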