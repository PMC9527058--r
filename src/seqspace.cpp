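#include "kenum.h"
using namespace Rcpp;

// PAM constraint check on the forward read: pam occupies genome positions
// p+1 .. p+plen (0-based) right after the k-window ending at p.
static inline bool pam_ok_fwd(const std::string &seq, long p, const std::string &pam) {
  long L = (long)seq.size(), plen = (long)pam.size();
  if (p + plen >= L) return false;
  for (long t = 0; t < plen; ++t) {
    if (pam[(size_t)t] == 'N' || pam[(size_t)t] == 'n') continue;
    int m = base_bit(pam[(size_t)t]);
    if (!(base_bit(seq[(size_t)(p + 1 + t)]) & m)) return false;
  }
  return true;
}

// PAM on the minus strand: the reverse-complement read of the window has the
// PAM 3' of it, i.e. the genome shows revcomp(PAM) immediately 5' of the
// window starting at i.
static inline bool pam_ok_rev(const std::string &seq, long i, const std::string &pam) {
  long plen = (long)pam.size();
  if (i - plen < 0) return false;
  for (long t = 0; t < plen; ++t) {
    if (pam[(size_t)t] == 'N' || pam[(size_t)t] == 'n') continue;
    int m = base_bit(pam[(size_t)t]);
    if (!(base_bit(comp_base(seq[(size_t)(i - 1 - t)])) & m)) return false;
  }
  return true;
}

// Scan chromosomes with the 2-bit sliding indices, invoking set-ops for every
// qualifying window. Shared by the presence bit array and the count database.
template <typename FSet>
static void scan_space(const CharacterVector &chromSeqs, int k,
                       const std::string &pam, const std::string &prefix,
                       FSet setter) {
  int p = (int)prefix.size();
  uint64_t pcode = 0;
  if (p > 0 && !seq2_index(prefix, pcode)) stop("prefix must be ACGT only");
  int sw = 2 * (k - p); // suffix width in bits
  uint64_t smask = (sw >= 64) ? ~0ULL : ((1ULL << sw) - 1ULL);
  uint64_t wmask = (2 * k >= 64) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  bool hasPam = !pam.empty();
  for (R_xlen_t ci = 0; ci < chromSeqs.size(); ++ci) {
    std::string seq = as<std::string>(chromSeqs[ci]);
    long L = (long)seq.size();
    uint64_t fwd = 0, rev = 0;
    int valid = 0;
    for (long pos = 0; pos < L; ++pos) {
      int c = code2(seq[(size_t)pos]);
      if (c < 0) { valid = 0; continue; } // restart past non-ACGT
      fwd = ((fwd << 2) | (uint64_t)c) & wmask;
      rev = (rev >> 2) | ((uint64_t)(3 - c) << (2 * (k - 1)));
      if (++valid < k) continue;
      long i = pos - k + 1; // window start
      if (!hasPam || pam_ok_fwd(seq, pos, pam)) {
        if (p == 0 || (fwd >> sw) == pcode) setter(fwd & smask);
      }
      if (!hasPam || pam_ok_rev(seq, i, pam)) {
        if (p == 0 || (rev >> sw) == pcode) setter(rev & smask);
      }
    }
  }
}

static R_xlen_t space_bytes(int k, int p, int bitsPerCell) {
  int width = 2 * (k - p);
  if (width > 50) stop("sequence space of 2^%d cells is too large; use a longer prefix", width);
  uint64_t ncell = 1ULL << width;
  uint64_t nbytes = (ncell * (uint64_t)bitsPerCell + 7ULL) / 8ULL;
  if (nbytes > (1ULL << 31))
    stop("sequence space would need %.1f GB; divide it with a longer prefix",
         (double)nbytes / 1073741824.0);
  return (R_xlen_t)nbytes;
}

// [[Rcpp::export]]
RawVector cpp_encode_seqspace(CharacterVector chromSeqs, int k,
                              std::string pam, std::string prefix) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  if ((int)prefix.size() >= k) stop("prefix length must be shorter than k");
  RawVector bits(space_bytes(k, (int)prefix.size(), 1));
  scan_space(chromSeqs, k, pam, prefix,
             [&](uint64_t idx) { set_bit(bits, idx); });
  return bits;
}

// [[Rcpp::export]]
double cpp_space_popcount(RawVector bits) {
  double n = 0;
  for (R_xlen_t i = 0; i < bits.size(); ++i) {
    unsigned v = bits[i];
    while (v) { n += v & 1; v >>= 1; }
  }
  return n;
}

// [[Rcpp::export]]
LogicalVector cpp_space_get(RawVector bits, CharacterVector seqs, int k,
                            std::string prefix) {
  int p = (int)prefix.size();
  int sw = 2 * (k - p);
  R_xlen_t n = seqs.size();
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    if ((int)s.size() != k) stop("query length %d does not match space k=%d",
        (int)s.size(), k);
    uint64_t idx;
    if (!seq2_index(s, idx)) stop("non-ACGT base in query");
    if (p > 0) {
      uint64_t pc, qp = idx >> sw;
      seq2_index(prefix, pc);
      if (qp != pc) { out[i] = NA_LOGICAL; continue; }
      idx &= (sw >= 64) ? ~0ULL : ((1ULL << sw) - 1ULL);
    }
    out[i] = get_bit(bits, idx);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_encode_countdb(CharacterVector chromSeqs, int k, int b,
                        std::string pam, std::string prefix) {
  if (k < 1 || k > 32) stop("k must be in 1..32");
  if (b < 2) stop("b must be >= 2 (one value is reserved as the overflow sentinel)");
  if (b > 32) stop("b must be <= 32");
  if ((int)prefix.size() >= k) stop("prefix length must be shorter than k");
  RawVector cells(space_bytes(k, (int)prefix.size(), b));
  uint64_t cap = (1ULL << b) - 2ULL;      // largest exact in-cell count
  uint64_t sentinel = (1ULL << b) - 1ULL;
  std::map<uint64_t, uint64_t> overflow;
  scan_space(chromSeqs, k, pam, prefix, [&](uint64_t idx) {
    uint64_t cur = get_cell(cells, idx, b);
    if (cur < cap) {
      set_cell(cells, idx, b, cur + 1ULL);
    } else if (cur == cap) {
      set_cell(cells, idx, b, sentinel);
      overflow[idx] = cap + 1ULL;
    } else {
      ++overflow[idx];
    }
  });
  CharacterVector ok((R_xlen_t)overflow.size());
  NumericVector oc((R_xlen_t)overflow.size());
  R_xlen_t j = 0;
  for (auto &kv : overflow) { ok[j] = u64_str(kv.first); oc[j] = (double)kv.second; ++j; }
  return List::create(_["cells"] = cells, _["overflowKeys"] = ok,
                      _["overflowCounts"] = oc);
}
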