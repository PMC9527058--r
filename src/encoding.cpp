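#include "kenum.h"
using namespace Rcpp;

// [[Rcpp::export]]
CharacterVector cpp_nuckey_encode(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(seqs[i])) { out[i] = NA_STRING; continue; }
    std::string s = as<std::string>(seqs[i]);
    if (s.empty() || s.size() > 20)
      stop("sequence length must be in 1..20 (got %d)", (int)s.size());
    out[i] = u64_str(nuckey_of(s));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_nuckey_decode(CharacterVector keys, int k) {
  R_xlen_t n = keys.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    if (CharacterVector::is_na(keys[i])) { out[i] = NA_STRING; continue; }
    out[i] = nuckey_seq(parse_u64(as<std::string>(keys[i])), k);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_seqindex_encode(std::string seq) {
  int k = (int)seq.size();
  if (k < 1 || k > 26)
    stop("sequence length must be in 1..26 for exact double indices");
  uint64_t fwd, rev;
  if (!seq2_index(seq, fwd)) stop("non-ACGT base in sequence");
  seq2_index(revcomp_str(seq), rev);
  return NumericVector::create(_["fwd"] = (double)fwd, _["rev"] = (double)rev);
}

// [[Rcpp::export]]
NumericVector cpp_seqindex_slide(double fwd, double rev, int k, std::string nextBase) {
  if (k < 1 || k > 26) stop("k must be in 1..26");
  if (nextBase.size() != 1) stop("nextBase must be a single character");
  int code = code2(nextBase[0]);
  if (code < 0) stop("non-ACGT base invalidates the sliding window");
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  uint64_t f = ((uint64_t)fwd << 2 | (uint64_t)code) & mask;
  uint64_t r = ((uint64_t)rev >> 2) |
    ((uint64_t)(3 - code) << (2 * (k - 1)));
  return NumericVector::create(_["fwd"] = (double)f, _["rev"] = (double)r);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}
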