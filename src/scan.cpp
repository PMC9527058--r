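#include "kenum.h"
#include <algorithm>
using namespace Rcpp;

// Scan one chromosome (both strands) for windows matching the pattern.
// Pattern is pre-parsed in R: windowLen, 0-based spacerOffset, constraint
// offsets within the window and allowed-base bitmasks (A=1,C=2,G=4,T=8;
// N=15 passes anything including ambiguous genome bases).
// Emitted pos is 1-based leftmost plus-strand coordinate of the spacer,
// negative on the minus strand. firstBaseMask restricts the spacer's first
// base (partitioned runs).
// [[Rcpp::export]]
List cpp_scan_chrom(std::string seq, int k, int windowLen, int spacerOffset,
                    IntegerVector consOffsets, IntegerVector consMasks,
                    int firstBaseMask) {
  long L = (long)seq.size();
  if (L > 2147483646L)
    stop("chromosome longer than 2^31-1: position field would overflow");
  int W = windowLen, s0 = spacerOffset, nc = consOffsets.size();
  std::vector<std::string> keys, spacers;
  std::vector<int> poss;
  std::string spacer((size_t)k, 'A');
  for (long i = 0; i + W <= L; ++i) {
    // forward strand read
    bool ok = true;
    for (int c = 0; c < nc && ok; ++c) {
      int m = consMasks[c];
      if (m == 15) continue;
      if (!(base_bit(seq[(size_t)(i + consOffsets[c])]) & m)) ok = false;
    }
    if (ok && (base_bit(seq[(size_t)(i + s0)]) & firstBaseMask)) {
      bool pure = true;
      for (int j = 0; j < k; ++j) {
        char c = upcase(seq[(size_t)(i + s0 + j)]);
        if (code3(c) < 0) { pure = false; break; }
        spacer[(size_t)j] = c;
      }
      if (pure) {
        keys.push_back(u64_str(nuckey_of(spacer)));
        spacers.push_back(spacer);
        poss.push_back((int)(i + s0 + 1));
      }
    }
    // minus strand: reverse-complement read of the same window
    ok = true;
    for (int c = 0; c < nc && ok; ++c) {
      int m = consMasks[c];
      if (m == 15) continue;
      char g = comp_base(seq[(size_t)(i + W - 1 - consOffsets[c])]);
      if (!(base_bit(g) & m)) ok = false;
    }
    if (ok && (base_bit(comp_base(seq[(size_t)(i + W - 1 - s0)])) & firstBaseMask)) {
      bool pure = true;
      for (int j = 0; j < k; ++j) {
        char c = upcase(comp_base(seq[(size_t)(i + W - 1 - s0 - j)]));
        if (code3(c) < 0) { pure = false; break; }
        spacer[(size_t)j] = c;
      }
      if (pure) {
        keys.push_back(u64_str(nuckey_of(spacer)));
        spacers.push_back(spacer);
        poss.push_back(-(int)(i + W - s0 - k + 1));
      }
    }
  }
  return List::create(_["key"] = wrap(keys), _["pos"] = wrap(poss),
                      _["spacer"] = wrap(spacers));
}

// Fixed 16-byte little-endian KeyedPosition record layout:
// uint64 NucKey, uint32 chrID, int32 pos.
// [[Rcpp::export]]
RawVector cpp_records_to_raw(CharacterVector keys, IntegerVector chr,
                             IntegerVector pos) {
  R_xlen_t n = keys.size();
  if (chr.size() != n || pos.size() != n)
    stop("keys, chr and pos must have equal length");
  RawVector out(n * 16);
  for (R_xlen_t i = 0; i < n; ++i) {
    uint64_t key = parse_u64(as<std::string>(keys[i]));
    uint32_t cid = (uint32_t)chr[i];
    int32_t p = pos[i];
    R_xlen_t o = i * 16;
    for (int j = 0; j < 8; ++j) out[o + j] = (Rbyte)((key >> (8 * j)) & 0xFF);
    for (int j = 0; j < 4; ++j) out[o + 8 + j] = (Rbyte)((cid >> (8 * j)) & 0xFF);
    uint32_t up = (uint32_t)p;
    for (int j = 0; j < 4; ++j) out[o + 12 + j] = (Rbyte)((up >> (8 * j)) & 0xFF);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_raw_to_records(RawVector bytes) {
  R_xlen_t nb = bytes.size();
  if (nb % 16 != 0)
    stop("corrupt bin data: %d bytes is not a multiple of the 16-byte record size",
         (int)nb);
  R_xlen_t n = nb / 16;
  CharacterVector keys(n);
  IntegerVector chr(n), pos(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    R_xlen_t o = i * 16;
    uint64_t key = 0;
    for (int j = 7; j >= 0; --j) key = (key << 8) | (uint64_t)bytes[o + j];
    uint32_t cid = 0;
    for (int j = 3; j >= 0; --j) cid = (cid << 8) | (uint32_t)bytes[o + 8 + j];
    uint32_t up = 0;
    for (int j = 3; j >= 0; --j) up = (up << 8) | (uint32_t)bytes[o + 12 + j];
    keys[i] = u64_str(key);
    chr[i] = (int)cid;
    pos[i] = (int)(int32_t)up;
  }
  return List::create(_["key"] = keys, _["chrID"] = chr, _["pos"] = pos);
}

// Sort KeyedPosition records by (NucKey, chrID, |pos|, strand) and compute
// the copy number of each run of equal NucKeys. Returns the 1-based
// permutation and the per-record copy number in sorted order.
// [[Rcpp::export]]
List cpp_sort_keyed(CharacterVector keys, IntegerVector chr, IntegerVector pos) {
  R_xlen_t n = keys.size();
  std::vector<uint64_t> kv((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i)
    kv[(size_t)i] = parse_u64(as<std::string>(keys[i]));
  std::vector<R_xlen_t> idx((size_t)n);
  for (R_xlen_t i = 0; i < n; ++i) idx[(size_t)i] = i;
  std::sort(idx.begin(), idx.end(), [&](R_xlen_t a, R_xlen_t b) {
    if (kv[(size_t)a] != kv[(size_t)b]) return kv[(size_t)a] < kv[(size_t)b];
    if (chr[a] != chr[b]) return chr[a] < chr[b];
    int pa = abs(pos[a]), pb = abs(pos[b]);
    if (pa != pb) return pa < pb;
    return pos[a] > pos[b];  // '+' (positive) before '-'
  });
  IntegerVector ord(n), copy(n);
  R_xlen_t i = 0;
  while (i < n) {
    R_xlen_t j = i;
    while (j < n && kv[(size_t)idx[(size_t)j]] == kv[(size_t)idx[(size_t)i]]) ++j;
    for (R_xlen_t t = i; t < j; ++t) copy[t] = (int)(j - i);
    i = j;
  }
  for (R_xlen_t t = 0; t < n; ++t) ord[t] = (int)(idx[(size_t)t] + 1);
  return List::create(_["order"] = ord, _["copy"] = copy);
}
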