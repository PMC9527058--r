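#ifndef KENUM_H
#define KENUM_H

#include <Rcpp.h>
#include <cstdint>
#include <string>
#include <cstdlib>

// 3-bit NucKey codes: A->000, C->001, T->010, G->011, EOS->111
inline int code3(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'T': case 't': return 2;
  case 'G': case 'g': return 3;
  default: return -1;
  }
}

inline char decode3(int v) {
  static const char tab[4] = {'A', 'C', 'T', 'G'};
  return tab[v & 3];
}

// 2-bit sequence-space codes: A->00, C->01, G->10, T->11
inline int code2(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

inline char decode2(int v) {
  static const char tab[4] = {'A', 'C', 'G', 'T'};
  return tab[v & 3];
}

inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

inline char upcase(char c) {
  return (c >= 'a' && c <= 'z') ? (char)(c - 32) : c;
}

// base -> membership bitmask for pattern constraints (A=1,C=2,G=4,T=8)
inline int base_bit(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 4;
  case 'T': case 't': return 8;
  default: return 0;
  }
}

// NucKey encode: fold (value<<3)|code over bases, then append EOS (111)
inline uint64_t nuckey_of(const std::string &s) {
  uint64_t v = 0;
  for (char c : s) {
    int code = code3(c);
    if (code < 0) Rcpp::stop("non-ACGT character '%s' in sequence", std::string(1, c).c_str());
    v = (v << 3) | (uint64_t)code;
  }
  return (v << 3) | 7ULL;
}

// Decode a NucKey. Leading A's encode as zero bits, so the k-mer length is
// not recoverable from the integer alone: pass k to restore the exact
// sequence, or k = 0 for the shortest consistent sequence.
inline std::string nuckey_seq(uint64_t key, int k = 0) {
  if ((key & 7ULL) != 7ULL)
    Rcpp::stop("invalid NucKey: missing end-of-string marker");
  key >>= 3;
  std::string out;
  while (key != 0) {
    int code = (int)(key & 7ULL);
    if (code > 3) Rcpp::stop("invalid NucKey: bad nucleotide field");
    out.push_back(decode3(code));
    key >>= 3;
  }
  if (k > 0) {
    if ((int)out.size() > k)
      Rcpp::stop("NucKey encodes more than k=%d nucleotides", k);
    while ((int)out.size() < k) out.push_back('A');
  } else if (out.empty()) {
    out.push_back('A'); // key 7 == "A": the shortest consistent sequence
  }
  std::reverse(out.begin(), out.end());
  return out;
}

inline uint64_t parse_u64(const std::string &s) {
  if (s.empty()) Rcpp::stop("empty NucKey string");
  uint64_t v = 0;
  for (char c : s) {
    if (c < '0' || c > '9')
      Rcpp::stop("malformed unsigned integer string '%s'", s.c_str());
    v = v * 10ULL + (uint64_t)(c - '0');
  }
  return v;
}

inline std::string u64_str(uint64_t v) { return std::to_string(v); }

// 2-bit pack, most-significant-first: first base in the highest in-use bits
inline bool seq2_index(const std::string &s, uint64_t &idx) {
  idx = 0;
  for (char c : s) {
    int code = code2(c);
    if (code < 0) return false;
    idx = (idx << 2) | (uint64_t)code;
  }
  return true;
}

inline std::string index2_seq(uint64_t idx, int k) {
  std::string out((size_t)k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    out[(size_t)i] = decode2((int)(idx & 3ULL));
    idx >>= 2;
  }
  return out;
}

inline std::string revcomp_str(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (char &c : out) c = comp_base(c);
  return out;
}

// bit array helpers, LSB-first within each byte
inline bool get_bit(const Rcpp::RawVector &bits, uint64_t i) {
  return (bits[(R_xlen_t)(i >> 3)] >> (i & 7ULL)) & 1;
}

inline void set_bit(Rcpp::RawVector &bits, uint64_t i) {
  bits[(R_xlen_t)(i >> 3)] |= (Rbyte)(1u << (i & 7ULL));
}

// b-bit packed counter cells over a raw vector, LSB-first bit order
inline uint64_t get_cell(const Rcpp::RawVector &cells, uint64_t i, int b) {
  uint64_t bit0 = i * (uint64_t)b, v = 0;
  for (int j = 0; j < b; ++j) {
    uint64_t bp = bit0 + (uint64_t)j;
    v |= (uint64_t)((cells[(R_xlen_t)(bp >> 3)] >> (bp & 7ULL)) & 1) << j;
  }
  return v;
}

inline void set_cell(Rcpp::RawVector &cells, uint64_t i, int b, uint64_t v) {
  uint64_t bit0 = i * (uint64_t)b;
  for (int j = 0; j < b; ++j) {
    uint64_t bp = bit0 + (uint64_t)j;
    Rbyte mask = (Rbyte)(1u << (bp & 7ULL));
    if ((v >> j) & 1) cells[(R_xlen_t)(bp >> 3)] |= mask;
    else cells[(R_xlen_t)(bp >> 3)] &= (Rbyte)~mask;
  }
}

#endif
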