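#ifndef DENOVOTX_KMER_UTILS_H
#define DENOVOTX_KMER_UTILS_H

#include <cstdint>
#include <string>

// 2-bit nucleotide packing; k-mers up to k = 31 fit in one 64-bit word.

inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
  }
  return -1;
}

inline uint64_t rc_code(uint64_t x, int k) {
  uint64_t y = 0;
  for (int i = 0; i < k; ++i) {
    y = (y << 2) | (3 - (x & 3));
    x >>= 2;
  }
  return y;
}

inline std::string decode_kmer(uint64_t x, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = "ACGT"[x & 3];
    x >>= 2;
  }
  return s;
}

// false if a non-ACGT symbol is hit
inline bool encode_kmer(const char* s, int k, uint64_t& out) {
  uint64_t x = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    x = (x << 2) | (uint64_t)c;
  }
  out = x;
  return true;
}

inline std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (std::string::size_type i = 0; i < r.size(); ++i) {
    switch (r[i]) {
      case 'A': r[i] = 'T'; break;
      case 'C': r[i] = 'G'; break;
      case 'G': r[i] = 'C'; break;
      case 'T': r[i] = 'A'; break;
      default:  r[i] = 'N'; break;
    }
  }
  return r;
}

#endif
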