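#ifndef DENOVOTX_FMINDEX_H
#define DENOVOTX_FMINDEX_H

#include <string>
#include <vector>
#include <array>
#include <set>
#include <unordered_map>
#include <algorithm>
#include "kmer_utils.h"

// FM index over the concatenation of indexed sequences, one sentinel '$'
// terminating each document. Sentinels sort before the nucleotide alphabet
// and among themselves in document order, giving a well-defined suffix
// array without per-document terminator symbols. Rank is checkpointed at a
// fixed stride; suffix-array positions are sampled at a fixed stride and
// recovered by LF-walking, so count() does O(1) work per pattern symbol.
class FMIndex {
public:
  std::vector<std::string> ids, seqs;

  std::string text;                   // concatenation with '$' after each doc
  std::string bwt;
  std::vector<long> doc_start;        // start offset of each doc within text
  long C[5];                          // first-column starts: $ A C G T
  int occ_stride, sa_stride;
  std::vector< std::array<int32_t, 4> > occ_ck;
  std::unordered_map<int32_t, int32_t> dollar_lf;  // bwt row of '$' -> F row
  std::unordered_map<int32_t, int32_t> sa_sample;  // bwt row -> text position
  long n;                             // text length including sentinels
  long pattern_steps;                 // cumulative backward-search steps

  struct Aln {
    int doc;
    long offset;
    char strand;
    int mismatches;
  };

  FMIndex(int occ_stride_ = 128, int sa_stride_ = 32)
      : occ_stride(occ_stride_), sa_stride(sa_stride_), n(0),
        pattern_steps(0) {
    rebuild();
  }

  void add(const std::string& id, const std::string& s) {
    ids.push_back(id);
    seqs.push_back(s);
  }

  // suffix array by prefix doubling (O(N log^2 N)); input symbols are
  // pre-ranked integers
  static std::vector<int32_t> build_sa(const std::vector<int32_t>& s) {
    long N = (long)s.size();
    std::vector<int32_t> sa(N), rank(N), tmp(N);
    if (N == 0) return sa;
    for (long i = 0; i < N; ++i) { sa[i] = (int32_t)i; rank[i] = s[i]; }
    for (long step = 1;; step <<= 1) {
      auto cmp = [&](int32_t a, int32_t b) {
        if (rank[a] != rank[b]) return rank[a] < rank[b];
        int32_t ra = (a + step < N) ? rank[a + step] : -1;
        int32_t rb = (b + step < N) ? rank[b + step] : -1;
        return ra < rb;
      };
      std::sort(sa.begin(), sa.end(), cmp);
      tmp[sa[0]] = 0;
      for (long i = 1; i < N; ++i)
        tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
      rank = tmp;
      if (rank[sa[N - 1]] == (int32_t)(N - 1)) break;
    }
    return sa;
  }

  int doc_of(long pos) const {
    return (int)(std::upper_bound(doc_start.begin(), doc_start.end(), pos) -
                 doc_start.begin()) - 1;
  }

  void rebuild() {
    text.clear();
    doc_start.clear();
    long ndocs = (long)seqs.size();
    for (long d = 0; d < ndocs; ++d) {
      doc_start.push_back((long)text.size());
      text += seqs[d];
      text += '$';
    }
    n = (long)text.size();
    bwt.clear();
    occ_ck.clear();
    dollar_lf.clear();
    sa_sample.clear();
    for (int c = 0; c < 5; ++c) C[c] = 0;
    if (n == 0) return;

    std::vector<int32_t> it(n);
    {
      long d = 0;
      for (long i = 0; i < n; ++i)
        it[i] = (text[i] == '$') ? (int32_t)d++
                                 : (int32_t)(ndocs + base_code(text[i]));
    }
    std::vector<int32_t> sa = build_sa(it);

    bwt.resize(n);
    long cnt[5] = {ndocs, 0, 0, 0, 0};
    for (long i = 0; i < n; ++i) {
      long p = (sa[i] == 0) ? n - 1 : sa[i] - 1;
      char c = text[p];
      bwt[i] = c;
      if (c == '$')
        dollar_lf[(int32_t)i] = (int32_t)doc_of(p);
      else
        cnt[1 + base_code(c)]++;
      if (sa[i] % sa_stride == 0)
        sa_sample[(int32_t)i] = sa[i];
    }
    C[0] = 0;
    for (int c = 1; c < 5; ++c) C[c] = C[c - 1] + cnt[c - 1];

    long nck = n / occ_stride + 1;
    occ_ck.assign(nck, std::array<int32_t, 4>({{0, 0, 0, 0}}));
    std::array<int32_t, 4> run = {{0, 0, 0, 0}};
    for (long i = 0; i <= n; ++i) {
      if (i % occ_stride == 0 && i / occ_stride < nck)
        occ_ck[i / occ_stride] = run;
      if (i < n && bwt[i] != '$')
        run[base_code(bwt[i])]++;
    }
  }

  long occ(int c, long i) const {
    long ck = i / occ_stride;
    long res = occ_ck[ck][c];
    for (long j = ck * occ_stride; j < i; ++j)
      if (bwt[j] != '$' && base_code(bwt[j]) == c) res++;
    return res;
  }

  long lf(long row) const {
    char c = bwt[row];
    if (c == '$') return dollar_lf.at((int32_t)row);
    int bc = base_code(c);
    return C[1 + bc] + occ(bc, row);
  }

  // backward search; on success [lo, hi) is the SA interval of the pattern
  bool search(const std::string& p, long& lo, long& hi) {
    lo = 0;
    hi = n;
    if (p.empty() || n == 0) { lo = hi = 0; return false; }
    for (long i = (long)p.size() - 1; i >= 0; --i) {
      int bc = base_code(p[i]);
      if (bc < 0) { lo = hi = 0; return false; }
      lo = C[1 + bc] + occ(bc, lo);
      hi = C[1 + bc] + occ(bc, hi);
      ++pattern_steps;
      if (lo >= hi) return false;
    }
    return true;
  }

  long count(const std::string& p) {
    long lo, hi;
    return search(p, lo, hi) ? hi - lo : 0;
  }

  std::vector<long> locate(long lo, long hi) {
    std::vector<long> out;
    for (long r = lo; r < hi; ++r) {
      long row = r, steps = 0;
      std::unordered_map<int32_t, int32_t>::const_iterator it;
      while ((it = sa_sample.find((int32_t)row)) == sa_sample.end()) {
        row = lf(row);
        ++steps;
      }
      out.push_back(it->second + steps);
    }
    return out;
  }

  // all full-length ungapped alignments of read with <= max_mm mismatches;
  // mismatch tolerance via pigeonhole seeding (max_mm + 1 exact segments)
  std::vector<Aln> align(const std::string& read, bool both_strands,
                         int max_mm) {
    std::vector<Aln> out;
    long m = (long)read.size();
    if (n == 0 || m == 0 || m <= max_mm) return out;
    int nstr = both_strands ? 2 : 1;
    for (int si = 0; si < nstr; ++si) {
      char strand = (si == 0) ? '+' : '-';
      std::string s = (si == 0) ? read : revcomp_str(read);
      if (max_mm == 0) {
        long lo, hi;
        if (search(s, lo, hi)) {
          std::vector<long> pos = locate(lo, hi);
          for (size_t i = 0; i < pos.size(); ++i) {
            int d = doc_of(pos[i]);
            Aln a = {d, pos[i] - doc_start[d], strand, 0};
            out.push_back(a);
          }
        }
      } else {
        int nseg = max_mm + 1;
        long seg = m / nseg;
        if (seg < 1) continue;
        std::set<long> cand;
        for (int j = 0; j < nseg; ++j) {
          long b = (long)j * seg;
          long e = (j == nseg - 1) ? m : b + seg;
          long lo, hi;
          if (!search(s.substr(b, e - b), lo, hi)) continue;
          std::vector<long> pos = locate(lo, hi);
          for (size_t i = 0; i < pos.size(); ++i) {
            long st = pos[i] - b;
            if (st >= 0 && st + m <= n) cand.insert(st);
          }
        }
        for (std::set<long>::iterator it = cand.begin(); it != cand.end();
             ++it) {
          long st = *it;
          int d = doc_of(st);
          long off = st - doc_start[d];
          if (off + m > (long)seqs[d].size()) continue;  // would span sentinel
          int mm = 0;
          bool ok = true;
          for (long i = 0; i < m; ++i) {
            if (text[st + i] != s[i] && ++mm > max_mm) { ok = false; break; }
          }
          if (ok) {
            Aln a = {d, off, strand, mm};
            out.push_back(a);
          }
        }
      }
    }
    return out;
  }
};

#endif
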