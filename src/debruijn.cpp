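#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include "fmindex.h"
#include "kmer_utils.h"

using namespace Rcpp;

// Hash-table de Bruijn graph: k-mer edges are the keys, occurrence counts
// the values; the flanking (k-1)-mer nodes are implicit. Edges are held as
// 2-bit packed 64-bit words (k <= 31). With strand-ambiguous data every
// k-mer is canonicalized to the lexicographic minimum of itself and its
// reverse complement before lookup.
class DBG {
public:
  int k;
  int alpha, beta;
  double capacity;
  bool canonical;
  uint64_t mask;
  std::unordered_map<uint64_t, int32_t> edges;
  std::vector<std::string> cand_seqs;  // all candidates emitted so far

  DBG(int k_, int alpha_, int beta_, double capacity_, bool canonical_)
      : k(k_), alpha(alpha_), beta(beta_), capacity(capacity_),
        canonical(canonical_) {
    mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  }

  uint64_t canon(uint64_t x) const {
    if (!canonical) return x;
    uint64_t r = rc_code(x, k);
    return x < r ? x : r;
  }

  // one read: canonicalized k-mers already present in the candidate index
  // are skipped, the rest increment the graph; a would-be capacity overflow
  // triggers a reduction (purging sub-alpha edges) first
  int add_read(const std::string& seq, FMIndex* fm) {
    int touched = 0;
    long L = (long)seq.size();
    if (L < k) return 0;
    uint64_t x = 0;
    int run = 0;
    for (long i = 0; i < L; ++i) {
      int c = base_code(seq[i]);
      if (c < 0) { run = 0; continue; }
      x = ((x << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      if (run > k) run = k;
      uint64_t key = canon(x);
      if (fm && fm->n > 0 && fm->count(decode_kmer(key, k)) > 0) continue;
      std::unordered_map<uint64_t, int32_t>::iterator it = edges.find(key);
      if (it != edges.end()) {
        it->second++;
        ++touched;
      } else {
        if ((double)edges.size() + 1.0 > capacity) reduce(fm, true);
        edges[key] = 1;
        ++touched;
      }
    }
    return touched;
  }

  // greedy path extraction from a seed edge: extend rightward while some
  // overlapping edge has count >= beta (ties -> lexicographically smallest
  // base), then leftward symmetrically; traversed edges are removed
  std::string extract_path(uint64_t seed_key) {
    edges.erase(seed_key);
    std::string path = decode_kmer(seed_key, k);
    for (;;) {  // rightward
      uint64_t px;
      encode_kmer(path.c_str() + (path.size() - (k - 1)), k - 1, px);
      int best = -1;
      uint64_t bestkey = 0;
      char bestbase = 0;
      for (int c = 0; c < 4; ++c) {
        uint64_t key = canon(((px << 2) | (uint64_t)c) & mask);
        std::unordered_map<uint64_t, int32_t>::iterator it = edges.find(key);
        if (it != edges.end() && it->second > best) {
          best = it->second;
          bestkey = key;
          bestbase = "ACGT"[c];
        }
      }
      if (best < beta) break;
      edges.erase(bestkey);
      path += bestbase;
    }
    for (;;) {  // leftward
      uint64_t px;
      encode_kmer(path.c_str(), k - 1, px);
      int best = -1;
      uint64_t bestkey = 0;
      char bestbase = 0;
      for (int c = 0; c < 4; ++c) {
        uint64_t key = canon(((uint64_t)c << (2 * (k - 1))) | px);
        std::unordered_map<uint64_t, int32_t>::iterator it = edges.find(key);
        if (it != edges.end() && it->second > best) {
          best = it->second;
          bestkey = key;
          bestbase = "ACGT"[c];
        }
      }
      if (best < beta) break;
      edges.erase(bestkey);
      path = std::string(1, bestbase) + path;
    }
    if (canonical) {
      std::string r = revcomp_str(path);
      if (r < path) path = r;
    }
    return path;
  }

  // traverse paths seeded at remaining edges with count >= alpha, most
  // frequent first (ties -> lexicographically smallest k-mer); candidates
  // go into the index; a capacity-triggered purge also drops sub-alpha
  // leftovers
  std::vector<std::string> reduce(FMIndex* fm, bool purge_sub_alpha) {
    std::vector< std::pair<uint64_t, int32_t> > snap(edges.begin(),
                                                     edges.end());
    std::sort(snap.begin(), snap.end(),
              [](const std::pair<uint64_t, int32_t>& a,
                 const std::pair<uint64_t, int32_t>& b) {
                if (a.second != b.second) return a.second > b.second;
                return a.first < b.first;
              });
    std::vector<std::string> out;
    for (size_t i = 0; i < snap.size(); ++i) {
      if (snap[i].second < alpha) break;  // sorted by count, descending
      std::unordered_map<uint64_t, int32_t>::iterator it =
          edges.find(snap[i].first);
      if (it == edges.end()) continue;  // consumed by an earlier path
      out.push_back(extract_path(snap[i].first));
    }
    if (purge_sub_alpha) {
      edges.clear();
      edges.rehash(0);
    }
    if (!out.empty()) {
      for (size_t i = 0; i < out.size(); ++i) {
        cand_seqs.push_back(out[i]);
        if (fm) {
          char id[32];
          snprintf(id, sizeof(id), "cand_%05d", (int)cand_seqs.size());
          fm->add(id, out[i]);
        }
      }
      if (fm) fm->rebuild();
    }
    return out;
  }
};

// [[Rcpp::export(name = ".dbg_new")]]
SEXP dbg_new(int k, int alpha, int beta, double capacity, bool canonical) {
  XPtr<DBG> p(new DBG(k, alpha, beta, capacity, canonical), true);
  return p;
}

// [[Rcpp::export(name = ".dbg_add_read")]]
int dbg_add_read(SEXP ptr, std::string seq, SEXP fm) {
  XPtr<DBG> p(ptr);
  FMIndex* f = NULL;
  if (!Rf_isNull(fm)) f = XPtr<FMIndex>(fm).get();
  return p->add_read(seq, f);
}

// [[Rcpp::export(name = ".dbg_add_reads")]]
void dbg_add_reads(SEXP ptr, CharacterVector seqs, SEXP fm) {
  XPtr<DBG> p(ptr);
  FMIndex* f = NULL;
  if (!Rf_isNull(fm)) f = XPtr<FMIndex>(fm).get();
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    p->add_read(as<std::string>(seqs[i]), f);
}

// [[Rcpp::export(name = ".dbg_extract_path")]]
String dbg_extract_path(SEXP ptr, std::string seed) {
  XPtr<DBG> p(ptr);
  uint64_t x;
  if ((int)seed.size() != p->k || !encode_kmer(seed.c_str(), p->k, x))
    stop("seed must be a %d-mer over {A,C,G,T}", p->k);
  x = p->canon(x);
  std::unordered_map<uint64_t, int32_t>::iterator it = p->edges.find(x);
  if (it == p->edges.end())
    stop("seed k-mer not present in the graph");
  if (it->second < p->alpha)
    stop("seed k-mer frequency %d is below alpha = %d", it->second, p->alpha);
  return p->extract_path(x);
}

// [[Rcpp::export(name = ".dbg_reduce")]]
CharacterVector dbg_reduce(SEXP ptr, SEXP fm, bool purge) {
  XPtr<DBG> p(ptr);
  FMIndex* f = NULL;
  if (!Rf_isNull(fm)) f = XPtr<FMIndex>(fm).get();
  return wrap(p->reduce(f, purge));
}

// [[Rcpp::export(name = ".dbg_edges")]]
IntegerVector dbg_edges(SEXP ptr) {
  XPtr<DBG> p(ptr);
  std::vector< std::pair<uint64_t, int32_t> > snap(p->edges.begin(),
                                                   p->edges.end());
  std::sort(snap.begin(), snap.end());
  IntegerVector out(snap.size());
  CharacterVector nm(snap.size());
  for (size_t i = 0; i < snap.size(); ++i) {
    out[i] = snap[i].second;
    nm[i] = decode_kmer(snap[i].first, p->k);
  }
  out.names() = nm;
  return out;
}

// test/setup helper: install edges with explicit counts
// [[Rcpp::export(name = ".dbg_set_edges")]]
void dbg_set_edges(SEXP ptr, CharacterVector kmers, IntegerVector counts) {
  XPtr<DBG> p(ptr);
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t x;
    if ((int)s.size() != p->k || !encode_kmer(s.c_str(), p->k, x))
      stop("edge %s is not a valid %d-mer", s.c_str(), p->k);
    p->edges[p->canon(x)] = counts[i];
  }
}

// [[Rcpp::export(name = ".dbg_size")]]
double dbg_size(SEXP ptr) {
  XPtr<DBG> p(ptr);
  return (double)p->edges.size();
}

// [[Rcpp::export(name = ".dbg_candidates")]]
CharacterVector dbg_candidates(SEXP ptr) {
  XPtr<DBG> p(ptr);
  return wrap(p->cand_seqs);
}

// [[Rcpp::export(name = ".kmerize")]]
CharacterVector kmerize_cpp(std::string seq, int k) {
  std::vector<std::string> out;
  long L = (long)seq.size();
  if (L >= k) {
    for (long i = 0; i + k <= L; ++i) {
      bool ok = true;
      for (long j = i; j < i + k; ++j)
        if (base_code(seq[j]) < 0) { ok = false; break; }
      if (ok) {
        std::string s = seq.substr(i, k);
        for (long j = 0; j < k; ++j) s[j] = "ACGT"[base_code(s[j])];
        out.push_back(s);
      }
    }
  }
  return wrap(out);
}

// for each query sequence: does every one of its k-mers occur in >= 1 read
// (under the strand policy)? Genes shorter than k report FALSE.
// [[Rcpp::export(name = ".kmers_all_in_reads")]]
LogicalVector kmers_all_in_reads(CharacterVector reads,
                                 CharacterVector queries, int k,
                                 bool canonical) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::unordered_set<uint64_t> seen;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    uint64_t x = 0;
    int run = 0;
    for (long i = 0; i < (long)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; continue; }
      x = ((x << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      if (run > k) run = k;
      uint64_t key = x;
      if (canonical) {
        uint64_t rc = rc_code(x, k);
        if (rc < key) key = rc;
      }
      seen.insert(key);
    }
  }
  LogicalVector out(queries.size());
  for (R_xlen_t q = 0; q < queries.size(); ++q) {
    std::string s = as<std::string>(queries[q]);
    bool all = (long)s.size() >= k;
    uint64_t x = 0;
    int run = 0;
    for (long i = 0; all && i < (long)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { all = false; break; }
      x = ((x << 2) | (uint64_t)c) & mask;
      if (++run < k) continue;
      if (run > k) run = k;
      uint64_t key = x;
      if (canonical) {
        uint64_t rc = rc_code(x, k);
        if (rc < key) key = rc;
      }
      if (!seen.count(key)) all = false;
    }
    out[q] = all;
  }
  return out;
}
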