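#include <Rcpp.h>
#include "fmindex.h"

using namespace Rcpp;

// [[Rcpp::export(name = ".fm_new")]]
SEXP fm_new(CharacterVector ids, CharacterVector seqs, int occ_stride,
            int sa_stride) {
  XPtr<FMIndex> p(new FMIndex(occ_stride, sa_stride), true);
  for (R_xlen_t i = 0; i < ids.size(); ++i)
    p->add(as<std::string>(ids[i]), as<std::string>(seqs[i]));
  p->rebuild();
  return p;
}

// [[Rcpp::export(name = ".fm_add")]]
void fm_add(SEXP ptr, CharacterVector ids, CharacterVector seqs) {
  XPtr<FMIndex> p(ptr);
  for (R_xlen_t i = 0; i < ids.size(); ++i)
    p->add(as<std::string>(ids[i]), as<std::string>(seqs[i]));
  p->rebuild();
}

// [[Rcpp::export(name = ".fm_ids")]]
CharacterVector fm_ids(SEXP ptr) {
  XPtr<FMIndex> p(ptr);
  return wrap(p->ids);
}

// [[Rcpp::export(name = ".fm_seqs")]]
CharacterVector fm_seqs(SEXP ptr) {
  XPtr<FMIndex> p(ptr);
  return wrap(p->seqs);
}

// [[Rcpp::export(name = ".fm_bwt")]]
String fm_bwt(SEXP ptr) {
  XPtr<FMIndex> p(ptr);
  return p->bwt;
}

// [[Rcpp::export(name = ".fm_total_length")]]
double fm_total_length(SEXP ptr) {
  // indexed length N, excluding sentinels
  XPtr<FMIndex> p(ptr);
  return (double)(p->n - (long)p->seqs.size());
}

// [[Rcpp::export(name = ".fm_count")]]
NumericVector fm_count(SEXP ptr, CharacterVector patterns) {
  XPtr<FMIndex> p(ptr);
  NumericVector out(patterns.size());
  for (R_xlen_t i = 0; i < patterns.size(); ++i)
    out[i] = (double)p->count(as<std::string>(patterns[i]));
  return out;
}

// [[Rcpp::export(name = ".fm_steps")]]
double fm_steps(SEXP ptr, bool reset) {
  XPtr<FMIndex> p(ptr);
  double s = (double)p->pattern_steps;
  if (reset) p->pattern_steps = 0;
  return s;
}

// [[Rcpp::export(name = ".fm_locate")]]
DataFrame fm_locate(SEXP ptr, std::string pattern) {
  XPtr<FMIndex> p(ptr);
  long lo, hi;
  std::vector<int> doc;
  std::vector<double> off;
  if (p->search(pattern, lo, hi)) {
    std::vector<long> pos = p->locate(lo, hi);
    std::sort(pos.begin(), pos.end());
    for (size_t i = 0; i < pos.size(); ++i) {
      int d = p->doc_of(pos[i]);
      doc.push_back(d + 1);  // 1-based doc index for R
      off.push_back((double)(pos[i] - p->doc_start[d]));
    }
  }
  return DataFrame::create(_["doc"] = doc, _["offset"] = off);
}

// [[Rcpp::export(name = ".fm_align")]]
DataFrame fm_align(SEXP ptr, CharacterVector reads, bool both_strands,
                   int max_mm) {
  XPtr<FMIndex> p(ptr);
  std::vector<int> query, doc, mm;
  std::vector<double> off;
  std::vector<std::string> strand;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::vector<FMIndex::Aln> as_ =
        p->align(as<std::string>(reads[i]), both_strands, max_mm);
    for (size_t j = 0; j < as_.size(); ++j) {
      query.push_back((int)i + 1);
      doc.push_back(as_[j].doc + 1);
      off.push_back((double)as_[j].offset);
      strand.push_back(std::string(1, as_[j].strand));
      mm.push_back(as_[j].mismatches);
    }
  }
  return DataFrame::create(_["query"] = query, _["doc"] = doc,
                           _["offset"] = off, _["strand"] = strand,
                           _["mismatches"] = mm,
                           _["stringsAsFactors"] = false);
}
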