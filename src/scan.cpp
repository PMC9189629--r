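#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Best ungapped placement of each query against each read.
//
// For read i, every query j is slid over offsets off_min[i]..off_max[i]
// (0-based start positions on the read). The aligned span is the query
// truncated at the read end; spans shorter than min_span are skipped.
// Score is matches - mismatches (match +1, mismatch -1). The best strictly
// greater score wins; ties keep the earliest (query, offset) seen, so the
// caller controls tie-breaking by pre-sorting queries.
//
// [[Rcpp::export]]
DataFrame scan_ungapped(CharacterVector reads, CharacterVector queries,
                        IntegerVector off_min, IntegerVector off_max,
                        int min_span) {
  const int n = reads.size(), nq = queries.size();
  const bool omin_scalar = off_min.size() == 1, omax_scalar = off_max.size() == 1;
  std::vector<std::string> qs(nq);
  for (int j = 0; j < nq; ++j) qs[j] = as<std::string>(queries[j]);

  IntegerVector q_idx(n, NA_INTEGER), score(n, NA_INTEGER),
      mism(n, NA_INTEGER), rstart(n, NA_INTEGER), rend(n, NA_INTEGER);

  for (int i = 0; i < n; ++i) {
    const std::string r = as<std::string>(reads[i]);
    const int rl = (int)r.size();
    int omin = omin_scalar ? off_min[0] : off_min[i];
    int omax = omax_scalar ? off_max[0] : off_max[i];
    if (omin < 0) omin = 0;
    int best = INT_MIN, bq = -1, bo = -1, bm = 0, bs = 0;
    for (int j = 0; j < nq; ++j) {
      const std::string &q = qs[j];
      const int ql = (int)q.size();
      for (int o = omin; o <= omax; ++o) {
        const int span = std::min(ql, rl - o);
        if (span < min_span) continue;
        int mm = 0;
        const char *rp = r.data() + o, *qp = q.data();
        for (int k = 0; k < span; ++k)
          if (rp[k] != qp[k]) ++mm;
        const int sc = span - 2 * mm;
        if (sc > best) {
          best = sc; bq = j; bo = o; bm = mm; bs = span;
        }
      }
    }
    if (bq >= 0) {
      q_idx[i] = bq + 1;
      score[i] = best;
      mism[i] = bm;
      rstart[i] = bo;
      rend[i] = bo + bs;
    }
  }
  return DataFrame::create(
      _["query"] = q_idx, _["score"] = score, _["mismatches"] = mism,
      _["read_start"] = rstart, _["read_end"] = rend);
}
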