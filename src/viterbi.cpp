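#include <Rcpp.h>
using namespace Rcpp;

// Generic 4-state max-score path decoder used by both the maximum-likelihood
// path builder (transition scores 0 / -Inf encoding the label grammar) and
// the HMM builder (log transition probabilities). States are ordered
// B, S, C, E; ties are broken toward the lower state index, so equal-score
// alternatives prefer background, then start, core, end.
//
// logemit:  L x 4 matrix of per-position per-state scores
// logtrans: 4 x 4 matrix of transition scores (from row to column)
// loginit:  length-4 initial scores (added at position 1)
// logfinal: length-4 terminal scores (added at position L)
//
// Returns list(path = integer L (1-based state ids), score = double).
// [[Rcpp::export]]
List viterbi4(NumericMatrix logemit, NumericMatrix logtrans,
              NumericVector loginit, NumericVector logfinal) {
  const int L = logemit.nrow();
  const int K = 4;
  if (L == 0)
    return List::create(_["path"] = IntegerVector(0),
                        _["score"] = R_NegInf);
  NumericMatrix dp(L, K);
  IntegerMatrix bt(L, K);
  for (int k = 0; k < K; ++k)
    dp(0, k) = loginit[k] + logemit(0, k);
  for (int i = 1; i < L; ++i) {
    for (int k = 0; k < K; ++k) {
      double best = R_NegInf;
      int arg = 0;
      for (int j = 0; j < K; ++j) {
        double v = dp(i - 1, j) + logtrans(j, k);
        if (v > best) { best = v; arg = j; }
      }
      dp(i, k) = best + logemit(i, k);
      bt(i, k) = arg;
    }
  }
  double best = R_NegInf;
  int last = 0;
  for (int k = 0; k < K; ++k) {
    double v = dp(L - 1, k) + logfinal[k];
    if (v > best) { best = v; last = k; }
  }
  IntegerVector path(L);
  path[L - 1] = last + 1;
  for (int i = L - 1; i > 0; --i) {
    last = bt(i, last);
    path[i - 1] = last + 1;
  }
  return List::create(_["path"] = path, _["score"] = best);
}
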