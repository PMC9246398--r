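#include <Rcpp.h>
using namespace Rcpp;

// Sequential forward fill.  q and s are 1-based indices into the alphabet;
// sub is the K x K substitution matrix (rows: database symbol, cols: query
// symbol); gap is the non-negative linear gap magnitude.
//
// Scans column-major (query symbol outer, database symbol inner) and keeps
// the FIRST maximum in that order (strict-greater replacement).  The
// direction rule matches cell_update(): diagonal wins all ties, a
// vertical/horizontal tie goes horizontal, and direction 0 is emitted
// exactly when the zero floor wins.
// [[Rcpp::export]]
List forward_fill_cpp(IntegerVector q, IntegerVector s, IntegerMatrix sub,
                      int gap) {
  const int N = q.size(), M = s.size();
  IntegerMatrix H(M + 1, N + 1), D(M + 1, N + 1);
  int maxVal = 0, posMi = 1, posMj = 1;
  for (int j = 0; j < N; ++j) {
    const int qj = q[j] - 1;
    for (int i = 0; i < M; ++i) {
      const int cd = H(i, j) + sub(s[i] - 1, qj);
      const int cy = H(i, j + 1) - gap;
      const int cv = H(i + 1, j) - gap;
      int score = 0, dir = 0;
      if (cd >= cy && cd >= cv && cd > 0) {
        score = cd; dir = 2;
      } else if (cy > cv && cy > 0) {
        score = cy; dir = 1;
      } else if (cv > 0) {
        score = cv; dir = 3;
      }
      H(i + 1, j + 1) = score;
      D(i + 1, j + 1) = dir;
      if (maxVal < score) {
        maxVal = score; posMi = i + 1; posMj = j + 1;
      }
    }
  }
  return List::create(_["H"] = H, _["D"] = D, _["max_value"] = maxVal,
                      _["max_row"] = posMi, _["max_col"] = posMj);
}
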