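#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment score with affine gaps (Gotoh).
// Sequences arrive pre-encoded as 0-based row/column indices into the
// substitution matrix; a gap of length L costs gap_open + L * gap_extend.
// Only the score is needed downstream (E-value assignment), so no traceback.
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector q, IntegerVector s, NumericMatrix mat,
                    double gap_open, double gap_extend) {
  const int n = q.size(), m = s.size();
  const double gfirst = gap_open + gap_extend;
  std::vector<double> H(m + 1, 0.0), E(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;          // H[i-1][0]
    double F = R_NegInf;        // gap in subject, current row
    H[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      // E[j]: vertical gap (consumes query letters); H[j] still holds row i-1
      E[j] = std::max(E[j] - gap_extend, H[j] - gfirst);
      // F: horizontal gap (consumes subject letters); H[j-1] is already row i
      F    = std::max(F    - gap_extend, H[j - 1] - gfirst);
      double h = diag + mat(q[i - 1], s[j - 1]);
      h = std::max(h, std::max(E[j], F));
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}
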