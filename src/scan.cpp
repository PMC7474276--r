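#include <Rcpp.h>
using namespace Rcpp;

// Integer window scores for one motif over one integer-encoded sequence.
//
// code: sequence encoded A,C,G,T -> 1..4, N/other -> 0
// sfwd, srev: width x 4 integer score matrices (forward motif and its
//             reverse complement) on the discretized log-odds grid
//
// Returns a 2 x (L - w + 1) IntegerMatrix: row 0 plus strand, row 1 minus
// strand; windows containing a 0 code get NA.
// [[Rcpp::export]]
IntegerMatrix window_scores(IntegerVector code, IntegerMatrix sfwd,
                            IntegerMatrix srev) {
  const int L = code.size();
  const int w = sfwd.nrow();
  if (srev.nrow() != w || sfwd.ncol() != 4 || srev.ncol() != 4)
    stop("score matrices must be width x 4 and of equal width");
  const int nw = L - w + 1;
  if (nw <= 0) return IntegerMatrix(2, 0);
  IntegerMatrix out(2, nw);
  for (int pos = 0; pos < nw; ++pos) {
    int sp = 0, sm = 0;
    bool okp = true, okm = true;  // NA scores (zero frequency) kill a strand
    for (int j = 0; j < w; ++j) {
      const int b = code[pos + j];
      if (b < 1 || b > 4) { okp = okm = false; break; }
      const int vf = sfwd(j, b - 1), vr = srev(j, b - 1);
      if (vf == NA_INTEGER) okp = false; else sp += vf;
      if (vr == NA_INTEGER) okm = false; else sm += vr;
      if (!okp && !okm) break;
    }
    out(0, pos) = okp ? sp : NA_INTEGER;
    out(1, pos) = okm ? sm : NA_INTEGER;
  }
  return out;
}
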