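#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch-style) alignment of two frequency profiles with a
// linear gap penalty. Profiles are (alphabet x length) column-frequency
// matrices; the expected substitution score of aligning column i of A with
// column j of B is sum_{a,b} A[a,i] * B[b,j] * S[a,b]. Traceback ties prefer
// diagonal, then up (gap in B), then left (gap in A), making the merge
// deterministic.
//
// Returns 1-based column indices into A and B along the merged alignment,
// with 0 marking a gap column.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B, NumericMatrix S,
                       double gap) {
  const int la = A.ncol(), lb = B.ncol(), na = A.nrow();
  if (S.nrow() != na || S.ncol() != na)
    stop("substitution matrix does not match profile alphabet");

  NumericMatrix H(la + 1, lb + 1);
  IntegerMatrix T(la + 1, lb + 1); // 0 = diag, 1 = up, 2 = left
  for (int i = 1; i <= la; ++i) { H(i, 0) = H(i - 1, 0) - gap; T(i, 0) = 1; }
  for (int j = 1; j <= lb; ++j) { H(0, j) = H(0, j - 1) - gap; T(0, j) = 2; }

  // expected column-pair scores
  NumericMatrix CS(la, lb);
  for (int i = 0; i < la; ++i) {
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < na; ++a) {
        const double fa = A(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < na; ++b) {
          const double fb = B(b, j);
          if (fb == 0.0) continue;
          s += fa * fb * S(a, b);
        }
      }
      CS(i, j) = s;
    }
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      const double d = H(i - 1, j - 1) + CS(i - 1, j - 1);
      const double u = H(i - 1, j) - gap;
      const double l = H(i, j - 1) - gap;
      if (d >= u && d >= l)      { H(i, j) = d; T(i, j) = 0; }
      else if (u >= l)           { H(i, j) = u; T(i, j) = 1; }
      else                       { H(i, j) = l; T(i, j) = 2; }
    }
  }

  std::vector<int> pa, pb;
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && T(i, j) == 0)      { pa.push_back(i); pb.push_back(j); --i; --j; }
    else if (i > 0 && (j == 0 || T(i, j) == 1)) { pa.push_back(i); pb.push_back(0); --i; }
    else                                      { pa.push_back(0); pb.push_back(j); --j; }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["a"] = wrap(pa), _["b"] = wrap(pb),
                      _["score"] = H(la, lb));
}
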