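#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment of two alignment profiles.
//
// A profile is a (symbols x columns) matrix of relative symbol frequencies
// (rows ordered as in `sub`; a trailing gap row is allowed and must score 0
// against everything, which the caller guarantees by padding `sub`).
// Column-vs-column score is the frequency-weighted average substitution
// score. Gap run of length L costs gap_open + (L - 1) * gap_ext.
//
// Traceback tie-break is fixed (diagonal > gap-in-b > gap-in-a) so that
// outputs are byte-reproducible.
//
// Returns the optimal score plus two paths: for each output column, the
// 1-based source column in each profile, or 0 where that profile takes a gap.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix pa, NumericMatrix pb, NumericMatrix sub,
                        double gap_open, double gap_ext) {
  const int la = pa.ncol(), lb = pb.ncol(), ns = pa.nrow();
  if (sub.nrow() != ns || sub.ncol() != ns)
    stop("substitution matrix does not match profile alphabet");

  // column-pair scores
  std::vector<double> cs((size_t)la * lb);
  for (int i = 0; i < la; ++i) {
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < ns; ++a) {
        const double fa = pa(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < ns; ++b) {
          const double fb = pb(b, j);
          if (fb != 0.0) s += fa * fb * sub(a, b);
        }
      }
      cs[(size_t)i * lb + j] = s;
    }
  }

  const int R = la + 1, C = lb + 1;
  std::vector<double> M((size_t)R * C, NEG_INF), X((size_t)R * C, NEG_INF),
      Y((size_t)R * C, NEG_INF);
  // traceback: which layer we came from (0 = M, 1 = X, 2 = Y)
  std::vector<unsigned char> tM((size_t)R * C), tX((size_t)R * C),
      tY((size_t)R * C);
  const size_t W = C;

  M[0] = 0.0;
  for (int i = 1; i < R; ++i) {
    X[(size_t)i * W] = -(gap_open + (i - 1) * gap_ext);
    tX[(size_t)i * W] = 1;
  }
  for (int j = 1; j < C; ++j) {
    Y[(size_t)j] = -(gap_open + (j - 1) * gap_ext);
    tY[(size_t)j] = 2;
  }

  for (int i = 1; i < R; ++i) {
    for (int j = 1; j < C; ++j) {
      const size_t ij = (size_t)i * W + j;
      const size_t di = ij - W - 1, up = ij - W, lf = ij - 1;
      // M: consume a column from both
      {
        double best = M[di];
        unsigned char t = 0;
        if (X[di] > best) { best = X[di]; t = 1; }
        if (Y[di] > best) { best = Y[di]; t = 2; }
        M[ij] = best + cs[(size_t)(i - 1) * lb + (j - 1)];
        tM[ij] = t;
      }
      // X: gap in b (consume column i of a)
      {
        double best = M[up] - gap_open;
        unsigned char t = 0;
        if (X[up] - gap_ext > best) { best = X[up] - gap_ext; t = 1; }
        if (Y[up] - gap_open > best) { best = Y[up] - gap_open; t = 2; }
        X[ij] = best;
        tX[ij] = t;
      }
      // Y: gap in a (consume column j of b)
      {
        double best = M[lf] - gap_open;
        unsigned char t = 0;
        if (X[lf] - gap_open > best) { best = X[lf] - gap_open; t = 1; }
        if (Y[lf] - gap_ext > best) { best = Y[lf] - gap_ext; t = 2; }
        Y[ij] = best;
        tY[ij] = t;
      }
    }
  }

  const size_t end = (size_t)la * W + lb;
  double score = M[end];
  int layer = 0;
  if (X[end] > score) { score = X[end]; layer = 1; }
  if (Y[end] > score) { score = Y[end]; layer = 2; }

  std::vector<int> ia, ib;
  ia.reserve(la + lb);
  ib.reserve(la + lb);
  int i = la, j = lb;
  while (i > 0 || j > 0) {
    const size_t ij = (size_t)i * W + j;
    if (layer == 0) {
      ia.push_back(i); ib.push_back(j);
      layer = tM[ij]; --i; --j;
    } else if (layer == 1) {
      ia.push_back(i); ib.push_back(0);
      layer = tX[ij]; --i;
    } else {
      ia.push_back(0); ib.push_back(j);
      layer = tY[ij]; --j;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());

  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(ia.begin(), ia.end()),
                      _["path_b"] = IntegerVector(ib.begin(), ib.end()));
}
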