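#include <Rcpp.h>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Three-state affine-gap alignment (Gotoh). States:
//   M  (0): x_i aligned to y_j (diagonal move)
//   Ix (1): x_i aligned to a gap (up move, consumes query)
//   Iy (2): y_j aligned to a gap (left move, consumes reference)
// A gap run of length k costs open + (k-1) * extend (open covers the first
// gapped position). Direct Ix<->Iy transitions are allowed and charged a new
// gap open, so adjacent gap runs in the two rows are two separate runs.
//
// Tie-breaking is exact (no epsilon): prefer predecessor state M, then Ix,
// then Iy at every choice, so the traceback yields the co-optimal alignment
// whose backward move sequence is lexicographically first under the move
// preference diagonal < up < left. For local alignment the end cell is the
// maximum-scoring M cell with smallest i+j, then smallest i, and on an exact
// tie between stopping and extending backwards, the traceback stops.

static inline int argmax3(double m, double x, double y) {
  int arg = 0;
  double best = m;
  if (x > best) { best = x; arg = 1; }
  if (y > best) { best = y; arg = 2; }
  return arg;
}

// [[Rcpp::export]]
List affine_align_cpp(NumericMatrix S, double open, double extend,
                      bool global) {
  const int m = S.nrow(), n = S.ncol();
  const double NEG = R_NegInf;

  NumericMatrix M(m + 1, n + 1), Ix(m + 1, n + 1), Iy(m + 1, n + 1);

  if (global) {
    M(0, 0) = 0.0;
    for (int i = 1; i <= m; ++i) {
      M(i, 0) = NEG;
      Ix(i, 0) = open + (i - 1) * extend;
      Iy(i, 0) = NEG;
    }
    for (int j = 1; j <= n; ++j) {
      M(0, j) = NEG;
      Ix(0, j) = NEG;
      Iy(0, j) = open + (j - 1) * extend;
    }
    Ix(0, 0) = NEG;
    Iy(0, 0) = NEG;
  } else {
    for (int i = 0; i <= m; ++i) { M(i, 0) = 0.0; Ix(i, 0) = NEG; Iy(i, 0) = NEG; }
    for (int j = 0; j <= n; ++j) { M(0, j) = 0.0; Ix(0, j) = NEG; Iy(0, j) = NEG; }
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      double prev = std::max(M(i - 1, j - 1),
                             std::max(Ix(i - 1, j - 1), Iy(i - 1, j - 1)));
      if (!global && prev < 0.0) prev = 0.0;
      M(i, j) = S(i - 1, j - 1) + prev;
      Ix(i, j) = std::max(M(i - 1, j) + open,
                          std::max(Ix(i - 1, j) + extend, Iy(i - 1, j) + open));
      Iy(i, j) = std::max(M(i, j - 1) + open,
                          std::max(Ix(i, j - 1) + open, Iy(i, j - 1) + extend));
    }
  }

  // locate alignment end
  int ei = 0, ej = 0, state = 0;
  double best;
  if (global) {
    ei = m; ej = n;
    best = M(m, n);
    state = argmax3(M(m, n), Ix(m, n), Iy(m, n));
    if (state == 1) best = Ix(m, n);
    if (state == 2) best = Iy(m, n);
  } else {
    best = 0.0;
    bool found = false;
    for (int i = 1; i <= m; ++i) {
      for (int j = 1; j <= n; ++j) {
        double v = M(i, j);
        if (v <= 0.0) continue;
        if (!found || v > best ||
            (v == best &&
             (i + j < ei + ej || (i + j == ei + ej && i < ei)))) {
          best = v; ei = i; ej = j; found = true;
        }
      }
    }
    if (!found) {
      return List::create(_["score"] = 0.0, _["start_i"] = 0, _["start_j"] = 0,
                          _["moves"] = "", _["empty"] = true);
    }
    state = 0;
  }

  // traceback (moves collected backwards, then reversed)
  std::string rev;
  int i = ei, j = ej;
  while (true) {
    if (global && i == 0 && j == 0) break;
    if (state == 0) {
      rev.push_back('D');
      double pm = M(i - 1, j - 1), px = Ix(i - 1, j - 1), py = Iy(i - 1, j - 1);
      double pb = std::max(pm, std::max(px, py));
      --i; --j;
      if (!global && pb <= 0.0) break;  // local start of alignment
      state = argmax3(pm, px, py);
    } else if (state == 1) {
      rev.push_back('U');
      double pm = M(i - 1, j) + open, px = Ix(i - 1, j) + extend,
             py = Iy(i - 1, j) + open;
      --i;
      state = argmax3(pm, px, py);
    } else {
      rev.push_back('L');
      double pm = M(i, j - 1) + open, px = Ix(i, j - 1) + open,
             py = Iy(i, j - 1) + extend;
      --j;
      state = argmax3(pm, px, py);
    }
  }
  std::reverse(rev.begin(), rev.end());

  return List::create(_["score"] = best, _["start_i"] = i, _["start_j"] = j,
                      _["moves"] = rev, _["empty"] = false);
}
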