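#include <Rcpp.h>
#include <string>
#include <vector>
#include <limits>

using namespace Rcpp;

// Affine-gap Needleman-Wunsch over {A,C,G,T,N}. Gap of length L costs
// open + (L-1)*ext. Three-state DP (M = aligned pair, X = gap in query row,
// Y = gap in ref row) with a fixed traceback preference M > X > Y so that
// ties resolve deterministically (match/mismatch, then gap-in-query, then
// gap-in-ref).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline int best3(double m, double x, double y) {
  // returns 0 for M, 1 for X, 2 for Y; preference M > X > Y on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(std::string ref, std::string query,
                      double match, double mismatch,
                      double gap_open, double gap_ext) {
  const int m = ref.size(), n = query.size();
  const int R = m + 1, C = n + 1;
  std::vector<double> M(R * C, NEG_INF), X(R * C, NEG_INF), Y(R * C, NEG_INF);
  // traceback: state entered at (i,j) stores predecessor state
  std::vector<signed char> tbM(R * C, -1), tbX(R * C, -1), tbY(R * C, -1);
  auto at = [C](int i, int j) { return i * C + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= m; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_ext;
    tbX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= n; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_ext;
    tbY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      // M state
      double dM = M[at(i - 1, j - 1)], dX = X[at(i - 1, j - 1)],
             dY = Y[at(i - 1, j - 1)];
      int pb = best3(dM, dX, dY);
      double dbest = (pb == 0) ? dM : (pb == 1 ? dX : dY);
      if (dbest > NEG_INF) {
        double s = (ref[i - 1] == query[j - 1]) ? match : mismatch;
        M[at(i, j)] = dbest + s;
        tbM[at(i, j)] = (signed char)pb;
      }
      // X state: consume ref[i-1], gap in query row
      double xM = M[at(i - 1, j)] + gap_open;
      double xX = X[at(i - 1, j)] + gap_ext;
      double xY = Y[at(i - 1, j)] + gap_open;
      int xb = best3(xM, xX, xY);
      double xbest = (xb == 0) ? xM : (xb == 1 ? xX : xY);
      if (xbest > NEG_INF) {
        X[at(i, j)] = xbest;
        tbX[at(i, j)] = (signed char)xb;
      }
      // Y state: consume query[j-1], gap in ref row
      double yM = M[at(i, j - 1)] + gap_open;
      double yX = X[at(i, j - 1)] + gap_open;
      double yY = Y[at(i, j - 1)] + gap_ext;
      int yb = best3(yM, yX, yY);
      double ybest = (yb == 0) ? yM : (yb == 1 ? yX : yY);
      if (ybest > NEG_INF) {
        Y[at(i, j)] = ybest;
        tbY[at(i, j)] = (signed char)yb;
      }
    }
  }

  int state;
  double score;
  if (m == 0 && n == 0) {
    state = 0;
    score = 0.0;
  } else {
    state = best3(M[at(m, n)], X[at(m, n)], Y[at(m, n)]);
    score = (state == 0) ? M[at(m, n)] : (state == 1 ? X[at(m, n)] : Y[at(m, n)]);
  }

  // traceback
  std::string ra, qa;
  ra.reserve(m + n);
  qa.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM[at(i, j)];
      ra.push_back(ref[i - 1]);
      qa.push_back(query[j - 1]);
      --i;
      --j;
      state = prev;
    } else if (state == 1) {
      int prev = tbX[at(i, j)];
      ra.push_back(ref[i - 1]);
      qa.push_back('-');
      --i;
      state = prev;
    } else {
      int prev = tbY[at(i, j)];
      ra.push_back('-');
      qa.push_back(query[j - 1]);
      --j;
      state = prev;
    }
  }
  std::string ref_row(ra.rbegin(), ra.rend());
  std::string query_row(qa.rbegin(), qa.rend());

  return List::create(_["ref_row"] = ref_row, _["query_row"] = query_row,
                      _["score"] = score);
}
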