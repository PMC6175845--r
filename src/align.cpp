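#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh) with deterministic traceback.
//
// Scores: +match for identical characters, +mismatch otherwise; a gap of
// length L costs gapOpen + L * gapExt.  Ties during traceback prefer the
// gap states (consume-reference, then consume-query) over the diagonal,
// which places indel runs at their 3'-most co-optimal position -- the HGVS
// normalisation convention, and the one that renders a premature stop as a
// substitution followed by a tail deletion.
//
// All scores are multiples of 0.5 for the default parameters, so exact
// double comparison in the traceback is safe; a small epsilon guards
// against user-supplied parameters that are not exactly representable.

static const double NEG_INF = -1e30;
static const double EPS = 1e-9;

// [[Rcpp::export(name = ".gotohAlign")]]
List gotohAlign(std::string ref, std::string qry,
                double match, double mismatch,
                double gapOpen, double gapExt) {
  const int m = ref.size();
  const int n = qry.size();
  if (m == 0 || n == 0)
    stop("sequences must be non-empty");

  // M: ref[i] aligned to qry[j]; Y: ref[i] aligned to gap (deletion in qry);
  // X: qry[j] aligned to gap (insertion relative to ref).
  std::vector<double> M((m + 1) * (n + 1), NEG_INF);
  std::vector<double> X((m + 1) * (n + 1), NEG_INF);
  std::vector<double> Y((m + 1) * (n + 1), NEG_INF);
  const int W = n + 1;
  const double open1 = gapOpen + gapExt;

  M[0] = 0.0;
  for (int j = 1; j <= n; ++j) X[j] = -(gapOpen + j * gapExt);
  for (int i = 1; i <= m; ++i) Y[i * W] = -(gapOpen + i * gapExt);

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j;
      const int up = (i - 1) * W + j;
      const int lf = i * W + (j - 1);
      const int dg = (i - 1) * W + (j - 1);
      double s = (ref[i - 1] == qry[j - 1]) ? match : mismatch;
      double dbest = M[dg];
      if (Y[dg] > dbest) dbest = Y[dg];
      if (X[dg] > dbest) dbest = X[dg];
      M[c] = dbest + s;
      // Y: gap in query, consumes ref[i-1]
      double yo = (M[up] > X[up] ? M[up] : X[up]) - open1;
      double ye = Y[up] - gapExt;
      Y[c] = yo > ye ? yo : ye;
      // X: gap in ref, consumes qry[j-1]
      double xo = (M[lf] > Y[lf] ? M[lf] : Y[lf]) - open1;
      double xe = X[lf] - gapExt;
      X[c] = xo > xe ? xo : xe;
    }
  }

  const int end = m * W + n;
  // preference Y > X > M among co-optimal end states
  const double best = std::max(M[end], std::max(X[end], Y[end]));
  int state; // 0 = M, 1 = Y, 2 = X
  if (Y[end] >= best - EPS) state = 1;
  else if (X[end] >= best - EPS) state = 2;
  else state = 0;

  std::string aref, aqry;
  aref.reserve(m + n);
  aqry.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 1) { // gap in query: emit ref[i-1] over '-'
      const int up = (i - 1) * W + j;
      aref.push_back(ref[i - 1]);
      aqry.push_back('-');
      // where did Y come from?
      double cur = Y[c];
      if (i == 1 && j == 0) { state = 0; --i; continue; }
      if (std::abs((Y[up] - gapExt) - cur) < EPS && i > 1) state = 1;
      else if (std::abs((X[up] - open1) - cur) < EPS) state = 2;
      else if (std::abs((M[up] - open1) - cur) < EPS) state = 0;
      else state = 1; // boundary column continuation
      --i;
    } else if (state == 2) { // gap in ref: emit '-' over qry[j-1]
      const int lf = i * W + (j - 1);
      aref.push_back('-');
      aqry.push_back(qry[j - 1]);
      double cur = X[c];
      if (i == 0 && j == 1) { state = 0; --j; continue; }
      if (std::abs((X[lf] - gapExt) - cur) < EPS && j > 1) state = 2;
      else if (std::abs((Y[lf] - open1) - cur) < EPS) state = 1;
      else if (std::abs((M[lf] - open1) - cur) < EPS) state = 0;
      else state = 2;
      --j;
    } else { // diagonal
      const int dg = (i - 1) * W + (j - 1);
      aref.push_back(ref[i - 1]);
      aqry.push_back(qry[j - 1]);
      double s = (ref[i - 1] == qry[j - 1]) ? match : mismatch;
      double cur = M[c];
      // predecessor state preference: Y > X > M
      if (std::abs((Y[dg] + s) - cur) < EPS) state = 1;
      else if (std::abs((X[dg] + s) - cur) < EPS) state = 2;
      else state = 0;
      --i; --j;
    }
    if (i == 0 && j > 0) state = 2;
    if (j == 0 && i > 0) state = 1;
  }
  std::reverse(aref.begin(), aref.end());
  std::reverse(aqry.begin(), aqry.end());

  return List::create(_["score"] = best,
                      _["ref"] = aref,
                      _["alt"] = aqry);
}
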