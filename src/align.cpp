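#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Profile alignment by dynamic programming (Gotoh-style, position-specific
// costs).  States are the profile match states in scheme order; a residue is
// either matched to a state or an insertion sitting after a state; states may
// be deleted.  Costs are in the same (bit) units as the emission scores.
//
//   emis      : nstates x 21 matrix, emis(j, a) = score of residue code a+1
//               at state j+1 (column 21 = ambiguous residue).
//   insOpen   : length nstates+1, cost of opening an insertion after state j
//               (index 0 = before the first state).
//   insExtend : length nstates+1, per-residue extension cost at the same slot.
//   delCost   : length nstates, cost of deleting state j.
//
// Returns best score plus, per residue, the matched state (1-based) or 0 for
// an insertion together with the state the insertion follows.
// [[Rcpp::export(name = ".profileAlignCpp")]]
List profileAlignCpp(IntegerVector seq, NumericMatrix emis,
                     NumericVector insOpen, NumericVector insExtend,
                     NumericVector delCost, bool traceback) {
  const int L = seq.size();
  const int S = emis.nrow();
  const double NEG = -std::numeric_limits<double>::infinity();

  // DP matrices (L+1) x (S+1); M = residue i matched to state j,
  // I = residue i inserted after state j, D = state j deleted, i consumed.
  std::vector<double> M((L + 1) * (S + 1), NEG);
  std::vector<double> I((L + 1) * (S + 1), NEG);
  std::vector<double> D((L + 1) * (S + 1), NEG);
  // traceback codes: 0 none, 1 from M, 2 from I, 3 from D, 4 start
  std::vector<unsigned char> tM, tI, tD;
  if (traceback) {
    tM.assign((L + 1) * (S + 1), 0);
    tI.assign((L + 1) * (S + 1), 0);
    tD.assign((L + 1) * (S + 1), 0);
  }
  auto at = [S](int i, int j) { return i * (S + 1) + j; };

  I[at(0, 0)] = 0.0;  // virtual start
  if (traceback) tI[at(0, 0)] = 4;
  for (int j = 1; j <= S; ++j) {  // leading deletions
    double fromI = I[at(0, j - 1)] - delCost[j - 1];
    double fromD = D[at(0, j - 1)] - delCost[j - 1];
    if (fromI >= fromD) { D[at(0, j)] = fromI; if (traceback) tD[at(0, j)] = 2; }
    else               { D[at(0, j)] = fromD; if (traceback) tD[at(0, j)] = 3; }
  }
  for (int i = 1; i <= L; ++i) {  // leading insertions (slot 0)
    I[at(i, 0)] = I[at(i - 1, 0)] -
      (i == 1 ? insOpen[0] : insExtend[0]);
    if (traceback) tI[at(i, 0)] = 2;
  }

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1] - 1;  // 0-based residue code
    for (int j = 1; j <= S; ++j) {
      // match
      double bm = M[at(i - 1, j - 1)], bi = I[at(i - 1, j - 1)],
             bd = D[at(i - 1, j - 1)];
      double best = bm; unsigned char tb = 1;
      if (bi > best) { best = bi; tb = 2; }
      if (bd > best) { best = bd; tb = 3; }
      M[at(i, j)] = best + emis(j - 1, a);
      if (traceback) tM[at(i, j)] = tb;
      // insertion after state j
      double im = M[at(i - 1, j)] - insOpen[j];
      double ii = I[at(i - 1, j)] - insExtend[j];
      double id = D[at(i - 1, j)] - insOpen[j];
      best = im; tb = 1;
      if (ii > best) { best = ii; tb = 2; }
      if (id > best) { best = id; tb = 3; }
      I[at(i, j)] = best;
      if (traceback) tI[at(i, j)] = tb;
      // deletion of state j
      double dm = M[at(i, j - 1)] - delCost[j - 1];
      double di = I[at(i, j - 1)] - delCost[j - 1];
      double dd = D[at(i, j - 1)] - delCost[j - 1];
      best = dm; tb = 1;
      if (di > best) { best = di; tb = 2; }
      if (dd > best) { best = dd; tb = 3; }
      D[at(i, j)] = best;
      if (traceback) tD[at(i, j)] = tb;
    }
  }

  double fin = M[at(L, S)]; int finState = 1;
  if (I[at(L, S)] > fin) { fin = I[at(L, S)]; finState = 2; }
  if (D[at(L, S)] > fin) { fin = D[at(L, S)]; finState = 3; }

  if (!traceback) {
    return List::create(_["score"] = fin);
  }

  // Trace back: per residue, matched state (1..S) or 0 = insertion, and the
  // slot (state index 0..S) an insertion follows.
  IntegerVector assign(L, 0), insAfter(L, NA_INTEGER);
  int i = L, j = S, cur = finState;
  while (i > 0 || j > 0) {
    if (cur == 1) {            // M: residue i matched to state j
      assign[i - 1] = j;
      cur = tM[at(i, j)];
      --i; --j;
    } else if (cur == 2) {     // I
      if (i == 0 && j == 0) break;  // virtual start
      unsigned char tb = tI[at(i, j)];
      if (tb == 4) break;
      assign[i - 1] = 0;
      insAfter[i - 1] = j;
      cur = tb;
      --i;
    } else {                   // D: state j deleted
      cur = tD[at(i, j)];
      --j;
    }
  }
  return List::create(_["score"] = fin, _["assign"] = assign,
                      _["insAfter"] = insAfter);
}
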