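#include <Rcpp.h>
using namespace Rcpp;

// All maximal scoring subsequences of a per-base score vector, by the
// linear-time left-to-right algorithm of Ruzzo & Tompa. A subsequence is
// maximal if it cannot be lengthened or shortened without lowering its
// score; the returned set is disjoint and ordered 5'->3'.
//
// The search for the rightmost listed subsequence whose left cumulative
// lies below the candidate's follows predecessor pointers (each entry
// stores the result of its own search), which skips whole blocks and keeps
// the pass linear even when the cumulative score drifts steadily downward
// and the list grows large.
//
// Returns a matrix with one row per maximal subsequence:
//   col 0: start (0-based), col 1: end (exclusive), col 2: score.
// [[Rcpp::export(name = ".maximal_scoring_subsequences")]]
NumericMatrix maximal_scoring_subsequences(NumericVector scores) {
  int n = scores.size();
  std::vector<double> L, R;  // cumulative total before start / at end
  std::vector<int> S, E;     // start, end (0-based half-open)
  std::vector<int> P;        // rightmost j < i with L[j] < L[i], else -1
  double cum = 0.0;
  for (int i = 0; i < n; ++i) {
    double s = scores[i];
    if (s <= 0.0) { cum += s; continue; }
    double Lk = cum, Rk = cum + s;
    int Sk = i, Ek = i + 1;
    cum += s;
    for (;;) {
      int j = (int)L.size() - 1;
      while (j >= 0 && L[j] >= Lk) j = P[j];
      if (j < 0 || R[j] >= Rk) {
        L.push_back(Lk); R.push_back(Rk); S.push_back(Sk); E.push_back(Ek);
        P.push_back(j);
        break;
      }
      // merge: the candidate extends I_j (and everything after it)
      Lk = L[j];
      Sk = S[j];
      L.resize(j); R.resize(j); S.resize(j); E.resize(j); P.resize(j);
    }
  }
  int k = (int)S.size();
  NumericMatrix out(k, 3);
  for (int i = 0; i < k; ++i) {
    out(i, 0) = S[i];
    out(i, 1) = E[i];
    out(i, 2) = R[i] - L[i];
  }
  colnames(out) = CharacterVector::create("start", "end", "score");
  return out;
}
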