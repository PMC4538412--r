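#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap costs.
// Scores: match +1, mismatch -1, gap -2 per gap position.
// Traceback ties are broken toward the diagonal, then toward the
// up move (gap in b), so the alignment is fully deterministic.

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b,
                  double match = 1.0, double mismatch = -1.0,
                  double gap = -2.0) {
  const int n = a.size(), m = b.size();
  NumericMatrix S(n + 1, m + 1);
  for (int i = 1; i <= n; ++i) S(i, 0) = i * gap;
  for (int j = 1; j <= m; ++j) S(0, j) = j * gap;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double diag = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      double up   = S(i - 1, j) + gap;
      double left = S(i, j - 1) + gap;
      double best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      S(i, j) = best;
    }
  }
  // traceback, diagonal preferred on ties
  std::string aa, bb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0) {
      double diag = S(i - 1, j - 1) + (a[i - 1] == b[j - 1] ? match : mismatch);
      if (S(i, j) == diag) {
        aa.push_back(a[i - 1]); bb.push_back(b[j - 1]);
        --i; --j;
        continue;
      }
    }
    if (i > 0 && S(i, j) == S(i - 1, j) + gap) {
      aa.push_back(a[i - 1]); bb.push_back('-');
      --i;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());
  return List::create(_["a"] = aa, _["b"] = bb, _["score"] = S(n, m));
}
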