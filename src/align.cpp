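#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh, three
// states). State codes: 0 = diagonal (match/mismatch), 1 = gap in b
// (column consumes a), 2 = gap in a (column consumes b). The first base
// of a gap costs gap_open; each further base costs gap_extend.
//
// Traceback is fully deterministic: at every maximisation, candidates
// are examined in the order diagonal, gap-in-b, gap-in-a and only a
// strictly larger score displaces the incumbent.
//
// Score matrices use two rolling rows; traceback predecessor states are
// stored per cell per state as one byte, so a 3.6 kb x 3.6 kb problem
// needs ~40 MB.

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const double NEG = -1e300;
  const size_t W = (size_t)m + 1;

  std::vector<double> Mprev(W), Xprev(W), Yprev(W), Mcur(W), Xcur(W), Ycur(W);
  std::vector<unsigned char> tbM((size_t)(n + 1) * W),
                             tbX((size_t)(n + 1) * W),
                             tbY((size_t)(n + 1) * W);

  // row 0
  Mprev[0] = 0.0; Xprev[0] = NEG; Yprev[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG; Xprev[j] = NEG;
    Yprev[j] = gap_open + (j - 1) * gap_extend;
    tbY[(size_t)0 * W + j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG; Ycur[0] = NEG;
    Xcur[0] = gap_open + (i - 1) * gap_extend;
    tbX[(size_t)i * W + 0] = (i == 1) ? 0 : 1;
    for (int j = 1; j <= m; ++j) {
      const size_t idx = (size_t)i * W + j;
      // diagonal
      double best = Mprev[j - 1]; unsigned char st = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; st = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; st = 2; }
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      Mcur[j] = (best <= NEG) ? NEG : best + s;
      tbM[idx] = st;
      // gap in b (consume a): from row i-1, same j
      best = Mprev[j] + gap_open; st = 0;
      if (Xprev[j] + gap_extend > best) { best = Xprev[j] + gap_extend; st = 1; }
      if (Yprev[j] + gap_open > best) { best = Yprev[j] + gap_open; st = 2; }
      Xcur[j] = best;
      tbX[idx] = st;
      // gap in a (consume b): from same row, j-1
      best = Mcur[j - 1] + gap_open; st = 0;
      if (Xcur[j - 1] + gap_open > best) { best = Xcur[j - 1] + gap_open; st = 1; }
      if (Ycur[j - 1] + gap_extend > best) { best = Ycur[j - 1] + gap_extend; st = 2; }
      Ycur[j] = best;
      tbY[idx] = st;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  double score = Mprev[m]; unsigned char state = 0;
  if (Xprev[m] > score) { score = Xprev[m]; state = 1; }
  if (Yprev[m] > score) { score = Yprev[m]; state = 2; }

  // traceback; op codes: 0 match, 1 mismatch, 2 gap in b, 3 gap in a
  std::vector<int> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t idx = (size_t)i * W + j;
    if (state == 0) {
      ops.push_back(a[i - 1] == b[j - 1] ? 0 : 1);
      state = tbM[idx]; --i; --j;
    } else if (state == 1) {
      ops.push_back(2);
      state = tbX[idx]; --i;
    } else {
      ops.push_back(3);
      state = tbY[idx]; --j;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = score,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
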