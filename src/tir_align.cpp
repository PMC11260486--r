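// Banded affine-gap alignment for end-anchored terminal inverted repeats.
//
// The query is the left end of the chromosome S, the subject the left end
// of revcomp(S): a TIR of length t is an alignment between the two
// prefixes starting within the first W bp of each. The DP is anchored in
// that W x W start corner (scores may start at 0 only there), runs along
// a diagonal band, and reports the maximum-score cell together with the
// alignment start and match statistics propagated through the band.

#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

namespace {

struct Cell {
  double score;
  int qs, ss;    // 0-based alignment start in query / subject
  int mat, cols; // matching columns / total columns
};

const double NEG = -1e18;

inline Cell neg_cell() { return Cell{NEG, -1, -1, 0, 0}; }

// Highest score wins; among equal-score alignments the most compact one
// (fewest columns, then smaller query start) — score-neutral gapped
// extensions past a repeat boundary must not inflate the reported span.
inline bool better_end(double sc, int cols, int qs,
                       double bsc, int bcols, int bqs) {
  if (sc != bsc) return sc > bsc;
  if (cols != bcols) return cols < bcols;
  return qs < bqs;
}

} // namespace

// [[Rcpp::export]]
List tir_banded_align_cpp(std::string A, std::string B, int W,
                          double match_s, double mismatch_s,
                          double gap_open, double gap_extend,
                          int band, double xdrop) {
  const int n = (int)A.size(), m = (int)B.size();
  const int width = 2 * band + 1;

  std::vector<Cell> Mprev(width), Mcur(width), Xprev(width), Xcur(width),
      Yprev(width), Ycur(width);
  for (int d = 0; d < width; ++d)
    Mprev[d] = Xprev[d] = Yprev[d] = neg_cell();

  bool found = false;
  Cell best = neg_cell();
  int best_i = -1, best_j = -1;

  for (int i = 1; i <= n; ++i) {
    double row_max = NEG;
    for (int d = 0; d < width; ++d) {
      const int j = i - band + d;
      if (j < 1 || j > m) {
        Mcur[d] = Xcur[d] = Ycur[d] = neg_cell();
        continue;
      }
      // --- M: consume A[i-1] vs B[j-1]; diagonal predecessors share d.
      Cell pre = neg_cell();
      if (Mprev[d].score > pre.score) pre = Mprev[d];
      if (Xprev[d].score > pre.score) pre = Xprev[d];
      if (Yprev[d].score > pre.score) pre = Yprev[d];
      if (i - 1 <= W && j - 1 <= W) {
        Cell fresh{0.0, i - 1, j - 1, 0, 0};
        if (fresh.score > pre.score) pre = fresh;
      }
      Cell mc = neg_cell();
      if (pre.score > NEG / 2) {
        const bool eq = A[(size_t)i - 1] == B[(size_t)j - 1];
        mc = pre;
        mc.score += eq ? match_s : mismatch_s;
        mc.mat += eq ? 1 : 0;
        mc.cols += 1;
      }
      Mcur[d] = mc;

      // --- X: gap in subject (consume A only); predecessor (i-1, j) = prev[d+1].
      Cell xc = neg_cell();
      if (d + 1 < width) {
        const Cell &mo = Mprev[d + 1], &xo = Xprev[d + 1];
        double s1 = mo.score > NEG / 2 ? mo.score + gap_open + gap_extend : NEG;
        double s2 = xo.score > NEG / 2 ? xo.score + gap_extend : NEG;
        if (s1 >= s2 && s1 > NEG / 2) { xc = mo; xc.score = s1; xc.cols += 1; }
        else if (s2 > NEG / 2)        { xc = xo; xc.score = s2; xc.cols += 1; }
      }
      Xcur[d] = xc;

      // --- Y: gap in query (consume B only); predecessor (i, j-1) = cur[d-1].
      Cell yc = neg_cell();
      if (d - 1 >= 0) {
        const Cell &mo = Mcur[d - 1], &yo = Ycur[d - 1];
        double s1 = mo.score > NEG / 2 ? mo.score + gap_open + gap_extend : NEG;
        double s2 = yo.score > NEG / 2 ? yo.score + gap_extend : NEG;
        if (s1 >= s2 && s1 > NEG / 2) { yc = mo; yc.score = s1; yc.cols += 1; }
        else if (s2 > NEG / 2)        { yc = yo; yc.score = s2; yc.cols += 1; }
      }
      Ycur[d] = yc;

      if (mc.score > row_max) row_max = mc.score;
      if (xc.score > row_max) row_max = xc.score;
      if (yc.score > row_max) row_max = yc.score;

      if (mc.score > 0 &&
          better_end(mc.score, mc.cols, mc.qs,
                     best.score, best.cols, best.qs)) {
        best = mc; best_i = i; best_j = j; found = true;
      }
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
    if (found && row_max < best.score - xdrop) break; // X-drop termination
  }

  if (!found)
    return List::create(Named("found") = false);
  return List::create(
      Named("found") = true, Named("score") = best.score,
      Named("qstart") = best.qs, Named("sstart") = best.ss,
      Named("qend") = best_i, Named("send") = best_j,
      Named("matches") = best.mat, Named("cols") = best.cols);
}
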