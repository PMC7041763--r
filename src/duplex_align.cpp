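// Local duplex alignment of a miRNA (processed 3'->5') against a target
// window (5'->3') under a complementarity scoring scheme: Watson-Crick pair,
// G:U wobble, mismatch, affine gaps. Substitution scores at miRNA seed
// positions (2-8 from the 5' end) carry a configurable weight.
//
// Bases are encoded upstream in R: A=0, C=1, G=2, T/U=3, other=4.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double subst_score(int mi, int tg, double match, double wobble,
                                 double mismatch) {
  if (mi > 3 || tg > 3) return mismatch;
  int s = mi + tg;
  if (s == 3) return match;            // A:U or C:G
  if (s == 5) return wobble;           // G:U
  return mismatch;
}

// Gotoh local alignment, all state transitions allowed, score only.
// mir is the miRNA already reversed (3'->5'); w the per-position weight in
// the same (reversed) order, applied to substitution scores.
static double align_score(const std::vector<int>& mir,
                          const std::vector<int>& tgt,
                          const std::vector<double>& w,
                          double match, double wobble, double mismatch,
                          double gap_open, double gap_extend) {
  const int n = mir.size(), m = tgt.size();
  const double NEG = -1e18;
  std::vector<double> M(m + 1, 0.0), Ix(m + 1, NEG), Iy(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diagM = 0.0, diagIx = NEG, diagIy = NEG; // cell (i-1, j-1)
    M[0] = 0.0; // local: fresh start allowed anywhere
    Ix[0] = NEG;
    Iy[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      double upM = M[j], upIx = Ix[j], upIy = Iy[j]; // cell (i-1, j)
      double s = w[i - 1] * subst_score(mir[i - 1], tgt[j - 1],
                                        match, wobble, mismatch);
      double mm = std::max(std::max(diagM, diagIx), diagIy) + s;
      double newM = std::max(0.0, mm);
      double newIx = std::max(std::max(upM + gap_open, upIx + gap_extend),
                              upIy + gap_open);
      double newIy = std::max(std::max(M[j - 1] + gap_open,
                                       Iy[j - 1] + gap_extend),
                              Ix[j - 1] + gap_open);
      diagM = upM; diagIx = upIx; diagIy = upIy;
      M[j] = newM; Ix[j] = newIx; Iy[j] = newIy;
      if (newM > best) best = newM;
    }
  }
  return best;
}

// [[Rcpp::export]]
double cpp_align_score(IntegerVector mir_rev, IntegerVector target,
                       NumericVector w_rev, double match, double wobble,
                       double mismatch, double gap_open, double gap_extend) {
  std::vector<int> a(mir_rev.begin(), mir_rev.end());
  std::vector<int> b(target.begin(), target.end());
  std::vector<double> w(w_rev.begin(), w_rev.end());
  return align_score(a, b, w, match, wobble, mismatch, gap_open, gap_extend);
}

// Best local-alignment score for every sliding window of `window_len` over
// the region (step 1). Windows shorter than the miRNA are skipped upstream.
// [[Rcpp::export]]
NumericVector cpp_window_scores(IntegerVector mir_rev, IntegerVector region,
                                NumericVector w_rev, int window_len,
                                double match, double wobble, double mismatch,
                                double gap_open, double gap_extend) {
  std::vector<int> a(mir_rev.begin(), mir_rev.end());
  std::vector<double> w(w_rev.begin(), w_rev.end());
  int L = region.size();
  int n_win = L - window_len + 1;
  if (n_win < 1) n_win = 0;
  NumericVector out(n_win);
  for (int s = 0; s < n_win; ++s) {
    std::vector<int> win(region.begin() + s, region.begin() + s + window_len);
    out[s] = align_score(a, win, w, match, wobble, mismatch,
                         gap_open, gap_extend);
  }
  return out;
}

// Full DP with traceback. Returns the best local alignment as an op string:
// 0 = substitution column, 1 = gap in target (miRNA base unpaired),
// 2 = gap in miRNA (target base unpaired), plus 1-based end coordinates.
// [[Rcpp::export]]
List cpp_align_traceback(IntegerVector mir_rev, IntegerVector target,
                         NumericVector w_rev, double match, double wobble,
                         double mismatch, double gap_open, double gap_extend) {
  const int n = mir_rev.size(), m = target.size();
  const double NEG = -1e18;
  // full matrices: windows are tiny so memory is irrelevant
  std::vector<std::vector<double> > M(n + 1, std::vector<double>(m + 1, 0.0));
  std::vector<std::vector<double> > Ix(n + 1, std::vector<double>(m + 1, NEG));
  std::vector<std::vector<double> > Iy(n + 1, std::vector<double>(m + 1, NEG));
  // back-pointers: which state fed each cell (0=M,1=Ix,2=Iy,3=local start)
  std::vector<std::vector<char> > bM(n + 1, std::vector<char>(m + 1, 3));
  std::vector<std::vector<char> > bIx(n + 1, std::vector<char>(m + 1, 0));
  std::vector<std::vector<char> > bIy(n + 1, std::vector<char>(m + 1, 0));
  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = w_rev[i - 1] * subst_score(mir_rev[i - 1], target[j - 1],
                                            match, wobble, mismatch);
      double dM = M[i - 1][j - 1], dIx = Ix[i - 1][j - 1],
             dIy = Iy[i - 1][j - 1];
      double from = dM; char bp = 0;
      if (dIx > from) { from = dIx; bp = 1; }
      if (dIy > from) { from = dIy; bp = 2; }
      double cand = from + s;
      if (cand < 0.0) { cand = 0.0; bp = 3; }
      M[i][j] = cand; bM[i][j] = bp;

      double oM = M[i - 1][j] + gap_open, eIx = Ix[i - 1][j] + gap_extend,
             oIy = Iy[i - 1][j] + gap_open;
      double vx = oM; char bx = 0;
      if (eIx > vx) { vx = eIx; bx = 1; }
      if (oIy > vx) { vx = oIy; bx = 2; }
      Ix[i][j] = vx; bIx[i][j] = bx;

      double oM2 = M[i][j - 1] + gap_open, eIy = Iy[i][j - 1] + gap_extend,
             oIx = Ix[i][j - 1] + gap_open;
      double vy = oM2; char by = 0;
      if (eIy > vy) { vy = eIy; by = 2; }
      if (oIx > vy) { vy = oIx; by = 1; }
      Iy[i][j] = vy; bIy[i][j] = by;

      if (M[i][j] > best) { best = M[i][j]; bi = i; bj = j; }
    }
  }
  std::vector<int> ops;
  int i = bi, j = bj, state = 0;
  while (i > 0 && j > 0 && best > 0.0) {
    if (state == 0) {
      char bp = bM[i][j];
      ops.push_back(0);
      --i; --j;
      if (bp == 3) break; // local alignment starts at this column
      state = bp;
    } else if (state == 1) {
      char bp = bIx[i][j];
      ops.push_back(1);
      --i;
      state = bp;
    } else {
      char bp = bIy[i][j];
      ops.push_back(2);
      --j;
      state = bp;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["score"] = best,
                      _["mi_end"] = bi, _["tgt_end"] = bj,
                      _["mi_start"] = i + 1, _["tgt_start"] = j + 1,
                      _["ops"] = IntegerVector(ops.begin(), ops.end()));
}
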