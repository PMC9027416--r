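#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Gotoh affine-gap global alignment.
//
// Gap cost convention: the first column of a gap run costs `gap_open`
// and every further column costs `gap_extend` (both supplied negative),
// i.e. a run of length L costs gap_open + (L - 1) * gap_extend.
// Terminal gaps are charged like internal ones: for circular genomes
// rotated into a common frame there is no privileged end.
//
// Three DP layers: M (column consumes a base from both rows),
// X (gap in the assembly row, reference base consumed),
// Y (gap in the reference row, assembly base consumed).
// Traceback for all three layers is packed into one byte per cell
// (2 bits each), so a 17 kb x 17 kb problem needs ~290 MB transiently.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List affine_global_align_cpp(const std::string& ref, const std::string& qry,
                             double match, double mismatch,
                             double gap_open, double gap_extend,
                             double max_cells) {
  const size_t m = ref.size(), n = qry.size();
  if (m == 0 || n == 0)
    stop("both sequences must be nonempty");
  const double cells = (double)(m + 1) * (double)(n + 1);
  if (cells > max_cells)
    stop("alignment problem of %.0f cells exceeds the guard of %.0f cells",
         cells, max_cells);

  // rolling score rows
  std::vector<double> Mprev(n + 1), Xprev(n + 1), Yprev(n + 1);
  std::vector<double> Mcur(n + 1), Xcur(n + 1), Ycur(n + 1);
  // packed traceback: bits 0-1 pred of M, 2-3 pred of X, 4-5 pred of Y
  // pred codes: 0 = M, 1 = X, 2 = Y
  std::vector<unsigned char> tb((m + 1) * (n + 1), 0);

  Mprev[0] = 0.0;
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (size_t j = 1; j <= n; ++j) {
    Mprev[j] = NEG_INF;
    Xprev[j] = NEG_INF;
    Yprev[j] = gap_open + (double)(j - 1) * gap_extend;
    tb[j] = (unsigned char)(2 << 4);  // Y extends Y
  }

  for (size_t i = 1; i <= m; ++i) {
    unsigned char* tbrow = &tb[i * (n + 1)];
    Mcur[0] = NEG_INF;
    Ycur[0] = NEG_INF;
    Xcur[0] = gap_open + (double)(i - 1) * gap_extend;
    tbrow[0] = (unsigned char)(1 << 2);  // X extends X
    const char rc = ref[i - 1];
    for (size_t j = 1; j <= n; ++j) {
      const double s = (rc == qry[j - 1]) ? match : mismatch;
      // M layer: diagonal predecessor, prefer M > X > Y on ties
      double best = Mprev[j - 1];
      unsigned char pred = 0;
      if (Xprev[j - 1] > best) { best = Xprev[j - 1]; pred = 1; }
      if (Yprev[j - 1] > best) { best = Yprev[j - 1]; pred = 2; }
      Mcur[j] = best + s;
      unsigned char code = pred;
      // X layer: vertical (ref base vs gap), prefer extension on ties
      double xe = Xprev[j] + gap_extend;
      double xm = Mprev[j] + gap_open;
      double xy = Yprev[j] + gap_open;
      double xbest = xe;
      unsigned char xpred = 1;
      if (xm > xbest) { xbest = xm; xpred = 0; }
      if (xy > xbest) { xbest = xy; xpred = 2; }
      Xcur[j] = xbest;
      code |= (unsigned char)(xpred << 2);
      // Y layer: horizontal (gap vs assembly base)
      double ye = Ycur[j - 1] + gap_extend;
      double ym = Mcur[j - 1] + gap_open;
      double yx = Xcur[j - 1] + gap_open;
      double ybest = ye;
      unsigned char ypred = 2;
      if (ym > ybest) { ybest = ym; ypred = 0; }
      if (yx > ybest) { ybest = yx; ypred = 1; }
      Ycur[j] = ybest;
      code |= (unsigned char)(ypred << 4);
      tbrow[j] = code;
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }

  double score = Mprev[n];
  int layer = 0;
  if (Xprev[n] > score) { score = Xprev[n]; layer = 1; }
  if (Yprev[n] > score) { score = Yprev[n]; layer = 2; }

  // traceback
  std::string rrow, arow;
  rrow.reserve(m + n);
  arow.reserve(m + n);
  size_t i = m, j = n;
  while (i > 0 || j > 0) {
    const unsigned char code = tb[i * (n + 1) + j];
    if (layer == 0) {
      rrow.push_back(ref[i - 1]);
      arow.push_back(qry[j - 1]);
      layer = code & 3;
      --i; --j;
    } else if (layer == 1) {
      rrow.push_back(ref[i - 1]);
      arow.push_back('-');
      layer = (code >> 2) & 3;
      --i;
    } else {
      rrow.push_back('-');
      arow.push_back(qry[j - 1]);
      layer = (code >> 4) & 3;
      --j;
    }
  }
  std::reverse(rrow.begin(), rrow.end());
  std::reverse(arow.begin(), arow.end());

  return List::create(_["ref_row"] = rrow, _["asm_row"] = arow,
                      _["score"] = score);
}

// Score-only prefix alignment: `ref` must be consumed end to end,
// `qry` is anchored at its start but its tail is free (unpenalized).
// Used to adjudicate candidate rotation offsets: the correct origin
// aligns the reference's leading window as a clean prefix of the
// assembly, while a displaced origin pays leading gap/mismatch costs.
// [[Rcpp::export]]
double prefix_align_score_cpp(const std::string& ref,
                              const std::string& qry,
                              double match, double mismatch,
                              double gap_open, double gap_extend) {
  const size_t m = ref.size(), n = qry.size();
  std::vector<double> Mprev(n + 1), Xprev(n + 1), Yprev(n + 1);
  std::vector<double> Mcur(n + 1), Xcur(n + 1), Ycur(n + 1);
  Mprev[0] = 0.0;
  Xprev[0] = NEG_INF;
  Yprev[0] = NEG_INF;
  for (size_t j = 1; j <= n; ++j) {
    Mprev[j] = NEG_INF;
    Xprev[j] = NEG_INF;
    Yprev[j] = gap_open + (double)(j - 1) * gap_extend;
  }
  for (size_t i = 1; i <= m; ++i) {
    Mcur[0] = NEG_INF;
    Ycur[0] = NEG_INF;
    Xcur[0] = gap_open + (double)(i - 1) * gap_extend;
    const char rc = ref[i - 1];
    for (size_t j = 1; j <= n; ++j) {
      const double s = (rc == qry[j - 1]) ? match : mismatch;
      double diag = std::max(Mprev[j - 1],
                             std::max(Xprev[j - 1], Yprev[j - 1]));
      Mcur[j] = diag + s;
      Xcur[j] = std::max(Xprev[j] + gap_extend,
                         std::max(Mprev[j], Yprev[j]) + gap_open);
      Ycur[j] = std::max(Ycur[j - 1] + gap_extend,
                         std::max(Mcur[j - 1], Xcur[j - 1]) + gap_open);
    }
    std::swap(Mprev, Mcur);
    std::swap(Xprev, Xcur);
    std::swap(Yprev, Ycur);
  }
  double best = NEG_INF;
  for (size_t j = 0; j <= n; ++j) {
    best = std::max(best, std::max(Mprev[j], Xprev[j]));
  }
  return best;
}

// Count exact base matches between `anchor` and every length-|anchor|
// window of `text` starting at offsets 0 .. n_offsets-1.
// Used by the rotation search over a doubled (self-concatenated) assembly.
// [[Rcpp::export]]
IntegerVector anchor_match_scores_cpp(const std::string& text,
                                      const std::string& anchor,
                                      int n_offsets) {
  const size_t k = anchor.size();
  IntegerVector out(n_offsets);
  for (int off = 0; off < n_offsets; ++off) {
    int sc = 0;
    const char* w = text.data() + off;
    for (size_t j = 0; j < k; ++j)
      if (w[j] == anchor[j]) ++sc;
    out[off] = sc;
  }
  return out;
}
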