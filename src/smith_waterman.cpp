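#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman with a fully deterministic traceback.
//
// Recurrences (rows i over a, columns j over b, 1-based DP indices):
//   E[i][j] = max(H[i-1][j] + open, E[i-1][j] + ext)   gap in b ("up")
//   F[i][j] = max(H[i][j-1] + open, F[i][j-1] + ext)   gap in a ("left")
//   H[i][j] = max(0, H[i-1][j-1] + s(a_i, b_j), E[i][j], F[i][j])
// The first residue of a gap costs `open`, each further residue `ext`.
//
// Tie-breaks: traceback starts at the earliest maximal H cell in row-major
// order; at each H cell the move preference is diagonal > up (E) > left (F);
// inside a gap chain, closing the gap (coming from H) is preferred over
// extending it when scores tie.

// [[Rcpp::export]]
List sw_align_cpp(std::string a, std::string b, IntegerMatrix mat,
                  int gap_open, int gap_extend) {
  const int la = a.size(), lb = b.size();
  // residue -> matrix index lookup
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(mat);
  for (int k = 0; k < rn.size(); ++k) {
    std::string r = as<std::string>(rn[k]);
    if (r.size() == 1) lut[(unsigned char)r[0]] = k;
  }
  std::vector<int> ai(la), bi(lb);
  for (int i = 0; i < la; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%c' not in substitution matrix", a[i]);
  }
  for (int j = 0; j < lb; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%c' not in substitution matrix", b[j]);
  }

  const int NEG = INT_MIN / 4;
  std::vector<std::vector<int>> H(la + 1, std::vector<int>(lb + 1, 0));
  std::vector<std::vector<int>> E(la + 1, std::vector<int>(lb + 1, NEG));
  std::vector<std::vector<int>> F(la + 1, std::vector<int>(lb + 1, NEG));

  int best = 0, bi_ = 0, bj_ = 0;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      int eo = H[i - 1][j] + gap_open, ee = E[i - 1][j] + gap_extend;
      E[i][j] = eo >= ee ? eo : ee;
      int fo = H[i][j - 1] + gap_open, fe = F[i][j - 1] + gap_extend;
      F[i][j] = fo >= fe ? fo : fe;
      int diag = H[i - 1][j - 1] + mat(ai[i - 1], bi[j - 1]);
      int h = 0;
      if (diag > h) h = diag;
      if (E[i][j] > h) h = E[i][j];
      if (F[i][j] > h) h = F[i][j];
      H[i][j] = h;
      if (h > best) { best = h; bi_ = i; bj_ = j; }  // earliest row-major max
    }
  }

  std::string aln_a, aln_b;
  int i = bi_, j = bj_;
  int a_end = bi_, b_end = bj_;
  // state: 0 = in H, 1 = in E (gap in b), 2 = in F (gap in a)
  int state = 0;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H[i][j] == 0) break;
      int diag = H[i - 1][j - 1] + mat(ai[i - 1], bi[j - 1]);
      if (H[i][j] == diag) {
        aln_a.push_back(a[i - 1]); aln_b.push_back(b[j - 1]);
        --i; --j;
      } else if (H[i][j] == E[i][j]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      aln_a.push_back(a[i - 1]); aln_b.push_back('-');
      // prefer closing the gap (H origin) on ties
      if (E[i][j] == H[i - 1][j] + gap_open) state = 0; // chain ends above
      --i;
    } else {
      aln_a.push_back('-'); aln_b.push_back(b[j - 1]);
      if (F[i][j] == H[i][j - 1] + gap_open) state = 0;
      --j;
    }
  }
  std::reverse(aln_a.begin(), aln_a.end());
  std::reverse(aln_b.begin(), aln_b.end());

  return List::create(_["score"] = best,
                      _["a_start"] = i, _["a_end"] = a_end,
                      _["b_start"] = j, _["b_end"] = b_end,
                      _["a_aln"] = aln_a, _["b_aln"] = aln_b);
}
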