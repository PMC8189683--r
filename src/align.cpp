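#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh). Gap cost
// convention: a gap of length k costs open + k * extend. Substitution
// scores come from a matrix passed from R together with its residue
// alphabet; unknown characters are rejected on the R side.

static const int NEG = -1000000000;

static void build_lut(const std::string& alphabet, int* lut) {
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (size_t i = 0; i < alphabet.size(); ++i)
    lut[(unsigned char)alphabet[i]] = (int)i;
}

static std::vector<int> encode(const std::string& s, const int* lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = lut[(unsigned char)s[i]];
  return v;
}

// score-only DP with two rolling rows
static int sw_score_one(const std::vector<int>& a, const std::vector<int>& b,
                        const IntegerMatrix& sub, int open, int extend) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Fcol(m + 1, NEG);  // F for current column j across rows
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int Erow = NEG;  // E for current row
    Hcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      Erow = std::max(Erow - extend, Hcur[j - 1] - open - extend);
      Fcol[j] = std::max(Fcol[j] - extend, Hprev[j] - open - extend);
      int h = std::max(Hprev[j - 1] + sub(a[i - 1], b[j - 1]),
                       std::max(Erow, Fcol[j]));
      if (h < 0) h = 0;
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_matrix_cpp")]]
NumericMatrix sw_score_matrix_cpp(CharacterVector seqs, IntegerMatrix sub,
                                  std::string alphabet, int open, int extend) {
  int lut[256];
  build_lut(alphabet, lut);
  const int u = seqs.size();
  std::vector<std::vector<int>> enc(u);
  for (int i = 0; i < u; ++i) enc[i] = encode(as<std::string>(seqs[i]), lut);
  NumericMatrix out(u, u);
  for (int i = 0; i < u; ++i) {
    out(i, i) = sw_score_one(enc[i], enc[i], sub, open, extend);
    for (int j = i + 1; j < u; ++j) {
      int s = sw_score_one(enc[i], enc[j], sub, open, extend);
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}

// Full pairwise alignment with traceback: local score plus match count and
// aligned-column count of one best local alignment. Deterministic
// tie-breaking: diagonal, then gap in the second sequence, then gap in the
// first.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string sa, std::string sb, IntegerMatrix sub,
                  std::string alphabet, int open, int extend) {
  int lut[256];
  build_lut(alphabet, lut);
  std::vector<int> a = encode(sa, lut), b = encode(sb, lut);
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<std::vector<int>> H(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int>> E(n + 1, std::vector<int>(m + 1, NEG));
  std::vector<std::vector<int>> F(n + 1, std::vector<int>(m + 1, NEG));
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      E[i][j] = std::max(E[i][j - 1] - extend, H[i][j - 1] - open - extend);
      F[i][j] = std::max(F[i - 1][j] - extend, H[i - 1][j] - open - extend);
      int h = std::max(H[i - 1][j - 1] + sub(a[i - 1], b[j - 1]),
                       std::max(E[i][j], F[i][j]));
      if (h < 0) h = 0;
      H[i][j] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, cols = 0;
  int state = 0;  // 0 = H, 1 = E (gap consuming b), 2 = F (gap consuming a)
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0 || H[i][j] == 0) break;
      if (H[i][j] == H[i - 1][j - 1] + sub(a[i - 1], b[j - 1])) {
        if (a[i - 1] == b[j - 1]) ++matches;
        ++cols; --i; --j;
      } else if (H[i][j] == F[i][j]) {
        state = 2;
      } else if (H[i][j] == E[i][j]) {
        state = 1;
      } else {
        break;
      }
    } else if (state == 1) {
      // consume one b residue; decide whether the gap opened here
      bool opened = (E[i][j] == H[i][j - 1] - open - extend);
      ++cols; --j;
      if (opened) state = 0;
    } else {
      bool opened = (F[i][j] == H[i - 1][j] - open - extend);
      ++cols; --i;
      if (opened) state = 0;
    }
  }
  return List::create(Named("score") = best, Named("matches") = matches,
                      Named("columns") = cols);
}
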