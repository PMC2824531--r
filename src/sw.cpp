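#include <Rcpp.h>
#include <cstring>
#include <climits>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman, Gotoh). A gap of length L
// costs gap_open + L * gap_extend. Residues absent from the scoring matrix
// score as the matrix minimum (worst-case substitution).

static void build_lut(const IntegerMatrix &smat, int lut[256]) {
  CharacterVector rn = rownames(smat);
  for (int i = 0; i < 256; ++i) lut[i] = -1;
  for (int i = 0; i < rn.size(); ++i) {
    const char *s = CHAR(STRING_ELT(rn, i));
    if (std::strlen(s) == 1) lut[(unsigned char)s[0]] = i;
  }
}

static int matrix_min(const IntegerMatrix &smat) {
  int mn = smat(0, 0);
  for (int i = 0; i < smat.nrow(); ++i)
    for (int j = 0; j < smat.ncol(); ++j)
      if (smat(i, j) < mn) mn = smat(i, j);
  return mn;
}

static std::vector<int> encode(const char *s, const int lut[256]) {
  size_t n = std::strlen(s);
  std::vector<int> v(n);
  for (size_t i = 0; i < n; ++i) v[i] = lut[(unsigned char)s[i]];
  return v;
}

// score-only SW for one encoded pair
static int sw_score(const std::vector<int> &a, const std::vector<int> &b,
                    const IntegerMatrix &smat, int smin, int go, int ge,
                    std::vector<int> &H, std::vector<int> &E) {
  const int n = (int)b.size();
  std::fill(H.begin(), H.begin() + n + 1, 0);
  std::fill(E.begin(), E.begin() + n + 1, INT_MIN / 4);
  int best = 0;
  const int open = go + ge;
  for (size_t i = 0; i < a.size(); ++i) {
    int diag = 0;       // H[i-1][j-1]
    int F = INT_MIN / 4;
    const int ai = a[i];
    const int *srow = (ai >= 0) ? &smat(ai, 0) : (const int *)0;
    const int nrow = smat.nrow();
    for (int j = 1; j <= n; ++j) {
      int e = E[j] - ge;
      int eo = H[j] - open;
      E[j] = (e > eo) ? e : eo;
      int f = F - ge;
      int fo = H[j - 1] - open;
      F = (f > fo) ? f : fo;
      int bj = b[j - 1];
      int sub = (srow && bj >= 0) ? srow[(size_t)bj * nrow] : smin;
      int h = diag + sub;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      diag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_block")]]
IntegerMatrix sw_score_block(CharacterVector query, CharacterVector subject,
                             IntegerMatrix smat, int gap_open, int gap_extend) {
  int lut[256];
  build_lut(smat, lut);
  const int smin = matrix_min(smat);
  const int nq = query.size(), ns = subject.size();
  std::vector<std::vector<int> > qe(nq), se(ns);
  size_t maxb = 1;
  for (int i = 0; i < nq; ++i) qe[i] = encode(CHAR(STRING_ELT(query, i)), lut);
  for (int j = 0; j < ns; ++j) {
    se[j] = encode(CHAR(STRING_ELT(subject, j)), lut);
    if (se[j].size() + 1 > maxb) maxb = se[j].size() + 1;
  }
  std::vector<int> H(maxb), E(maxb);
  IntegerMatrix out(nq, ns);
  for (int i = 0; i < nq; ++i) {
    if (qe[i].empty()) stop("empty query sequence at position %d", i + 1);
    for (int j = 0; j < ns; ++j) {
      if (se[j].empty()) stop("empty subject sequence at position %d", j + 1);
      out(i, j) = sw_score(qe[i], se[j], smat, smin, gap_open, gap_extend,
                           H, E);
    }
  }
  return out;
}

// Full DP with traceback for one pair. Ties in the end cell resolved to the
// smallest (query, subject) end coordinates; path ties prefer diagonal, then
// gap-in-subject (up), then gap-in-query (left).
// [[Rcpp::export(name = ".sw_align_one")]]
List sw_align_one(std::string a, std::string b, IntegerMatrix smat,
                  int gap_open, int gap_extend) {
  int lut[256];
  build_lut(smat, lut);
  const int smin = matrix_min(smat);
  std::vector<int> av = encode(a.c_str(), lut), bv = encode(b.c_str(), lut);
  const int m = (int)av.size(), n = (int)bv.size();
  if (m == 0 || n == 0) stop("empty sequence");
  const int open = gap_open + gap_extend;
  const int NEG = INT_MIN / 4;
  std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
      F((m + 1) * (n + 1), NEG);
  const int nrow = smat.nrow();
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= m; ++i) {
    const int ai = av[i - 1];
    for (int j = 1; j <= n; ++j) {
      size_t c = (size_t)i * (n + 1) + j, up = c - (n + 1), lf = c - 1;
      E[c] = std::max(E[lf] - gap_extend, H[lf] - open);
      F[c] = std::max(F[up] - gap_extend, H[up] - open);
      int bjc = bv[j - 1];
      int sub = (ai >= 0 && bjc >= 0) ? smat(ai, bjc) : smin;
      int h = H[up - 1] + sub;
      if (F[c] > h) h = F[c];
      if (E[c] > h) h = E[c];
      if (h < 0) h = 0;
      H[c] = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0)
    return List::create(_["score"] = 0, _["qstart"] = 0, _["qend"] = 0,
                        _["sstart"] = 0, _["send"] = 0, _["length"] = 0,
                        _["matches"] = 0, _["mismatch"] = 0, _["gapopen"] = 0);
  // traceback
  int i = bi, j = bj, state = 0;  // 0 = H, 1 = E (left), 2 = F (up)
  int len = 0, matches = 0, mism = 0, gapopen = 0;
  int qend = bi, send = bj;
  while (true) {
    size_t c = (size_t)i * (n + 1) + j;
    if (state == 0) {
      if (H[c] == 0) break;
      int sub = (av[i - 1] >= 0 && bv[j - 1] >= 0) ? smat(av[i - 1], bv[j - 1])
                                                   : smin;
      size_t d = c - (n + 1) - 1;
      if (H[c] == H[d] + sub) {
        ++len;
        if (av[i - 1] == bv[j - 1] && av[i - 1] >= 0) ++matches; else ++mism;
        --i; --j;
      } else if (H[c] == F[c]) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 2) {  // gap in subject, consume query residue
      size_t up = c - (n + 1);
      ++len;
      if (F[c] == H[up] - open) { ++gapopen; state = 0; }
      else state = 2;
      --i;
    } else {  // gap in query, consume subject residue
      size_t lf = c - 1;
      ++len;
      if (E[c] == H[lf] - open) { ++gapopen; state = 0; }
      else state = 1;
      --j;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = i + 1, _["qend"] = qend,
                      _["sstart"] = j + 1, _["send"] = send, _["length"] = len,
                      _["matches"] = matches, _["mismatch"] = mism,
                      _["gapopen"] = gapopen);
}
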