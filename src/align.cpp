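#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Affine-gap alignment kernels. Scoring convention throughout: a gap of
// length L costs gap_open + L * gap_extend (opening charge plus one
// extension per gap position), matching Biostrings::pairwiseAlignment.

static const double NEG = -1e30;
static const double EPS = 1e-9;

struct SubstMatrix {
  std::vector<int> lookup;        // char -> row index, -1 if absent
  std::vector<double> s;          // n x n
  int n;
  int xi;                         // index of 'X' (fallback), -1 if absent
  SubstMatrix(const NumericMatrix &m) {
    n = m.nrow();
    CharacterVector rn = rownames(m);
    lookup.assign(256, -1);
    xi = -1;
    for (int i = 0; i < n; ++i) {
      const char *p = CHAR(STRING_ELT(rn, i));
      lookup[(unsigned char)p[0]] = i;
      if (p[0] == 'X') xi = i;
    }
    s.assign((size_t)n * n, 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) s[(size_t)i * n + j] = m(i, j);
  }
  int idx(char c) const {
    int i = lookup[(unsigned char)c];
    if (i < 0) {
      if (xi >= 0) return xi;
      stop("residue '%c' not covered by the substitution matrix", c);
    }
    return i;
  }
  double score(int i, int j) const { return s[(size_t)i * n + j]; }
};

struct GotohTables {
  int n, m;
  size_t W;
  std::vector<double> M, X, Y;    // X: gap in b (consume a), Y: gap in a
  double best;
};

static void gotoh_fill(const std::vector<int> &ai, const std::vector<int> &bi,
                       const SubstMatrix &S, double go, double ge, GotohTables &T) {
  int n = (int)ai.size(), m = (int)bi.size();
  T.n = n; T.m = m; T.W = (size_t)m + 1;
  size_t W = T.W;
  T.M.assign((size_t)(n + 1) * W, NEG);
  T.X.assign((size_t)(n + 1) * W, NEG);
  T.Y.assign((size_t)(n + 1) * W, NEG);
  T.M[0] = 0.0;
  for (int i = 1; i <= n; ++i) T.X[(size_t)i * W] = -(go + ge * i);
  for (int j = 1; j <= m; ++j) T.Y[(size_t)j] = -(go + ge * j);
  for (int i = 1; i <= n; ++i) {
    size_t r = (size_t)i * W, p = r - W;
    for (int j = 1; j <= m; ++j) {
      double d = std::max(T.M[p + j - 1], std::max(T.X[p + j - 1], T.Y[p + j - 1]));
      T.M[r + j] = d + S.score(ai[i - 1], bi[j - 1]);
      T.X[r + j] = std::max(T.M[p + j] - go - ge, T.X[p + j] - ge);
      T.Y[r + j] = std::max(T.M[r + j - 1] - go - ge, T.Y[r + j - 1] - ge);
    }
  }
  size_t e = (size_t)n * W + m;
  T.best = std::max(T.M[e], std::max(T.X[e], T.Y[e]));
}

// Traceback. Emits operations into ops: 0 = diagonal, 1 = gap in a
// (consume b), 2 = gap in b (consume a). Tie preference at every choice
// point: diagonal first, then gap in a, then gap in b.
static void gotoh_traceback(const std::vector<int> &ai, const std::vector<int> &bi,
                            const SubstMatrix &S, double go, double ge,
                            const GotohTables &T, std::vector<int> &ops) {
  int i = T.n, j = T.m;
  size_t W = T.W;
  size_t e = (size_t)i * W + j;
  int state;
  if (std::fabs(T.M[e] - T.best) < EPS) state = 0;
  else if (std::fabs(T.Y[e] - T.best) < EPS) state = 1;
  else state = 2;
  while (i > 0 || j > 0) {
    if (i == 0) state = 1;
    else if (j == 0) state = 2;
    size_t r = (size_t)i * W, p = r - W;
    if (state == 0) {
      ops.push_back(0);
      double prev = T.M[r + j] - S.score(ai[i - 1], bi[j - 1]);
      --i; --j;
      size_t q = (size_t)i * W + j;
      if (std::fabs(T.M[q] - prev) < EPS) state = 0;
      else if (std::fabs(T.Y[q] - prev) < EPS) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back(1);
      double cur = T.Y[r + j];
      double vM = T.M[r + j - 1] - go - ge;
      state = (std::fabs(vM - cur) < EPS) ? 0 : 1;
      --j;
    } else {
      ops.push_back(2);
      double cur = T.X[r + j];
      double vM = T.M[p + j] - go - ge;
      state = (std::fabs(vM - cur) < EPS) ? 0 : 2;
      --i;
    }
  }
  std::reverse(ops.begin(), ops.end());
}

static void encode(const std::string &s, const SubstMatrix &S, std::vector<int> &v) {
  v.resize(s.size());
  for (size_t k = 0; k < s.size(); ++k) v[k] = S.idx(s[k]);
}

// Needleman-Wunsch/Gotoh global alignment with affine gaps and traceback.
// [[Rcpp::export(name = ".gotoh_global_cpp")]]
List gotoh_global_cpp(std::string a, std::string b, NumericMatrix smat,
                      double gap_open, double gap_extend) {
  SubstMatrix S(smat);
  std::vector<int> ai, bi;
  encode(a, S, ai); encode(b, S, bi);
  GotohTables T;
  gotoh_fill(ai, bi, S, gap_open, gap_extend, T);
  std::vector<int> ops;
  gotoh_traceback(ai, bi, S, gap_open, gap_extend, T, ops);
  std::string ra, rb;
  ra.reserve(ops.size()); rb.reserve(ops.size());
  int i = 0, j = 0, matches = 0;
  for (size_t k = 0; k < ops.size(); ++k) {
    if (ops[k] == 0) {
      ra.push_back(a[i]); rb.push_back(b[j]);
      if (a[i] == b[j]) ++matches;
      ++i; ++j;
    } else if (ops[k] == 1) {
      ra.push_back('-'); rb.push_back(b[j]); ++j;
    } else {
      ra.push_back(a[i]); rb.push_back('-'); ++i;
    }
  }
  return List::create(_["score"] = T.best, _["aligned_a"] = ra,
                      _["aligned_b"] = rb, _["matches"] = matches,
                      _["columns"] = (int)ops.size());
}

// all-pairs percent identity (matches / alignment columns, gaps included)
// [[Rcpp::export(name = ".pairwise_identity_cpp")]]
NumericMatrix pairwise_identity_cpp(CharacterVector seqs, NumericMatrix smat,
                                    double gap_open, double gap_extend) {
  SubstMatrix S(smat);
  int n = seqs.size();
  std::vector<std::string> raw(n);
  std::vector<std::vector<int>> enc(n);
  for (int i = 0; i < n; ++i) {
    raw[i] = as<std::string>(seqs[i]);
    encode(raw[i], S, enc[i]);
  }
  NumericMatrix out(n, n);
  GotohTables T;
  std::vector<int> ops;
  for (int i = 0; i < n; ++i) {
    out(i, i) = 100.0;
    for (int j = i + 1; j < n; ++j) {
      gotoh_fill(enc[i], enc[j], S, gap_open, gap_extend, T);
      ops.clear();
      gotoh_traceback(enc[i], enc[j], S, gap_open, gap_extend, T, ops);
      int a = 0, b = 0, matches = 0;
      for (size_t k = 0; k < ops.size(); ++k) {
        if (ops[k] == 0) {
          if (raw[i][a] == raw[j][b]) ++matches;
          ++a; ++b;
        } else if (ops[k] == 1) ++b;
        else ++a;
      }
      double pid = ops.empty() ? 0.0 : 100.0 * matches / (double)ops.size();
      out(i, j) = pid; out(j, i) = pid;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Smith-Waterman local alignment score with affine gaps (score only)
// [[Rcpp::export(name = ".sw_local_cpp")]]
double sw_local_cpp(std::string a, std::string b, NumericMatrix smat,
                    double gap_open, double gap_extend) {
  SubstMatrix S(smat);
  std::vector<int> ai, bi;
  encode(a, S, ai); encode(b, S, bi);
  int n = (int)ai.size(), m = (int)bi.size();
  std::vector<double> H(m + 1, 0.0), E(m + 1, NEG), Hp(m + 1, 0.0), Ep(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double F = NEG;
    H[0] = 0.0; E[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(Hp[j] - gap_open - gap_extend, Ep[j] - gap_extend);
      F = std::max(H[j - 1] - gap_open - gap_extend, F - gap_extend);
      double v = Hp[j - 1] + S.score(ai[i - 1], bi[j - 1]);
      v = std::max(v, std::max(E[j], F));
      if (v < 0.0) v = 0.0;
      H[j] = v;
      if (v > best) best = v;
    }
    std::swap(H, Hp); std::swap(E, Ep);
  }
  return best;
}
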