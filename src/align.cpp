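#include <Rcpp.h>
using namespace Rcpp;

// Smith-Waterman local alignment with affine gaps (Gotoh), deterministic
// tie-breaking: the best cell is the highest-scoring cell with the smallest
// (row, col); traceback prefers diagonal over up (gap in target) over left
// (gap in query).  A gap of length L costs gap_open + gap_extend * L.
//
// q, t are 0-based integer encodings into the rows/cols of S.

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int n = q.size(), m = t.size();
  const double gofirst = gap_open + gap_extend;
  NumericMatrix H(n + 1, m + 1), E(n + 1, m + 1), F(n + 1, m + 1);
  const double NEG = -1e18;
  for (int j = 0; j <= m; ++j) { E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { E(i, 0) = NEG; F(i, 0) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double e = std::max(H(i, j - 1) - gofirst, E(i, j - 1) - gap_extend);
      double f = std::max(H(i - 1, j) - gofirst, F(i - 1, j) - gap_extend);
      double d = H(i - 1, j - 1) + S(q[i - 1], t[j - 1]);
      double h = 0.0;
      if (d > h) h = d;
      if (f > h) h = f;
      if (e > h) h = e;
      E(i, j) = e; F(i, j) = f; H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::vector<int> qpos, tpos;
  int i = bi, j = bj;
  int state = 0; // 0 = H, 1 = F (up), 2 = E (left)
  const double eps = 1e-9;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (H(i, j) <= 0.0) break;
      double d = H(i - 1, j - 1) + S(q[i - 1], t[j - 1]);
      if (std::abs(H(i, j) - d) < eps) {
        qpos.push_back(i); tpos.push_back(j);
        --i; --j;
      } else if (std::abs(H(i, j) - F(i, j)) < eps) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) { // gap in target: consume query
      double open = H(i - 1, j) - gofirst;
      bool closed = std::abs(F(i, j) - open) < eps;
      --i;
      if (closed) state = 0;
    } else {             // gap in query: consume target
      double open = H(i, j - 1) - gofirst;
      bool closed = std::abs(E(i, j) - open) < eps;
      --j;
      if (closed) state = 0;
    }
  }

  IntegerMatrix pairs(qpos.size(), 2);
  for (size_t k = 0; k < qpos.size(); ++k) { // reverse to ascending order
    pairs(k, 0) = qpos[qpos.size() - 1 - k];
    pairs(k, 1) = tpos[tpos.size() - 1 - k];
  }
  int qs = 0, qe = -1, ts = 0, te = -1;
  if (best > 0.0) { qs = i + 1; qe = bi; ts = j + 1; te = bj; }
  return List::create(_["score"] = best, _["pairs"] = pairs,
                      _["query_start"] = qs, _["query_end"] = qe,
                      _["target_start"] = ts, _["target_end"] = te);
}

// Exhaustive local-alignment oracle: enumerates every monotone non-empty
// matching of query/target positions; the affine gap cost between
// consecutive matched pairs is charged separately per sequence.  Feasible
// for short sequences only (the number of matchings is C(n+m, n) - 1).
static void enum_rec(const IntegerVector& q, const IntegerVector& t,
                     const NumericMatrix& S, double go, double ge,
                     int i, int j, double sc, double& best) {
  if (sc > best) best = sc;
  const int n = q.size(), m = t.size();
  const bool root = (i == 0 && j == 0);
  for (int i2 = i + 1; i2 <= n; ++i2) {
    for (int j2 = j + 1; j2 <= m; ++j2) {
      double cost = 0.0;
      if (!root) { // a local alignment starts at its first matched pair
        int gi = i2 - i - 1, gj = j2 - j - 1;
        if (gi > 0) cost += go + ge * gi;
        if (gj > 0) cost += go + ge * gj;
      }
      enum_rec(q, t, S, go, ge, i2, j2,
               sc - cost + S(q[i2 - 1], t[j2 - 1]), best);
    }
  }
}

// [[Rcpp::export]]
double sw_enumerate_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                        double gap_open, double gap_extend) {
  double best = 0.0;
  enum_rec(q, t, S, gap_open, gap_extend, 0, 0, 0.0, best);
  return best;
}

// Cleavage-window scores for every internal bond of every peptide.
// W is a 12 x 20 matrix (rows P6..P1,P1'..P6'); pep entries are 0-based
// residue encodings; positions outside the peptide contribute 0.

// [[Rcpp::export]]
List bond_scores_cpp(List peptides, NumericMatrix W) {
  const int np = peptides.size();
  List out(np);
  for (int p = 0; p < np; ++p) {
    IntegerVector pep = peptides[p];
    const int L = pep.size();
    int nb = L > 1 ? L - 1 : 0;
    NumericVector sc(nb);
    for (int c = 1; c <= nb; ++c) { // bond after residue c (1-based)
      double s = 0.0;
      for (int k = 0; k < 12; ++k) {
        int pos = c - 5 + k;        // P6 at c-5 ... P6' at c+6
        if (pos >= 1 && pos <= L) s += W(k, pep[pos - 1]);
      }
      sc[c - 1] = s;
    }
    out[p] = sc;
  }
  return out;
}
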