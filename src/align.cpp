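#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment kernels.
//
// Gap costs follow the BLAST convention: a gap of length L costs
// open + ext * L, i.e. the first gapped position already pays the
// extension penalty on top of the opening penalty.

static const int NEG = -1000000000;

// Score-only Smith-Waterman over all pairs of two sequence sets.
// Sequences are 1-based integer codes into the substitution matrix.
// When symmetric is true (a and b are the same set) only the upper
// triangle is computed and mirrored.
// [[Rcpp::export]]
IntegerMatrix sw_score_all_cpp(List a_seqs, List b_seqs, IntegerMatrix sub,
                               int open, int ext, bool symmetric) {
  int na = a_seqs.size(), nb = b_seqs.size();
  int k = sub.nrow();
  // row-major copy of the substitution matrix for cache-friendly lookup
  std::vector<int> S((size_t)k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) S[(size_t)i * k + j] = sub(i, j);

  std::vector<std::vector<int>> A(na), B(nb);
  for (int i = 0; i < na; ++i) {
    IntegerVector v = a_seqs[i];
    A[i].assign(v.begin(), v.end());
    for (size_t t = 0; t < A[i].size(); ++t) A[i][t] -= 1;
  }
  if (symmetric) {
    B = A;
    nb = na;
  } else {
    for (int i = 0; i < nb; ++i) {
      IntegerVector v = b_seqs[i];
      B[i].assign(v.begin(), v.end());
      for (size_t t = 0; t < B[i].size(); ++t) B[i][t] -= 1;
    }
  }

  IntegerMatrix out(na, nb);
  int goe = open + ext;
  std::vector<int> H, F;
  for (int ia = 0; ia < na; ++ia) {
    const std::vector<int> &a = A[ia];
    int la = (int)a.size();
    int jb0 = symmetric ? (ia + 1) : 0;
    for (int ib = jb0; ib < nb; ++ib) {
      const std::vector<int> &b = B[ib];
      int lb = (int)b.size();
      H.assign(lb + 1, 0);
      F.assign(lb + 1, NEG);
      int best = 0;
      for (int i = 1; i <= la; ++i) {
        const int *srow = &S[(size_t)a[i - 1] * k];
        int diag = 0, hprev = 0, e = NEG;
        for (int j = 1; j <= lb; ++j) {
          int hup = H[j];
          int f = F[j] - ext, f2 = hup - goe;
          if (f2 > f) f = f2;
          F[j] = f;
          int e2 = hprev - goe;
          e = e - ext;
          if (e2 > e) e = e2;
          int h = diag + srow[b[j - 1]];
          if (e > h) h = e;
          if (f > h) h = f;
          if (h < 0) h = 0;
          if (h > best) best = h;
          diag = hup;
          H[j] = h;
          hprev = h;
        }
      }
      out(ia, ib) = best;
      if (symmetric) out(ib, ia) = best;
    }
    if (symmetric) out(ia, ia) = 0;  // self comparisons are never used
  }
  return out;
}

// Full affine-gap DP with traceback over an arbitrary precomputed
// column-score matrix Sm (rows index sequence/profile a, columns b).
// Used for sequence-sequence and profile-profile alignment alike.
// local = TRUE gives Smith-Waterman, FALSE Needleman-Wunsch(-Gotoh).
// Traceback ties resolve match first, then gap-in-a (consume b),
// then gap-in-b, giving a deterministic alignment.
// Returns list(score, a_idx, b_idx): parallel vectors of 1-based
// positions with NA marking a gap in that row.
// [[Rcpp::export]]
List affine_align_cpp(NumericMatrix Sm, double open, double ext, bool local) {
  int la = Sm.nrow(), lb = Sm.ncol();
  double ninf = -1e30;
  double goe = open + ext;
  // full matrices: H (match state), E (gap in a), F (gap in b)
  NumericMatrix H(la + 1, lb + 1), E(la + 1, lb + 1), F(la + 1, lb + 1);
  for (int i = 0; i <= la; ++i)
    for (int j = 0; j <= lb; ++j) { E(i, j) = ninf; F(i, j) = ninf; }
  H(0, 0) = 0;
  for (int i = 1; i <= la; ++i) {
    F(i, 0) = -(open + ext * i);
    H(i, 0) = local ? 0 : F(i, 0);
  }
  for (int j = 1; j <= lb; ++j) {
    E(0, j) = -(open + ext * j);
    H(0, j) = local ? 0 : E(0, j);
  }
  double best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double e = std::max(E(i, j - 1) - ext, H(i, j - 1) - goe);
      double f = std::max(F(i - 1, j) - ext, H(i - 1, j) - goe);
      double h = H(i - 1, j - 1) + Sm(i - 1, j - 1);
      if (e > h) h = e;
      if (f > h) h = f;
      if (local && h < 0) h = 0;
      E(i, j) = e;
      F(i, j) = f;
      H(i, j) = h;
      if (local && h > best) { best = h; bi = i; bj = j; }
    }
  }
  std::vector<int> ai, bjv;
  double score;
  int i, j;
  if (local) {
    score = best;
    if (best <= 0)
      return List::create(_["score"] = 0.0, _["a_idx"] = IntegerVector(0),
                          _["b_idx"] = IntegerVector(0));
    i = bi; j = bj;
  } else {
    score = H(la, lb);
    i = la; j = lb;
  }
  const double tol = 1e-9;
  int state = 0;  // 0 = H, 1 = E (gap in a), 2 = F (gap in b)
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (local && std::abs(H(i, j)) <= tol) break;  // hit the zero floor
      if (i > 0 && j > 0 &&
          std::abs(H(i, j) - (H(i - 1, j - 1) + Sm(i - 1, j - 1))) <= tol) {
        ai.push_back(i); bjv.push_back(j);
        --i; --j;
      } else if (std::abs(H(i, j) - E(i, j)) <= tol) {
        state = 1;
      } else if (std::abs(H(i, j) - F(i, j)) <= tol) {
        state = 2;
      } else if (i == 0) {
        state = 1;
      } else if (j == 0) {
        state = 2;
      } else {
        stop("alignment traceback failed");
      }
    } else if (state == 1) {
      // gap in a: consume b[j]
      ai.push_back(NA_INTEGER); bjv.push_back(j);
      bool stay = (j > 1 && std::abs(E(i, j) - (E(i, j - 1) - ext)) <= tol &&
                   !(std::abs(E(i, j) - (H(i, j - 1) - goe)) <= tol));
      --j;
      if (!stay) state = 0;
    } else {
      ai.push_back(i); bjv.push_back(NA_INTEGER);
      bool stay = (i > 1 && std::abs(F(i, j) - (F(i - 1, j) - ext)) <= tol &&
                   !(std::abs(F(i, j) - (H(i - 1, j) - goe)) <= tol));
      --i;
      if (!stay) state = 0;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bjv.begin(), bjv.end());
  IntegerVector av(ai.size()), bv(bjv.size());
  for (size_t t = 0; t < ai.size(); ++t) { av[t] = ai[t]; bv[t] = bjv[t]; }
  return List::create(_["score"] = score, _["a_idx"] = av, _["b_idx"] = bv);
}
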