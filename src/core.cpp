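// Packed-bit support vectors and counting kernels.
//
// A sample bitset over n samples is stored as an R integer vector of length
// 2 * ceil(n/64); the buffer is reinterpreted as ceil(n/64) unsigned 64-bit
// words (R integer vector data is 8-byte aligned). Padding bits beyond n are
// kept at zero by construction; all kernels rely on that.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
using namespace Rcpp;

static inline int words64(int n) { return (n + 63) / 64; }

static inline const uint64_t *wptr(const IntegerVector &v) {
  return reinterpret_cast<const uint64_t *>(INTEGER(const_cast<IntegerVector &>(v)));
}
static inline uint64_t *wptr(IntegerVector &v) {
  return reinterpret_cast<uint64_t *>(INTEGER(v));
}
static inline const uint64_t *colptr(const IntegerMatrix &m, int j) {
  return reinterpret_cast<const uint64_t *>(&m(0, j));
}
static inline uint64_t *colptr(IntegerMatrix &m, int j) {
  return reinterpret_cast<uint64_t *>(&m(0, j));
}

#ifdef _MSC_VER
static inline int popcnt64(uint64_t x) {
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
}
#else
#define popcnt64 __builtin_popcountll
#endif

// [[Rcpp::export(name = ".bs_pack")]]
IntegerVector bs_pack(LogicalVector x) {
  int n = x.size(), W = words64(n > 0 ? n : 1);
  IntegerVector out(2 * W);  // zero-initialised
  uint64_t *w = wptr(out);
  for (int i = 0; i < n; ++i)
    if (x[i] == TRUE) w[i >> 6] |= (uint64_t(1) << (i & 63));
  return out;
}

// [[Rcpp::export(name = ".bs_unpack")]]
LogicalVector bs_unpack(IntegerVector b, int n) {
  LogicalVector out(n);
  const uint64_t *w = wptr(b);
  for (int i = 0; i < n; ++i)
    out[i] = (w[i >> 6] >> (i & 63)) & uint64_t(1);
  return out;
}

// [[Rcpp::export(name = ".bs_popcount")]]
int bs_popcount(IntegerVector b) {
  int W = b.size() / 2, c = 0;
  const uint64_t *w = wptr(b);
  for (int i = 0; i < W; ++i) c += popcnt64(w[i]);
  return c;
}

// [[Rcpp::export(name = ".bs_and_popcount")]]
int bs_and_popcount(IntegerVector a, IntegerVector b) {
  int W = a.size() / 2, c = 0;
  const uint64_t *wa = wptr(a), *wb = wptr(b);
  for (int i = 0; i < W; ++i) c += popcnt64(wa[i] & wb[i]);
  return c;
}

// [[Rcpp::export(name = ".bs_or")]]
IntegerVector bs_or(IntegerVector a, IntegerVector b) {
  int len = a.size();
  IntegerVector out(len);
  uint64_t *wo = wptr(out);
  const uint64_t *wa = wptr(a), *wb = wptr(b);
  for (int i = 0; i < len / 2; ++i) wo[i] = wa[i] | wb[i];
  return out;
}

// Binarize genotype rows into bitset columns.
// geno: L x n integer matrix; rows: 1-based row indices; encoding: 1 =
// dominant (bit iff value >= 1), 2 = recessive (bit iff value == 2).
// [[Rcpp::export(name = ".bm_binarize")]]
IntegerMatrix bm_binarize(IntegerMatrix geno, IntegerVector rows, int encoding) {
  int n = geno.ncol(), W = words64(n > 0 ? n : 1), m = rows.size();
  IntegerMatrix out(2 * W, m);
  for (int j = 0; j < m; ++j) {
    uint64_t *w = colptr(out, j);
    int r = rows[j] - 1;
    for (int i = 0; i < n; ++i) {
      int v = geno(r, i);
      bool bit = (encoding == 1) ? (v >= 1) : (v == 2);
      if (bit) w[i >> 6] |= (uint64_t(1) << (i & 63));
    }
  }
  return out;
}

// Columnwise OR of two bit matrices of identical shape.
// [[Rcpp::export(name = ".bm_or")]]
IntegerMatrix bm_or(IntegerMatrix a, IntegerMatrix b) {
  IntegerMatrix out(a.nrow(), a.ncol());
  const uint64_t *wa = reinterpret_cast<const uint64_t *>(INTEGER(a));
  const uint64_t *wb = reinterpret_cast<const uint64_t *>(INTEGER(b));
  uint64_t *wo = reinterpret_cast<uint64_t *>(INTEGER(out));
  R_xlen_t tot = (R_xlen_t)a.nrow() / 2 * a.ncol();
  for (R_xlen_t i = 0; i < tot; ++i) wo[i] = wa[i] | wb[i];
  return out;
}

// OR selected parent columns with selected new single-marker columns:
// out[, j] = parents[, pidx[j]] | cols[, cidx[j]]  (1-based indices).
// [[Rcpp::export(name = ".bm_or_gather")]]
IntegerMatrix bm_or_gather(IntegerMatrix parents, IntegerVector pidx,
                           IntegerMatrix cols, IntegerVector cidx) {
  int W2 = parents.nrow(), m = pidx.size();
  IntegerMatrix out(W2, m);
  int W = W2 / 2;
  for (int j = 0; j < m; ++j) {
    const uint64_t *wp = colptr(parents, pidx[j] - 1);
    const uint64_t *wc = colptr(cols, cidx[j] - 1);
    uint64_t *wo = colptr(out, j);
    for (int i = 0; i < W; ++i) wo[i] = wp[i] | wc[i];
  }
  return out;
}

// Per-stratum counts for every support column.
// supports: 2W x P; members, cases: 2W x C. Returns x (C x P) and a (C x P).
// [[Rcpp::export(name = ".bm_strat_counts")]]
List bm_strat_counts(IntegerMatrix supports, IntegerMatrix members,
                     IntegerMatrix cases) {
  int W = supports.nrow() / 2, P = supports.ncol(), C = members.ncol();
  IntegerMatrix x(C, P), a(C, P);
  for (int p = 0; p < P; ++p) {
    const uint64_t *ws = colptr(supports, p);
    for (int c = 0; c < C; ++c) {
      const uint64_t *wm = colptr(members, c), *wc = colptr(cases, c);
      int cx = 0, ca = 0;
      for (int i = 0; i < W; ++i) {
        cx += popcnt64(ws[i] & wm[i]);
        ca += popcnt64(ws[i] & wc[i]);
      }
      x(c, p) = cx;
      a(c, p) = ca;
    }
  }
  return List::create(_["x"] = x, _["a"] = a);
}

// Cross popcount table: out[p, k] = popcount(A[, p] & B[, k]).
// Used for Westfall-Young permutation case counts (B columns are permuted
// case masks, disjointness across strata makes the union count sufficient).
// [[Rcpp::export(name = ".bm_cross_popcount")]]
IntegerMatrix bm_cross_popcount(IntegerMatrix A, IntegerMatrix B) {
  int W = A.nrow() / 2, P = A.ncol(), K = B.ncol();
  IntegerMatrix out(P, K);
  for (int k = 0; k < K; ++k) {
    const uint64_t *wb = colptr(B, k);
    for (int p = 0; p < P; ++p) {
      const uint64_t *wa = colptr(A, p);
      int c = 0;
      for (int i = 0; i < W; ++i) c += popcnt64(wa[i] & wb[i]);
      out(p, k) = c;
    }
  }
  return out;
}

// Update running per-permutation maximum CMH statistic.
// S: P x K permuted case-count sums (from .bm_cross_popcount);
// esum, den: length-P expected sums and variance denominators of each
// pattern (margins are permutation-invariant); maxT: length-K running
// maxima, updated in place semantics via returned copy.
// [[Rcpp::export(name = ".wy_max_stat")]]
NumericVector wy_max_stat(IntegerMatrix S, NumericVector esum,
                          NumericVector den, NumericVector maxT) {
  int P = S.nrow(), K = S.ncol();
  NumericVector out = clone(maxT);
  for (int k = 0; k < K; ++k) {
    double m = out[k];
    for (int p = 0; p < P; ++p) {
      if (den[p] <= 0) continue;
      double d = S(p, k) - esum[p];
      double T = d * d / den[p];
      if (T > m) m = T;
    }
    out[k] = m;
  }
  return out;
}

// Descendant envelope on the CMH statistic scale.
//
// For pattern support margins x (per stratum) the minimum attainable p-value
// of any descendant, whose support is a superset so x'_c in [x_c, n_c], is
// lower-bounded by the chi-square survival function at the maximum corner
// statistic over that box. The maximum is searched over the per-stratum
// candidate set {x_c, n1_c, n_c - n1_c, n_c} clamped to [x_c, n_c] (the kinks
// and endpoints of the corner statistics), either jointly over the cartesian
// product (tight = true) or via the separable Cauchy-Schwarz bound
// (sum u)^2 / sum v <= sum_c u_c^2 / v_c, maximizing each stratum on its own
// (tight = false; provably valid for any candidate placement because each
// single-stratum corner statistic is unimodal with maximum at a candidate).
//
// x: C x P; nn, n1: length-C margins. Returns length-P max statistic.
// [[Rcpp::export(name = ".bm_envelope_T")]]
NumericVector bm_envelope_T(IntegerMatrix x, IntegerVector nn,
                            IntegerVector n1, bool tight) {
  int C = x.nrow(), P = x.ncol();
  NumericVector out(P);
  std::vector<double> candU(4 * C), candL(4 * C), candV(4 * C);
  std::vector<int> ncand(C);
  for (int p = 0; p < P; ++p) {
    // build candidate lists per stratum
    for (int c = 0; c < C; ++c) {
      double n = nn[c], m1 = n1[c], xc = x(c, p);
      int k = 0;
      if (n <= 1 || m1 <= 0 || m1 >= n) { ncand[c] = 0; continue; }
      double cand[4] = {xc, m1, n - m1, n};
      for (int t = 0; t < 4; ++t) {
        double xp = cand[t];
        if (xp < xc) xp = xc;
        if (xp > n) xp = n;
        // dedup
        bool dup = false;
        for (int s = 0; s < k; ++s)
          if (candU[4 * c + s] == xp) { dup = true; break; }
        if (dup) continue;
        candU[4 * c + k] = xp;  // temporarily store x' value
        ++k;
      }
      // convert stored x' values into (u_up, u_low, v)
      for (int s = 0; s < k; ++s) {
        double xp = candU[4 * c + s];
        double e = xp * m1 / n;
        double aU = xp < m1 ? xp : m1;
        double aL = xp - (n - m1); if (aL < 0) aL = 0;
        double v = xp * (n - xp) * m1 * (n - m1) / (n * n * (n - 1));
        candU[4 * c + s] = aU - e;   // >= 0
        candL[4 * c + s] = aL - e;   // <= 0
        candV[4 * c + s] = v;
      }
      ncand[c] = k;
    }
    double best = 0.0;
    if (!tight || C > 6) {
      // separable bound: sum of per-stratum maxima of u^2 / v
      double tot = 0.0;
      for (int c = 0; c < C; ++c) {
        double bc = 0.0;
        for (int s = 0; s < ncand[c]; ++s) {
          double v = candV[4 * c + s];
          if (v <= 0) continue;
          double tU = candU[4 * c + s] * candU[4 * c + s] / v;
          double tL = candL[4 * c + s] * candL[4 * c + s] / v;
          if (tU > bc) bc = tU;
          if (tL > bc) bc = tL;
        }
        tot += bc;
      }
      best = tot;
    } else {
      // joint maximization over the cartesian candidate product
      std::vector<int> idx(C, 0);
      bool done = false;
      while (!done) {
        double sU = 0.0, sL = 0.0, sV = 0.0;
        for (int c = 0; c < C; ++c) {
          if (ncand[c] == 0) continue;
          int s = idx[c];
          sU += candU[4 * c + s];
          sL += candL[4 * c + s];
          sV += candV[4 * c + s];
        }
        if (sV > 0) {
          double tU = sU * sU / sV, tL = sL * sL / sV;
          if (tU > best) best = tU;
          if (tL > best) best = tL;
        }
        // advance odometer (strata with no candidates are fixed)
        done = true;
        for (int c = 0; c < C; ++c) {
          if (ncand[c] <= 1) continue;
          if (++idx[c] < ncand[c]) { done = false; break; }
          idx[c] = 0;
        }
      }
    }
    out[p] = best;
  }
  return out;
}
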