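// Minimum-free-energy RNA secondary structure by dynamic programming.
//
// Energy model (kcal/mol), shared with the R-side brute-force evaluator:
//  - hairpin loop of u >= 3 unpaired nt:      hairpin_a + hairpin_b * u
//  - stacked pair (u1 = u2 = 0):              stack[outer][inner] (table)
//  - bulge/interior loop (u1 + u2 <= cap):    interior_a + interior_b * (u1+u2)
//  - multiloop, k branches (incl. closing),
//    u unpaired:                              multi_a + multi_b*k + multi_c*u
//  - exterior loop:                           0
// Pairs allowed: AU, UA, GC, CG, GU, UG; no pseudoknots.  The empty
// structure has energy 0, so the optimum is always <= 0.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e9;
static const double EPS = 1e-6;

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'U': return 3; case 'T': return 3;
  }
  return -1;
}

// pair type: AU UA GC CG GU UG -> 0..5, else -1
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 0;
  if (a == 3 && b == 0) return 1;
  if (a == 2 && b == 1) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 3) return 4;
  if (a == 3 && b == 2) return 5;
  return -1;
}

struct Fold {
  int n, maxloop;
  std::vector<int> s;
  const NumericMatrix &stack;
  double ha, hb, ia, ib, ma, mb, mc;
  std::vector<double> V, WM, WM2;
  std::vector<double> W;           // W[i] = MFE of suffix s[i..n-1], exterior
  std::vector<int> pairv;

  Fold(const std::vector<int> &seq, const NumericMatrix &st, NumericVector par)
    : n(seq.size()), maxloop((int)par["maxloop"]), s(seq), stack(st),
      ha(par["hairpin_a"]), hb(par["hairpin_b"]),
      ia(par["interior_a"]), ib(par["interior_b"]),
      ma(par["multi_a"]), mb(par["multi_b"]), mc(par["multi_c"]),
      V(n * n, INF), WM(n * n, INF), WM2(n * n, INF),
      W(n + 1, 0.0), pairv(n, -1) {}

  inline int ix(int i, int j) const { return i * n + j; }
  inline int pt(int i, int j) const { return pair_type(s[i], s[j]); }

  double two_loop(int i, int j, int p, int q) const {
    int u1 = p - i - 1, u2 = j - q - 1;
    if (u1 == 0 && u2 == 0) return stack(pt(i, j), pt(p, q));
    return ia + ib * (u1 + u2);
  }

  void run() {
    // single sweep by increasing span: V(i,j) needs V/WM2 of smaller spans,
    // WM/WM2(i,j) need V of the same cell and WM of smaller spans
    for (int span = 4; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        if (pt(i, j) >= 0) {
          double best = ha + hb * (j - i - 1);  // hairpin
          for (int p = i + 1; p <= j - 5 && p - i - 1 <= maxloop; ++p) {
            for (int q = j - 1; q >= p + 4; --q) {
              int u = (p - i - 1) + (j - q - 1);
              if (u > maxloop) break;
              if (pt(p, q) < 0 || V[ix(p, q)] >= INF / 2) continue;
              double e = two_loop(i, j, p, q) + V[ix(p, q)];
              if (e < best) best = e;
            }
          }
          if (j - i >= 11 && WM2[ix(i + 1, j - 1)] < INF / 2) {
            double e = ma + mb + WM2[ix(i + 1, j - 1)];
            if (e < best) best = e;
          }
          V[ix(i, j)] = best;
        }
        double best = INF;
        if (pt(i, j) >= 0 && V[ix(i, j)] < INF / 2)
          best = std::min(best, V[ix(i, j)] + mb);
        if (j - 1 - i >= 4 && WM[ix(i, j - 1)] < INF / 2)
          best = std::min(best, WM[ix(i, j - 1)] + mc);
        if (j - (i + 1) >= 4 && WM[ix(i + 1, j)] < INF / 2)
          best = std::min(best, WM[ix(i + 1, j)] + mc);
        double best2 = INF;
        for (int k = i + 4; k < j; ++k) {
          if (WM[ix(i, k)] >= INF / 2) continue;
          if (k + 1 <= j - 4 && WM[ix(k + 1, j)] < INF / 2) {
            double e = WM[ix(i, k)] + WM[ix(k + 1, j)];
            if (e < best2) best2 = e;
          }
        }
        // unpaired nts between/around multiloop branches are charged mc
        // through the WM factors' own unpaired options
        best = std::min(best, best2);
        WM[ix(i, j)] = best;
        WM2[ix(i, j)] = best2;
      }
    }
    W[n] = 0.0;
    if (n >= 1) W[n - 1] = 0.0;
    for (int i = n - 2; i >= 0; --i) {
      double best = W[i + 1];
      for (int j = i + 4; j < n; ++j) {
        if (pt(i, j) < 0 || V[ix(i, j)] >= INF / 2) continue;
        double e = V[ix(i, j)] + W[j + 1];
        if (e < best) best = e;
      }
      W[i] = best;
    }
  }

  void trace_V(int i, int j);
  void trace_WM(int i, int j);
  void trace_WM2(int i, int j);

  void trace_W() {
    int i = 0;
    while (i < n - 1) {
      if (std::fabs(W[i] - W[i + 1]) < EPS) { ++i; continue; }  // prefer unpaired on ties
      bool found = false;
      for (int j = i + 4; j < n && !found; ++j) {
        if (pt(i, j) < 0 || V[ix(i, j)] >= INF / 2) continue;
        if (std::fabs(V[ix(i, j)] + W[j + 1] - W[i]) < EPS) {
          pairv[i] = j; pairv[j] = i;
          trace_V(i, j);
          i = j + 1;
          found = true;
        }
      }
      if (!found) ++i;  // numerical fallback: treat as unpaired
    }
  }
};

void Fold::trace_V(int i, int j) {
  double v = V[ix(i, j)];
  if (std::fabs(v - (ha + hb * (j - i - 1))) < EPS) return;  // hairpin
  for (int p = i + 1; p <= j - 5 && p - i - 1 <= maxloop; ++p) {
    for (int q = j - 1; q >= p + 4; --q) {
      int u = (p - i - 1) + (j - q - 1);
      if (u > maxloop) break;
      if (pt(p, q) < 0 || V[ix(p, q)] >= INF / 2) continue;
      if (std::fabs(two_loop(i, j, p, q) + V[ix(p, q)] - v) < EPS) {
        pairv[p] = q; pairv[q] = p;
        trace_V(p, q);
        return;
      }
    }
  }
  if (j - i >= 6 && WM2[ix(i + 1, j - 1)] < INF / 2 &&
      std::fabs(ma + mb + WM2[ix(i + 1, j - 1)] - v) < EPS) {
    trace_WM2(i + 1, j - 1);
    return;
  }
}

void Fold::trace_WM2(int i, int j) {
  double v = WM2[ix(i, j)];
  for (int k = i + 4; k < j; ++k) {
    if (WM[ix(i, k)] >= INF / 2 || k + 1 > j - 4 ||
        WM[ix(k + 1, j)] >= INF / 2) continue;
    if (std::fabs(WM[ix(i, k)] + WM[ix(k + 1, j)] - v) < EPS) {
      trace_WM(i, k);
      trace_WM(k + 1, j);
      return;
    }
  }
}

void Fold::trace_WM(int i, int j) {
  double v = WM[ix(i, j)];
  if (pt(i, j) >= 0 && V[ix(i, j)] < INF / 2 &&
      std::fabs(V[ix(i, j)] + mb - v) < EPS) {
    pairv[i] = j; pairv[j] = i;
    trace_V(i, j);
    return;
  }
  if (j - (i + 1) >= 4 && WM[ix(i + 1, j)] < INF / 2 &&
      std::fabs(WM[ix(i + 1, j)] + mc - v) < EPS) { trace_WM(i + 1, j); return; }
  if (j - 1 - i >= 4 && WM[ix(i, j - 1)] < INF / 2 &&
      std::fabs(WM[ix(i, j - 1)] + mc - v) < EPS) { trace_WM(i, j - 1); return; }
  trace_WM2(i, j);
}

// [[Rcpp::export(name = ".fold_mfe_cpp")]]
List fold_mfe_cpp(std::string seq, NumericMatrix stack, NumericVector par) {
  int n = seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = base_idx(seq[i]);
    if (s[i] < 0) stop("invalid character '%s' at position %d",
                       std::string(1, seq[i]).c_str(), i + 1);
  }
  if (n < 5) {
    return List::create(_["energy"] = 0.0,
                        _["structure"] = std::string(n, '.'));
  }
  Fold f(s, stack, par);
  f.run();
  double mfe = f.W[0];
  std::string db(n, '.');
  if (mfe < -EPS) {
    f.trace_W();
    for (int i = 0; i < n; ++i)
      if (f.pairv[i] > i) { db[i] = '('; db[f.pairv[i]] = ')'; }
    // recompute nothing: report the DP optimum
  } else {
    mfe = 0.0;
  }
  return List::create(_["energy"] = mfe, _["structure"] = db);
}
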