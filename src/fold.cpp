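#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Simplified nested-structure energy model: per-pair energies (kT) by pair
// type, a bonus for each stacked adjacency (i,j)/(i+1,j-1), hairpin loops of
// at least min_loop unpaired nucleotides. Structure weight = exp(-E).
// All matrices are 1-based internally to match the R-side convention.

static inline int pair_type(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 1;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 3;
  return 0;
}

struct FoldModel {
  double e_gc, e_au, e_gu, e_stack;
  int min_loop;
  double pair_energy(char a, char b) const {
    switch (pair_type(a, b)) {
      case 1: return e_gc;
      case 2: return e_au;
      case 3: return e_gu;
    }
    return R_PosInf;
  }
};

// [[Rcpp::export]]
List fold_partition_cpp(std::string seq, double e_gc, double e_au,
                        double e_gu, double e_stack, int min_loop) {
  const int n = (int)seq.size();
  FoldModel mod{e_gc, e_au, e_gu, e_stack, min_loop};
  const double s = std::exp(-e_stack);

  // W(i,j): Boltzmann weight of pair (i,j) alone; 0 if disallowed
  std::vector<double> W((n + 2) * (n + 2), 0.0), Z(W), Zb(W), Zout(W);
  const int stride = n + 2;
  auto at = [stride](int i, int j) { return i * stride + j; };

  for (int i = 1; i <= n; ++i)
    for (int j = i + min_loop + 1; j <= n; ++j) {
      double e = mod.pair_energy(seq[i - 1], seq[j - 1]);
      if (std::isfinite(e)) W[at(i, j)] = std::exp(-e);
    }

  auto Zget = [&](int i, int j) { return (i > j) ? 1.0 : Z[at(i, j)]; };
  auto Zbget = [&](int i, int j) {
    return (i >= 1 && j <= n && j - i > min_loop) ? Zb[at(i, j)] : 0.0;
  };

  // inside recursions, by increasing interval length
  for (int len = 1; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (W[at(i, j)] > 0.0) {
        // interior: any structure of [i+1, j-1]; an immediately nested pair
        // (i+1, j-1) picks up the stacking bonus
        double inner = Zget(i + 1, j - 1) + (s - 1.0) * Zbget(i + 1, j - 1);
        Zb[at(i, j)] = W[at(i, j)] * inner;
      }
      // unique decomposition on the leftmost position i
      double z = Zget(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k)
        if (W[at(i, k)] > 0.0) z += Zb[at(i, k)] * Zget(k + 1, j);
      Z[at(i, j)] = z;
    }
  }
  const double Ztot = Zget(1, n);

  // outside: sum over the innermost enclosing pair (k,l); sigma carries the
  // stacking bonus when the encloser is immediately adjacent
  NumericMatrix P(n, n);
  for (int len = n; len >= min_loop + 2; --len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (W[at(i, j)] <= 0.0) continue;
      double zo = Zget(1, i - 1) * Zget(j + 1, n);
      for (int k = 1; k <= i - 1; ++k) {
        for (int l = j + 1; l <= n; ++l) {
          if (W[at(k, l)] <= 0.0) continue;
          double sigma = (k == i - 1 && l == j + 1) ? s : 1.0;
          zo += W[at(k, l)] * sigma * Zout[at(k, l)] *
                Zget(k + 1, i - 1) * Zget(j + 1, l - 1);
        }
      }
      Zout[at(i, j)] = zo;
      double p = Zb[at(i, j)] * zo / Ztot;
      P(i - 1, j - 1) = p;
      P(j - 1, i - 1) = p;
    }
  }

  NumericVector q(n);
  for (int i = 0; i < n; ++i) {
    double tot = 0.0;
    for (int j = 0; j < n; ++j) tot += P(i, j);
    q[i] = 1.0 - tot;
  }
  return List::create(_["p"] = P, _["q"] = q, _["Z"] = Ztot);
}

// ---- MFE with deterministic tie-breaking -----------------------------------
// Objective, lexicographic: (energy, number of pairs); traceback prefers the
// lexicographically smallest sorted pair set among co-optimal structures.

static const double EPS = 1e-9;

struct MfeTables {
  int n, min_loop, stride;
  double e_stack;
  std::vector<double> Epair, Eb, M;
  std::vector<int> Nb, Nm;
  int at(int i, int j) const { return i * stride + j; }
  double Mget(int i, int j) const { return (i > j) ? 0.0 : M[at(i, j)]; }
  int Nmget(int i, int j) const { return (i > j) ? 0 : Nm[at(i, j)]; }
  bool better(double e1, int n1, double e2, int n2) const {
    if (e1 < e2 - EPS) return true;
    if (e1 > e2 + EPS) return false;
    return n1 < n2;
  }
  bool equal(double e1, int n1, double e2, int n2) const {
    return std::fabs(e1 - e2) <= EPS && n1 == n2;
  }
};

static void trace_M(const MfeTables& T, int i, int j,
                    std::vector<std::pair<int, int>>& out);

static void trace_B(const MfeTables& T, int i, int j,
                    std::vector<std::pair<int, int>>& out) {
  out.push_back({i, j});
  double target = T.Eb[T.at(i, j)] - T.Epair[T.at(i, j)];
  int npt = T.Nb[T.at(i, j)] - 1;
  // interior [i+1, j-1]: prefer pairing i+1 with the smallest partner
  for (int k = i + 1 + T.min_loop + 1; k <= j - 1; ++k) {
    if (!std::isfinite(T.Eb[T.at(i + 1, k)])) continue;
    double val;
    int np;
    if (k < j - 1) {
      val = T.Eb[T.at(i + 1, k)] + T.Mget(k + 1, j - 1);
      np = T.Nb[T.at(i + 1, k)] + T.Nmget(k + 1, j - 1);
    } else {  // stacked helix continuation
      val = T.Eb[T.at(i + 1, j - 1)] + T.e_stack;
      np = T.Nb[T.at(i + 1, j - 1)];
    }
    if (T.equal(val, np, target, npt)) {
      trace_B(T, i + 1, k, out);
      if (k < j - 1) trace_M(T, k + 1, j - 1, out);
      return;
    }
  }
  trace_M(T, i + 2, j - 1, out);  // i+1 unpaired
}

static void trace_M(const MfeTables& T, int i, int j,
                    std::vector<std::pair<int, int>>& out) {
  while (i <= j) {
    double target = T.M[T.at(i, j)];
    int npt = T.Nm[T.at(i, j)];
    if (npt == 0) return;
    bool paired = false;
    for (int k = i + T.min_loop + 1; k <= j; ++k) {
      if (!std::isfinite(T.Eb[T.at(i, k)])) continue;
      double val = T.Eb[T.at(i, k)] + T.Mget(k + 1, j);
      int np = T.Nb[T.at(i, k)] + T.Nmget(k + 1, j);
      if (T.equal(val, np, target, npt)) {
        trace_B(T, i, k, out);
        i = k + 1;
        paired = true;
        break;
      }
    }
    if (!paired) i += 1;  // i unpaired
  }
}

// [[Rcpp::export]]
List fold_mfe_cpp(std::string seq, double e_gc, double e_au, double e_gu,
                  double e_stack, int min_loop) {
  const int n = (int)seq.size();
  FoldModel mod{e_gc, e_au, e_gu, e_stack, min_loop};
  MfeTables T;
  T.n = n;
  T.min_loop = min_loop;
  T.stride = n + 2;
  T.e_stack = e_stack;
  size_t sz = (size_t)(n + 2) * (n + 2);
  T.Epair.assign(sz, R_PosInf);
  T.Eb.assign(sz, R_PosInf);
  T.M.assign(sz, 0.0);
  T.Nb.assign(sz, 0);
  T.Nm.assign(sz, 0);

  for (int i = 1; i <= n; ++i)
    for (int j = i + min_loop + 1; j <= n; ++j)
      T.Epair[T.at(i, j)] = mod.pair_energy(seq[i - 1], seq[j - 1]);

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 1; i + len - 1 <= n; ++i) {
      int j = i + len - 1;
      if (std::isfinite(T.Epair[T.at(i, j)])) {
        // best interior not pairing (i+1, j-1) together
        double bE = T.Mget(i + 2, j - 1);
        int bN = T.Nmget(i + 2, j - 1);
        for (int k = i + 1 + min_loop + 1; k <= j - 2; ++k) {
          if (!std::isfinite(T.Eb[T.at(i + 1, k)])) continue;
          double e = T.Eb[T.at(i + 1, k)] + T.Mget(k + 1, j - 1);
          int np = T.Nb[T.at(i + 1, k)] + T.Nmget(k + 1, j - 1);
          if (T.better(e, np, bE, bN)) { bE = e; bN = np; }
        }
        // stacked continuation
        if (j - 1 - (i + 1) > min_loop &&
            std::isfinite(T.Eb[T.at(i + 1, j - 1)])) {
          double e = T.Eb[T.at(i + 1, j - 1)] + e_stack;
          int np = T.Nb[T.at(i + 1, j - 1)];
          if (T.better(e, np, bE, bN)) { bE = e; bN = np; }
        }
        T.Eb[T.at(i, j)] = T.Epair[T.at(i, j)] + bE;
        T.Nb[T.at(i, j)] = bN + 1;
      }
      double bE = T.Mget(i + 1, j);
      int bN = T.Nmget(i + 1, j);
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!std::isfinite(T.Eb[T.at(i, k)])) continue;
        double e = T.Eb[T.at(i, k)] + T.Mget(k + 1, j);
        int np = T.Nb[T.at(i, k)] + T.Nmget(k + 1, j);
        if (T.better(e, np, bE, bN)) { bE = e; bN = np; }
      }
      T.M[T.at(i, j)] = bE;
      T.Nm[T.at(i, j)] = bN;
    }
  }
  // shorter intervals hold no pairs: M = 0, Nm = 0 already

  std::vector<std::pair<int, int>> pairs;
  if (n > 0) trace_M(T, 1, n, pairs);
  IntegerMatrix pm(pairs.size(), 2);
  for (size_t r = 0; r < pairs.size(); ++r) {
    pm(r, 0) = pairs[r].first;
    pm(r, 1) = pairs[r].second;
  }
  return List::create(_["pairs"] = pm, _["energy"] = (n > 0) ? T.Mget(1, n) : 0.0,
                      _["npairs"] = (int)pairs.size());
}
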