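// Secondary-structure dynamic programming under a simplified per-pair
// energy model: MFE folding, McCaskill partition function and base-pair
// probabilities, all honouring hard constraints.
//
// Conventions (0-based internally, 1-based at the R interface):
//   sequence: integer code A=0, C=1, G=2, U=3
//   constraint code: 0 '.', 1 'x' (unpaired), 2 '|' (paired either side),
//                    3 '<' (paired with a downstream partner),
//                    4 '>' (paired with an upstream partner)
//   pairE: 4x4 matrix of pair energies (kcal/mol); entries >= 0 mark
//          non-canonical, disallowed pairs.
//
// The partition function uses per-nucleotide rescaling keyed to the MFE
// energy density (ViennaRNA-style) so that Z stays representable for
// n <= 500; Z is returned as log(Z).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INF = 1e18;

struct FoldCtx {
  int n;
  int mh;                 // min unpaired bases enclosed by a pair
  double kT;
  std::vector<int> s;     // sequence codes
  std::vector<int> cons;  // constraint codes
  const NumericMatrix* pairE;

  inline bool can_pair(int i, int j) const {
    if (j - i - 1 < mh) return false;
    if ((*pairE)(s[i], s[j]) >= 0.0) return false;
    int ci = cons[i], cj = cons[j];
    if (!(ci == 0 || ci == 2 || ci == 3)) return false; // i pairs downstream
    if (!(cj == 0 || cj == 2 || cj == 4)) return false; // j pairs upstream
    return true;
  }
  inline bool can_unpair(int p) const { return cons[p] == 0 || cons[p] == 1; }
  inline double e(int i, int j) const { return (*pairE)(s[i], s[j]); }
};

// W(i,j): minimal energy over interval [i, j]; left-end decomposition so
// the traceback tie-break (prefer the leftmost position paired, then the
// 5'-most partner) falls out naturally.
static void mfe_fill(const FoldCtx& C, std::vector<std::vector<double> >& W) {
  int n = C.n;
  W.assign(n + 1, std::vector<double>(n + 1, 0.0));
  // W indexed [i][j] for 0 <= i <= j < n; empty interval accessed as j < i -> 0
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i; j < n; ++j) {
      double best = C.can_unpair(i) ? W[i + 1][j] : INF;
      // interpret W[x][y] with y < x as 0 via guards
      for (int k = i + C.mh + 1; k <= j; ++k) {
        if (!C.can_pair(i, k)) continue;
        double inner = (k - 1 >= i + 1) ? W[i + 1][k - 1] : 0.0;
        double outer = (k + 1 <= j) ? W[k + 1][j] : 0.0;
        if (inner >= INF || outer >= INF) continue;
        double cand = C.e(i, k) + inner + outer;
        if (cand < best) best = cand;
      }
      W[i][j] = best;
    }
  }
}

static void mfe_traceback(const FoldCtx& C,
                          const std::vector<std::vector<double> >& W,
                          int i, int j, std::vector<int>& partner) {
  while (i <= j) {
    double target = W[i][j];
    bool paired = false;
    for (int k = i + C.mh + 1; k <= j; ++k) {
      if (!C.can_pair(i, k)) continue;
      double inner = (k - 1 >= i + 1) ? W[i + 1][k - 1] : 0.0;
      double outer = (k + 1 <= j) ? W[k + 1][j] : 0.0;
      if (inner >= INF || outer >= INF) continue;
      if (std::fabs(C.e(i, k) + inner + outer - target) < 1e-9) {
        partner[i] = k; partner[k] = i;
        if (k - 1 >= i + 1) mfe_traceback(C, W, i + 1, k - 1, partner);
        i = k + 1;  // continue on the right remainder
        paired = true;
        break;
      }
    }
    if (!paired) ++i;  // leftmost position unpaired
  }
}

// Scaled inside recursion. Qs[i][j] = Q(i,j) / c^(j-i+1); empty interval = 1.
static bool inside_fill(const FoldCtx& C, double logc,
                        std::vector<std::vector<double> >& Qs,
                        std::vector<std::vector<double> >& Qbs) {
  int n = C.n;
  double invc = std::exp(-logc), invc2 = invc * invc;
  Qs.assign(n, std::vector<double>(n, 0.0));
  Qbs.assign(n, std::vector<double>(n, 0.0));
  for (int i = n - 1; i >= 0; --i) {
    for (int j = i; j < n; ++j) {
      // paired-at-i term and Qbs row
      double acc = 0.0;
      for (int k = i + C.mh + 1; k <= j; ++k) {
        if (!C.can_pair(i, k)) continue;
        double inner = (k - 1 >= i + 1) ? Qs[i + 1][k - 1] : 1.0;
        double qb = std::exp(-C.e(i, k) / C.kT) * invc2 * inner;
        Qbs[i][k] = qb;
        double outer = (k + 1 <= j) ? Qs[k + 1][j] : 1.0;
        acc += qb * outer;
      }
      if (C.can_unpair(i)) acc += invc * ((i + 1 <= j) ? Qs[i + 1][j] : 1.0);
      Qs[i][j] = acc;
    }
  }
  return Qs[0][n - 1] > 0.0;
}

// Outside recursion for pair probabilities; O(n^4), intended for n in the
// low hundreds. Qhs(i,j) scaled by c^(n - (j-i+1)).
static void outside_fill(const FoldCtx& C, double logc,
                         const std::vector<std::vector<double> >& Qs,
                         std::vector<std::vector<double> >& Qhs) {
  int n = C.n;
  double invc2 = std::exp(-2.0 * logc);
  Qhs.assign(n, std::vector<double>(n, 0.0));
  auto Q = [&](int a, int b) -> double {  // inside over [a,b], empty = 1
    if (a > b) return 1.0;
    return Qs[a][b];
  };
  for (int span = n; span >= C.mh + 2; --span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      if (!C.can_pair(i, j)) continue;
      double acc = Q(0, i - 1) * Q(j + 1, n - 1);
      for (int k = 0; k < i; ++k) {
        for (int l = j + 1; l < n; ++l) {
          if (!C.can_pair(k, l)) continue;
          if (Qhs[k][l] == 0.0) continue;
          acc += std::exp(-C.e(k, l) / C.kT) * invc2 * Qhs[k][l] *
                 Q(k + 1, i - 1) * Q(j + 1, l - 1);
        }
      }
      Qhs[i][j] = acc;
    }
  }
}

// [[Rcpp::export(name = ".fold_dp")]]
List fold_dp(IntegerVector seq, IntegerVector cons, NumericMatrix pairE,
             int min_hairpin, double kT, bool want_pf, bool want_bpp) {
  FoldCtx C;
  C.n = seq.size();
  C.mh = min_hairpin;
  C.kT = kT;
  C.s.assign(seq.begin(), seq.end());
  C.cons.assign(cons.begin(), cons.end());
  C.pairE = &pairE;
  int n = C.n;

  std::vector<std::vector<double> > W;
  mfe_fill(C, W);
  double emfe = W[0][n - 1];
  bool sat = emfe < INF;

  IntegerVector partner(n, 0);
  if (sat) {
    std::vector<int> p(n, -1);
    mfe_traceback(C, W, 0, n - 1, p);
    for (int i = 0; i < n; ++i) partner[i] = (p[i] >= 0) ? p[i] + 1 : 0;
  }

  List out = List::create(_["satisfiable"] = sat,
                          _["partner"] = partner,
                          _["mfe_energy"] = sat ? emfe : NA_REAL);
  if (!want_pf || !sat) {
    if (want_pf) out["log_z"] = NA_REAL;
    return out;
  }

  double logc = std::max(0.0, -emfe / (kT * n));
  std::vector<std::vector<double> > Qs, Qbs;
  bool pf_ok = inside_fill(C, logc, Qs, Qbs);
  double logz = pf_ok ? std::log(Qs[0][n - 1]) + n * logc : R_NegInf;
  out["log_z"] = logz;

  if (want_bpp && pf_ok) {
    std::vector<std::vector<double> > Qhs;
    outside_fill(C, logc, Qs, Qhs);
    NumericMatrix bpp(n, n);
    double ztot = Qs[0][n - 1];
    for (int i = 0; i < n; ++i)
      for (int j = i + C.mh + 1; j < n; ++j)
        if (C.can_pair(i, j) && Qbs[i][j] > 0.0) {
          double p = Qbs[i][j] * Qhs[i][j] / ztot;
          if (p < 0) p = 0; if (p > 1) p = 1;
          bpp(i, j) = p;
        }
    out["bpp"] = bpp;
  }
  return out;
}
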