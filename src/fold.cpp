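#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Simplified nearest-neighbor energy model (kcal/mol).
//
// Pair stabilities are additive: a stack of pairs p over q contributes
// v(p) + v(q), which makes the model exactly symmetric under
// reverse-complementation. Loop penalties are linear in loop size. The model
// is deliberately small enough to verify by exhaustive enumeration (the pure
// R oracle in R/fold-oracle.R mirrors these constants).
static const double V_AU = -1.1;  // A:U and U:A
static const double V_GC = -2.2;  // G:C and C:G
static const double V_GU = -0.8;  // G:U and U:G wobble
static const double HAIRPIN_BASE = 4.5;   // loop of 3 unpaired nt
static const double HAIRPIN_PER_NT = 0.3; // per extra unpaired nt
static const double LOOP_BASE = 2.0;      // bulge / internal loop
static const double LOOP_PER_NT = 0.5;
static const double ML_CLOSE = 3.4;       // multiloop closing penalty
static const double ML_BRANCH = 0.4;      // per branch helix
static const double ML_UNPAIRED = 0.1;    // per unpaired nt in a multiloop
static const int MIN_HAIRPIN = 3;         // steric minimum loop size
static const int MAXLOOP = 30;            // interior-loop size cap in the DP
static const double INF = 1e9;
static const double EPS = 1e-9;

// bases coded 0=A, 1=C, 2=G, 3=U(T)
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1; // AU
  if (a == 3 && b == 0) return 2; // UA
  if (a == 2 && b == 1) return 3; // GC
  if (a == 1 && b == 2) return 4; // CG
  if (a == 2 && b == 3) return 5; // GU
  if (a == 3 && b == 2) return 6; // UG
  return 0;
}

static inline double pair_v(int pt) {
  switch (pt) {
    case 1: case 2: return V_AU;
    case 3: case 4: return V_GC;
    case 5: case 6: return V_GU;
    default: return 0.0;
  }
}

static inline double hairpin_e(int L) {
  return HAIRPIN_BASE + HAIRPIN_PER_NT * (L - MIN_HAIRPIN);
}

static inline double loop_e(int u) { return LOOP_BASE + LOOP_PER_NT * u; }

struct FoldDP {
  int n;
  const std::vector<int>& s;
  const std::vector<bool>& forbid;
  std::vector<double> V, WM, WMT; // WMT = transposed WM for cache locality
  std::vector<double> W;
  std::vector<int> partner;

  FoldDP(const std::vector<int>& seq, const std::vector<bool>& fb)
    : n((int)seq.size()), s(seq), forbid(fb),
      V((size_t)n * n, INF), WM((size_t)n * n, INF),
      WMT((size_t)n * n, INF), W(n + 1, 0.0), partner(n, -1) {}

  inline double& v_at(int i, int j) { return V[(size_t)i * n + j]; }
  inline double& wm_at(int i, int j) { return WM[(size_t)i * n + j]; }
  inline double& wmt_at(int i, int j) { return WMT[(size_t)j * n + i]; }

  inline bool can_pair(int i, int j) const {
    return j - i - 1 >= MIN_HAIRPIN && !forbid[i] && !forbid[j] &&
           pair_type(s[i], s[j]) > 0;
  }

  void fill() {
    for (int span = MIN_HAIRPIN + 1; span < n; ++span) {
      for (int i = 0; i + span < n; ++i) {
        int j = i + span;
        // V(i,j): energy given i pairs j
        double best = INF;
        if (can_pair(i, j)) {
          best = hairpin_e(j - i - 1);
          int pt_out = pair_type(s[i], s[j]);
          for (int k = i + 1; k <= j - 1 && k - i - 1 <= MAXLOOP; ++k) {
            for (int l = j - 1; l > k; --l) {
              int u1 = k - i - 1, u2 = j - l - 1;
              if (u1 + u2 > MAXLOOP) break;
              double vin = v_at(k, l);
              if (vin >= INF / 2) continue;
              double e;
              if (u1 == 0 && u2 == 0) {
                e = vin + pair_v(pt_out) + pair_v(pair_type(s[k], s[l]));
              } else {
                e = vin + loop_e(u1 + u2);
              }
              if (e < best) best = e;
            }
          }
          // multiloop: split into two WM segments (>= 1 branch each);
          // row of WM(i+1, .) and row of WMT(., j-1) are both contiguous
          {
            const double* wmrow = &WM[(size_t)(i + 1) * n];
            const double* wmtrow = &WMT[(size_t)(j - 1) * n];
            for (int k = i + 5; k <= j - 6; ++k) {
              double e1 = wmrow[k], e2 = wmtrow[k + 1];
              if (e1 >= INF / 2 || e2 >= INF / 2) continue;
              double e = ML_CLOSE + ML_BRANCH + e1 + e2;
              if (e < best) best = e;
            }
          }
        }
        v_at(i, j) = best;

        // WM(i,j): >= 1 branch inside a multiloop
        double wm = INF;
        if (wm_at(i + 1, j) < INF / 2)
          wm = std::min(wm, wm_at(i + 1, j) + ML_UNPAIRED);
        if (wm_at(i, j - 1) < INF / 2)
          wm = std::min(wm, wm_at(i, j - 1) + ML_UNPAIRED);
        if (best < INF / 2) wm = std::min(wm, best + ML_BRANCH);
        {
          const double* wmrow = &WM[(size_t)i * n];
          const double* wmtrow = &WMT[(size_t)j * n];
          for (int k = i + 4; k <= j - 5; ++k) {
            double e1 = wmrow[k], e2 = wmtrow[k + 1];
            if (e1 >= INF / 2 || e2 >= INF / 2) continue;
            if (e1 + e2 < wm) wm = e1 + e2;
          }
        }
        wm_at(i, j) = wm;
        wmt_at(i, j) = wm;
      }
    }
    // short spans: WM base cases (no pair possible)
    // external loop
    for (int j = 1; j <= n; ++j) {
      double best = W[j - 1]; // j-th base (0-based j-1) unpaired
      for (int i = 1; i <= j; ++i) {
        double v = (j - i >= MIN_HAIRPIN + 1) ? v_at(i - 1, j - 1) : INF;
        if (v >= INF / 2) continue;
        double e = W[i - 1] + v;
        if (e < best) best = e;
      }
      W[j] = best;
    }
  }

  void trace_v(int i, int j) {
    partner[i] = j;
    partner[j] = i;
    double target = v_at(i, j);
    if (std::abs(target - hairpin_e(j - i - 1)) < EPS) return;
    int pt_out = pair_type(s[i], s[j]);
    for (int k = i + 1; k <= j - 1 && k - i - 1 <= MAXLOOP; ++k) {
      for (int l = j - 1; l > k; --l) {
        int u1 = k - i - 1, u2 = j - l - 1;
        if (u1 + u2 > MAXLOOP) break;
        double vin = v_at(k, l);
        if (vin >= INF / 2) continue;
        double e = (u1 == 0 && u2 == 0)
          ? vin + pair_v(pt_out) + pair_v(pair_type(s[k], s[l]))
          : vin + loop_e(u1 + u2);
        if (std::abs(e - target) < EPS) { trace_v(k, l); return; }
      }
    }
    for (int k = i + 1; k <= j - 2; ++k) {
      double e1 = wm_at(i + 1, k), e2 = wm_at(k + 1, j - 1);
      if (e1 >= INF / 2 || e2 >= INF / 2) continue;
      if (std::abs(ML_CLOSE + ML_BRANCH + e1 + e2 - target) < EPS) {
        trace_wm(i + 1, k);
        trace_wm(k + 1, j - 1);
        return;
      }
    }
    Rcpp::stop("fold traceback failed (V)");
  }

  void trace_wm(int i, int j) {
    double target = wm_at(i, j);
    if (i + 1 <= j && wm_at(i + 1, j) < INF / 2 &&
        std::abs(wm_at(i + 1, j) + ML_UNPAIRED - target) < EPS) {
      trace_wm(i + 1, j); return;
    }
    if (i <= j - 1 && wm_at(i, j - 1) < INF / 2 &&
        std::abs(wm_at(i, j - 1) + ML_UNPAIRED - target) < EPS) {
      trace_wm(i, j - 1); return;
    }
    if (v_at(i, j) < INF / 2 &&
        std::abs(v_at(i, j) + ML_BRANCH - target) < EPS) {
      trace_v(i, j); return;
    }
    for (int k = i + 1; k <= j - 1; ++k) {
      double e1 = wm_at(i, k), e2 = wm_at(k + 1, j);
      if (e1 >= INF / 2 || e2 >= INF / 2) continue;
      if (std::abs(e1 + e2 - target) < EPS) {
        trace_wm(i, k); trace_wm(k + 1, j); return;
      }
    }
    Rcpp::stop("fold traceback failed (WM)");
  }

  void trace() {
    int j = n;
    while (j >= 1) {
      if (std::abs(W[j] - W[j - 1]) < EPS) { --j; continue; }
      bool found = false;
      for (int i = 1; i <= j; ++i) {
        double v = (j - i >= MIN_HAIRPIN + 1) ? v_at(i - 1, j - 1) : INF;
        if (v >= INF / 2) continue;
        if (std::abs(W[i - 1] + v - W[j]) < EPS) {
          trace_v(i - 1, j - 1);
          j = i - 1;
          found = true;
          break;
        }
      }
      if (!found) Rcpp::stop("fold traceback failed (W)");
    }
  }
};

static std::vector<int> as_codes(const IntegerVector& s) {
  std::vector<int> v(s.size());
  for (int i = 0; i < s.size(); ++i) v[i] = s[i];
  return v;
}

// [[Rcpp::export(name = ".c_fold")]]
List c_fold(IntegerVector seq, LogicalVector forbid) {
  int n = seq.size();
  if (n == 0) stop("empty sequence");
  std::vector<int> s = as_codes(seq);
  std::vector<bool> fb(n, false);
  for (int i = 0; i < n; ++i) fb[i] = forbid[i];
  FoldDP dp(s, fb);
  if (n > MIN_HAIRPIN + 1) dp.fill();
  double mfe = (n >= 1) ? dp.W[n] : 0.0;
  if (mfe > 0) mfe = 0.0; // empty structure always available
  if (n > MIN_HAIRPIN + 1 && dp.W[n] < -EPS) dp.trace();
  std::string db(n, '.');
  IntegerVector partner(n, 0);
  for (int i = 0; i < n; ++i) {
    if (dp.partner[i] >= 0) {
      partner[i] = dp.partner[i] + 1;
      db[i] = (dp.partner[i] > i) ? '(' : ')';
    }
  }
  double energy = (dp.n > MIN_HAIRPIN + 1 && dp.W[n] < -EPS) ? dp.W[n] : 0.0;
  return List::create(_["energy"] = energy,
                      _["structure"] = db,
                      _["partner"] = partner);
}

// [[Rcpp::export(name = ".c_duplex")]]
double c_duplex(IntegerVector a, IntegerVector b) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<int> av = as_codes(a), bv = as_codes(b);
  std::vector<double> D((size_t)n * m, INF);
  double best = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = m - 1; j >= 0; --j) {
      int pt = pair_type(av[i], bv[j]);
      if (pt == 0) continue;
      double d = 0.0; // first (5'-most on a) pair of the duplex
      for (int i2 = 0; i2 < i; ++i2) {
        for (int j2 = j + 1; j2 < m; ++j2) {
          double prev = D[(size_t)i2 * m + j2];
          if (prev >= INF / 2) continue;
          int u1 = i - i2 - 1, u2 = j2 - j - 1;
          double cost = (u1 == 0 && u2 == 0)
            ? pair_v(pair_type(av[i2], bv[j2])) + pair_v(pt)
            : loop_e(u1 + u2);
          if (prev + cost < d) d = prev + cost;
        }
      }
      D[(size_t)i * m + j] = d;
      if (d < best) best = d;
    }
  }
  return best;
}
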