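// Nearest-neighbour secondary-structure dynamic programming.
//
// Two engines: (1) Nussinov base-pair maximization (small-instance oracle and
// teaching baseline); (2) a Zuker-style minimum-free-energy folder with
// hairpin/stack/bulge/internal/multibranch loop terms. The MFE folder accepts
// an optional per-pair penalty matrix used by the suboptimal-enumeration
// driver on the R side. Energies in kcal/mol. All indices 0-based internally,
// 1-based in the returned pair lists.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const double INF = 1e9;

// base codes: 0=A 1=C 2=G 3=U (T is mapped to U on the R side)
// pair types: 1=AU 2=UA 3=GC 4=CG 5=GU 6=UG, 0 = not allowed
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 2 && b == 1) return 3;
  if (a == 1 && b == 2) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

struct EModel {
  double stack[7][7];                 // [outer pair type][inner pair type]
  std::vector<double> hairpin;        // index = loop size (0 unused)
  std::vector<double> bulge;
  std::vector<double> internal_;
  double ml_a, ml_b, ml_c;            // multiloop: closing + per-branch + per-unpaired
  double loop_coef;                   // log extrapolation coefficient beyond table end
  int min_loop, max_internal;
};

static std::vector<double> table_from_R(NumericVector v) {
  // v[k] is the penalty for loop size k+1
  std::vector<double> t(v.size() + 1, INF);
  for (int k = 0; k < v.size(); ++k)
    t[k + 1] = NumericVector::is_na(v[k]) || !R_finite(v[k]) ? INF : v[k];
  return t;
}

static EModel model_from_R(List model) {
  EModel m;
  NumericMatrix st = model["stack"];
  if (st.nrow() != 6 || st.ncol() != 6) stop("stack table must be 6x6");
  for (int a = 1; a <= 6; ++a)
    for (int b = 1; b <= 6; ++b)
      m.stack[a][b] = st(a - 1, b - 1);
  m.hairpin   = table_from_R(model["hairpin"]);
  m.bulge     = table_from_R(model["bulge"]);
  m.internal_ = table_from_R(model["internal"]);
  m.ml_a = as<double>(model["ml_a"]);
  m.ml_b = as<double>(model["ml_b"]);
  m.ml_c = as<double>(model["ml_c"]);
  m.loop_coef = as<double>(model["loop_coef"]);
  m.min_loop = as<int>(model["min_loop"]);
  m.max_internal = as<int>(model["max_internal"]);
  return m;
}

static inline double loop_pen(const std::vector<double>& tab, int L, double coef) {
  if (L <= 0) return INF;
  int last = (int)tab.size() - 1;
  if (L <= last) return tab[L];
  return tab[last] + coef * std::log((double)L / last);
}

// ---------------------------------------------------------------- Nussinov

// [[Rcpp::export(name = ".nussinov_cpp")]]
List nussinov_cpp(IntegerVector seq, int min_loop) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<int> N((size_t)n * n, 0);
  auto idx = [n](int i, int j) { return (size_t)i * n + j; };

  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = N[idx(i + 1, j)];                       // i unpaired
      for (int k = i + min_loop + 1; k <= j; ++k) {      // i pairs k
        if (!pair_type(s[i], s[k])) continue;
        int inner = (k - 1 >= i + 1) ? N[idx(i + 1, k - 1)] : 0;
        int outer = (k + 1 <= j) ? N[idx(k + 1, j)] : 0;
        int cand = inner + outer + 1;
        if (cand > best) best = cand;
      }
      N[idx(i, j)] = best;
    }
  }

  // traceback: prefer pairing the 5'-most base, with the 3'-most partner
  std::vector<std::pair<int, int>> pairs;
  std::vector<std::pair<int, int>> todo;
  if (n > 0) todo.push_back({0, n - 1});
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (j - i < min_loop + 1) continue;
    int target = N[idx(i, j)];
    if (target == 0) continue;
    bool paired = false;
    for (int k = j; k >= i + min_loop + 1; --k) {
      if (!pair_type(s[i], s[k])) continue;
      int inner = (k - 1 >= i + 1) ? N[idx(i + 1, k - 1)] : 0;
      int outer = (k + 1 <= j) ? N[idx(k + 1, j)] : 0;
      if (inner + outer + 1 == target) {
        pairs.push_back({i, k});
        if (k - 1 > i + 1 - 1) todo.push_back({i + 1, k - 1});
        if (k + 1 <= j) todo.push_back({k + 1, j});
        paired = true;
        break;
      }
    }
    if (!paired) todo.push_back({i + 1, j});
  }

  IntegerMatrix pm(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    pm(k, 0) = pairs[k].first + 1;
    pm(k, 1) = pairs[k].second + 1;
  }
  return List::create(_["max_pairs"] = n > 0 ? N[idx(0, n - 1)] : 0,
                      _["pairs"] = pm);
}

// ---------------------------------------------------------------- Zuker MFE

struct Folder {
  int n;
  std::vector<int> s;
  EModel m;
  std::vector<double> V, WM;
  std::vector<double> W;
  const double* pen;   // n*n penalty matrix or nullptr
  double eps = 1e-7;

  size_t idx(int i, int j) const { return (size_t)i * n + j; }
  double v(int i, int j)  const { return (i >= 0 && j < n && j - i > m.min_loop) ? V[idx(i, j)] : INF; }
  double wm(int i, int j) const { return (i >= 0 && j < n && i <= j) ? WM[idx(i, j)] : INF; }
  double wext(int j) const { return j < 0 ? 0.0 : W[j]; }
  double penalty(int i, int j) const { return pen ? pen[idx(i, j)] : 0.0; }

  double hp(int L) const { return loop_pen(m.hairpin, L, m.loop_coef); }
  double bp(int L) const { return loop_pen(m.bulge, L, m.loop_coef); }
  double ip(int L) const { return loop_pen(m.internal_, L, m.loop_coef); }

  void fill() {
    V.assign((size_t)n * n, INF);
    WM.assign((size_t)n * n, INF);
    W.assign(n, 0.0);

    for (int len = m.min_loop + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        int pt = pair_type(s[i], s[j]);
        double best = INF;
        if (pt) {
          best = hp(j - i - 1);
          // stack
          int pti = pair_type(s[i + 1], s[j - 1]);
          if (pti) {
            double in = v(i + 1, j - 1);
            if (in < INF / 2) best = std::min(best, m.stack[pt][pti] + in);
          }
          // bulge / internal, total unpaired 1..max_internal
          for (int n1 = 0; n1 <= m.max_internal; ++n1) {
            int h = i + 1 + n1;
            if (h + m.min_loop + 1 >= j) break;
            int n2max = m.max_internal - n1;
            for (int n2 = (n1 == 0 ? 1 : 0); n2 <= n2max; ++n2) {
              int l = j - 1 - n2;
              if (l <= h + m.min_loop) break;
              double in = v(h, l);
              if (in >= INF / 2) continue;
              double lp = (n1 == 0 || n2 == 0) ? bp(n1 + n2) : ip(n1 + n2);
              best = std::min(best, in + lp);
            }
          }
          // multiloop: >= 2 branches inside
          for (int k = i + 2; k <= j - 2; ++k) {
            double a1 = wm(i + 1, k - 1), a2 = wm(k, j - 1);
            if (a1 < INF / 2 && a2 < INF / 2)
              best = std::min(best, m.ml_a + a1 + a2);
          }
          if (best < INF / 2) best += penalty(i, j);
        }
        V[idx(i, j)] = best;
      }
      // WM over the same spans (needs V of this span)
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double best = INF;
        double vv = V[idx(i, j)];
        if (vv < INF / 2) best = vv + m.ml_b;
        double a = wm(i + 1, j);
        if (a < INF / 2) best = std::min(best, a + m.ml_c);
        a = wm(i, j - 1);
        if (a < INF / 2) best = std::min(best, a + m.ml_c);
        for (int k = i + 1; k <= j; ++k) {
          double a1 = wm(i, k - 1), a2 = wm(k, j);
          if (a1 < INF / 2 && a2 < INF / 2) best = std::min(best, a1 + a2);
        }
        WM[idx(i, j)] = best;
      }
    }
    // short spans of WM (can hold no branch) stay INF; W external
    for (int j = 0; j < n; ++j) {
      double best = wext(j - 1);            // j unpaired
      for (int i = 0; i + m.min_loop + 1 <= j; ++i) {
        double vv = V[idx(i, j)];
        if (vv < INF / 2) best = std::min(best, wext(i - 1) + vv);
      }
      W[j] = best;
    }
  }

  // --- traceback ---
  enum Task { TB_W, TB_V, TB_WM };
  std::vector<std::pair<int, int>> pairs;

  void traceback() {
    pairs.clear();
    std::vector<std::pair<Task, std::pair<int, int>>> todo;
    if (n > 0) todo.push_back({TB_W, {0, n - 1}});
    while (!todo.empty()) {
      auto t = todo.back();
      todo.pop_back();
      int i = t.second.first, j = t.second.second;
      switch (t.first) {
      case TB_W: {
        // region is 0..j; find how j is resolved
        while (j >= 0) {
          if (std::fabs(W[j] - wext(j - 1)) < eps) { --j; continue; }
          bool found = false;
          for (int i2 = 0; i2 + m.min_loop + 1 <= j; ++i2) {
            double vv = V[idx(i2, j)];
            if (vv < INF / 2 && std::fabs(wext(i2 - 1) + vv - W[j]) < eps) {
              todo.push_back({TB_V, {i2, j}});
              j = i2 - 1;
              found = true;
              break;
            }
          }
          if (!found) stop("internal error: external traceback failed");
        }
        break;
      }
      case TB_V: {
        pairs.push_back({i, j});
        int pt = pair_type(s[i], s[j]);
        double target = V[idx(i, j)] - penalty(i, j);
        if (std::fabs(hp(j - i - 1) - target) < eps) break;
        int pti = pair_type(s[i + 1], s[j - 1]);
        if (pti) {
          double in = v(i + 1, j - 1);
          if (in < INF / 2 && std::fabs(m.stack[pt][pti] + in - target) < eps) {
            todo.push_back({TB_V, {i + 1, j - 1}});
            goto done_v;
          }
        }
        for (int n1 = 0; n1 <= m.max_internal; ++n1) {
          int h = i + 1 + n1;
          if (h + m.min_loop + 1 >= j) break;
          for (int n2 = (n1 == 0 ? 1 : 0); n2 <= m.max_internal - n1; ++n2) {
            int l = j - 1 - n2;
            if (l <= h + m.min_loop) break;
            double in = v(h, l);
            if (in >= INF / 2) continue;
            double lp = (n1 == 0 || n2 == 0) ? bp(n1 + n2) : ip(n1 + n2);
            if (std::fabs(in + lp - target) < eps) {
              todo.push_back({TB_V, {h, l}});
              goto done_v;
            }
          }
        }
        for (int k = i + 2; k <= j - 2; ++k) {
          double a1 = wm(i + 1, k - 1), a2 = wm(k, j - 1);
          if (a1 < INF / 2 && a2 < INF / 2 &&
              std::fabs(m.ml_a + a1 + a2 - target) < eps) {
            todo.push_back({TB_WM, {i + 1, k - 1}});
            todo.push_back({TB_WM, {k, j - 1}});
            goto done_v;
          }
        }
        stop("internal error: V traceback failed");
        done_v: break;
      }
      case TB_WM: {
        double target = WM[idx(i, j)];
        double vv = v(i, j);
        if (vv < INF / 2 && std::fabs(vv + m.ml_b - target) < eps) {
          todo.push_back({TB_V, {i, j}});
          break;
        }
        double a = wm(i + 1, j);
        if (a < INF / 2 && std::fabs(a + m.ml_c - target) < eps) {
          todo.push_back({TB_WM, {i + 1, j}});
          break;
        }
        a = wm(i, j - 1);
        if (a < INF / 2 && std::fabs(a + m.ml_c - target) < eps) {
          todo.push_back({TB_WM, {i, j - 1}});
          break;
        }
        {
          bool found = false;
          for (int k = i + 1; k <= j; ++k) {
            double a1 = wm(i, k - 1), a2 = wm(k, j);
            if (a1 < INF / 2 && a2 < INF / 2 &&
                std::fabs(a1 + a2 - target) < eps) {
              todo.push_back({TB_WM, {i, k - 1}});
              todo.push_back({TB_WM, {k, j}});
              found = true;
              break;
            }
          }
          if (!found) stop("internal error: WM traceback failed");
        }
        break;
      }
      }
    }
  }
};

// [[Rcpp::export(name = ".zuker_fold_cpp")]]
List zuker_fold_cpp(IntegerVector seq, List model,
                    Nullable<NumericMatrix> penalty = R_NilValue) {
  Folder f;
  f.n = seq.size();
  f.s.assign(seq.begin(), seq.end());
  f.m = model_from_R(model);
  NumericMatrix pm;
  f.pen = nullptr;
  if (penalty.isNotNull()) {
    pm = penalty.get();
    if (pm.nrow() != f.n || pm.ncol() != f.n) stop("penalty matrix has wrong size");
    f.pen = REAL(pm);
  }
  double energy = 0.0;
  if (f.n > f.m.min_loop + 1) {
    f.fill();
    energy = f.W[f.n - 1];
    f.traceback();
  }
  IntegerMatrix out(f.pairs.size(), 2);
  for (size_t k = 0; k < f.pairs.size(); ++k) {
    out(k, 0) = f.pairs[k].first + 1;
    out(k, 1) = f.pairs[k].second + 1;
  }
  return List::create(_["pairs"] = out, _["energy"] = energy);
}
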