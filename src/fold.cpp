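#include <Rcpp.h>
#include <vector>
#include <utility>
#include <array>
#include <cmath>
using namespace Rcpp;

// Base encoding fixed by the R wrappers: A=0, C=1, G=2, U=3.
// Pair types index the 6x6 stacking table: 1 AU, 2 UA, 3 CG, 4 GC, 5 GU, 6 UG.
static inline int pair_type(int a, int b) {
  if (a == 0 && b == 3) return 1;
  if (a == 3 && b == 0) return 2;
  if (a == 1 && b == 2) return 3;
  if (a == 2 && b == 1) return 4;
  if (a == 2 && b == 3) return 5;
  if (a == 3 && b == 2) return 6;
  return 0;
}

static const double BIG = 1e9;
static const double EPS = 1e-9;

// Minimum-energy fold under a stacking-plus-initiation nearest-neighbour
// model.  A helix of k pairs scores the sum of its k-1 stack terms plus one
// helix_init penalty; unpaired bases and loops are otherwise free.  Hairpin
// loops must hold >= min_loop unpaired bases.
// V(i,j): minimum energy over structures on [i..j] in which (i,j) is paired,
//         excluding the initiation charge of the helix that (i,j) heads.
// W(i,j): minimum energy over all structures on [i..j] (inits included).
// Traceback prefers leaving a base unpaired on energy ties, so pairs appear
// only where they strictly lower the energy (a 0-energy fold is all dots),
// and splits take the 5'-most partner that achieves the minimum.
// [[Rcpp::export]]
List fold_mfe_cpp(IntegerVector seq, NumericMatrix stack, int min_loop,
                  double helix_init) {
  int n = seq.size();
  IntegerVector partner(n, 0);
  if (n < min_loop + 2)
    return List::create(_["energy"] = 0.0, _["partner"] = partner);

  std::vector<int> s(seq.begin(), seq.end());
  std::vector<double> V((size_t)n * n, BIG), W((size_t)n * n, 0.0);
  #define IDX(i, j) ((size_t)(i) * n + (j))

  for (int span = min_loop + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      int pt = pair_type(s[i], s[j]);
      if (pt && j - i - 1 >= min_loop) {
        double v = W[IDX(i + 1, j - 1)];
        int pti = pair_type(s[i + 1], s[j - 1]);
        if (pti && (j - 1) - (i + 1) - 1 >= min_loop) {
          double cand = stack(pt - 1, pti - 1) + V[IDX(i + 1, j - 1)];
          if (cand < v) v = cand;
        }
        V[IDX(i, j)] = v;
      }
      double w = W[IDX(i + 1, j)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (V[IDX(i, k)] >= BIG / 2) continue;
        double c = helix_init + V[IDX(i, k)] +
          (k + 1 <= j ? W[IDX(k + 1, j)] : 0.0);
        if (c < w - EPS) w = c;
      }
      W[IDX(i, j)] = w;
    }
  }

  // traceback: frames are (i, j, mode) with mode 0 = W, 1 = V
  std::vector<std::array<int, 3>> todo;
  todo.push_back({0, n - 1, 0});
  while (!todo.empty()) {
    std::array<int, 3> fr = todo.back();
    todo.pop_back();
    int i = fr[0], j = fr[1], mode = fr[2];
    if (j - i + 1 < min_loop + 2) continue;
    if (mode == 0) {
      double w = W[IDX(i, j)];
      if (w > -EPS) continue;  // 0-energy interval: all unpaired
      if (std::abs(w - W[IDX(i + 1, j)]) < EPS) {
        todo.push_back({i + 1, j, 0});
        continue;
      }
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (V[IDX(i, k)] >= BIG / 2) continue;
        double c = helix_init + V[IDX(i, k)] +
          (k + 1 <= j ? W[IDX(k + 1, j)] : 0.0);
        if (std::abs(c - w) < EPS) {
          partner[i] = k + 1;  // 1-based
          partner[k] = i + 1;
          todo.push_back({i, k, 1});
          if (k + 1 <= j) todo.push_back({k + 1, j, 0});
          break;
        }
      }
    } else {
      // (i,j) is paired; decide whether (i+1,j-1) continues the helix
      double v = V[IDX(i, j)];
      if (std::abs(v - W[IDX(i + 1, j - 1)]) < EPS) {
        todo.push_back({i + 1, j - 1, 0});
        continue;
      }
      partner[i + 1] = j;      // position i+1 pairs with j-1 (1-based values)
      partner[j - 1] = i + 2;
      todo.push_back({i + 1, j - 1, 1});
    }
  }

  return List::create(_["energy"] = W[IDX(0, n - 1)], _["partner"] = partner);
  #undef IDX
}

// ---------------------------------------------------------------------------
// Exhaustive-enumeration oracle.  Deliberately naive and independent of the
// DP above: it generates every valid secondary structure by interval
// recursion (no memoisation) and scores each complete structure with a
// separate linear scan that adds one stack term per adjacently nested pair.
// Used only to validate fold_mfe_cpp on short sequences.
namespace {

struct EnumState {
  const std::vector<int>* s;
  const NumericMatrix* stack;
  int min_loop;
  int n;
  double helix_init;
  std::vector<int> partner;  // -1 unpaired
  double best;
  long long count;
  long long max_structures;
};

double score_structure(const EnumState& st) {
  double e = 0.0;
  for (int i = 0; i < st.n; ++i) {
    int j = st.partner[i];
    if (j > i) {
      // helix head (no enclosing stacked pair) pays the initiation charge
      if (!(i - 1 >= 0 && j + 1 < st.n && st.partner[i - 1] == j + 1)) {
        e += st.helix_init;
      }
      if (i + 1 < st.n && st.partner[i + 1] == j - 1 && j - 1 > i + 1) {
        int pt  = pair_type((*st.s)[i], (*st.s)[j]);
        int pti = pair_type((*st.s)[i + 1], (*st.s)[j - 1]);
        e += (*st.stack)(pt - 1, pti - 1);
      }
    }
  }
  return e;
}

void enum_rec(EnumState& st, std::vector<std::pair<int, int>>& todo) {
  if (todo.empty()) {
    double e = score_structure(st);
    if (e < st.best) st.best = e;
    if (++st.count > st.max_structures)
      stop("structure enumeration exceeded max_structures");
    return;
  }
  std::pair<int, int> iv = todo.back();
  todo.pop_back();
  int i = iv.first, j = iv.second;
  if (j - i < st.min_loop + 1) {
    // too short to hold any pair: every base stays unpaired
    enum_rec(st, todo);
  } else {
    // i unpaired
    todo.push_back(std::make_pair(i + 1, j));
    enum_rec(st, todo);
    todo.pop_back();
    // i paired with k
    for (int k = i + st.min_loop + 1; k <= j; ++k) {
      if (!pair_type((*st.s)[i], (*st.s)[k])) continue;
      st.partner[i] = k;
      st.partner[k] = i;
      todo.push_back(std::make_pair(k + 1, j));
      todo.push_back(std::make_pair(i + 1, k - 1));
      enum_rec(st, todo);
      todo.pop_back();
      todo.pop_back();
      st.partner[i] = -1;
      st.partner[k] = -1;
    }
  }
  todo.push_back(iv);
}

}  // namespace

// [[Rcpp::export]]
List enumerate_mfe_cpp(IntegerVector seq, NumericMatrix stack, int min_loop,
                       double helix_init, double max_structures) {
  int n = seq.size();
  EnumState st;
  std::vector<int> s(seq.begin(), seq.end());
  st.s = &s;
  st.stack = &stack;
  st.min_loop = min_loop;
  st.n = n;
  st.helix_init = helix_init;
  st.partner.assign(n, -1);
  st.best = 0.0;
  st.count = 0;
  st.max_structures = (long long)max_structures;
  std::vector<std::pair<int, int>> todo;
  todo.push_back(std::make_pair(0, n - 1));
  enum_rec(st, todo);
  return List::create(_["energy"] = st.best,
                      _["n_structures"] = (double)st.count);
}
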