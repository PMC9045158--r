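// Single-hairpin minimum-free-energy search.
//
// Two independent routes over the same integer ("cents" = 0.01 kcal/mol)
// nearest-neighbor tables:
//   * fold_min_hairpin_cpp  - bottom-up dynamic programming over closing
//     pairs, with a >= min_stem pair-count dimension and pinned tie-breaks.
//   * fold_oracle_dfs_cpp   - exhaustive depth-first enumeration of every
//     valid single-hairpin structure (test oracle; small sequences only).
//
// Search space: one terminal loop (>= min_loop unpaired nt), helices
// interrupted only by bulges / internal loops of at most max_defect nt per
// side, pairs drawn from {AU, UA, CG, GC, GU, UG}. Energies are summed as
// integers so results are exactly reproducible across platforms.

#include <Rcpp.h>
#include <climits>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int INFE = INT_MAX / 4;
static const int MAX_DEFECT = 6;

// pair type codes: AU=0 UA=1 CG=2 GC=3 GU=4 UG=5, -1 = not pairable
// base codes: A=0 C=1 G=2 U=3
static inline int ptype(int a, int b) {
  static const int tab[4][4] = {
    /*A*/ {-1, -1, -1,  0},
    /*C*/ {-1, -1,  2, -1},
    /*G*/ {-1,  3, -1,  4},
    /*U*/ { 1, -1,  5, -1}
  };
  return tab[a][b];
}

struct Tables {
  int stack[6][6];
  std::vector<int> hairpin;   // hairpin[k] = init for loop size k (k >= 3)
  int bulge[MAX_DEFECT + 1];          // 1..6
  int internal_[2 * MAX_DEFECT + 1];  // total size 2..12 (7..12 extrapolated)
  int term_au;
};

static Tables make_tables(const List& pc, int n) {
  Tables t;
  NumericMatrix S = pc["stack"];
  // R-side matrix rows/cols are ordered AU,UA,CG,GC,GU,UG to match ptype
  for (int i = 0; i < 6; ++i)
    for (int j = 0; j < 6; ++j)
      t.stack[i][j] = (int) S(i, j);
  NumericVector hp = pc["hairpin"], bu = pc["bulge"], in = pc["internal"];
  double js_rt = as<double>(pc["js_rt"]);
  int hmax = 2 + hp.size();          // table covers 3..hmax
  t.hairpin.assign(std::max(n + 1, hmax + 1), INFE);
  for (int k = 3; k <= hmax; ++k) t.hairpin[k] = (int) hp[k - 3];
  for (int k = hmax + 1; k <= n; ++k)
    t.hairpin[k] = (int) hp[hmax - 3] +
      (int) std::lround(100.0 * js_rt * std::log((double) k / hmax));
  for (int k = 1; k <= MAX_DEFECT; ++k) t.bulge[k] = (int) bu[k - 1];
  int imax = 1 + in.size();          // table covers 2..imax
  for (int k = 2; k <= imax; ++k) t.internal_[k] = (int) in[k - 2];
  for (int k = imax + 1; k <= 2 * MAX_DEFECT; ++k)
    t.internal_[k] = (int) in[imax - 2] +
      (int) std::lround(100.0 * js_rt * std::log((double) k / imax));
  t.term_au = as<int>(pc["term_au"]);
  return t;
}

// energy of the transition from outer pair (i,j) to inner pair (k,l)
static inline int transition(const Tables& t, const std::vector<int>& s,
                             int i, int j, int k, int l) {
  int d5 = k - i - 1, d3 = j - l - 1;
  if (d5 == 0 && d3 == 0)
    return t.stack[ptype(s[i], s[j])][ptype(s[k], s[l])];
  if (d5 == 0 || d3 == 0) return t.bulge[d5 + d3];
  return t.internal_[d5 + d3];
}

static inline bool closes_with_penalty(int pt) {
  return pt == 0 || pt == 1 || pt == 4 || pt == 5;  // AU, UA, GU, UG
}

// [[Rcpp::export]]
List fold_min_hairpin_cpp(IntegerVector seq, List pc, int min_stem,
                          int min_loop) {
  int n = seq.size();
  if (n > 5000) stop("sequence longer than 5000 nt");
  std::vector<int> s(seq.begin(), seq.end());
  Tables t = make_tables(pc, n);

  // D[c][i*n+j]: best (E, -bp) for a hairpin closed by pair (i,j)
  // containing at least c+1 pairs (c = 0 .. min_stem-1), 0-based indices.
  int C = std::max(min_stem, 1);
  std::vector<std::vector<int> > E(C, std::vector<int>(n * n, INFE));
  std::vector<std::vector<int> > BP(C, std::vector<int>(n * n, 0));
  std::vector<std::vector<int> > CK(C, std::vector<int>(n * n, -2));
  std::vector<std::vector<int> > CL(C, std::vector<int>(n * n, -2));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int pt = ptype(s[i], s[j]);
      if (pt < 0) continue;
      for (int c = 0; c < C; ++c) {
        int bestE = INFE, bestBP = 0, bk = -2, bl = -2;
        if (c == 0 && span - 1 >= min_loop) {  // bare hairpin close
          bestE = t.hairpin[span - 1];
          bestBP = 1; bk = -1; bl = -1;
        }
        int cin = (c == 0) ? 0 : c - 1;
        int kmax = std::min(i + 1 + MAX_DEFECT, j - 1);
        for (int k = i + 1; k <= kmax; ++k) {
          int lmin = std::max(k + 1, j - 1 - MAX_DEFECT);
          for (int l = lmin; l <= j - 1; ++l) {
            if (E[cin][k * n + l] >= INFE) continue;
            int e = E[cin][k * n + l] + transition(t, s, i, j, k, l);
            int bp = BP[cin][k * n + l] + 1;
            if (e < bestE || (e == bestE && bp > bestBP)) {
              bestE = e; bestBP = bp; bk = k; bl = l;
            }
          }
        }
        E[c][i * n + j] = bestE;
        BP[c][i * n + j] = bestBP;
        CK[c][i * n + j] = bk;
        CL[c][i * n + j] = bl;
      }
    }
  }

  // top-level selection: min (E + closing penalty, -bp, i, j)
  int top = C - 1;
  int bestE = INFE, bestBP = 0, bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      if (E[top][i * n + j] >= INFE) continue;
      int pt = ptype(s[i], s[j]);
      int e = E[top][i * n + j] + (closes_with_penalty(pt) ? t.term_au : 0);
      int bp = BP[top][i * n + j];
      if (e < bestE || (e == bestE && bp > bestBP) ||
          (e == bestE && bp == bestBP && (bi < 0 || i < bi ||
                                          (i == bi && j < bj)))) {
        bestE = e; bestBP = bp; bi = i; bj = j;
      }
    }
  }
  if (bi < 0)
    return List::create(_["found"] = false);

  // traceback
  std::vector<int> pi, pj;
  int c = top, i = bi, j = bj;
  while (i >= 0) {
    pi.push_back(i + 1); pj.push_back(j + 1);   // 1-based for R
    int k = CK[c][i * n + j], l = CL[c][i * n + j];
    if (k == -1) break;                          // hairpin close
    c = (c == 0) ? 0 : c - 1;
    i = k; j = l;
  }
  IntegerMatrix pairs(pi.size(), 2);
  for (size_t q = 0; q < pi.size(); ++q) { pairs(q, 0) = pi[q]; pairs(q, 1) = pj[q]; }
  return List::create(_["found"] = true, _["dG_cents"] = bestE,
                      _["bp"] = bestBP, _["pairs"] = pairs);
}

// ---------------------------------------------------------------------
// Exhaustive depth-first enumeration oracle.

struct DfsBest {
  long long count;
  int bestE, bestBP, bi, bj;
  std::vector<std::pair<int,int> > path, bestPath;
};

static void dfs_extend(const Tables& t, const std::vector<int>& s,
                       int min_stem, int min_loop, int outer_pt,
                       int k, int l, int e, int bp, DfsBest& st,
                       long long limit) {
  if (st.count > limit) stop("oracle enumeration limit exceeded");
  // close here?
  if (l - k - 1 >= min_loop) {
    ++st.count;
    if (bp >= min_stem) {
      int tot = e + t.hairpin[l - k - 1] +
        (closes_with_penalty(outer_pt) ? t.term_au : 0);
      int i0 = st.path.front().first;
      int j0 = st.path.front().second;
      if (tot < st.bestE || (tot == st.bestE && bp > st.bestBP) ||
          (tot == st.bestE && bp == st.bestBP &&
           (st.bi < 0 || i0 < st.bi || (i0 == st.bi && j0 < st.bj)))) {
        st.bestE = tot; st.bestBP = bp; st.bi = i0; st.bj = j0;
        st.bestPath = st.path;
      }
    }
  }
  // extend inward
  for (int k2 = k + 1; k2 <= std::min(k + 1 + MAX_DEFECT, l - 1); ++k2) {
    for (int l2 = std::max(k2 + 1, l - 1 - MAX_DEFECT); l2 <= l - 1; ++l2) {
      if (ptype(s[k2], s[l2]) < 0) continue;
      if (l2 - k2 - 1 < min_loop) continue;  // must still admit a loop
      st.path.push_back(std::make_pair(k2, l2));
      dfs_extend(t, s, min_stem, min_loop, outer_pt, k2, l2,
                 e + transition(t, s, k, l, k2, l2), bp + 1, st, limit);
      st.path.pop_back();
    }
  }
}

// [[Rcpp::export]]
List fold_oracle_dfs_cpp(IntegerVector seq, List pc, int min_stem,
                         int min_loop) {
  int n = seq.size();
  if (n > 60) stop("oracle restricted to sequences of at most 60 nt");
  std::vector<int> s(seq.begin(), seq.end());
  Tables t = make_tables(pc, n);
  DfsBest st; st.count = 0; st.bestE = INFE; st.bestBP = 0;
  st.bi = -1; st.bj = -1;
  const long long limit = 50000000LL;
  for (int i = 0; i < n; ++i) {
    for (int j = i + min_loop + 1; j < n; ++j) {
      int pt = ptype(s[i], s[j]);
      if (pt < 0) continue;
      st.path.clear();
      st.path.push_back(std::make_pair(i, j));
      dfs_extend(t, s, min_stem, min_loop, pt, i, j, 0, 1, st, limit);
    }
  }
  if (st.bi < 0)
    return List::create(_["found"] = false,
                        _["n_structures"] = (double) st.count);
  IntegerMatrix pairs(st.bestPath.size(), 2);
  for (size_t q = 0; q < st.bestPath.size(); ++q) {
    pairs(q, 0) = st.bestPath[q].first + 1;
    pairs(q, 1) = st.bestPath[q].second + 1;
  }
  return List::create(_["found"] = true, _["dG_cents"] = st.bestE,
                      _["bp"] = st.bestBP, _["pairs"] = pairs,
                      _["n_structures"] = (double) st.count);
}
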