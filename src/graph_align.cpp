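#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Base codes shared with the R side: A=0 C=1 G=2 T=3 N=4 '-'=5.
static const int NCODE = 4;
static const int GAPCODE = 5;

// Banded-free fitting alignment of a read against a window of the leveled
// PRG. The graph has one node per level boundary; the edges of level l
// (1-based) are lab[ptr[l-1] .. ptr[l]-1]. '-' edges are traversed for free
// and preserve the affine gap state; 'N' edges match any read base with the
// match score. The read is aligned globally up to soft clips (per-base
// penalty `clip`); graph start/end positions are free within the window.
//
// States: 0 = M (diagonal), 1 = I (read insertion), 2 = D (read deletion).
// Backpointer ops: 0 = start, 1 = M, 2 = I, 3 = D, 4 = gap-edge traversal.
//
// `drop` prunes cells more than `drop` below the running per-boundary
// maximum (set >= 1e17 to disable, as the brute-force oracle comparison
// requires).
// [[Rcpp::export]]
List cpp_graph_align(IntegerVector ptr, IntegerVector lab,
                     int w0, int w1,
                     IntegerVector read, NumericVector eps,
                     double gap_open, double gap_ext,
                     double clip, double drop) {
  const int m = read.size();
  const int W = w1 - w0 + 1;
  if (W < 1) stop("empty alignment window");
  const double NEG = -1e18;
  const bool do_prune = (drop < 1e17);
  const bool do_clip = (clip > -1e8);

  const size_t ncell = (size_t)(W + 1) * (m + 1) * 3;
  std::vector<double> S(ncell, NEG);
  std::vector<int> bp_op(ncell, -1), bp_state(ncell, -1), bp_lab(ncell, -1);
  std::vector<char> anch(ncell, 0);

  auto IX = [&](int b, int j, int st) -> size_t {
    return ((size_t)b * (m + 1) + j) * 3 + st;
  };

  double best = NEG;
  int best_b = -1, best_j = -1, best_st = -1;

  for (int b = 0; b <= W; ++b) {
    // fresh fitting starts at this boundary (optionally mid-read via clipping)
    {
      size_t ix = IX(b, 0, 0);
      if (0.0 > S[ix]) { S[ix] = 0.0; bp_op[ix] = 0; anch[ix] = 0; }
      if (do_clip) {
        for (int j = 1; j <= m; ++j) {
          double v = clip * j;
          size_t jx = IX(b, j, 0);
          if (v > S[jx]) { S[jx] = v; bp_op[jx] = 0; anch[jx] = 0; }
        }
      }
    }
    // read insertions within this boundary
    for (int j = 1; j <= m; ++j) {
      double fm = S[IX(b, j - 1, 0)] + gap_open;
      double fi = S[IX(b, j - 1, 1)] + gap_ext;
      double fd = S[IX(b, j - 1, 2)] + gap_open;
      double v = fm; int st = 0;
      if (fi > v) { v = fi; st = 1; }
      if (fd > v) { v = fd; st = 2; }
      size_t ix = IX(b, j, 1);
      if (v > S[ix] || (v == S[ix] && anch[IX(b, j - 1, st)] > anch[ix])) {
        if (v <= NEG / 2) continue;
        S[ix] = v; bp_op[ix] = 2; bp_state[ix] = st; bp_lab[ix] = -1;
        anch[ix] = anch[IX(b, j - 1, st)];
      }
    }
    // end-of-alignment candidates (only anchored cells: >= 1 aligned base)
    for (int j = 0; j <= m; ++j) {
      for (int st = 0; st < 3; ++st) {
        size_t ix = IX(b, j, st);
        if (!anch[ix] || S[ix] <= NEG / 2) continue;
        double v = S[ix] + (j < m ? clip * (m - j) : 0.0);
        if (j < m && !do_clip) continue;
        if (v > best) { best = v; best_b = b; best_j = j; best_st = st; }
      }
    }
    if (b == W) break;

    // pruning against the per-boundary maximum
    if (do_prune) {
      double bmax = NEG;
      for (int j = 0; j <= m; ++j)
        for (int st = 0; st < 3; ++st)
          if (S[IX(b, j, st)] > bmax) bmax = S[IX(b, j, st)];
      double thr = bmax - drop;
      for (int j = 0; j <= m; ++j)
        for (int st = 0; st < 3; ++st) {
          size_t ix = IX(b, j, st);
          if (S[ix] < thr) S[ix] = NEG;
        }
    }

    // propagate across level lv = w0 + b (1-based)
    const int lv = w0 + b;
    const int e0 = ptr[lv - 1], e1 = ptr[lv];
    bool has_gap = false;
    int first_base = -1;
    for (int e = e0; e < e1; ++e) {
      if (lab[e] == GAPCODE) has_gap = true;
      else if (first_base < 0) first_base = lab[e];
    }

    for (int j = 0; j <= m; ++j) {
      // gap edges: free traversal, state preserved
      if (has_gap) {
        for (int st = 0; st < 3; ++st) {
          size_t from = IX(b, j, st), to = IX(b + 1, j, st);
          if (S[from] > S[to] ||
              (S[from] == S[to] && anch[from] > anch[to])) {
            if (S[from] <= NEG / 2) continue;
            S[to] = S[from]; bp_op[to] = 4; bp_state[to] = st;
            bp_lab[to] = GAPCODE; anch[to] = anch[from];
          }
        }
      }
      if (first_base >= 0) {
        // read deletion: consume a level without a read base
        {
          double fm = S[IX(b, j, 0)] + gap_open;
          double fi = S[IX(b, j, 1)] + gap_open;
          double fd = S[IX(b, j, 2)] + gap_ext;
          double v = fm; int st = 0;
          if (fi > v) { v = fi; st = 1; }
          if (fd > v) { v = fd; st = 2; }
          size_t to = IX(b + 1, j, 2);
          if (v > S[to] && v > NEG / 2) {
            S[to] = v; bp_op[to] = 3; bp_state[to] = st; bp_lab[to] = first_base;
            anch[to] = anch[IX(b, j, st)];
          }
        }
        // diagonal moves for every distinct base edge
        if (j < m) {
          const int rb = read[j];
          const double e_j = eps[j];
          const double match = std::log1p(-e_j);
          const double mism = std::log(e_j / 3.0);
          for (int e = e0; e < e1; ++e) {
            const int c = lab[e];
            if (c == GAPCODE) continue;
            const double sc = (c == NCODE || c == rb) ? match : mism;
            double v = S[IX(b, j, 0)]; int st = 0;
            if (S[IX(b, j, 1)] > v) { v = S[IX(b, j, 1)]; st = 1; }
            if (S[IX(b, j, 2)] > v) { v = S[IX(b, j, 2)]; st = 2; }
            v += sc;
            size_t to = IX(b + 1, j + 1, 0);
            if (v > S[to] && v > NEG / 2) {
              S[to] = v; bp_op[to] = 1; bp_state[to] = st; bp_lab[to] = c;
              anch[to] = 1;
            }
          }
        }
      }
    }
  }

  if (best_b < 0) {
    return List::create(_["score"] = R_NegInf,
                        _["cols"] = IntegerMatrix(0, 4),
                        _["clip_left"] = 0, _["clip_right"] = 0);
  }

  // traceback
  std::vector<int> col_level, col_rpos, col_op, col_lab;
  int b = best_b, j = best_j, st = best_st;
  while (true) {
    size_t ix = IX(b, j, st);
    int op = bp_op[ix];
    if (op == 0) break;
    if (op == 1) {
      col_level.push_back(w0 + b - 1); col_rpos.push_back(j);
      col_op.push_back(1); col_lab.push_back(bp_lab[ix]);
      b -= 1; j -= 1; st = bp_state[ix];
    } else if (op == 2) {
      col_level.push_back(0); col_rpos.push_back(j);
      col_op.push_back(2); col_lab.push_back(-1);
      j -= 1; st = bp_state[ix];
    } else if (op == 3) {
      col_level.push_back(w0 + b - 1); col_rpos.push_back(0);
      col_op.push_back(3); col_lab.push_back(bp_lab[ix]);
      b -= 1; st = bp_state[ix];
    } else { // gap edge
      col_level.push_back(w0 + b - 1); col_rpos.push_back(0);
      col_op.push_back(4); col_lab.push_back(GAPCODE);
      b -= 1; st = bp_state[ix];
    }
  }
  const int n = col_level.size();
  IntegerMatrix cols(n, 4);
  for (int i = 0; i < n; ++i) {
    cols(i, 0) = col_level[n - 1 - i];
    cols(i, 1) = col_rpos[n - 1 - i];
    cols(i, 2) = col_op[n - 1 - i];
    cols(i, 3) = col_lab[n - 1 - i];
  }
  colnames(cols) = CharacterVector::create("level", "read_pos", "op", "label");
  return List::create(_["score"] = best,
                      _["cols"] = cols,
                      _["clip_left"] = j,
                      _["clip_right"] = m - best_j);
}
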