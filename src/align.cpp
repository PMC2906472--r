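#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap dynamic programming over a precomputed column-score matrix.
//
// Both routines are generic in the objects being aligned: S(i, j) is the
// score of pairing column i of object A with column j of object B, so the
// same kernel serves residue-vs-residue, profile-vs-profile and
// model-vs-sequence alignment.  A gap of length k costs gap_open + k * gap_ext.
//
// Determinism: every max is resolved in a fixed order (match state first,
// then gap-in-B ["up"], then gap-in-A ["left"]), so tied optima always yield
// the same alignment on every platform.

static const double NEG_INF = -1e30;

inline int argmax3(double m, double x, double y) {
  // preference order M > X > Y on ties
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".nw_affine_cpp")]]
List nw_affine_cpp(NumericMatrix S, double gap_open, double gap_ext,
                   bool penalize_ends = true) {
  const int na = S.nrow(), nb = S.ncol();
  // state matrices: M ends in a match, X ends with gap in B (A consumed),
  // Y ends with gap in A (B consumed)
  NumericMatrix M(na + 1, nb + 1), X(na + 1, nb + 1), Y(na + 1, nb + 1);
  IntegerMatrix pM(na + 1, nb + 1), pX(na + 1, nb + 1), pY(na + 1, nb + 1);

  M(0, 0) = 0.0;
  X(0, 0) = Y(0, 0) = NEG_INF;
  for (int i = 1; i <= na; ++i) {
    M(i, 0) = Y(i, 0) = NEG_INF;
    X(i, 0) = penalize_ends ? -(gap_open + i * gap_ext) : 0.0;
    pX(i, 0) = 1;
  }
  for (int j = 1; j <= nb; ++j) {
    M(0, j) = X(0, j) = NEG_INF;
    Y(0, j) = penalize_ends ? -(gap_open + j * gap_ext) : 0.0;
    pY(0, j) = 2;
  }

  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      int am = argmax3(dm, dx, dy);
      double dbest = (am == 0) ? dm : (am == 1 ? dx : dy);
      M(i, j) = dbest + S(i - 1, j - 1);
      pM(i, j) = am;

      // X: consume row i of A against a gap
      double xo = M(i - 1, j) - (gap_open + gap_ext);
      double xe = X(i - 1, j) - gap_ext;
      double xy = Y(i - 1, j) - (gap_open + gap_ext);
      int ax = argmax3(xo, xe, xy);
      X(i, j) = (ax == 0) ? xo : (ax == 1 ? xe : xy);
      pX(i, j) = ax;

      // Y: consume column j of B against a gap
      double yo = M(i, j - 1) - (gap_open + gap_ext);
      double yx = X(i, j - 1) - (gap_open + gap_ext);
      double ye = Y(i, j - 1) - gap_ext;
      int ay = argmax3(yo, yx, ye);
      Y(i, j) = (ay == 0) ? yo : (ay == 1 ? yx : ye);
      pY(i, j) = ay;
    }
  }

  // locate endpoint
  int ei = na, ej = nb, state;
  double score;
  if (penalize_ends) {
    state = argmax3(M(na, nb), X(na, nb), Y(na, nb));
    score = (state == 0) ? M(na, nb) : (state == 1 ? X(na, nb) : Y(na, nb));
  } else {
    // free terminal gaps: best cell on the last row or last column
    score = NEG_INF; state = 0;
    for (int i = 0; i <= na; ++i) {
      int st = argmax3(M(i, nb), X(i, nb), Y(i, nb));
      double sc = (st == 0) ? M(i, nb) : (st == 1 ? X(i, nb) : Y(i, nb));
      if (sc > score) { score = sc; ei = i; ej = nb; state = st; }
    }
    for (int j = 0; j <= nb; ++j) {
      int st = argmax3(M(na, j), X(na, j), Y(na, j));
      double sc = (st == 0) ? M(na, j) : (st == 1 ? X(na, j) : Y(na, j));
      if (sc > score) { score = sc; ei = na; ej = j; state = st; }
    }
  }

  // traceback
  std::vector<int> pa, pb;
  // free trailing gaps first
  for (int i = na; i > ei; --i) { pa.push_back(i); pb.push_back(0); }
  for (int j = nb; j > ej; --j) { pa.push_back(0); pb.push_back(j); }
  int i = ei, j = ej;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = pM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = pX(i, j);
      pa.push_back(i); pb.push_back(0);
      --i; state = prev;
      if (i == 0 && j == 0) break;
      if (i == 0 && j > 0) state = 2;   // remaining leading gaps in A
    } else {
      int prev = pY(i, j);
      pa.push_back(0); pb.push_back(j);
      --j; state = prev;
      if (i == 0 && j == 0) break;
      if (j == 0 && i > 0) state = 1;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = score,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// [[Rcpp::export(name = ".sw_affine_cpp")]]
List sw_affine_cpp(NumericMatrix S, double gap_open, double gap_ext) {
  const int na = S.nrow(), nb = S.ncol();
  NumericMatrix M(na + 1, nb + 1), X(na + 1, nb + 1), Y(na + 1, nb + 1);
  IntegerMatrix pM(na + 1, nb + 1), pX(na + 1, nb + 1), pY(na + 1, nb + 1);
  // pM code 3 marks a fresh local start.  Boundary states are unreachable:
  // a local path may only begin via the fresh-start clamp inside M, never
  // with a gap, so traceback always terminates at a match column.
  for (int i = 0; i <= na; ++i) { M(i, 0) = X(i, 0) = Y(i, 0) = NEG_INF; }
  for (int j = 0; j <= nb; ++j) { M(0, j) = X(0, j) = Y(0, j) = NEG_INF; }

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      double dm = M(i - 1, j - 1), dx = X(i - 1, j - 1), dy = Y(i - 1, j - 1);
      int am = argmax3(dm, dx, dy);
      double dbest = (am == 0) ? dm : (am == 1 ? dx : dy);
      if (dbest < 0.0) { dbest = 0.0; am = 3; }
      M(i, j) = dbest + S(i - 1, j - 1);
      pM(i, j) = am;

      double xo = M(i - 1, j) - (gap_open + gap_ext);
      double xe = X(i - 1, j) - gap_ext;
      double xy = Y(i - 1, j) - (gap_open + gap_ext);
      int ax = argmax3(xo, xe, xy);
      X(i, j) = (ax == 0) ? xo : (ax == 1 ? xe : xy);
      pX(i, j) = ax;

      double yo = M(i, j - 1) - (gap_open + gap_ext);
      double yx = X(i, j - 1) - (gap_open + gap_ext);
      double ye = Y(i, j - 1) - gap_ext;
      int ay = argmax3(yo, yx, ye);
      Y(i, j) = (ay == 0) ? yo : (ay == 1 ? yx : ye);
      pY(i, j) = ay;

      // local optimum must end in a match column (tie: earliest cell wins)
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["a_start"] = 0, _["a_end"] = -1,
                        _["b_start"] = 0, _["b_end"] = -1,
                        _["path_a"] = IntegerVector(0),
                        _["path_b"] = IntegerVector(0));
  }

  std::vector<int> pa, pb;
  int i = bi, j = bj, state = 0;
  while (true) {
    if (state == 0) {
      int prev = pM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j;
      if (prev == 3) break;
      state = prev;
    } else if (state == 1) {
      int prev = pX(i, j);
      pa.push_back(i); pb.push_back(0);
      --i; state = prev;
    } else {
      int prev = pY(i, j);
      pa.push_back(0); pb.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  return List::create(_["score"] = best,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj,
                      _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                      _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}
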