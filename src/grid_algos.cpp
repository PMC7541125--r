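#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// 8-neighbour offsets, fixed order N, NE, E, SE, S, SW, W, NW.
// This order is the deterministic tie-break used throughout the package.
static const int DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

struct Cell {
  double key;
  long long order; // insertion counter: deterministic pop order on ties
  int r, c;
};
struct CellGreater {
  bool operator()(const Cell &a, const Cell &b) const {
    if (a.key != b.key) return a.key > b.key;
    return a.order > b.order;
  }
};

// Priority-flood depression filling with an epsilon gradient: every cell
// ends strictly above the neighbour it spills through, so the filled
// surface has no pits and no flats and D8 drainage to the border is
// guaranteed.
// [[Rcpp::export]]
NumericMatrix fill_depressions_cpp(NumericMatrix dem, double eps) {
  int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix out(nr, nc);
  std::vector<bool> closed((size_t)nr * nc, false);
  std::priority_queue<Cell, std::vector<Cell>, CellGreater> pq;
  long long counter = 0;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      out(r, c) = dem(r, c);
      if (r == 0 || r == nr - 1 || c == 0 || c == nc - 1) {
        pq.push({dem(r, c), counter++, r, c});
        closed[(size_t)r * nc + c] = true;
      }
    }

  while (!pq.empty()) {
    Cell cur = pq.top();
    pq.pop();
    for (int k = 0; k < 8; ++k) {
      int r2 = cur.r + DR[k], c2 = cur.c + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      size_t idx = (size_t)r2 * nc + c2;
      if (closed[idx]) continue;
      closed[idx] = true;
      double lifted = out(cur.r, cur.c) + eps;
      if (out(r2, c2) < lifted) out(r2, c2) = lifted;
      pq.push({out(r2, c2), counter++, r2, c2});
    }
  }
  return out;
}

// Multi-source least accumulated cost over the 8-connected grid graph.
// friction holds minutes to traverse one full cell; NA/Inf = impassable.
// Cost of a move i -> j is 0.5 * (f_i + f_j) * d with d = 1 (cardinal) or
// sqrt(2) (diagonal). Sources start at 0. Returns minutes; unreachable
// passable cells get +Inf, impassable cells NA.
// [[Rcpp::export]]
NumericMatrix cost_distance_cpp(NumericMatrix friction,
                                IntegerVector src_rows,
                                IntegerVector src_cols) {
  int nr = friction.nrow(), nc = friction.ncol();
  const double SQRT2 = std::sqrt(2.0);
  NumericMatrix dist(nr, nc);
  std::vector<bool> done((size_t)nr * nc, false);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      dist(r, c) = R_PosInf;

  std::priority_queue<Cell, std::vector<Cell>, CellGreater> pq;
  long long counter = 0;
  int n_src = src_rows.size();
  for (int s = 0; s < n_src; ++s) {
    int r = src_rows[s] - 1, c = src_cols[s] - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source cell outside grid");
    double f = friction(r, c);
    if (NumericMatrix::is_na(f) || !R_finite(f)) continue; // impassable source
    dist(r, c) = 0.0;
    pq.push({0.0, counter++, r, c});
  }
  if (pq.empty()) stop("all source cells are impassable");

  while (!pq.empty()) {
    Cell cur = pq.top();
    pq.pop();
    size_t idx = (size_t)cur.r * nc + cur.c;
    if (done[idx]) continue;
    done[idx] = true;
    double f0 = friction(cur.r, cur.c);
    for (int k = 0; k < 8; ++k) {
      int r2 = cur.r + DR[k], c2 = cur.c + DC[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      double f1 = friction(r2, c2);
      if (NumericMatrix::is_na(f1) || !R_finite(f1)) continue;
      double d = (DR[k] != 0 && DC[k] != 0) ? SQRT2 : 1.0;
      double nd = cur.key + 0.5 * (f0 + f1) * d;
      if (nd < dist(r2, c2)) {
        dist(r2, c2) = nd;
        pq.push({nd, counter++, r2, c2});
      }
    }
  }

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double f = friction(r, c);
      if (NumericMatrix::is_na(f) || !R_finite(f)) dist(r, c) = NA_REAL;
    }
  return dist;
}
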