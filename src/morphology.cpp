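#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Binary morphology with a disc structuring element {(dr,dc): dr^2+dc^2 <= r^2}.
// Border convention preserves the opening/closing duality: pixels outside the
// image count as foreground for erosion and background for dilation.

static std::vector<std::pair<int,int>> disc_offsets(double radius) {
  std::vector<std::pair<int,int>> off;
  int r = (int)std::floor(radius);
  for (int di = -r; di <= r; ++di)
    for (int dj = -r; dj <= r; ++dj)
      if ((double)di * di + (double)dj * dj <= radius * radius)
        off.push_back(std::make_pair(di, dj));
  return off;
}

// [[Rcpp::export]]
LogicalMatrix cpp_binary_erode(LogicalMatrix M, double radius) {
  const int h = M.nrow(), w = M.ncol();
  if (radius <= 0) return clone(M);
  std::vector<std::pair<int,int>> off = disc_offsets(radius);
  LogicalMatrix O(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      if (!M(i, j)) { O(i, j) = FALSE; continue; }
      bool all_in = true;
      for (size_t k = 0; k < off.size() && all_in; ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii >= 0 && ii < h && jj >= 0 && jj < w && !M(ii, jj)) all_in = false;
      }
      O(i, j) = all_in;
    }
  return O;
}

// [[Rcpp::export]]
LogicalMatrix cpp_binary_dilate(LogicalMatrix M, double radius) {
  const int h = M.nrow(), w = M.ncol();
  if (radius <= 0) return clone(M);
  std::vector<std::pair<int,int>> off = disc_offsets(radius);
  LogicalMatrix O(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      if (M(i, j)) { O(i, j) = TRUE; continue; }
      bool any_in = false;
      for (size_t k = 0; k < off.size() && !any_in; ++k) {
        int ii = i + off[k].first, jj = j + off[k].second;
        if (ii >= 0 && ii < h && jj >= 0 && jj < w && M(ii, jj)) any_in = true;
      }
      O(i, j) = any_in;
    }
  return O;
}

// Connected-component labelling, 8-connectivity, labels 1..K assigned in
// raster-scan discovery order (stable ordering for relabelling contracts).
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix M) {
  const int h = M.nrow(), w = M.ncol();
  IntegerMatrix L(h, w);
  std::vector<int> qi(h * w), qj(h * w);
  int next = 0;
  for (int i0 = 0; i0 < h; ++i0)
    for (int j0 = 0; j0 < w; ++j0) {
      if (!M(i0, j0) || L(i0, j0)) continue;
      ++next;
      int head = 0, tail = 0;
      qi[tail] = i0; qj[tail] = j0; ++tail;
      L(i0, j0) = next;
      while (head < tail) {
        int i = qi[head], j = qj[head]; ++head;
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            if (!di && !dj) continue;
            int ii = i + di, jj = j + dj;
            if (ii >= 0 && ii < h && jj >= 0 && jj < w && M(ii, jj) && !L(ii, jj)) {
              L(ii, jj) = next;
              qi[tail] = ii; qj[tail] = jj; ++tail;
            }
          }
      }
    }
  return L;
}

// Fill holes: background components (4-connectivity) not reachable from the
// image border become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(LogicalMatrix M) {
  const int h = M.nrow(), w = M.ncol();
  std::vector<char> reach((size_t)h * w, 0);
  std::vector<int> qi(h * w), qj(h * w);
  int head = 0, tail = 0;
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j) {
      bool border = (i == 0 || i == h - 1 || j == 0 || j == w - 1);
      if (border && !M(i, j) && !reach[(size_t)i * w + j]) {
        reach[(size_t)i * w + j] = 1;
        qi[tail] = i; qj[tail] = j; ++tail;
      }
    }
  const int d4i[4] = {-1, 1, 0, 0}, d4j[4] = {0, 0, -1, 1};
  while (head < tail) {
    int i = qi[head], j = qj[head]; ++head;
    for (int k = 0; k < 4; ++k) {
      int ii = i + d4i[k], jj = j + d4j[k];
      if (ii >= 0 && ii < h && jj >= 0 && jj < w && !M(ii, jj) &&
          !reach[(size_t)ii * w + jj]) {
        reach[(size_t)ii * w + jj] = 1;
        qi[tail] = ii; qj[tail] = jj; ++tail;
      }
    }
  }
  LogicalMatrix O(h, w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      O(i, j) = M(i, j) || !reach[(size_t)i * w + j];
  return O;
}

// Moore boundary tracing of a single 8-connected object, clockwise, starting
// from the topmost-then-leftmost foreground pixel. Returns an n x 2 matrix of
// 0-based (row, col) points forming a closed loop (start not repeated).
// [[Rcpp::export]]
IntegerMatrix cpp_moore_contour(LogicalMatrix M) {
  const int h = M.nrow(), w = M.ncol();
  int si = -1, sj = -1;
  for (int i = 0; i < h && si < 0; ++i)
    for (int j = 0; j < w; ++j)
      if (M(i, j)) { si = i; sj = j; break; }
  if (si < 0) stop("empty mask: no contour");
  // clockwise Moore neighbourhood starting at N (row axis points down)
  const int di[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dj[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  auto fg = [&](int i, int j) {
    return i >= 0 && i < h && j >= 0 && j < w && M(i, j);
  };
  bool isolated = true;
  for (int k = 0; k < 8 && isolated; ++k)
    if (fg(si + di[k], sj + dj[k])) isolated = false;
  std::vector<int> ri, rj;
  if (isolated) {
    ri.push_back(si); rj.push_back(sj);
  } else {
    // backtrack starts at N of the start pixel (background: start is topmost)
    int ci = si, cj = sj, bdir = 0;
    int first_dir = -1;
    const size_t guard = (size_t)8 * h * w + 16;
    size_t steps = 0;
    while (true) {
      // scan clockwise from just past the backtrack direction
      int found = -1;
      for (int t = 0; t < 8; ++t) {
        int k = (bdir + 1 + t) % 8;
        if (fg(ci + di[k], cj + dj[k])) { found = k; break; }
      }
      if (found < 0) break;  // unreachable for non-isolated pixel
      // Jacob's criterion: stop on re-entering the start pixel about to
      // repeat the first move
      if (ci == si && cj == sj) {
        if (first_dir < 0) first_dir = found;
        else if (found == first_dir) break;
      }
      ri.push_back(ci); rj.push_back(cj);
      // new backtrack: the last background neighbour examined (predecessor
      // of `found`), expressed as a direction from the next pixel
      int prev = (found + 7) % 8;
      int ni = ci + di[found], nj = cj + dj[found];
      int bi = ci + di[prev], bj = cj + dj[prev];
      int nb = -1;
      for (int t = 0; t < 8; ++t)
        if (ni + di[t] == bi && nj + dj[t] == bj) { nb = t; break; }
      if (nb < 0) nb = (found + 4) % 8;
      ci = ni; cj = nj; bdir = nb;
      if (++steps > guard) break;
    }
  }
  IntegerMatrix P(ri.size(), 2);
  for (size_t t = 0; t < ri.size(); ++t) { P(t, 0) = ri[t]; P(t, 1) = rj[t]; }
  return P;
}

// Grow labels outward into unlabelled mask pixels by multi-source BFS
// (8-connectivity): each mask pixel joins its nearest labelled region.
// Restores the rim removed by the pre-distance-map erosion.
// [[Rcpp::export]]
IntegerMatrix cpp_grow_labels(IntegerMatrix L, LogicalMatrix mask) {
  const int h = L.nrow(), w = L.ncol();
  IntegerMatrix O(clone(L));
  std::vector<int> qi, qj;
  qi.reserve((size_t)h * w); qj.reserve((size_t)h * w);
  for (int i = 0; i < h; ++i)
    for (int j = 0; j < w; ++j)
      if (O(i, j) > 0) { qi.push_back(i); qj.push_back(j); }
  size_t head = 0;
  while (head < qi.size()) {
    int i = qi[head], j = qj[head]; ++head;
    int lab = O(i, j);
    for (int di = -1; di <= 1; ++di)
      for (int dj = -1; dj <= 1; ++dj) {
        if (!di && !dj) continue;
        int ii = i + di, jj = j + dj;
        if (ii >= 0 && ii < h && jj >= 0 && jj < w && mask(ii, jj) &&
            O(ii, jj) == 0) {
          O(ii, jj) = lab;
          qi.push_back(ii); qj.push_back(jj);
        }
      }
  }
  return O;
}
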