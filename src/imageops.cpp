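#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Symmetric (half-sample) reflection: -1 -> 0, -2 -> 1, n -> n-1, n+1 -> n-2.
static inline int reflect(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Local median over a square window (odd side), reflective padding.
// Sliding 256-bin histogram along each row of the output; intensities 0..255.
// [[Rcpp::export]]
IntegerMatrix cpp_local_median(IntegerMatrix img, int window) {
  if (window < 3 || window % 2 == 0) stop("window must be an odd integer >= 3");
  const int nr = img.nrow(), nc = img.ncol(), h = window / 2;
  const int target = (window * window) / 2 + 1;  // rank of the median (odd count)
  IntegerMatrix out(nr, nc);
  std::vector<int> hist(256);
  for (int i = 0; i < nr; ++i) {
    std::fill(hist.begin(), hist.end(), 0);
    for (int dj = -h; dj <= h; ++dj) {
      int jj = reflect(dj, nc);
      for (int di = -h; di <= h; ++di)
        ++hist[img(reflect(i + di, nr), jj)];
    }
    for (int j = 0; j < nc; ++j) {
      if (j > 0) {
        int jout = reflect(j - 1 - h, nc), jin = reflect(j + h, nc);
        for (int di = -h; di <= h; ++di) {
          int ii = reflect(i + di, nr);
          --hist[img(ii, jout)];
          ++hist[img(ii, jin)];
        }
      }
      int cum = 0, med = 0;
      for (int v = 0; v < 256; ++v) {
        cum += hist[v];
        if (cum >= target) { med = v; break; }
      }
      out(i, j) = med;
    }
  }
  return out;
}

// Local mean and (population) standard deviation over a disc of the given
// radius in pixels, reflective padding. Used by the Phansalkar threshold.
// [[Rcpp::export]]
List cpp_local_mean_sd(NumericMatrix img, int radius) {
  if (radius < 1) stop("radius must be >= 1");
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dx, dy;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= radius * radius) { dx.push_back(di); dy.push_back(dj); }
  const int m = (int)dx.size();
  NumericMatrix mean(nr, nc), sd(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0, s2 = 0.0;
      for (int k = 0; k < m; ++k) {
        double v = img(reflect(i + dx[k], nr), reflect(j + dy[k], nc));
        s += v; s2 += v * v;
      }
      double mu = s / m, var = s2 / m - mu * mu;
      mean(i, j) = mu;
      sd(i, j) = var > 0 ? std::sqrt(var) : 0.0;
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}

// Connected-component labeling (4- or 8-connectivity), labels 1..k, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int,int> > stack;
  int next = 0;
  const int dx8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dy8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = (connectivity == 8) ? 8 : 4;
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!mask(i, j) || lab(i, j)) continue;
    lab(i, j) = ++next;
    stack.push_back(std::make_pair(i, j));
    while (!stack.empty()) {
      std::pair<int,int> p = stack.back(); stack.pop_back();
      for (int k = 0; k < nnb; ++k) {
        int ii = p.first + dx8[k], jj = p.second + dy8[k];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (mask(ii, jj) && !lab(ii, jj)) {
          lab(ii, jj) = next;
          stack.push_back(std::make_pair(ii, jj));
        }
      }
    }
  }
  return lab;
}

static inline int at(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Guo-Hall thinning to 1-px-wide 8-connected centerlines (two alternating
// parallel subiterations; homotopy-preserving).
// [[Rcpp::export]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix cur = clone(mask);
  bool changed = true;
  std::vector<std::pair<int,int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
        if (!cur(i, j)) continue;
        // p1..p8 clockwise from north; rows grow downward
        int p1 = at(cur, i - 1, j),     p2 = at(cur, i - 1, j + 1);
        int p3 = at(cur, i,     j + 1), p4 = at(cur, i + 1, j + 1);
        int p5 = at(cur, i + 1, j),     p6 = at(cur, i + 1, j - 1);
        int p7 = at(cur, i,     j - 1), p8 = at(cur, i - 1, j - 1);
        int C = ((!p1) & (p2 | p3)) + ((!p3) & (p4 | p5)) +
                ((!p5) & (p6 | p7)) + ((!p7) & (p8 | p1));
        int N1 = (p1 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
        int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p1);
        int N = N1 < N2 ? N1 : N2;
        int m = pass == 0 ? ((p5 | p6 | (!p8)) & p7) : ((p1 | p2 | (!p4)) & p3);
        if (C == 1 && N >= 2 && N <= 3 && m == 0)
          kill.push_back(std::make_pair(i, j));
      }
      if (!kill.empty()) changed = true;
      for (size_t k = 0; k < kill.size(); ++k)
        cur(kill[k].first, kill[k].second) = false;
    }
  }
  return cur;
}

static std::vector<std::pair<int,int> > disc_offsets(int radius) {
  std::vector<std::pair<int,int> > off;
  for (int di = -radius; di <= radius; ++di)
    for (int dj = -radius; dj <= radius; ++dj)
      if (di * di + dj * dj <= radius * radius) off.push_back(std::make_pair(di, dj));
  return off;
}

// Binary dilation with a disc structuring element; outside-image is background.
// [[Rcpp::export]]
LogicalMatrix cpp_dilate_disc(LogicalMatrix mask, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(mask);
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int,int> > off = disc_offsets(radius);
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!mask(i, j)) continue;
    for (size_t k = 0; k < off.size(); ++k) {
      int ii = i + off[k].first, jj = j + off[k].second;
      if (ii >= 0 && ii < nr && jj >= 0 && jj < nc) out(ii, jj) = true;
    }
  }
  return out;
}

// Binary erosion with a disc structuring element; outside-image is background.
// [[Rcpp::export]]
LogicalMatrix cpp_erode_disc(LogicalMatrix mask, int radius) {
  if (radius < 0) stop("radius must be >= 0");
  if (radius == 0) return clone(mask);
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<std::pair<int,int> > off = disc_offsets(radius);
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!mask(i, j)) continue;
    bool keep = true;
    for (size_t k = 0; k < off.size() && keep; ++k) {
      int ii = i + off[k].first, jj = j + off[k].second;
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc || !mask(ii, jj)) keep = false;
    }
    out(i, j) = keep;
  }
  return out;
}

// Geodesic dilation of `seed` inside `mask` with a 3x3 (8-connected)
// structuring element, `iters` times; iters < 0 iterates to stability
// (full morphological reconstruction by dilation).
// [[Rcpp::export]]
LogicalMatrix cpp_geodesic_dilate(LogicalMatrix seed, LogicalMatrix mask, int iters) {
  const int nr = seed.nrow(), nc = seed.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc) stop("seed/mask shape mismatch");
  LogicalMatrix cur = clone(seed);
  int it = 0;
  bool changed = true;
  while (changed && (iters < 0 || it < iters)) {
    changed = false;
    LogicalMatrix nxt = clone(cur);
    for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
      if (cur(i, j) || !mask(i, j)) continue;
      for (int di = -1; di <= 1 && !nxt(i, j); ++di)
        for (int dj = -1; dj <= 1; ++dj) {
          int ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (cur(ii, jj)) { nxt(i, j) = true; changed = true; break; }
        }
    }
    cur = nxt;
    ++it;
  }
  return cur;
}

// Rasterize stroked polyline segments. `segs` has columns x0,y0,x1,y1 in
// pixel units where the center of pixel (row i, col j) is (x = j + 0.5,
// y = i + 0.5); a pixel is set when its center lies within halfwidth of the
// segment (round caps).
// [[Rcpp::export]]
LogicalMatrix cpp_stroke(int nrow, int ncol, NumericMatrix segs, NumericVector halfwidth) {
  if (segs.nrow() != halfwidth.size()) stop("one halfwidth per segment required");
  LogicalMatrix out(nrow, ncol);
  for (int s = 0; s < segs.nrow(); ++s) {
    double x0 = segs(s, 0), y0 = segs(s, 1), x1 = segs(s, 2), y1 = segs(s, 3);
    double hw = halfwidth[s];
    if (hw <= 0) continue;
    int jlo = std::max(0, (int)std::floor(std::min(x0, x1) - hw - 1.0));
    int jhi = std::min(ncol - 1, (int)std::ceil(std::max(x0, x1) + hw));
    int ilo = std::max(0, (int)std::floor(std::min(y0, y1) - hw - 1.0));
    int ihi = std::min(nrow - 1, (int)std::ceil(std::max(y0, y1) + hw));
    double vx = x1 - x0, vy = y1 - y0;
    double len2 = vx * vx + vy * vy;
    for (int j = jlo; j <= jhi; ++j) {
      double px = j + 0.5;
      for (int i = ilo; i <= ihi; ++i) {
        if (out(i, j)) continue;
        double py = i + 0.5;
        double t = 0.0;
        if (len2 > 0) {
          t = ((px - x0) * vx + (py - y0) * vy) / len2;
          if (t < 0) t = 0; else if (t > 1) t = 1;
        }
        double dx = px - (x0 + t * vx), dy = py - (y0 + t * vy);
        if (dx * dx + dy * dy <= hw * hw) out(i, j) = true;
      }
    }
  }
  return out;
}

// Count 8-neighbour steps among skeleton pixels restricted to `included`;
// returns c(axial, diagonal). A diagonal pair is a step only when it has no
// common axial skeleton neighbour: at a staircase corner the two axial edges
// already trace the path, and counting the diagonal shortcut as well would
// overestimate the length of every corner.
// [[Rcpp::export]]
IntegerVector cpp_skeleton_edges(LogicalMatrix skel, LogicalMatrix included) {
  const int nr = skel.nrow(), nc = skel.ncol();
  if (included.nrow() != nr || included.ncol() != nc) stop("shape mismatch");
  long axial = 0, diag = 0;
  LogicalMatrix on(nr, nc);
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i)
    on(i, j) = skel(i, j) && included(i, j);
  for (int j = 0; j < nc; ++j) for (int i = 0; i < nr; ++i) {
    if (!on(i, j)) continue;
    // forward neighbours only, so each unordered pair is counted once
    if (i + 1 < nr && on(i + 1, j)) ++axial;
    if (j + 1 < nc && on(i, j + 1)) ++axial;
    if (i + 1 < nr && j + 1 < nc && on(i + 1, j + 1) &&
        !on(i + 1, j) && !on(i, j + 1)) ++diag;
    if (i + 1 < nr && j - 1 >= 0 && on(i + 1, j - 1) &&
        !on(i + 1, j) && !on(i, j - 1)) ++diag;
  }
  return IntegerVector::create((int)axial, (int)diag);
}
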