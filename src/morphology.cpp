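// Low-level raster morphology for nucleus detection.
// Matrices are R column-major; a pixel (row i, col j) is index i + j*nr.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx(int i, int j, int nr) { return i + j * nr; }

// Separable Gaussian blur with edge replication. sigma in pixels.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * radius + 1);
  double s = 0.0;
  for (int t = -radius; t <= radius; ++t) {
    k[t + radius] = std::exp(-0.5 * t * t / (sigma * sigma));
    s += k[t + radius];
  }
  for (double& v : k) v /= s;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along rows (vertical)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int ii = i + t;
        if (ii < 0) ii = 0; else if (ii >= nr) ii = nr - 1;
        acc += k[t + radius] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  // along cols (horizontal)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = -radius; t <= radius; ++t) {
        int jj = j + t;
        if (jj < 0) jj = 0; else if (jj >= nc) jj = nc - 1;
        acc += k[t + radius] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  return out;
}

// Fill holes: background flood-filled (4-connectivity) from the border;
// any off-mask pixel not reached is a hole and gets set.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside(nr * nc, 0);
  std::queue<int> q;
  auto push_bg = [&](int i, int j) {
    int p = idx(i, j, nr);
    if (!mask(i, j) && !outside[p]) { outside[p] = 1; q.push(p); }
  };
  for (int i = 0; i < nr; ++i) { push_bg(i, 0); push_bg(i, nc - 1); }
  for (int j = 0; j < nc; ++j) { push_bg(0, j); push_bg(nr - 1, j); }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int i = p % nr, j = p / nr;
    for (int d = 0; d < 4; ++d) {
      int ii = i + di[d], jj = j + dj[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) && !outside[idx(ii, jj, nr)]) {
        outside[idx(ii, jj, nr)] = 1;
        q.push(idx(ii, jj, nr));
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = mask(i, j) || !outside[idx(i, j, nr)];
  return out;
}

// Grayscale reconstruction by dilation (Vincent 1993 hybrid algorithm),
// 8-connectivity. Requires marker <= mask everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct(const NumericMatrix& marker,
                              const NumericMatrix& mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  if (mask.nrow() != nr || mask.ncol() != nc)
    stop("marker and mask dimensions differ");
  NumericMatrix J(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (marker(i, j) > mask(i, j)) stop("marker exceeds mask");
      J(i, j) = marker(i, j);
    }

  // raster scan: N+ neighbours (above row, left)
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      double m = J(i, j);
      if (i > 0) {
        m = std::max(m, J(i - 1, j));
        if (j > 0) m = std::max(m, J(i - 1, j - 1));
        if (j < nc - 1) m = std::max(m, J(i - 1, j + 1));
      }
      if (j > 0) m = std::max(m, J(i, j - 1));
      J(i, j) = std::min(m, mask(i, j));
    }
  // anti-raster scan + queue seeding
  std::queue<int> fifo;
  for (int j = nc - 1; j >= 0; --j)
    for (int i = nr - 1; i >= 0; --i) {
      double m = J(i, j);
      if (i < nr - 1) {
        m = std::max(m, J(i + 1, j));
        if (j > 0) m = std::max(m, J(i + 1, j - 1));
        if (j < nc - 1) m = std::max(m, J(i + 1, j + 1));
      }
      if (j < nc - 1) m = std::max(m, J(i, j + 1));
      J(i, j) = std::min(m, mask(i, j));
      // queue if some N- neighbour could still grow
      bool enq = false;
      const int di[4] = {1, 1, 1, 0}, dj[4] = {-1, 0, 1, 1};
      for (int d = 0; d < 4 && !enq; ++d) {
        int ii = i + di[d], jj = j + dj[d];
        if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
        if (J(ii, jj) < J(i, j) && J(ii, jj) < mask(ii, jj)) enq = true;
      }
      if (enq) fifo.push(idx(i, j, nr));
    }
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!fifo.empty()) {
    int p = fifo.front(); fifo.pop();
    int i = p % nr, j = p / nr;
    for (int d = 0; d < 8; ++d) {
      int ii = i + di8[d], jj = j + dj8[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (J(ii, jj) < J(i, j) && mask(ii, jj) != J(ii, jj)) {
        J(ii, jj) = std::min(J(i, j), mask(ii, jj));
        fifo.push(idx(ii, jj, nr));
      }
    }
  }
  return J;
}

// Connected-component labelling (BFS), connectivity 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity = 8) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int ndir = (connectivity == 4) ? 4 : 8;
  const int di4[4] = {-1, 1, 0, 0}, dj4[4] = {0, 0, -1, 1};
  int next = 0;
  std::queue<int> q;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push(idx(i, j, nr));
      while (!q.empty()) {
        int p = q.front(); q.pop();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < ndir; ++d) {
          int ii = pi + (connectivity == 4 ? di4[d] : di8[d]);
          int jj = pj + (connectivity == 4 ? dj4[d] : dj8[d]);
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (mask(ii, jj) && lab(ii, jj) == 0) {
            lab(ii, jj) = next;
            q.push(idx(ii, jj, nr));
          }
        }
      }
    }
  return lab;
}

struct WsNode {
  double elev; long order; int pix; int label;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // lower elevation first
    return a.order > b.order;                      // FIFO tie-break
  }
};

// Marker-based watershed by priority flooding, restricted to mask.
// Floods ascending `elev` (pass the negated intensity to split at ridges
// of a bright image). Unlabelled mask pixels unreachable from markers
// remain 0. 4-connectivity flood keeps fronts compact and deterministic.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& elev,
                            const IntegerMatrix& markers,
                            const LogicalMatrix& mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (markers(i, j) > 0 && mask(i, j)) {
        lab(i, j) = markers(i, j);
        pq.push({elev(i, j), order++, idx(i, j, nr), markers(i, j)});
      }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!pq.empty()) {
    WsNode nd = pq.top(); pq.pop();
    int i = nd.pix % nr, j = nd.pix / nr;
    for (int d = 0; d < 4; ++d) {
      int ii = i + di[d], jj = j + dj[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
      lab(ii, jj) = nd.label;
      double e = std::max(nd.elev, elev(ii, jj));  // flood never recedes
      pq.push({e, order++, idx(ii, jj, nr), nd.label});
    }
  }
  return lab;
}

struct ExNode {
  double dist; long order; int pix; int label; int seed;
  bool operator<(const ExNode& o) const {
    if (dist != o.dist) return dist > o.dist;
    return order > o.order;
  }
};

// Expand labelled regions outward by up to max_dist pixels, assigning each
// free pixel to the label owning the nearest labelled pixel (Euclidean,
// centre-to-centre). Seed coordinates are propagated so distances stay
// exact; ties resolve to the lower label for determinism.
// [[Rcpp::export]]
IntegerMatrix cpp_expand_labels(const IntegerMatrix& labels,
                                double max_dist) {
  int nr = labels.nrow(), nc = labels.ncol();
  IntegerMatrix out = clone(labels);
  std::vector<double> best(nr * nc,
                           std::numeric_limits<double>::infinity());
  std::priority_queue<ExNode> pq;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (labels(i, j) > 0) {
        int p = idx(i, j, nr);
        best[p] = 0.0;
        pq.push({0.0, order++, p, labels(i, j), p});
      }
  const int di8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dj8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  while (!pq.empty()) {
    ExNode nd = pq.top(); pq.pop();
    if (nd.dist > best[nd.pix]) continue;
    int i = nd.pix % nr, j = nd.pix / nr;
    int si = nd.seed % nr, sj = nd.seed / nr;
    for (int d = 0; d < 8; ++d) {
      int ii = i + di8[d], jj = j + dj8[d];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      int p = idx(ii, jj, nr);
      if (labels(ii, jj) > 0) continue;  // nuclei keep their own label
      double dd = std::sqrt((double)((ii - si) * (ii - si) +
                                     (jj - sj) * (jj - sj)));
      if (dd > max_dist) continue;
      if (dd < best[p] - 1e-12 ||
          (std::abs(dd - best[p]) <= 1e-12 && nd.label < out(ii, jj))) {
        best[p] = dd;
        out(ii, jj) = nd.label;
        pq.push({dd, order++, p, nd.label, nd.seed});
      }
    }
  }
  return out;
}
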