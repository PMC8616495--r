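// Low-level image kernels for the segmentation pipeline and the movie
// renderer. All matrices are column-major (R layout); coordinates are
// (row, col), 1-based only at the R interface.
#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int reflect(int i, int n) {
  // mirror boundary without repeating the edge sample twice in a row
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// Separable Gaussian blur with mirror boundary. sigma <= 0 returns a copy.
// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& img, double sigma) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  if (sigma <= 0) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  std::vector<double> k = gauss_kernel(sigma);
  int r = ((int)k.size() - 1) / 2;
  NumericMatrix tmp(H, W);
  const double* kp = k.data();
  // columns (vertical pass); interior rows need no boundary handling
  for (int c = 0; c < W; ++c) {
    const double* col = &img(0, c);
    double* tcol = &tmp(0, c);
    int i = 0;
    for (; i < std::min(r, H); ++i) {
      double acc = 0.0;
      for (int j = -r; j <= r; ++j) acc += kp[j + r] * col[reflect(i + j, H)];
      tcol[i] = acc;
    }
    for (; i < H - r; ++i) {
      double acc = 0.0;
      const double* base = col + i - r;
      for (int j = 0; j <= 2 * r; ++j) acc += kp[j] * base[j];
      tcol[i] = acc;
    }
    for (; i < H; ++i) {
      double acc = 0.0;
      for (int j = -r; j <= r; ++j) acc += kp[j + r] * col[reflect(i + j, H)];
      tcol[i] = acc;
    }
  }
  // rows (horizontal pass); process by output column for locality
  for (int c = 0; c < W; ++c) {
    double* ocol = &out(0, c);
    bool interior = (c >= r && c < W - r);
    for (int j = -r; j <= r; ++j) {
      int src = interior ? c + j : reflect(c + j, W);
      const double* scol = &tmp(0, src);
      double kj = kp[j + r];
      if (j == -r)
        for (int i = 0; i < H; ++i) ocol[i] = kj * scol[i];
      else
        for (int i = 0; i < H; ++i) ocol[i] += kj * scol[i];
    }
  }
  return out;
}

// 4-neighbour Laplacian, replicate boundary.
// [[Rcpp::export]]
NumericMatrix cpp_laplacian(const NumericMatrix& img) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int i = 0; i < H; ++i) {
      double up = img(i > 0 ? i - 1 : 0, c);
      double dn = img(i < H - 1 ? i + 1 : H - 1, c);
      double lf = img(i, c > 0 ? c - 1 : 0);
      double rt = img(i, c < W - 1 ? c + 1 : W - 1);
      out(i, c) = up + dn + lf + rt - 4.0 * img(i, c);
    }
  return out;
}

// Running min (or max) along each column with half-window w, clamp boundary.
static void run_extreme_cols(const NumericMatrix& in, NumericMatrix& out,
                             int w, bool take_min) {
  int H = in.nrow(), W = in.ncol();
  for (int c = 0; c < W; ++c) {
    std::deque<int> q;  // indices, monotone
    for (int i = 0; i < H + w; ++i) {
      if (i < H) {
        double v = in(i, c);
        while (!q.empty() &&
               (take_min ? in(q.back(), c) >= v : in(q.back(), c) <= v))
          q.pop_back();
        q.push_back(i);
      }
      int center = i - w;
      if (center >= 0) {
        while (q.front() < center - w) q.pop_front();
        out(center, c) = in(q.front(), c);
      }
    }
  }
}

// Grayscale erosion/dilation by a disk of integer radius, via chord
// decomposition: for each column offset dx the disk contributes a vertical
// chord of half-length cy(dx); the result is the extreme over shifted
// column-filtered copies. Boundary: clamp (replicate edge).
static NumericMatrix disk_morph(const NumericMatrix& img, int radius,
                                bool take_min) {
  int H = img.nrow(), W = img.ncol();
  double init = take_min ? R_PosInf : R_NegInf;
  NumericMatrix out(H, W);
  std::fill(out.begin(), out.end(), init);
  NumericMatrix colf(H, W);
  for (int dx = -radius; dx <= radius; ++dx) {
    int cy = (int)std::floor(std::sqrt((double)radius * radius - (double)dx * dx));
    run_extreme_cols(img, colf, cy, take_min);
    for (int c = 0; c < W; ++c) {
      int src = c + dx;
      if (src < 0) src = 0;
      if (src >= W) src = W - 1;
      for (int i = 0; i < H; ++i) {
        double v = colf(i, src);
        if (take_min ? v < out(i, c) : v > out(i, c)) out(i, c) = v;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_disk_erode(const NumericMatrix& img, int radius) {
  return disk_morph(img, radius, true);
}

// [[Rcpp::export]]
NumericMatrix cpp_disk_dilate(const NumericMatrix& img, int radius) {
  return disk_morph(img, radius, false);
}

// 8-connected component labelling (iterative stack flood fill).
// [[Rcpp::export]]
IntegerMatrix cpp_label8(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int c = 0; c < W; ++c)
    for (int i = 0; i < H; ++i) {
      if (!mask(i, c) || lab(i, c)) continue;
      ++next;
      stack.push_back(std::make_pair(i, c));
      lab(i, c) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            if (!di && !dj) continue;
            int ni = p.first + di, nj = p.second + dj;
            if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
            if (mask(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.push_back(std::make_pair(ni, nj));
            }
          }
      }
    }
  return lab;
}

// Fill holes: background flood fill (4-connected, matching 8-connected
// foreground) from the border; unreached background pixels become foreground.
// [[Rcpp::export]]
LogicalMatrix cpp_fill_holes(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix outside(H, W);  // reachable background
  std::vector<std::pair<int, int> > stack;
  for (int c = 0; c < W; ++c) {
    if (!mask(0, c)) stack.push_back(std::make_pair(0, c));
    if (!mask(H - 1, c)) stack.push_back(std::make_pair(H - 1, c));
  }
  for (int i = 0; i < H; ++i) {
    if (!mask(i, 0)) stack.push_back(std::make_pair(i, 0));
    if (!mask(i, W - 1)) stack.push_back(std::make_pair(i, W - 1));
  }
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    if (outside(p.first, p.second)) continue;
    outside(p.first, p.second) = true;
    for (int d = 0; d < 4; ++d) {
      int ni = p.first + di[d], nj = p.second + dj[d];
      if (ni < 0 || nj < 0 || ni >= H || nj >= W) continue;
      if (!mask(ni, nj) && !outside(ni, nj))
        stack.push_back(std::make_pair(ni, nj));
    }
  }
  LogicalMatrix filled(H, W);
  for (int c = 0; c < W; ++c)
    for (int i = 0; i < H; ++i) filled(i, c) = mask(i, c) || !outside(i, c);
  return filled;
}

// Moore-neighbour boundary trace of a single (filled, 8-connected) object.
// Returns c(Ne, No, Nc): even (axis) steps, odd (diagonal) steps, direction
// changes around the closed chain. A 1-pixel object returns c(0, 0, 0).
// [[Rcpp::export]]
IntegerVector cpp_trace_chain(const LogicalMatrix& mask) {
  int H = mask.nrow(), W = mask.ncol();
  // pad by 1 so neighbour lookups never leave the array
  int Hp = H + 2, Wp = W + 2;
  std::vector<char> pad((size_t)Hp * Wp, 0);
  int sr = -1, sc = -1;
  for (int i = 0; i < H && sr < 0; ++i)
    for (int c = 0; c < W; ++c)
      if (mask(i, c)) {
        if (sr < 0) { sr = i + 1; sc = c + 1; }
      }
  for (int c = 0; c < W; ++c)
    for (int i = 0; i < H; ++i)
      if (mask(i, c)) pad[(size_t)(c + 1) * Hp + (i + 1)] = 1;
  IntegerVector res(3);
  if (sr < 0) return res;
  // clockwise neighbour order starting north; (drow, dcol)
  const int nr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int nc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  std::vector<int> chain;
  int cr = sr, cc = sc;
  int backtrack = 6;  // came from the west (raster-first pixel contract)
  long guard = 8L * Hp * Wp;
  while (guard-- > 0) {
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (backtrack + k) % 8;
      int ni = cr + nr[d], nj = cc + nc[d];
      if (pad[(size_t)nj * Hp + ni]) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    chain.push_back(found);
    cr += nr[found];
    cc += nc[found];
    backtrack = (found + 4) % 8;
    if (cr == sr && cc == sc) {
      // peek the next move; stop when the chain would repeat its first step
      int nxt = -1;
      for (int k = 1; k <= 8; ++k) {
        int d = (backtrack + k) % 8;
        int ni = cr + nr[d], nj = cc + nc[d];
        if (pad[(size_t)nj * Hp + ni]) { nxt = d; break; }
      }
      if (nxt == chain[0]) break;
    }
  }
  int ne = 0, no = 0, ncnr = 0;
  int n = (int)chain.size();
  for (int i = 0; i < n; ++i) {
    if (chain[i] % 2 == 0) ++ne; else ++no;
    if (chain[i] != chain[(i + n - 1) % n]) ++ncnr;
  }
  res[0] = ne; res[1] = no; res[2] = ncnr;
  return res;
}

// Rasterize filled disks (centres in pixel units, 1-based) into a mask.
// [[Rcpp::export]]
LogicalMatrix cpp_render_disks(const NumericVector& rows,
                               const NumericVector& cols, double radius,
                               int H, int W) {
  LogicalMatrix out(H, W);
  double r2 = radius * radius;
  int n = rows.size();
  for (int m = 0; m < n; ++m) {
    double cy = rows[m] - 1.0, cx = cols[m] - 1.0;
    int i0 = std::max(0, (int)std::floor(cy - radius));
    int i1 = std::min(H - 1, (int)std::ceil(cy + radius));
    int j0 = std::max(0, (int)std::floor(cx - radius));
    int j1 = std::min(W - 1, (int)std::ceil(cx + radius));
    for (int j = j0; j <= j1; ++j) {
      double dx = j - cx;
      for (int i = i0; i <= i1; ++i) {
        double dy = i - cy;
        if (dy * dy + dx * dx <= r2) out(i, j) = true;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
int cpp_disks_footprint(const NumericVector& rows, const NumericVector& cols,
                        double radius, int H, int W) {
  LogicalMatrix m = cpp_render_disks(rows, cols, radius, H, W);
  int s = 0;
  for (LogicalMatrix::iterator it = m.begin(); it != m.end(); ++it)
    if (*it) ++s;
  return s;
}
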