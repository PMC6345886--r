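// Low-level voxel kernels backing the 3D segmentation workflow.
// Arrays are passed as flat numeric vectors with dim = c(nz, ny, nx),
// index = z + nz * (y + ny * x), i.e. R's native array layout for [z, y, x].

#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>

using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

static inline int idx3(int z, int y, int x, int nz, int ny) {
  return z + nz * (y + ny * x);
}

// Rank filter over an arbitrary voxel footprint (offsets: K x 3, columns
// dz, dy, dx). stat: 0 = min, 1 = max, 2 = median. Borders replicate.
// [[Rcpp::export]]
NumericVector cpp_footprint_filter(NumericVector arr, IntegerVector dim,
                                   IntegerMatrix off, int stat) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int K = off.nrow();
  NumericVector out(arr.size());
  std::vector<double> buf(K);
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        for (int k = 0; k < K; ++k) {
          int zz = clampi(z + off(k, 0), 0, nz - 1);
          int yy = clampi(y + off(k, 1), 0, ny - 1);
          int xx = clampi(x + off(k, 2), 0, nx - 1);
          buf[k] = arr[idx3(zz, yy, xx, nz, ny)];
        }
        double v;
        if (stat == 0) {
          v = *std::min_element(buf.begin(), buf.end());
        } else if (stat == 1) {
          v = *std::max_element(buf.begin(), buf.end());
        } else {
          int mid = K / 2;
          std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
          v = buf[mid];
          if (K % 2 == 0) {
            double lo = *std::max_element(buf.begin(), buf.begin() + mid);
            v = 0.5 * (v + lo);
          }
        }
        out[idx3(z, y, x, nz, ny)] = v;
      }
    }
  }
  return out;
}

// Mask of voxels equal to the maximum of their box neighbourhood
// (half-widths hw = c(hz, hy, hx); borders clamp).
// [[Rcpp::export]]
LogicalVector cpp_local_max_mask(NumericVector arr, IntegerVector dim,
                                 IntegerVector hw) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int hz = hw[0], hy = hw[1], hx = hw[2];
  LogicalVector out(arr.size());
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) {
      for (int z = 0; z < nz; ++z) {
        double centre = arr[idx3(z, y, x, nz, ny)];
        bool ismax = true;
        for (int dx = -hx; dx <= hx && ismax; ++dx) {
          int xx = clampi(x + dx, 0, nx - 1);
          for (int dy = -hy; dy <= hy && ismax; ++dy) {
            int yy = clampi(y + dy, 0, ny - 1);
            for (int dz = -hz; dz <= hz; ++dz) {
              int zz = clampi(z + dz, 0, nz - 1);
              if (arr[idx3(zz, yy, xx, nz, ny)] > centre) {
                ismax = false;
                break;
              }
            }
          }
        }
        out[idx3(z, y, x, nz, ny)] = ismax;
      }
    }
  }
  return out;
}

static void neighbour_offsets(int conn, std::vector<int> &dz,
                              std::vector<int> &dy, std::vector<int> &dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nn = std::abs(a) + std::abs(b) + std::abs(c);
        if (conn == 6 && nn != 1) continue;
        dz.push_back(a);
        dy.push_back(b);
        dx.push_back(c);
      }
}

// Connected-component labelling of a binary volume (conn = 6 or 26).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int conn) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = mask.size();
  std::vector<int> dz, dy, dx;
  neighbour_offsets(conn, dz, dy, dx);
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int x = cur / (nz * ny);
      int rem = cur - x * nz * ny;
      int y = rem / nz;
      int z = rem - y * nz;
      for (size_t k = 0; k < dz.size(); ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        int j = idx3(zz, yy, xx, nz, ny);
        if (mask[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

struct WsNode {
  double val;
  long order;
  int idx;
  int lab;
};
struct WsCmp {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.val != b.val) return a.val < b.val;  // highest intensity first
    return a.order > b.order;                  // FIFO among ties
  }
};

// Seeded watershed by priority flooding: regions grow from labelled seeds
// through `mask`, brightest voxels first (26-connectivity). Deterministic.
// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector intensity, IntegerVector seeds,
                                   LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const int n = intensity.size();
  std::vector<int> dz, dy, dx;
  neighbour_offsets(26, dz, dy, dx);
  IntegerVector lab(n, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  long order = 0;
  for (int i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      pq.push(WsNode{intensity[i], order++, i, seeds[i]});
    }
  }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    if (lab[nd.idx] != 0) continue;
    lab[nd.idx] = nd.lab;
    int x = nd.idx / (nz * ny);
    int rem = nd.idx - x * nz * ny;
    int y = rem / nz;
    int z = rem - y * nz;
    for (size_t k = 0; k < dz.size(); ++k) {
      int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
        continue;
      int j = idx3(zz, yy, xx, nz, ny);
      if (mask[j] && lab[j] == 0) {
        pq.push(WsNode{intensity[j], order++, j, nd.lab});
      }
    }
  }
  return lab;
}

static void parabolic_pass_1d(std::vector<double> &f, double c, bool erode) {
  const int n = (int)f.size();
  std::vector<double> out(n);
  for (int i = 0; i < n; ++i) {
    double best = erode ? R_PosInf : R_NegInf;
    for (int j = 0; j < n; ++j) {
      double d = (double)(i - j);
      double v = erode ? f[j] + c * d * d : f[j] - c * d * d;
      if (erode ? (v < best) : (v > best)) best = v;
    }
    out[i] = best;
  }
  f.swap(out);
}

static void parabolic_morph_2d(std::vector<double> &img, int nrow, int ncol,
                               double c, bool erode) {
  std::vector<double> line;
  // columns (first index fastest in R matrices)
  line.resize(nrow);
  for (int j = 0; j < ncol; ++j) {
    for (int i = 0; i < nrow; ++i) line[i] = img[i + nrow * j];
    parabolic_pass_1d(line, c, erode);
    for (int i = 0; i < nrow; ++i) img[i + nrow * j] = line[i];
  }
  // rows
  line.resize(ncol);
  for (int i = 0; i < nrow; ++i) {
    for (int j = 0; j < ncol; ++j) line[j] = img[i + nrow * j];
    parabolic_pass_1d(line, c, erode);
    for (int j = 0; j < ncol; ++j) img[i + nrow * j] = line[j];
  }
}

// Sliding-paraboloid background: grayscale opening of a 2D plane with the
// additively-separable paraboloid structuring function z = d^2 / (2 * radius).
// Returns the background estimate.
// [[Rcpp::export]]
NumericMatrix cpp_paraboloid_background(NumericMatrix img, double radius) {
  const int nrow = img.nrow(), ncol = img.ncol();
  const double c = 1.0 / (2.0 * radius);
  std::vector<double> work(img.begin(), img.end());
  parabolic_morph_2d(work, nrow, ncol, c, true);   // erosion
  parabolic_morph_2d(work, nrow, ncol, c, false);  // dilation -> opening
  NumericMatrix out(nrow, ncol);
  std::copy(work.begin(), work.end(), out.begin());
  return out;
}
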