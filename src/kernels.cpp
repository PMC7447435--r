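// Low-level volumetric kernels: 3D convolution (im2col + GEMM), exact
// Euclidean distance transform, separable Gaussian blur, regional maxima,
// seeded watershed, connected components, inter-label boundary mask.
// All arrays are R column-major with dim = (d1, d2, d3[, channels]); the
// "scan order" used for deterministic tie-breaking is R's linear index order.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline void get_dim3(const RObject& x, int& d1, int& d2, int& d3) {
  IntegerVector d = x.attr("dim");
  d1 = d[0]; d2 = d[1]; d3 = d[2];
}

// ---------------------------------------------------------------------------
// im2col for "same" zero-padded convolution with odd kernel (k1,k2,k3).
// Column layout matches the column-major flattening of a weight array with
// dim (k1, k2, k3, cin, cout): column index = kx1 + k1*(kx2 + k2*(kx3 + k3*ci)).
static arma::mat im2col3d(const NumericVector& x,
                          int d1, int d2, int d3, int cin,
                          int k1, int k2, int k3) {
  const int n = d1 * d2 * d3;
  const int p1 = (k1 - 1) / 2, p2 = (k2 - 1) / 2, p3 = (k3 - 1) / 2;
  arma::mat cols(n, (size_t)k1 * k2 * k3 * cin, arma::fill::zeros);
  const double* xp = x.begin();
  size_t col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = xp + (size_t)ci * n;
    for (int kx3 = 0; kx3 < k3; ++kx3)
    for (int kx2 = 0; kx2 < k2; ++kx2)
    for (int kx1 = 0; kx1 < k1; ++kx1, ++col) {
      const int o1 = kx1 - p1, o2 = kx2 - p2, o3 = kx3 - p3;
      double* dst = cols.colptr(col);
      const int i3lo = std::max(0, -o3), i3hi = std::min(d3, d3 - o3);
      const int i2lo = std::max(0, -o2), i2hi = std::min(d2, d2 - o2);
      const int i1lo = std::max(0, -o1), i1hi = std::min(d1, d1 - o1);
      for (int i3 = i3lo; i3 < i3hi; ++i3)
      for (int i2 = i2lo; i2 < i2hi; ++i2) {
        const size_t src_off = (size_t)(i3 + o3) * d1 * d2 + (size_t)(i2 + o2) * d1;
        const size_t dst_off = (size_t)i3 * d1 * d2 + (size_t)i2 * d1;
        const double* s = xc + src_off + o1;
        double* t = dst + dst_off;
        for (int i1 = i1lo; i1 < i1hi; ++i1) t[i1] = s[i1];
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_forward(NumericVector x, NumericVector w, NumericVector bias) {
  IntegerVector xd = x.attr("dim");   // (d1,d2,d3,cin)
  IntegerVector wd = w.attr("dim");   // (k1,k2,k3,cin,cout)
  int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3];
  int k1 = wd[0], k2 = wd[1], k3 = wd[2], cout = wd[4];
  if (wd[3] != cin) stop("conv: channel mismatch");
  const int n = d1 * d2 * d3;
  arma::mat cols = im2col3d(x, d1, d2, d3, cin, k1, k2, k3);
  arma::mat W(w.begin(), (size_t)k1 * k2 * k3 * cin, cout, false, true);
  arma::mat Y = cols * W;
  NumericVector out((size_t)n * cout);
  for (int co = 0; co < cout; ++co) {
    double b = bias[co];
    double* op = out.begin() + (size_t)co * n;
    const double* yp = Y.colptr(co);
    for (int i = 0; i < n; ++i) op[i] = yp[i] + b;
  }
  out.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
  return out;
}

// col2im: scatter-add the column matrix back into a (d1,d2,d3,cin) array.
static NumericVector col2im3d(const arma::mat& cols,
                              int d1, int d2, int d3, int cin,
                              int k1, int k2, int k3) {
  const int n = d1 * d2 * d3;
  const int p1 = (k1 - 1) / 2, p2 = (k2 - 1) / 2, p3 = (k3 - 1) / 2;
  NumericVector dx((size_t)n * cin);
  size_t col = 0;
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = dx.begin() + (size_t)ci * n;
    for (int kx3 = 0; kx3 < k3; ++kx3)
    for (int kx2 = 0; kx2 < k2; ++kx2)
    for (int kx1 = 0; kx1 < k1; ++kx1, ++col) {
      const int o1 = kx1 - p1, o2 = kx2 - p2, o3 = kx3 - p3;
      const double* src = cols.colptr(col);
      const int i3lo = std::max(0, -o3), i3hi = std::min(d3, d3 - o3);
      const int i2lo = std::max(0, -o2), i2hi = std::min(d2, d2 - o2);
      const int i1lo = std::max(0, -o1), i1hi = std::min(d1, d1 - o1);
      for (int i3 = i3lo; i3 < i3hi; ++i3)
      for (int i2 = i2lo; i2 < i2hi; ++i2) {
        const size_t dst_off = (size_t)(i3 + o3) * d1 * d2 + (size_t)(i2 + o2) * d1;
        const size_t src_off = (size_t)i3 * d1 * d2 + (size_t)i2 * d1;
        double* t = xc + dst_off + o1;
        const double* s = src + src_off;
        for (int i1 = i1lo; i1 < i1hi; ++i1) t[i1] += s[i1];
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(d1, d2, d3, cin);
  return dx;
}

// [[Rcpp::export]]
List cpp_conv3d_backward(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim");
  IntegerVector wd = w.attr("dim");
  int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3];
  int k1 = wd[0], k2 = wd[1], k3 = wd[2], cout = wd[4];
  const int n = d1 * d2 * d3;
  arma::mat cols = im2col3d(x, d1, d2, d3, cin, k1, k2, k3);
  arma::mat W(w.begin(), (size_t)k1 * k2 * k3 * cin, cout, false, true);
  arma::mat dY(dy.begin(), n, cout, false, true);
  arma::mat dW = cols.t() * dY;                 // (K x cout)
  arma::mat dcols = dY * W.t();                 // (n x K)
  NumericVector dx = col2im3d(dcols, d1, d2, d3, cin, k1, k2, k3);
  NumericVector dwv(dW.memptr(), dW.memptr() + dW.n_elem);
  dwv.attr("dim") = wd;
  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) db[co] = arma::accu(dY.col(co));
  return List::create(_["dx"] = dx, _["dw"] = dwv, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (distance to nearest mask==1
// voxel), Felzenszwalb & Huttenlocher separable lower-envelope passes.
// `f` uses a large finite sentinel (EDT_BIG) for "no source"; vanilla
// lower-envelope algorithm then works unchanged.
static const double EDT_BIG = 1e30;

static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n,
                   std::vector<int>& v, std::vector<double>& z) {
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask) {
  int d1, d2, d3; get_dim3(mask, d1, d2, d3);
  const double INF = EDT_BIG;
  size_t n = (size_t)d1 * d2 * d3;
  NumericVector D(n);
  for (size_t i = 0; i < n; ++i) D[i] = mask[i] ? 0.0 : INF;
  int m = std::max(d1, std::max(d2, d3));
  std::vector<double> f(m), dd(m), z(m + 1);
  std::vector<int> v(m);
  // axis 1
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i2 = 0; i2 < d2; ++i2) {
      size_t off = (size_t)i3 * d1 * d2 + (size_t)i2 * d1;
      bool any = false;
      for (int i = 0; i < d1; ++i) { f[i] = D[off + i]; if (f[i] < 1e29) any = true; }
      if (!any) continue;
      edt_1d(f, dd, d1, v, z);
      for (int i = 0; i < d1; ++i) D[off + i] = dd[i];
    }
  // axis 2
  for (int i3 = 0; i3 < d3; ++i3)
    for (int i1 = 0; i1 < d1; ++i1) {
      size_t base = (size_t)i3 * d1 * d2 + i1;
      bool any = false;
      for (int i = 0; i < d2; ++i) { f[i] = D[base + (size_t)i * d1]; if (f[i] < 1e29) any = true; }
      if (!any) continue;
      edt_1d(f, dd, d2, v, z);
      for (int i = 0; i < d2; ++i) D[base + (size_t)i * d1] = dd[i];
    }
  // axis 3
  for (int i2 = 0; i2 < d2; ++i2)
    for (int i1 = 0; i1 < d1; ++i1) {
      size_t base = (size_t)i2 * d1 + i1;
      bool any = false;
      for (int i = 0; i < d3; ++i) { f[i] = D[base + (size_t)i * d1 * d2]; if (f[i] < 1e29) any = true; }
      if (!any) continue;
      edt_1d(f, dd, d3, v, z);
      for (int i = 0; i < d3; ++i) D[base + (size_t)i * d1 * d2] = dd[i];
    }
  D.attr("dim") = IntegerVector::create(d1, d2, d3);
  return D;
}

// ---------------------------------------------------------------------------
// Separable Gaussian blur, symmetric reflection at borders (d c b a | a b c d),
// kernel truncated at radius round(4*sigma) and renormalized. Axes of size 1
// are skipped.
static void blur_axis(std::vector<double>& buf, const std::vector<double>& ker,
                      int n, int r) {
  static thread_local std::vector<double> tmp;
  tmp.assign(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double acc = 0.0;
    for (int k = -r; k <= r; ++k) {
      int j = i + k;
      // symmetric reflect into [0, n)
      while (j < 0 || j >= n) { if (j < 0) j = -j - 1; if (j >= n) j = 2 * n - j - 1; }
      acc += ker[k + r] * buf[j];
    }
    tmp[i] = acc;
  }
  buf = tmp;
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur3d(NumericVector x, double sigma) {
  int d1, d2, d3; get_dim3(x, d1, d2, d3);
  NumericVector out = clone(x);
  if (sigma <= 0) { out.attr("dim") = IntegerVector::create(d1, d2, d3); return out; }
  int r = (int)std::lround(4.0 * sigma);
  if (r < 1) r = 1;
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int k = -r; k <= r; ++k) { ker[k + r] = std::exp(-0.5 * k * k / (sigma * sigma)); s += ker[k + r]; }
  for (auto& v : ker) v /= s;
  std::vector<double> buf;
  if (d1 > 1) {
    buf.resize(d1);
    for (int i3 = 0; i3 < d3; ++i3) for (int i2 = 0; i2 < d2; ++i2) {
      size_t off = (size_t)i3 * d1 * d2 + (size_t)i2 * d1;
      for (int i = 0; i < d1; ++i) buf[i] = out[off + i];
      blur_axis(buf, ker, d1, r);
      for (int i = 0; i < d1; ++i) out[off + i] = buf[i];
    }
  }
  if (d2 > 1) {
    buf.resize(d2);
    for (int i3 = 0; i3 < d3; ++i3) for (int i1 = 0; i1 < d1; ++i1) {
      size_t base = (size_t)i3 * d1 * d2 + i1;
      for (int i = 0; i < d2; ++i) buf[i] = out[base + (size_t)i * d1];
      blur_axis(buf, ker, d2, r);
      for (int i = 0; i < d2; ++i) out[base + (size_t)i * d1] = buf[i];
    }
  }
  if (d3 > 1) {
    buf.resize(d3);
    for (int i2 = 0; i2 < d2; ++i2) for (int i1 = 0; i1 < d1; ++i1) {
      size_t base = (size_t)i2 * d1 + i1;
      for (int i = 0; i < d3; ++i) buf[i] = out[base + (size_t)i * d1 * d2];
      blur_axis(buf, ker, d3, r);
      for (int i = 0; i < d3; ++i) out[base + (size_t)i * d1 * d2] = buf[i];
    }
  }
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  return out;
}

static const int NB = 6;
static inline int neighbors6(int idx, int d1, int d2, int d3, int* out) {
  int i1 = idx % d1, rest = idx / d1, i2 = rest % d2, i3 = rest / d2;
  int cnt = 0;
  if (i1 > 0)      out[cnt++] = idx - 1;
  if (i1 < d1 - 1) out[cnt++] = idx + 1;
  if (i2 > 0)      out[cnt++] = idx - d1;
  if (i2 < d2 - 1) out[cnt++] = idx + d1;
  if (i3 > 0)      out[cnt++] = idx - d1 * d2;
  if (i3 < d3 - 1) out[cnt++] = idx + d1 * d2;
  return cnt;
}

// ---------------------------------------------------------------------------
// Regional maxima with plateau handling: each connected (6-conn) plateau of
// equal value with no strictly greater neighbor contributes exactly one seed,
// placed at its lowest scan-order voxel. Returns integer labels (0 elsewhere),
// seed ids numbered 1..K in scan order of their anchor voxel.
// [[Rcpp::export]]
IntegerVector cpp_regional_maxima(NumericVector x) {
  int d1, d2, d3; get_dim3(x, d1, d2, d3);
  int n = d1 * d2 * d3;
  IntegerVector seeds(n);
  seeds.attr("dim") = IntegerVector::create(d1, d2, d3);
  std::vector<char> visited(n, 0);
  std::vector<int> stack, plateau;
  int nb[NB];
  int next_id = 1;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    double v = x[i];
    stack.clear(); plateau.clear();
    stack.push_back(i); visited[i] = 1;
    bool is_max = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      plateau.push_back(c);
      int cnt = neighbors6(c, d1, d2, d3, nb);
      for (int k = 0; k < cnt; ++k) {
        int j = nb[k];
        if (x[j] > v) is_max = false;
        else if (x[j] == v && !visited[j]) { visited[j] = 1; stack.push_back(j); }
      }
    }
    if (is_max) { seeds[i] = next_id++; } // i is the lowest scan-order plateau voxel
  }
  return seeds;
}

// ---------------------------------------------------------------------------
// Seeded watershed by priority flooding: voxels with higher `priority` are
// assigned first; ties broken by insertion order (scan order for the initial
// seed fronts), which makes the labeling deterministic. 6-connectivity.
struct WsEntry {
  double p; long long ord; int idx;
};
struct WsCmp {
  bool operator()(const WsEntry& a, const WsEntry& b) const {
    if (a.p != b.p) return a.p < b.p;      // max-heap on priority
    return a.ord > b.ord;                  // earlier insertion first
  }
};

// [[Rcpp::export]]
IntegerVector cpp_seeded_watershed(NumericVector priority, IntegerVector seeds) {
  int d1, d2, d3; get_dim3(priority, d1, d2, d3);
  int n = d1 * d2 * d3;
  IntegerVector lab(n);
  lab.attr("dim") = IntegerVector::create(d1, d2, d3);
  std::priority_queue<WsEntry, std::vector<WsEntry>, WsCmp> pq;
  long long ord = 0;
  for (int i = 0; i < n; ++i) {
    lab[i] = seeds[i];
    if (seeds[i] > 0) pq.push({priority[i], ord++, i});
  }
  int nb[NB];
  while (!pq.empty()) {
    WsEntry e = pq.top(); pq.pop();
    int l = lab[e.idx];
    int cnt = neighbors6(e.idx, d1, d2, d3, nb);
    for (int k = 0; k < cnt; ++k) {
      int j = nb[k];
      if (lab[j] == 0) { lab[j] = l; pq.push({priority[j], ord++, j}); }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// 6-connected components of a binary mask, labeled 1..K in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector mask) {
  int d1, d2, d3; get_dim3(mask, d1, d2, d3);
  int n = d1 * d2 * d3;
  IntegerVector lab(n);
  lab.attr("dim") = IntegerVector::create(d1, d2, d3);
  std::vector<int> stack;
  int nb[NB];
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    lab[i] = next; stack.clear(); stack.push_back(i);
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cnt = neighbors6(c, d1, d2, d3, nb);
      for (int k = 0; k < cnt; ++k) {
        int j = nb[k];
        if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Two-voxel-thick inter-label boundary: a voxel is marked iff any voxel in
// its 26-neighborhood carries a different positive label, so both flanking
// voxels of every inter-label face are marked. For flat axis-aligned
// interfaces this is exactly the two adjacent voxel layers; oblique
// interfaces are marked at the (slightly larger) thickness their geometry
// requires, which keeps the boundary band closed under a Gaussian blur +
// 0.5 threshold. Faces against label 0 (ignore) are not boundaries.
// [[Rcpp::export]]
IntegerVector cpp_boundary_mask(IntegerVector labels) {
  int d1, d2, d3; get_dim3(labels, d1, d2, d3);
  int n = d1 * d2 * d3;
  IntegerVector out(n);
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  for (int i = 0; i < n; ++i) {
    int li = labels[i];
    if (li <= 0) continue;
    int i1 = i % d1, rest = i / d1, i2 = rest % d2, i3 = rest / d2;
    bool hit = false;
    for (int o3 = -1; o3 <= 1 && !hit; ++o3) {
      int j3 = i3 + o3; if (j3 < 0 || j3 >= d3) continue;
      for (int o2 = -1; o2 <= 1 && !hit; ++o2) {
        int j2 = i2 + o2; if (j2 < 0 || j2 >= d2) continue;
        for (int o1 = -1; o1 <= 1 && !hit; ++o1) {
          int j1 = i1 + o1; if (j1 < 0 || j1 >= d1) continue;
          int lj = labels[j1 + d1 * (j2 + (size_t)d2 * j3)];
          if (lj > 0 && lj != li) hit = true;
        }
      }
    }
    if (hit) out[i] = 1;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Sliding-window box sums with zero padding (used by SSIM); window = 2r+1 per
// axis (axes of size 1 keep window 1).
// [[Rcpp::export]]
NumericVector cpp_boxsum3d(NumericVector x, int r) {
  int d1, d2, d3; get_dim3(x, d1, d2, d3);
  NumericVector out = clone(x);
  auto pass = [&](int len, int stride, size_t base) {
    static thread_local std::vector<double> tmp;
    tmp.assign(len, 0.0);
    for (int i = 0; i < len; ++i) {
      double acc = 0.0;
      int lo = std::max(0, i - r), hi = std::min(len - 1, i + r);
      for (int j = lo; j <= hi; ++j) acc += out[base + (size_t)j * stride];
      tmp[i] = acc;
    }
    for (int i = 0; i < len; ++i) out[base + (size_t)i * stride] = tmp[i];
  };
  if (d1 > 1)
    for (int i3 = 0; i3 < d3; ++i3) for (int i2 = 0; i2 < d2; ++i2)
      pass(d1, 1, (size_t)i3 * d1 * d2 + (size_t)i2 * d1);
  if (d2 > 1)
    for (int i3 = 0; i3 < d3; ++i3) for (int i1 = 0; i1 < d1; ++i1)
      pass(d2, d1, (size_t)i3 * d1 * d2 + i1);
  if (d3 > 1)
    for (int i2 = 0; i2 < d2; ++i2) for (int i1 = 0; i1 < d1; ++i1)
      pass(d3, d1 * d2, (size_t)i2 * d1 + i1);
  out.attr("dim") = IntegerVector::create(d1, d2, d3);
  return out;
}
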