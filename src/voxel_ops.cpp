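#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Volumes are column-major arrays with dim (ny, nx, nz); linear index
// i = y + ny * (x + nx * z), all 0-based here.

// ---------------------------------------------------------------------------
// Connected-component labeling.
// connectivity: 26 or 6 (full 3-D), 8 or 4 (within-slice only, dz = 0).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int ny = dims[0], nx = dims[1];
  const int nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");

  std::vector<int> dy, dx, dz;
  const int zlo = (connectivity == 4 || connectivity == 8) ? 0 : -1;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = zlo; c <= -zlo; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if ((connectivity == 6 || connectivity == 4) && manh != 1) continue;
        dy.push_back(a); dx.push_back(b); dz.push_back(c);
      }
  const int noff = (int)dy.size();

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int cur = 0;
  const R_xlen_t plane = (R_xlen_t)ny * nx;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    lab[i] = ++cur;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t v = stack.back(); stack.pop_back();
      int z = (int)(v / plane);
      int rem = (int)(v % plane);
      int x = rem / ny, y = rem % ny;
      for (int k = 0; k < noff; ++k) {
        int yy = y + dy[k], xx = x + dx[k], zz = z + dz[k];
        if (yy < 0 || yy >= ny || xx < 0 || xx >= nx || zz < 0 || zz >= nz)
          continue;
        R_xlen_t u = yy + (R_xlen_t)ny * (xx + (R_xlen_t)nx * zz);
        if (mask[u] && !lab[u]) { lab[u] = cur; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// Separable binary box dilation: out = OR over a box window of half-widths
// (ry, rx, rz). Erosion is done in R as !dilate(!mask).
// ---------------------------------------------------------------------------

static void dilate_axis(std::vector<char> &v, int ny, int nx, int nz,
                        int axis, int r) {
  if (r <= 0) return;
  const R_xlen_t plane = (R_xlen_t)ny * nx;
  int len, nlines;
  if (axis == 0) { len = ny; nlines = nx * nz; }
  else if (axis == 1) { len = nx; nlines = ny * nz; }
  else { len = nz; nlines = ny * nx; }
  std::vector<char> line(len);
  for (int L = 0; L < nlines; ++L) {
    R_xlen_t base; R_xlen_t stride;
    if (axis == 0) { int x = L % nx, z = L / nx; base = (R_xlen_t)ny * x + plane * z; stride = 1; }
    else if (axis == 1) { int y = L % ny, z = L / ny; base = y + plane * z; stride = ny; }
    else { base = L; stride = plane; }
    int cnt = 0;
    // initialize window [0, r)
    for (int i = 0; i < len && i <= r - 1; ++i) cnt += v[base + stride * i] != 0;
    for (int i = 0; i < len; ++i) {
      int hi = i + r, lo = i - r - 1;
      if (hi < len) cnt += v[base + stride * hi] != 0;
      if (lo >= 0) cnt -= v[base + stride * lo] != 0;
      line[i] = cnt > 0;
    }
    for (int i = 0; i < len; ++i) v[base + stride * i] = line[i];
  }
}

// [[Rcpp::export]]
LogicalVector box_dilate_cpp(LogicalVector mask, IntegerVector dims,
                             IntegerVector radius) {
  const int ny = dims[0], nx = dims[1];
  const int nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t n = (R_xlen_t)ny * nx * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  std::vector<char> v(n);
  for (R_xlen_t i = 0; i < n; ++i) v[i] = mask[i] == TRUE;
  dilate_axis(v, ny, nx, nz, 0, radius[0]);
  dilate_axis(v, ny, nx, nz, 1, radius[1]);
  if (radius.size() > 2) dilate_axis(v, ny, nx, nz, 2, radius[2]);
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = v[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Exact slicewise squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher): distance of every TRUE voxel to the nearest FALSE voxel,
// computed independently per z-slice in voxel units.
// ---------------------------------------------------------------------------

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt2d_slicewise_cpp(LogicalVector mask, IntegerVector dims) {
  const int ny = dims[0], nx = dims[1];
  const int nz = dims.size() > 2 ? dims[2] : 1;
  const R_xlen_t plane = (R_xlen_t)ny * nx;
  const double INF = 1e18;
  NumericVector out((R_xlen_t)plane * nz);
  int m = std::max(ny, nx);
  std::vector<double> f(m), d(m), z(m + 1);
  std::vector<int> v(m);
  std::vector<double> g(plane);
  for (int zz = 0; zz < nz; ++zz) {
    R_xlen_t off = plane * zz;
    // pass 1: along y (columns of the slice)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y)
        f[y] = mask[off + y + (R_xlen_t)ny * x] ? INF : 0.0;
      dt1d(f, d, ny, v, z);
      for (int y = 0; y < ny; ++y) g[y + (R_xlen_t)ny * x] = d[y];
    }
    // pass 2: along x
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[y + (R_xlen_t)ny * x];
      dt1d(f, d, nx, v, z);
      for (int x = 0; x < nx; ++x) out[off + y + (R_xlen_t)ny * x] = d[x];
    }
  }
  return out; // squared distances
}

// ---------------------------------------------------------------------------
// 2-D convolution, "same" padding, odd kernel. Activations are column-major
// arrays dim (H, W, C, N); weights dim (K, K, Cin, Cout).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector conv2d_fwd_cpp(NumericVector x, IntegerVector xdim,
                             NumericVector w, IntegerVector wdim,
                             NumericVector b) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Cin = wdim[2], Cout = wdim[3];
  if (Cin != C) stop("channel mismatch");
  const int pad = K / 2;
  NumericVector y((R_xlen_t)H * W * Cout * N);
  const double *X = x.begin(); const double *Wt = w.begin();
  double *Y = y.begin();
  const R_xlen_t xs_c = (R_xlen_t)H * W, xs_n = xs_c * C;
  const R_xlen_t ys_c = (R_xlen_t)H * W, ys_n = ys_c * Cout;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      double *yp = Y + ys_n * n + ys_c * co;
      const double bb = b[co];
      for (R_xlen_t i = 0; i < ys_c; ++i) yp[i] = bb;
      for (int ci = 0; ci < C; ++ci) {
        const double *xp = X + xs_n * n + xs_c * ci;
        for (int kw = 0; kw < K; ++kw) {
          int dw = kw - pad;
          int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
          for (int kh = 0; kh < K; ++kh) {
            int dh = kh - pad;
            int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const double wv = Wt[kh + (R_xlen_t)K * (kw + (R_xlen_t)K * (ci + (R_xlen_t)Cin * co))];
            if (wv == 0.0) continue;
            for (int ww = w0; ww < w1; ++ww) {
              const double *xcol = xp + (R_xlen_t)H * (ww + dw) + dh;
              double *ycol = yp + (R_xlen_t)H * ww;
              for (int hh = h0; hh < h1; ++hh)
                ycol[hh] += wv * xcol[hh];
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List conv2d_bwd_cpp(NumericVector x, IntegerVector xdim,
                    NumericVector w, IntegerVector wdim,
                    NumericVector dy) {
  const int H = xdim[0], W = xdim[1], C = xdim[2], N = xdim[3];
  const int K = wdim[0], Cin = wdim[2], Cout = wdim[3];
  const int pad = K / 2;
  NumericVector dx((R_xlen_t)H * W * C * N);
  NumericVector dw((R_xlen_t)K * K * Cin * Cout);
  NumericVector db(Cout);
  const double *X = x.begin(); const double *Wt = w.begin();
  const double *DY = dy.begin();
  double *DX = dx.begin(); double *DW = dw.begin();
  const R_xlen_t xs_c = (R_xlen_t)H * W, xs_n = xs_c * C;
  const R_xlen_t ys_c = (R_xlen_t)H * W, ys_n = ys_c * Cout;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double *dyp = DY + ys_n * n + ys_c * co;
      double s = 0.0;
      for (R_xlen_t i = 0; i < ys_c; ++i) s += dyp[i];
      db[co] += s;
      for (int ci = 0; ci < C; ++ci) {
        const double *xp = X + xs_n * n + xs_c * ci;
        double *dxp = DX + xs_n * n + xs_c * ci;
        for (int kw = 0; kw < K; ++kw) {
          int dwo = kw - pad;
          int w0 = std::max(0, -dwo), w1 = std::min(W, W - dwo);
          for (int kh = 0; kh < K; ++kh) {
            int dh = kh - pad;
            int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
            const R_xlen_t wi = kh + (R_xlen_t)K * (kw + (R_xlen_t)K * (ci + (R_xlen_t)Cin * co));
            const double wv = Wt[wi];
            double acc = 0.0;
            for (int ww = w0; ww < w1; ++ww) {
              const double *xcol = xp + (R_xlen_t)H * (ww + dwo) + dh;
              double *dxcol = dxp + (R_xlen_t)H * (ww + dwo) + dh;
              const double *dycol = dyp + (R_xlen_t)H * ww;
              for (int hh = h0; hh < h1; ++hh) {
                const double g = dycol[hh];
                acc += g * xcol[hh];
                dxcol[hh] += g * wv;
              }
            }
            DW[wi] += acc;
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// ---------------------------------------------------------------------------
// Exact two-sided permutation p-value for the Spearman statistic: enumerates
// all distinct permutations of the y-ranks (std::next_permutation handles
// ties) and counts |cov| >= |observed cov|. Feasible for n <= 10.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
double spearman_perm_pvalue_cpp(NumericVector rx, NumericVector ry) {
  const int n = rx.size();
  std::vector<double> a(n), b(n);
  double mx = 0, my = 0;
  for (int i = 0; i < n; ++i) { mx += rx[i]; my += ry[i]; }
  mx /= n; my /= n;
  for (int i = 0; i < n; ++i) { a[i] = rx[i] - mx; b[i] = ry[i] - my; }
  double obs = 0.0;
  for (int i = 0; i < n; ++i) obs += a[i] * b[i];
  obs = std::fabs(obs);
  std::sort(b.begin(), b.end());
  double cnt = 0, tot = 0;
  const double eps = 1e-9;
  do {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += a[i] * b[i];
    if (std::fabs(s) >= obs - eps) cnt += 1;
    tot += 1;
  } while (std::next_permutation(b.begin(), b.end()));
  return cnt / tot;
}
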