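// Low-level numerical kernels: 3D convolution (im2col + GEMM) with gradients,
// max-pooling, trilinear resizing, separable Gaussian smoothing, squared
// Euclidean distance transform, probabilistic streamline propagation and
// voxel resampling. All arrays are column-major with dims (X, Y, Z[, C]).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int vidx(int x, int y, int z, int X, int Y) {
  return x + X * (y + Y * z);
}

// im2col for 'same' zero-padded k x k x k convolution.
// Row i = voxel, column r = kx + k*(ky + k*(kz + k*c)).
static arma::mat im2col3d(const double* x, int X, int Y, int Z, int C, int k) {
  const int N = X * Y * Z, p = (k - 1) / 2, K3 = k * k * k;
  arma::mat cols(N, (size_t)K3 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)N * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * c));
          double* dst = cols.colptr(col);
          const int dx = kx - p, dy = ky - p, dz = kz - p;
          for (int z = 0; z < Z; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              const double* src = xc + vidx(x0 + dx, sy, sz, X, Y);
              double* d = dst + vidx(x0, y, z, X, Y);
              for (int xx = x0; xx < x1; ++xx) *d++ = *src++;
            }
          }
        }
  }
  return cols;
}

// [[Rcpp::export]]
NumericMatrix cpp_im2col(NumericVector x, IntegerVector dims, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int N = X * Y * Z, p = (k - 1) / 2;
  NumericMatrix cols(N, k * k * k * C);      // zero-initialized by R
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)N * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * c));
          double* dst = &cols(0, col);
          const int dx = kx - p, dy = ky - p, dz = kz - p;
          for (int z = 0; z < Z; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              std::memcpy(dst + vidx(x0, y, z, X, Y),
                          xc + vidx(x0 + dx, sy, sz, X, Y),
                          sizeof(double) * (x1 - x0));
            }
          }
        }
  }
  return cols;
}

// scatter-add of unfolded gradients back to the input grid
// [[Rcpp::export]]
NumericVector cpp_col2im(NumericMatrix gcols, IntegerVector dims, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int N = X * Y * Z, p = (k - 1) / 2;
  NumericVector gx((size_t)N * C);
  gx.attr("dim") = dims;
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    double* gxc = gxp + (size_t)N * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * c));
          const double* src = &gcols(0, col);
          const int dx = kx - p, dy = ky - p, dz = kz - p;
          for (int z = 0; z < Z; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              double* d = gxc + vidx(x0 + dx, sy, sz, X, Y);
              const double* s = src + vidx(x0, y, z, X, Y);
              for (int xx = x0; xx < x1; ++xx) *d++ += *s++;
            }
          }
        }
  }
  return gx;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, IntegerVector dims,
                             NumericMatrix w, NumericVector b, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int N = X * Y * Z, Cout = w.ncol();
  arma::mat cols = im2col3d(x.begin(), X, Y, Z, C, k);
  arma::mat W(w.begin(), w.nrow(), Cout, false);
  arma::mat out = cols * W;
  for (int c = 0; c < Cout; ++c) out.col(c) += b[c];
  NumericVector y(out.begin(), out.end());
  y.attr("dim") = IntegerVector::create(X, Y, Z, Cout);
  return y;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd(NumericVector x, IntegerVector dims, NumericMatrix w,
                    NumericVector gout, int k) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int N = X * Y * Z, Cout = w.ncol(), p = (k - 1) / 2;
  arma::mat cols = im2col3d(x.begin(), X, Y, Z, C, k);
  arma::mat G(gout.begin(), N, Cout, false);
  arma::mat W(w.begin(), w.nrow(), Cout, false);
  arma::mat gW = cols.t() * G;
  arma::rowvec gb = arma::sum(G, 0);
  arma::mat gcols = G * W.t();          // N x (k^3 * C)
  // col2im: scatter-add back to input gradient
  NumericVector gx(x.size());
  gx.attr("dim") = dims;
  double* gxp = gx.begin();
  for (int c = 0; c < C; ++c) {
    double* gxc = gxp + (size_t)N * c;
    for (int kz = 0; kz < k; ++kz)
      for (int ky = 0; ky < k; ++ky)
        for (int kx = 0; kx < k; ++kx) {
          const int col = kx + k * (ky + k * (kz + k * c));
          const double* src = gcols.colptr(col);
          const int dx = kx - p, dy = ky - p, dz = kz - p;
          for (int z = 0; z < Z; ++z) {
            const int sz = z + dz;
            if (sz < 0 || sz >= Z) continue;
            for (int y = 0; y < Y; ++y) {
              const int sy = y + dy;
              if (sy < 0 || sy >= Y) continue;
              const int x0 = std::max(0, -dx), x1 = std::min(X, X - dx);
              double* d = gxc + vidx(x0 + dx, sy, sz, X, Y);
              const double* s = src + vidx(x0, y, z, X, Y);
              for (int xx = x0; xx < x1; ++xx) *d++ += *s++;
            }
          }
        }
  }
  return List::create(_["gx"] = gx,
                      _["gw"] = NumericMatrix(gW.n_rows, gW.n_cols, gW.begin()),
                      _["gb"] = NumericVector(gb.begin(), gb.end()));
}

// 2x2x2 max-pool, stride 2. Returns pooled values and flat argmax indices.
// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = X / 2, Yo = Y / 2, Zo = Z / 2, No = Xo * Yo * Zo, N = X * Y * Z;
  NumericVector y((size_t)No * C);
  IntegerVector am((size_t)No * C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)N * c;
    double* yc = y.begin() + (size_t)No * c;
    int* ac = am.begin() + (size_t)No * c;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          double best = -INFINITY; int bi = -1;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                int i = vidx(2 * xx + dx, 2 * yy + dy, 2 * z + dz, X, Y);
                if (xc[i] > best) { best = xc[i]; bi = i; }
              }
          int o = vidx(xx, yy, z, Xo, Yo);
          yc[o] = best; ac[o] = bi + c * N;
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gout, IntegerVector argmax,
                                IntegerVector in_dims) {
  size_t n = (size_t)in_dims[0] * in_dims[1] * in_dims[2] * in_dims[3];
  NumericVector gx(n);
  gx.attr("dim") = in_dims;
  for (R_xlen_t i = 0; i < gout.size(); ++i) gx[argmax[i]] += gout[i];
  return gx;
}

struct LinW { int i0, i1; double w0, w1; };
static std::vector<LinW> lin_weights(int n_out, int n_in) {
  std::vector<LinW> w(n_out);
  double s = (double)n_in / n_out;
  for (int i = 0; i < n_out; ++i) {
    double p = (i + 0.5) * s - 0.5;
    int i0 = (int)std::floor(p);
    double f = p - i0;
    int a = std::min(std::max(i0, 0), n_in - 1);
    int b = std::min(std::max(i0 + 1, 0), n_in - 1);
    w[i] = {a, b, 1.0 - f, f};
  }
  return w;
}

// [[Rcpp::export]]
NumericVector cpp_resize_trilinear_fwd(NumericVector x, IntegerVector dims,
                                       IntegerVector out_dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2], C = dims[3];
  const int Xo = out_dims[0], Yo = out_dims[1], Zo = out_dims[2];
  const int N = X * Y * Z, No = Xo * Yo * Zo;
  auto wx = lin_weights(Xo, X), wy = lin_weights(Yo, Y), wz = lin_weights(Zo, Z);
  NumericVector y((size_t)No * C);
  for (int c = 0; c < C; ++c) {
    const double* xc = x.begin() + (size_t)N * c;
    double* yc = y.begin() + (size_t)No * c;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          const LinW &a = wx[xx], &b = wy[yy], &d = wz[z];
          double v = 0.0;
          v += d.w0 * (b.w0 * (a.w0 * xc[vidx(a.i0,b.i0,d.i0,X,Y)] + a.w1 * xc[vidx(a.i1,b.i0,d.i0,X,Y)])
                     + b.w1 * (a.w0 * xc[vidx(a.i0,b.i1,d.i0,X,Y)] + a.w1 * xc[vidx(a.i1,b.i1,d.i0,X,Y)]));
          v += d.w1 * (b.w0 * (a.w0 * xc[vidx(a.i0,b.i0,d.i1,X,Y)] + a.w1 * xc[vidx(a.i1,b.i0,d.i1,X,Y)])
                     + b.w1 * (a.w0 * xc[vidx(a.i0,b.i1,d.i1,X,Y)] + a.w1 * xc[vidx(a.i1,b.i1,d.i1,X,Y)]));
          yc[vidx(xx, yy, z, Xo, Yo)] = v;
        }
  }
  y.attr("dim") = IntegerVector::create(Xo, Yo, Zo, C);
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_resize_trilinear_bwd(NumericVector gout, IntegerVector out_dims,
                                       IntegerVector in_dims) {
  const int X = in_dims[0], Y = in_dims[1], Z = in_dims[2], C = in_dims[3];
  const int Xo = out_dims[0], Yo = out_dims[1], Zo = out_dims[2];
  const int N = X * Y * Z, No = Xo * Yo * Zo;
  auto wx = lin_weights(Xo, X), wy = lin_weights(Yo, Y), wz = lin_weights(Zo, Z);
  NumericVector gx((size_t)N * C);
  gx.attr("dim") = in_dims;
  for (int c = 0; c < C; ++c) {
    double* gxc = gx.begin() + (size_t)N * c;
    const double* gc = gout.begin() + (size_t)No * c;
    for (int z = 0; z < Zo; ++z)
      for (int yy = 0; yy < Yo; ++yy)
        for (int xx = 0; xx < Xo; ++xx) {
          const LinW &a = wx[xx], &b = wy[yy], &d = wz[z];
          double g = gc[vidx(xx, yy, z, Xo, Yo)];
          gxc[vidx(a.i0,b.i0,d.i0,X,Y)] += g * a.w0 * b.w0 * d.w0;
          gxc[vidx(a.i1,b.i0,d.i0,X,Y)] += g * a.w1 * b.w0 * d.w0;
          gxc[vidx(a.i0,b.i1,d.i0,X,Y)] += g * a.w0 * b.w1 * d.w0;
          gxc[vidx(a.i1,b.i1,d.i0,X,Y)] += g * a.w1 * b.w1 * d.w0;
          gxc[vidx(a.i0,b.i0,d.i1,X,Y)] += g * a.w0 * b.w0 * d.w1;
          gxc[vidx(a.i1,b.i0,d.i1,X,Y)] += g * a.w1 * b.w0 * d.w1;
          gxc[vidx(a.i0,b.i1,d.i1,X,Y)] += g * a.w0 * b.w1 * d.w1;
          gxc[vidx(a.i1,b.i1,d.i1,X,Y)] += g * a.w1 * b.w1 * d.w1;
        }
  }
  return gx;
}

// Separable Gaussian smoothing of a 3D volume, kernel truncated at 3*sigma,
// renormalized at the borders (so constants are preserved exactly).
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth3d(NumericVector x, IntegerVector dims, double sigma) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) { kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma)); s += kern[i + r]; }
  for (auto &v : kern) v /= s;
  std::vector<double> a(x.begin(), x.end()), b(a.size());
  const int dim3[3] = {X, Y, Z};
  const int stride[3] = {1, X, X * Y};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = dim3[ax], st = stride[ax];
    for (int z = 0; z < Z; ++z)
      for (int y = 0; y < Y; ++y)
        for (int xx = 0; xx < X; ++xx) {
          int idx3[3] = {xx, y, z};
          int base = vidx(xx, y, z, X, Y);
          double acc = 0.0, wsum = 0.0;
          int p = idx3[ax];
          int lo = std::max(-r, -p), hi = std::min(r, n - 1 - p);
          for (int o = lo; o <= hi; ++o) { acc += kern[o + r] * a[base + o * st]; wsum += kern[o + r]; }
          b[base] = acc / wsum;
        }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = IntegerVector::create(X, Y, Z);
  return out;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), weight w2 = spacing^2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n, double w2) {
  std::vector<int> v(n); std::vector<double> zb(n + 1);
  int k = 0; v[0] = 0; zb[0] = -INFINITY; zb[1] = INFINITY;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) / (2.0 * w2 * (q - v[k]));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    d[q] = w2 * (q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) to the nearest nonzero voxel of mask.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dims, NumericVector spacing) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const double BIG = 1e15;
  std::vector<double> d((size_t)X * Y * Z);
  for (size_t i = 0; i < d.size(); ++i) d[i] = mask[i] ? 0.0 : BIG;
  const int dim3[3] = {X, Y, Z};
  const int stride[3] = {1, X, X * Y};
  for (int ax = 0; ax < 3; ++ax) {
    const int n = dim3[ax], st = stride[ax];
    double w2 = spacing[ax] * spacing[ax];
    std::vector<double> f(n), o(n);
    for (int z = 0; z < (ax == 2 ? 1 : Z); ++z)
      for (int y = 0; y < (ax == 1 ? 1 : Y); ++y)
        for (int xx = 0; xx < (ax == 0 ? 1 : X); ++xx) {
          int base = vidx(xx, y, z, X, Y);
          for (int i = 0; i < n; ++i) f[i] = d[base + (size_t)i * st];
          dt1d(f, o, n, w2);
          for (int i = 0; i < n; ++i) d[base + (size_t)i * st] = o[i];
        }
  }
  NumericVector out(d.begin(), d.end());
  out.attr("dim") = dims;
  return out;
}

static inline bool inside(double px, double py, double pz, int X, int Y, int Z) {
  return px > -0.5 && py > -0.5 && pz > -0.5 && px < X - 0.5 && py < Y - 0.5 && pz < Z - 0.5;
}

// von Mises-Fisher sample about unit vector mu (uses R's RNG).
static void vmf_sample(const double* mu, double kappa, double* out) {
  if (!R_finite(kappa) || kappa > 1e8) { out[0] = mu[0]; out[1] = mu[1]; out[2] = mu[2]; return; }
  double u = unif_rand();
  double w = 1.0 + std::log(u + (1.0 - u) * std::exp(-2.0 * kappa)) / kappa;
  if (w > 1.0) w = 1.0; if (w < -1.0) w = -1.0;
  // orthonormal basis perpendicular to mu
  double ax[3] = {1, 0, 0};
  if (std::fabs(mu[0]) > 0.9) { ax[0] = 0; ax[1] = 1; }
  double e1[3] = {mu[1] * ax[2] - mu[2] * ax[1], mu[2] * ax[0] - mu[0] * ax[2], mu[0] * ax[1] - mu[1] * ax[0]};
  double n1 = std::sqrt(e1[0]*e1[0] + e1[1]*e1[1] + e1[2]*e1[2]);
  for (int i = 0; i < 3; ++i) e1[i] /= n1;
  double e2[3] = {mu[1]*e1[2] - mu[2]*e1[1], mu[2]*e1[0] - mu[0]*e1[2], mu[0]*e1[1] - mu[1]*e1[0]};
  double th = 2.0 * M_PI * unif_rand();
  double st = std::sqrt(std::max(0.0, 1.0 - w * w));
  for (int i = 0; i < 3; ++i) out[i] = w * mu[i] + st * (std::cos(th) * e1[i] + std::sin(th) * e2[i]);
}

// Probabilistic streamline propagation (bidirectional from each seed).
// v1: (X,Y,Z,3) principal directions; mask: (X,Y,Z) 0/1 tracking mask;
// seeds: n x 3 zero-based voxel coordinates; step in voxel units.
// reason codes: 1 = mask exit / volume exit, 2 = angle failure, 3 = length cap.
// [[Rcpp::export]]
List cpp_track(NumericVector v1, IntegerVector dims, IntegerVector mask,
               NumericMatrix seeds, double step, double max_angle_deg,
               double kappa, int max_steps, int max_tries) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int N = X * Y * Z;
  const double cosmax = std::cos(max_angle_deg * M_PI / 180.0);
  const int ns = seeds.nrow();
  List out(ns);
  IntegerVector reason_fwd(ns), reason_bwd(ns);
  for (int si = 0; si < ns; ++si) {
    double seed[3] = {seeds(si, 0), seeds(si, 1), seeds(si, 2)};
    std::vector<double> branch[2];
    int reasons[2] = {3, 3};
    for (int dir = 0; dir < 2; ++dir) {
      double p[3] = {seed[0], seed[1], seed[2]};
      int ix = (int)std::lround(p[0]), iy = (int)std::lround(p[1]), iz = (int)std::lround(p[2]);
      if (!inside(p[0], p[1], p[2], X, Y, Z) || !mask[vidx(ix, iy, iz, X, Y)]) { reasons[dir] = 1; continue; }
      int vi = vidx(ix, iy, iz, X, Y);
      double prev[3] = {v1[vi], v1[vi + N], v1[vi + 2 * N]};
      double nv = std::sqrt(prev[0]*prev[0] + prev[1]*prev[1] + prev[2]*prev[2]);
      if (nv < 1e-12) { reasons[dir] = 2; continue; }
      for (int i = 0; i < 3; ++i) prev[i] /= nv;
      if (dir == 1) for (int i = 0; i < 3; ++i) prev[i] = -prev[i];
      for (int stp = 0; stp < max_steps; ++stp) {
        ix = (int)std::lround(p[0]); iy = (int)std::lround(p[1]); iz = (int)std::lround(p[2]);
        vi = vidx(ix, iy, iz, X, Y);
        double mu[3] = {v1[vi], v1[vi + N], v1[vi + 2 * N]};
        nv = std::sqrt(mu[0]*mu[0] + mu[1]*mu[1] + mu[2]*mu[2]);
        if (nv < 1e-12) { reasons[dir] = 2; break; }
        for (int i = 0; i < 3; ++i) mu[i] /= nv;
        if (mu[0]*prev[0] + mu[1]*prev[1] + mu[2]*prev[2] < 0)
          for (int i = 0; i < 3; ++i) mu[i] = -mu[i];
        double d[3]; bool ok = false;
        for (int t = 0; t < max_tries; ++t) {
          vmf_sample(mu, kappa, d);
          if (d[0]*prev[0] + d[1]*prev[1] + d[2]*prev[2] >= cosmax) { ok = true; break; }
        }
        if (!ok) { reasons[dir] = 2; break; }
        double q[3] = {p[0] + step * d[0], p[1] + step * d[1], p[2] + step * d[2]};
        if (!inside(q[0], q[1], q[2], X, Y, Z)) { reasons[dir] = 1; break; }
        int qx = (int)std::lround(q[0]), qy = (int)std::lround(q[1]), qz = (int)std::lround(q[2]);
        if (!mask[vidx(qx, qy, qz, X, Y)]) { reasons[dir] = 1; break; }
        branch[dir].insert(branch[dir].end(), q, q + 3);
        for (int i = 0; i < 3; ++i) { p[i] = q[i]; prev[i] = d[i]; }
      }
    }
    const int nb = (int)branch[1].size() / 3, nf = (int)branch[0].size() / 3;
    NumericMatrix pts(nb + 1 + nf, 3);
    for (int i = 0; i < nb; ++i)       // reversed backward branch first
      for (int j = 0; j < 3; ++j) pts(i, j) = branch[1][(size_t)3 * (nb - 1 - i) + j];
    for (int j = 0; j < 3; ++j) pts(nb, j) = seed[j];
    for (int i = 0; i < nf; ++i)
      for (int j = 0; j < 3; ++j) pts(nb + 1 + i, j) = branch[0][(size_t)3 * i + j];
    out[si] = pts;
    reason_fwd[si] = reasons[0]; reason_bwd[si] = reasons[1];
  }
  return List::create(_["points"] = out, _["reason_fwd"] = reason_fwd,
                      _["reason_bwd"] = reason_bwd);
}

// Distinct-streamline visitation counts: each streamline increments a voxel
// at most once regardless of how many of its points fall inside it.
// [[Rcpp::export]]
IntegerVector cpp_visitation(List streamlines, IntegerVector dims) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const size_t N = (size_t)X * Y * Z;
  IntegerVector cnt(N);
  std::vector<int> stamp(N, -1);
  for (int s = 0; s < streamlines.size(); ++s) {
    NumericMatrix m = streamlines[s];
    for (int i = 0; i < m.nrow(); ++i) {
      int x = (int)std::lround(m(i, 0)), y = (int)std::lround(m(i, 1)), z = (int)std::lround(m(i, 2));
      if (x < 0 || y < 0 || z < 0 || x >= X || y >= Y || z >= Z) continue;
      size_t v = vidx(x, y, z, X, Y);
      if (stamp[v] != s) { stamp[v] = s; ++cnt[v]; }
    }
  }
  cnt.attr("dim") = dims;
  return cnt;
}

// Eigen-decomposition of per-voxel symmetric 3x3 tensors.
// coef: n x 6 (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz). Returns eigenvalues sorted
// descending (n x 3) and the principal eigenvector (n x 3).
// [[Rcpp::export]]
List cpp_eig3_sym(NumericMatrix coef) {
  const int n = coef.nrow();
  NumericMatrix evals(n, 3), v1(n, 3);
  arma::mat33 D;
  arma::vec3 ev;
  arma::mat33 V;
  for (int i = 0; i < n; ++i) {
    D(0,0) = coef(i,0); D(0,1) = D(1,0) = coef(i,1); D(0,2) = D(2,0) = coef(i,2);
    D(1,1) = coef(i,3); D(1,2) = D(2,1) = coef(i,4); D(2,2) = coef(i,5);
    arma::eig_sym(ev, V, D);    // ascending
    for (int j = 0; j < 3; ++j) evals(i, j) = ev(2 - j);
    for (int j = 0; j < 3; ++j) v1(i, j) = V(j, 2);
  }
  return List::create(_["evals"] = evals, _["v1"] = v1);
}

// Sample a 3D volume at arbitrary voxel coordinates (n x 3, zero-based).
// mode 0 = trilinear (border-clamped), 1 = nearest; outside -> fill.
// [[Rcpp::export]]
NumericVector cpp_sample3d(NumericVector vol, IntegerVector dims,
                           NumericMatrix coords, int mode, double fill) {
  const int X = dims[0], Y = dims[1], Z = dims[2];
  const int n = coords.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1), pz = coords(i, 2);
    if (px < -0.5 || py < -0.5 || pz < -0.5 || px > X - 0.5 || py > Y - 0.5 || pz > Z - 0.5) {
      out[i] = fill; continue;
    }
    if (mode == 1) {
      int x = std::min(std::max((int)std::lround(px), 0), X - 1);
      int y = std::min(std::max((int)std::lround(py), 0), Y - 1);
      int z = std::min(std::max((int)std::lround(pz), 0), Z - 1);
      out[i] = vol[vidx(x, y, z, X, Y)];
    } else {
      int x0 = (int)std::floor(px), y0 = (int)std::floor(py), z0 = (int)std::floor(pz);
      double fx = px - x0, fy = py - y0, fz = pz - z0;
      int x1 = x0 + 1, y1 = y0 + 1, z1 = z0 + 1;
      int cx0 = std::min(std::max(x0, 0), X - 1), cx1 = std::min(std::max(x1, 0), X - 1);
      int cy0 = std::min(std::max(y0, 0), Y - 1), cy1 = std::min(std::max(y1, 0), Y - 1);
      int cz0 = std::min(std::max(z0, 0), Z - 1), cz1 = std::min(std::max(z1, 0), Z - 1);
      double v =
        (1-fz) * ((1-fy) * ((1-fx) * vol[vidx(cx0,cy0,cz0,X,Y)] + fx * vol[vidx(cx1,cy0,cz0,X,Y)])
                +  fy    * ((1-fx) * vol[vidx(cx0,cy1,cz0,X,Y)] + fx * vol[vidx(cx1,cy1,cz0,X,Y)]))
        + fz   * ((1-fy) * ((1-fx) * vol[vidx(cx0,cy0,cz1,X,Y)] + fx * vol[vidx(cx1,cy0,cz1,X,Y)])
                +  fy    * ((1-fx) * vol[vidx(cx0,cy1,cz1,X,Y)] + fx * vol[vidx(cx1,cy1,cz1,X,Y)]));
      out[i] = v;
    }
  }
  return out;
}
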