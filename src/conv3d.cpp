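#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cstring>
#include <vector>
using namespace Rcpp;

// 3D convolution stack for the spatio-temporal residual U-Net.
// Array layout is R column-major with dims (nx, ny, nt, channels);
// kernels are (3,3,3,cin,cout), zero padding 1, stride 1 (correlation
// convention, no kernel flip). Convolutions are lowered to im2col + BLAS
// dgemm; the im2col column ordering matches the column-major kernel layout
// (3x3x3 offsets fastest, then input channel).

static inline long idx4(long x, long y, long t, long c, long nx, long ny, long nt) {
  return x + nx * (y + ny * (t + nt * c));
}

// copy the (a,b,c)-shifted channel volume of x into column `col` of A
// (nvox rows), zero outside bounds
static void im2col_fill(const double *xc, double *col,
                        long nx, long ny, long nt, int a, int b, int c) {
  long nvox = nx * ny * nt;
  std::memset(col, 0, nvox * sizeof(double));
  long tlo = std::max(0L, (long)-c), thi = nt - 1 - std::max(0L, (long)c);
  long ylo = std::max(0L, (long)-b), yhi = ny - 1 - std::max(0L, (long)b);
  long xlo = std::max(0L, (long)-a), xhi = nx - 1 - std::max(0L, (long)a);
  long len = xhi - xlo + 1;
  if (len <= 0) return;
  for (long t = tlo; t <= thi; ++t)
    for (long y = ylo; y <= yhi; ++y)
      std::memcpy(col + idx4(xlo, y, t, 0, nx, ny, nt),
                  xc + idx4(xlo + a, y + b, t + c, 0, nx, ny, nt),
                  len * sizeof(double));
}

// scatter-add column `col` back with the inverse shift (adjoint of im2col_fill)
static void col2im_add(const double *col, double *xc,
                       long nx, long ny, long nt, int a, int b, int c) {
  long tlo = std::max(0L, (long)-c), thi = nt - 1 - std::max(0L, (long)c);
  long ylo = std::max(0L, (long)-b), yhi = ny - 1 - std::max(0L, (long)b);
  long xlo = std::max(0L, (long)-a), xhi = nx - 1 - std::max(0L, (long)a);
  long len = xhi - xlo + 1;
  if (len <= 0) return;
  for (long t = tlo; t <= thi; ++t)
    for (long y = ylo; y <= yhi; ++y) {
      double *dst = xc + idx4(xlo + a, y + b, t + c, 0, nx, ny, nt);
      const double *src = col + idx4(xlo, y, t, 0, nx, ny, nt);
      for (long i = 0; i < len; ++i) dst[i] += src[i];
    }
}

static void build_im2col(const double *px, double *A,
                         long nx, long ny, long nt, int cin) {
  long nvox = nx * ny * nt;
  long j = 0;
  for (int ci = 0; ci < cin; ++ci)
    for (int c = -1; c <= 1; ++c)
      for (int b = -1; b <= 1; ++b)
        for (int a = -1; a <= 1; ++a, ++j)
          im2col_fill(px + nvox * ci, A + nvox * j, nx, ny, nt, a, b, c);
}

// [[Rcpp::export]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                        IntegerVector dims, int cin, int cout) {
  long nx = dims[0], ny = dims[1], nt = dims[2];
  long nvox = nx * ny * nt;
  int K = 27 * cin;
  NumericVector out(nvox * cout);
  std::vector<double> A((size_t)nvox * K);
  build_im2col(x.begin(), A.data(), nx, ny, nt, cin);
  const double one = 1.0, zero = 0.0;
  int m = (int)nvox, n = cout, k = K;
  F77_CALL(dgemm)("N", "N", &m, &n, &k, &one, A.data(), &m,
                  w.begin(), &k, &zero, out.begin(), &m FCONE FCONE);
  double *po = out.begin();
  for (int co = 0; co < cout; ++co) {
    double bias = b[co];
    double *oc = po + nvox * co;
    for (long i = 0; i < nvox; ++i) oc[i] += bias;
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nt, cout);
  return out;
}

// [[Rcpp::export]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gout,
               IntegerVector dims, int cin, int cout) {
  long nx = dims[0], ny = dims[1], nt = dims[2];
  long nvox = nx * ny * nt;
  int K = 27 * cin;
  NumericVector gx(nvox * cin), gw(27L * cin * cout), gb(cout);
  std::vector<double> A((size_t)nvox * K), GA((size_t)nvox * K);
  build_im2col(x.begin(), A.data(), nx, ny, nt, cin);
  const double one = 1.0, zero = 0.0;
  int m = (int)nvox, n = cout, k = K;
  // gW = A^T * gout ; gA = gout * W^T
  F77_CALL(dgemm)("T", "N", &k, &n, &m, &one, A.data(), &m,
                  gout.begin(), &m, &zero, gw.begin(), &k FCONE FCONE);
  F77_CALL(dgemm)("N", "T", &m, &k, &n, &one, gout.begin(), &m,
                  w.begin(), &k, &zero, GA.data(), &m FCONE FCONE);
  // col2im: accumulate shifted columns into gx
  long j = 0;
  for (int ci = 0; ci < cin; ++ci)
    for (int c = -1; c <= 1; ++c)
      for (int b2 = -1; b2 <= 1; ++b2)
        for (int a = -1; a <= 1; ++a, ++j)
          col2im_add(GA.data() + nvox * j, gx.begin() + nvox * ci,
                     nx, ny, nt, a, b2, c);
  const double *pg = gout.begin();
  for (int co = 0; co < cout; ++co) {
    const double *gc = pg + nvox * co;
    double sb = 0.0;
    for (long i = 0; i < nvox; ++i) sb += gc[i];
    gb[co] = sb;
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nt, cin);
  gw.attr("dim") = IntegerVector::create(3, 3, 3, cin, cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 max pooling; all three dims must be even. Returns pooled array and
// 0-based argmax linear indices into the input (per output element).
// [[Rcpp::export]]
List maxpool3d_fw(NumericVector x, IntegerVector dims, int ch) {
  long nx = dims[0], ny = dims[1], nt = dims[2];
  long ox = nx / 2, oy = ny / 2, ot = nt / 2;
  long onv = ox * oy * ot;
  NumericVector out(onv * ch);
  IntegerVector arg(onv * ch);
  const double *px = x.begin();
  for (int c = 0; c < ch; ++c) {
    for (long t = 0; t < ot; ++t)
    for (long y = 0; y < oy; ++y)
    for (long xx = 0; xx < ox; ++xx) {
      double best = -1e300; long bi = -1;
      for (int dt = 0; dt < 2; ++dt)
      for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        long ii = idx4(2 * xx + dx, 2 * y + dy, 2 * t + dt, c, nx, ny, nt);
        if (px[ii] > best) { best = px[ii]; bi = ii; }
      }
      long oi = xx + ox * (y + oy * (t + ot * (long)c));
      out[oi] = best; arg[oi] = (int)bi;
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, ot, ch);
  return List::create(_["y"] = out, _["arg"] = arg);
}

// [[Rcpp::export]]
NumericVector maxpool3d_bw(NumericVector gy, IntegerVector arg, IntegerVector dims_x, int ch) {
  long nx = dims_x[0], ny = dims_x[1], nt = dims_x[2];
  NumericVector gx(nx * ny * nt * (long)ch);
  for (long i = 0; i < gy.size(); ++i) gx[arg[i]] += gy[i];
  gx.attr("dim") = IntegerVector::create(nx, ny, nt, ch);
  return gx;
}

// Transposed convolution, kernel 2x2x2, stride 2 (doubles every dim).
// Weights (2,2,2,cin,cout).
// [[Rcpp::export]]
NumericVector upconv3d_fw(NumericVector x, NumericVector w, NumericVector b,
                          IntegerVector dims, int cin, int cout) {
  long nx = dims[0], ny = dims[1], nt = dims[2];
  long ox = 2 * nx, oy = 2 * ny, ot = 2 * nt;
  long onv = ox * oy * ot;
  NumericVector out(onv * cout);
  const double *px = x.begin(), *pw = w.begin();
  double *po = out.begin();
  long nvox = nx * ny * nt;
  for (int co = 0; co < cout; ++co) {
    double *oc = po + onv * co;
    double bias = b[co];
    for (long i = 0; i < onv; ++i) oc[i] = bias;
    for (int ci = 0; ci < cin; ++ci) {
      const double *ic = px + nvox * ci;
      for (int dt = 0; dt < 2; ++dt)
      for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        double wv = pw[dx + 2L * (dy + 2L * (dt + 2L * (ci + (long)cin * co)))];
        for (long t = 0; t < nt; ++t)
        for (long y = 0; y < ny; ++y) {
          const double *irow = ic + idx4(0, y, t, 0, nx, ny, nt);
          double *orow = oc + (2 * 0 + dx) + ox * ((2 * y + dy) + oy * ((2 * t + dt) + ot * 0L));
          for (long xx = 0; xx < nx; ++xx) orow[2 * xx] += wv * irow[xx];
        }
      }
    }
  }
  out.attr("dim") = IntegerVector::create(ox, oy, ot, cout);
  return out;
}

// [[Rcpp::export]]
List upconv3d_bw(NumericVector x, NumericVector w, NumericVector gout,
                 IntegerVector dims, int cin, int cout) {
  long nx = dims[0], ny = dims[1], nt = dims[2];
  long ox = 2 * nx, oy = 2 * ny, ot = 2 * nt;
  long onv = ox * oy * ot, nvox = nx * ny * nt;
  NumericVector gx(nvox * cin), gw(8L * cin * cout), gb(cout);
  const double *px = x.begin(), *pw = w.begin(), *pg = gout.begin();
  double *pgx = gx.begin(), *pgw = gw.begin();
  for (int co = 0; co < cout; ++co) {
    const double *gc = pg + onv * co;
    double sb = 0.0;
    for (long i = 0; i < onv; ++i) sb += gc[i];
    gb[co] = sb;
    for (int ci = 0; ci < cin; ++ci) {
      const double *ic = px + nvox * ci;
      double *gxc = pgx + nvox * ci;
      for (int dt = 0; dt < 2; ++dt)
      for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        long wi = dx + 2L * (dy + 2L * (dt + 2L * (ci + (long)cin * co)));
        double wv = pw[wi], acc = 0.0;
        for (long t = 0; t < nt; ++t)
        for (long y = 0; y < ny; ++y) {
          const double *irow = ic + idx4(0, y, t, 0, nx, ny, nt);
          double *gxrow = gxc + idx4(0, y, t, 0, nx, ny, nt);
          const double *grow = gc + dx + ox * ((2 * y + dy) + oy * ((2 * t + dt) + ot * 0L));
          for (long xx = 0; xx < nx; ++xx) {
            double g = grow[2 * xx];
            acc += irow[xx] * g;
            gxrow[xx] += wv * g;
          }
        }
        pgw[wi] = acc;
      }
    }
  }
  gx.attr("dim") = IntegerVector::create(nx, ny, nt, cin);
  gw.attr("dim") = IntegerVector::create(2, 2, 2, cin, cout);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}
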