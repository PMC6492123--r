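#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Modified Bessel function of the first kind, order zero.
// Abramowitz & Stegun 9.8.1 / 9.8.2 polynomial approximations (~2e-7 relative).
// Used for BOTH the gridding kernel and the deapodization so that forward,
// adjoint and roll-off correction share one kernel definition exactly.
static double bessi0(double x) {
  double ax = std::fabs(x), y;
  if (ax < 3.75) {
    y = x / 3.75; y *= y;
    return 1.0 + y * (3.5156229 + y * (3.0899424 + y * (1.2067492 +
           y * (0.2659732 + y * (0.0360768 + y * 0.0045813)))));
  }
  y = 3.75 / ax;
  return (std::exp(ax) / std::sqrt(ax)) *
         (0.39894228 + y * (0.01328592 + y * (0.00225319 + y * (-0.00157565 +
          y * (0.00916281 + y * (-0.02057706 + y * (0.02635537 +
          y * (-0.01647633 + y * 0.00392377))))))));
}

// Kaiser-Bessel kernel value at grid-unit offset u, width w, shape beta.
static inline double kb(double u, double w, double beta) {
  double t = 2.0 * u / w;
  double arg = 1.0 - t * t;
  if (arg < 0.0) return 0.0;
  return bessi0(beta * std::sqrt(arg)) / bessi0(beta);
}

// [[Rcpp::export]]
NumericVector kb_eval(NumericVector u, double width, double beta) {
  int n = u.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = kb(u[i], width, beta);
  return out;
}

static inline int wrap(int j, int G) {
  j %= G; if (j < 0) j += G; return j;
}

// Interpolate complex grid (G x G, re/im) at non-integer positions p (n x 2,
// 0-based continuous grid indices; column 1 = row index, column 2 = col index).
// Periodic wrap-around, consistent with DFT periodicity.
// [[Rcpp::export]]
List kb_interp(NumericMatrix gre, NumericMatrix gim, NumericMatrix p,
               double width, double beta) {
  int G = gre.nrow(), n = p.nrow();
  int hw = (int)std::ceil(width / 2.0);
  int span = 2 * hw + 1;
  std::vector<double> wx(span), wy(span);
  std::vector<int> jxs(span), jys(span);
  NumericVector ore(n), oim(n);
  for (int i = 0; i < n; ++i) {
    double px = p(i, 0), py = p(i, 1);
    int x0 = (int)std::ceil(px - width / 2.0);
    int y0 = (int)std::ceil(py - width / 2.0);
    for (int d = 0; d < span; ++d) {
      wx[d] = kb(x0 + d - px, width, beta);
      wy[d] = kb(y0 + d - py, width, beta);
      jxs[d] = wrap(x0 + d, G);
      jys[d] = wrap(y0 + d, G);
    }
    double sre = 0.0, sim = 0.0;
    for (int dy = 0; dy < span; ++dy) {
      if (wy[dy] == 0.0) continue;
      const double *cre = &gre(0, jys[dy]), *cim = &gim(0, jys[dy]);
      double rre = 0.0, rim = 0.0;
      for (int dx = 0; dx < span; ++dx) {
        if (wx[dx] == 0.0) continue;
        rre += wx[dx] * cre[jxs[dx]];
        rim += wx[dx] * cim[jxs[dx]];
      }
      sre += wy[dy] * rre;
      sim += wy[dy] * rim;
    }
    ore[i] = sre; oim[i] = sim;
  }
  return List::create(_["re"] = ore, _["im"] = oim);
}

// Adjoint of kb_interp: spread complex sample values onto a G x G grid.
// [[Rcpp::export]]
List kb_spread(NumericVector vre, NumericVector vim, NumericMatrix p, int G,
               double width, double beta) {
  int n = p.nrow();
  int hw = (int)std::ceil(width / 2.0);
  int span = 2 * hw + 1;
  std::vector<double> wx(span), wy(span);
  std::vector<int> jxs(span), jys(span);
  NumericMatrix gre(G, G), gim(G, G);
  for (int i = 0; i < n; ++i) {
    double px = p(i, 0), py = p(i, 1);
    int x0 = (int)std::ceil(px - width / 2.0);
    int y0 = (int)std::ceil(py - width / 2.0);
    for (int d = 0; d < span; ++d) {
      wx[d] = kb(x0 + d - px, width, beta);
      wy[d] = kb(y0 + d - py, width, beta);
      jxs[d] = wrap(x0 + d, G);
      jys[d] = wrap(y0 + d, G);
    }
    for (int dy = 0; dy < span; ++dy) {
      if (wy[dy] == 0.0) continue;
      double wre = wy[dy] * vre[i], wim = wy[dy] * vim[i];
      double *cre = &gre(0, jys[dy]), *cim = &gim(0, jys[dy]);
      for (int dx = 0; dx < span; ++dx) {
        if (wx[dx] == 0.0) continue;
        cre[jxs[dx]] += wx[dx] * wre;
        cim[jxs[dx]] += wx[dx] * wim;
      }
    }
  }
  return List::create(_["re"] = gre, _["im"] = gim);
}
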