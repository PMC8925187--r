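#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Standard normal CDF
static inline double phid(double x) {
  return 0.5 * erfc(-x * M_SQRT1_2);
}

// Gauss-Legendre abscissae/weights (half rules; symmetric)
static const double GL6X[3] = {0.9324695142031522, 0.6612093864662647,
                               0.2386191860831970};
static const double GL6W[3] = {0.1713244923791705, 0.3607615730481384,
                               0.4679139345726904};
static const double GL12X[6] = {0.9815606342467191, 0.9041172563704750,
                                0.7699026741943050, 0.5873179542866171,
                                0.3678314989981802, 0.1252334085114692};
static const double GL12W[6] = {0.04717533638651177, 0.1069393259953183,
                                0.1600783285433464,  0.2031674267230659,
                                0.2334925365383547,  0.2491470458134029};
static const double GL20X[10] = {0.9931285991850949, 0.9639719272779138,
                                 0.9122344282513259, 0.8391169718222188,
                                 0.7463319064601508, 0.6360536807265150,
                                 0.5108670019508271, 0.3737060887154196,
                                 0.2277858511416451, 0.07652652113349733};
static const double GL20W[10] = {0.01761400713915212, 0.04060142980038694,
                                 0.06267204833410906, 0.08327674157670475,
                                 0.1019301198172404,  0.1181945319615184,
                                 0.1316886384491766,  0.1420961093183821,
                                 0.1491729864726037,  0.1527533871307259};

// P(X <= h, Y <= k) for standard bivariate normal with correlation r.
// Moderate |r|: Genz (2004) single quadrature over sin-transformed angle.
// |r| >= 0.925: direct quadrature of the conditional-probability integral,
// which is robust (if slightly less accurate) arbitrarily close to |r| = 1.
static double bvn_cdf_1(double h, double k, double r) {
  if (!R_finite(h) && !R_finite(k)) {
    if (h > 0 && k > 0) return 1.0;
    return 0.0;
  }
  if (!R_finite(h)) return (h > 0) ? phid(k) : 0.0;
  if (!R_finite(k)) return (k > 0) ? phid(h) : 0.0;
  if (r == 0.0) return phid(h) * phid(k);
  double ar = std::fabs(r);
  if (ar < 0.925) {
    const double *x, *w; int ng;
    if (ar < 0.3)       { x = GL6X;  w = GL6W;  ng = 3; }
    else if (ar < 0.75) { x = GL12X; w = GL12W; ng = 6; }
    else                { x = GL20X; w = GL20W; ng = 10; }
    double hk = h * k, hs = (h * h + k * k) / 2.0;
    double asr = std::asin(r) / 2.0, bvn = 0.0;
    for (int i = 0; i < ng; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double sn = std::sin(asr * (is * x[i] + 1.0));
        bvn += w[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
      }
    }
    bvn = bvn * asr / (2.0 * M_PI) + phid(h) * phid(k);
    if (bvn < 0.0) bvn = 0.0;
    if (bvn > 1.0) bvn = 1.0;
    return bvn;
  }
  // High-correlation branch: integrate phi(x) * Phi((k - r x)/s) over x <= h
  // with 80 panels of 20-point Gauss-Legendre is overkill; 8 panels suffice.
  double s = std::sqrt((1.0 - r) * (1.0 + r));
  double lo = -8.5, hi = h;
  if (hi <= lo) return 0.0;
  if (hi > 8.5) hi = 8.5;
  int npanel = 8;
  double width = (hi - lo) / npanel, bvn = 0.0;
  for (int p = 0; p < npanel; p++) {
    double a = lo + p * width, c = a + width / 2.0, hw = width / 2.0;
    for (int i = 0; i < 10; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double xx = c + is * hw * GL20X[i];
        double dens = M_1_SQRT_2PI * std::exp(-0.5 * xx * xx);
        bvn += hw * GL20W[i] * dens * phid((k - r * xx) / s);
      }
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// [[Rcpp::export]]
NumericVector bvn_cdf(NumericVector h, NumericVector k, NumericVector r) {
  R_xlen_t n = std::max(h.size(), std::max(k.size(), r.size()));
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) {
    out[i] = bvn_cdf_1(h[i % h.size()], k[i % k.size()], r[i % r.size()]);
  }
  return out;
}

// Cell probabilities for a two-way ordinal table under the bivariate normal
// model: interior thresholds tau1 (length R1-1), tau2 (length R2-1).
static void cell_probs(double rho, const NumericVector &tau1,
                       const NumericVector &tau2, std::vector<double> &P,
                       int R1, int R2) {
  // cumulative grid including +/- infinity edges
  std::vector<double> F((R1 + 1) * (R2 + 1));
  for (int i = 0; i <= R1; i++) {
    double a = (i == 0) ? R_NegInf : (i == R1 ? R_PosInf : tau1[i - 1]);
    for (int j = 0; j <= R2; j++) {
      double b = (j == 0) ? R_NegInf : (j == R2 ? R_PosInf : tau2[j - 1]);
      F[i * (R2 + 1) + j] = bvn_cdf_1(a, b, rho);
    }
  }
  for (int i = 1; i <= R1; i++) {
    for (int j = 1; j <= R2; j++) {
      double p = F[i * (R2 + 1) + j] - F[(i - 1) * (R2 + 1) + j] -
                 F[i * (R2 + 1) + (j - 1)] + F[(i - 1) * (R2 + 1) + (j - 1)];
      P[(i - 1) * R2 + (j - 1)] = (p > 1e-14) ? p : 1e-14;
    }
  }
}

// [[Rcpp::export]]
double polychoric_negll(double rho, NumericVector tau1, NumericVector tau2,
                        NumericMatrix counts) {
  int R1 = counts.nrow(), R2 = counts.ncol();
  std::vector<double> P(R1 * R2);
  cell_probs(rho, tau1, tau2, P, R1, R2);
  double ll = 0.0;
  for (int i = 0; i < R1; i++)
    for (int j = 0; j < R2; j++)
      if (counts(i, j) > 0) ll += counts(i, j) * std::log(P[i * R2 + j]);
  return -ll;
}

// Per-cell log-probabilities (for per-observation scores).
// [[Rcpp::export]]
NumericMatrix polychoric_cell_logp(double rho, NumericVector tau1,
                                   NumericVector tau2, int R1, int R2) {
  std::vector<double> P(R1 * R2);
  cell_probs(rho, tau1, tau2, P, R1, R2);
  NumericMatrix out(R1, R2);
  for (int i = 0; i < R1; i++)
    for (int j = 0; j < R2; j++) out(i, j) = std::log(P[i * R2 + j]);
  return out;
}
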