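#include <Rcpp.h>
using namespace Rcpp;

// One contig pair's abundance distance for one sample: the non-shared area
// of the two implied normal depth distributions. Mirrors adp_single() in
// R/abundance.R (same branch threshold and variance floor semantics).
static double adp_one(double mu1, double v1, double mu2, double v2,
                      double var_floor) {
  if (v1 < var_floor) v1 = var_floor;
  if (v2 < var_floor) v2 = var_floor;
  if (v1 > v2) {
    double t = v1; v1 = v2; v2 = t;
    t = mu1; mu1 = mu2; mu2 = t;
  }
  double out;
  if ((v2 - v1) <= 1e-12 * v2) {
    double s = std::sqrt(v1);
    double k0 = (mu1 + mu2) / 2.0;
    out = std::fabs(R::pnorm(k0, mu1, s, 1, 0) - R::pnorm(k0, mu2, s, 1, 0));
  } else {
    double dm = mu1 - mu2;
    double disc = v1 * v2 * (dm * dm + 2.0 * (v2 - v1) * std::log(std::sqrt(v2 / v1)));
    double s = disc > 0 ? std::sqrt(disc) : 0.0;
    double denom = v2 - v1;
    double lin = mu1 * v2 - mu2 * v1;
    double k1 = (lin - s) / denom;
    double k2 = (lin + s) / denom;
    if (k1 > k2) { double t = k1; k1 = k2; k2 = t; }
    double sd1 = std::sqrt(v1), sd2 = std::sqrt(v2);
    out = std::fabs(R::pnorm(k2, mu1, sd1, 1, 0) - R::pnorm(k1, mu1, sd1, 1, 0) +
                    R::pnorm(k1, mu2, sd2, 1, 0) - R::pnorm(k2, mu2, sd2, 1, 0));
  }
  if (out < 0) out = 0;
  if (out > 1) out = 1;
  return out;
}

// Dense composite distance matrix. Each unordered pair is computed once
// (exact symmetry by construction):
//   d    = Euclidean TNF distance
//   tdp  = plogis(b + c d), b and c bilinear over the size grid via the
//          per-contig weight rows W (WB = W %*% b_surface, WC likewise),
//          with the smaller-length contig's row on the left
//   adp  = geometric mean of adp_one over informative samples
//   comp = tdp if no informative sample; max(tdp, adp) if tdp > switch;
//          else adp * w + tdp * (1 - w), w = min(log(n+1)/log(m+1), alpha)
// [[Rcpp::export]]
NumericMatrix composite_kernel(const NumericMatrix& tnf,
                               const NumericMatrix& WB,
                               const NumericMatrix& WC,
                               const NumericMatrix& W,
                               const NumericVector& lengths,
                               const NumericMatrix& means,
                               const NumericMatrix& vars,
                               bool have_cov, double min_cv, double var_floor,
                               double log_m1, double alpha,
                               double tdp_switch) {
  int n = tnf.nrow(), K = tnf.ncol(), G = W.ncol();
  int S = have_cov ? means.ncol() : 0;
  NumericMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d2 = 0.0;
      for (int k = 0; k < K; ++k) {
        double diff = tnf(i, k) - tnf(j, k);
        d2 += diff * diff;
      }
      double d = std::sqrt(d2);
      int lo = (lengths[i] <= lengths[j]) ? i : j;
      int hi = (lo == i) ? j : i;
      double b = 0.0, c = 0.0;
      for (int g = 0; g < G; ++g) {
        b += WB(lo, g) * W(hi, g);
        c += WC(lo, g) * W(hi, g);
      }
      double t = 1.0 / (1.0 + std::exp(-(b + c * d)));
      double comp = t;
      if (S > 0) {
        double slog = 0.0;
        int cnt = 0;
        for (int s = 0; s < S; ++s) {
          double m1 = means(i, s), m2 = means(j, s);
          if (m1 > min_cv || m2 > min_cv) {
            double p = adp_one(m1, vars(i, s), m2, vars(j, s), var_floor);
            slog += std::log(p > 1e-300 ? p : 1e-300);
            ++cnt;
          }
        }
        if (cnt > 0) {
          double adp = std::exp(slog / cnt);
          if (t > tdp_switch) {
            comp = t > adp ? t : adp;
          } else {
            double w = std::log((double)cnt + 1.0) / log_m1;
            if (w > alpha) w = alpha;
            comp = adp * w + t * (1.0 - w);
          }
        }
      }
      D(i, j) = comp;
      D(j, i) = comp;
    }
  }
  return D;
}
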