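// Per-marker REML linear mixed model with a kinship random effect,
// after a one-off eigendecomposition of the kinship matrix (done in R).
//
// Model: y = a + x b + u + e,  u ~ N(0, sg2 K), e ~ N(0, se2 I).
// With K = U D U', rotate y, x and the intercept by U'. For a given
// delta = se2/sg2 the GLS solution is weighted least squares with weights
// 1/(d_i + delta). The restricted likelihood is maximised over log(delta)
// in [-10, 10] per marker by a coarse bracket followed by Brent's method
// (tolerance 1e-6), GEMMA-style. The Wald statistic is (b/se)^2 ~ chisq(1).

#include <Rcpp.h>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct RemlEval {
  const double* d;
  const double* y;   // rotated phenotype
  const double* x0;  // rotated intercept
  const double* x;   // rotated marker
  int n;

  // returns the (negated, constant-dropped) restricted log-likelihood;
  // fills GLS pieces when `fit` is non-null
  double operator()(double logdelta, double* fit = nullptr) const {
    double delta = std::exp(logdelta);
    double s00 = 0, s01 = 0, s11 = 0, sy0 = 0, sy1 = 0, syy = 0, ld = 0;
    for (int i = 0; i < n; ++i) {
      double dv = d[i] + delta;
      double w = 1.0 / dv;
      double a = x0[i], b = x[i], yy = y[i];
      s00 += w * a * a;
      s01 += w * a * b;
      s11 += w * b * b;
      sy0 += w * a * yy;
      sy1 += w * b * yy;
      syy += w * yy * yy;
      ld += std::log(dv);
    }
    double det = s00 * s11 - s01 * s01;
    if (det <= 0 || !std::isfinite(det))
      return std::numeric_limits<double>::max();
    double b1 = (s11 * sy0 - s01 * sy1) / det;   // intercept
    double b2 = (s00 * sy1 - s01 * sy0) / det;   // marker effect
    double R = syy - b1 * sy0 - b2 * sy1;
    if (R <= 0 || !std::isfinite(R))
      return std::numeric_limits<double>::max();
    if (fit) {
      fit[0] = b2;
      double sg2 = R / (n - 2);                  // REML variance scale
      fit[1] = std::sqrt(sg2 * s00 / det);       // se(b2)
      fit[2] = R;
    }
    return (n - 2) * std::log(R) + ld + std::log(det);
  }
};

// Brent minimisation on [lo, hi] starting from a bracketing triplet
double brent_min(const RemlEval& f, double lo, double hi, double tol) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = a + gold * (b - a), w = x, v = x;
  double fx = f(x), fw = fx, fv = fx;
  double e = 0.0, dmove = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    bool parab = false;
    if (std::fabs(e) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = dmove;
      if (!(std::fabs(p) >= std::fabs(0.5 * q * etemp) || p <= q * (a - x) ||
            p >= q * (b - x))) {
        parab = true;
        dmove = p / q;
        double u = x + dmove;
        if (u - a < tol2 || b - u < tol2)
          dmove = (xm - x >= 0 ? tol1 : -tol1);
      }
    }
    if (!parab) {
      e = (x >= xm ? a - x : b - x);
      dmove = gold * e;
    }
    double u = (std::fabs(dmove) >= tol1) ? x + dmove
                                          : x + (dmove >= 0 ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u;
      fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  return x;
}

}  // namespace

// [[Rcpp::export(name = ".lmm_reml_cpp")]]
List lmm_reml_cpp(NumericVector d, NumericVector Uty, NumericVector Utone,
                  NumericMatrix UtX, double logdelta_lo = -10.0,
                  double logdelta_hi = 10.0, double tol = 1e-6) {
  int n = d.size(), m = UtX.ncol();
  NumericVector beta(m, NA_REAL), se(m, NA_REAL), chi2(m, NA_REAL),
      logdelta(m, NA_REAL);
  LogicalVector ok(m, false);

  const int ngrid = 21;
  std::vector<double> grid(ngrid);
  for (int k = 0; k < ngrid; ++k)
    grid[k] = logdelta_lo + (logdelta_hi - logdelta_lo) * k / (ngrid - 1);

  for (int j = 0; j < m; ++j) {
    RemlEval f{&d[0], &Uty[0], &Utone[0], &UtX(0, j), n};
    // coarse bracket
    double best = grid[0], fbest = f(grid[0]);
    for (int k = 1; k < ngrid; ++k) {
      double fv = f(grid[k]);
      if (fv < fbest) { fbest = fv; best = grid[k]; }
    }
    if (fbest == std::numeric_limits<double>::max()) continue;  // singular
    double lo = std::max(logdelta_lo, best - (grid[1] - grid[0]));
    double hi = std::min(logdelta_hi, best + (grid[1] - grid[0]));
    double opt = brent_min(f, lo, hi, tol);
    if (f(opt) > fbest) opt = best;  // guard: keep grid point if Brent worsened
    double fit[3];
    if (f(opt, fit) == std::numeric_limits<double>::max()) continue;
    beta[j] = fit[0];
    se[j] = fit[1];
    chi2[j] = (fit[0] / fit[1]) * (fit[0] / fit[1]);
    logdelta[j] = opt;
    ok[j] = true;
  }
  return List::create(_["beta"] = beta, _["se"] = se, _["chi2"] = chi2,
                      _["logdelta"] = logdelta, _["ok"] = ok);
}
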