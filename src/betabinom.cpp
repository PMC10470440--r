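// Beta-binomial background-error likelihood machinery.
//
// The beta-binomial is parameterised by the mean error fraction mu and the
// overdispersion rho, with shape parameters
//   alpha = mu * (1 - rho) / rho,  beta = (1 - mu) * (1 - rho) / rho,
// so that rho -> 0 recovers the binomial and rho -> 1 maximal overdispersion.
// The likelihood-ratio site test maximises mu by Brent search on
// (MU_LO, MU_HI) at tolerance MU_TOL; these constants are part of the
// published numerical contract and must not drift.

#include <Rcpp.h>
using namespace Rcpp;

static const double MU_LO = 1e-8;
static const double MU_HI = 0.5;
static const double MU_TOL = 1e-10;

// lgamma(x + d) - lgamma(x), stable for huge x when d is a small integer
// (the binomial limit rho -> 0 sends the shape parameters to +Inf and the
// naive difference loses all precision).
static double lgamma_diff(double x, double d) {
  if (d == 0.0) return 0.0;
  if (d == std::floor(d) && d > 0 && d <= 1024.0) {
    double s = 0.0;
    for (int j = 0; j < (int)d; ++j) s += std::log(x + j);
    return s;
  }
  return R::lgammafn(x + d) - R::lgammafn(x);
}

// log beta-binomial pmf; the (k=0, n=0) empty observation has probability 1.
static double bb_lpmf(double k, double n, double mu, double rho) {
  if (n <= 0.0) return 0.0;
  double a = mu * (1.0 - rho) / rho;
  double b = (1.0 - mu) * (1.0 - rho) / rho;
  return R::lchoose(n, k) + lgamma_diff(a, k) + lgamma_diff(b, n - k) -
         lgamma_diff(a + b, n);
}

// [[Rcpp::export]]
NumericVector bb_loglik_cpp(NumericVector k, NumericVector n, double mu,
                            double rho) {
  int len = k.size();
  NumericVector out(len);
  for (int i = 0; i < len; ++i) out[i] = bb_lpmf(k[i], n[i], mu, rho);
  return out;
}

// Sum of log-likelihood terms over a set of observations, dropping the
// lchoose constants (irrelevant for maximisation and LRT differences).
// The observation set is a background block (both strands, one shared mean
// under the model) plus up to two extra observations (the tested sample's
// forward and reverse strand, likewise sharing one mean).
struct SiteObs {
  const double *k;
  const double *n;
  int m;
  double xk[2], xn[2];  // extra observations (the tested sample's strands)
  int n_extra;
  double rho;
};

static double site_negll(double mu, const SiteObs &obs) {
  double rho = obs.rho;
  double a = mu * (1.0 - rho) / rho;
  double b = (1.0 - mu) * (1.0 - rho) / rho;
  double lab = R::lbeta(a, b);
  double s = 0.0;
  for (int i = 0; i < obs.m; ++i) {
    double ni = obs.n[i];
    if (ni > 0.0) s += R::lbeta(obs.k[i] + a, ni - obs.k[i] + b) - lab;
  }
  for (int j = 0; j < obs.n_extra; ++j)
    if (obs.xn[j] > 0.0)
      s += R::lbeta(obs.xk[j] + a, obs.xn[j] - obs.xk[j] + b) - lab;
  return -s;
}

// Brent's method (golden section + successive parabolic interpolation) for
// the 1-D minimum of site_negll over mu in (MU_LO, MU_HI).
static double brent_max_ll(const SiteObs &obs) {
  const double c = (3.0 - std::sqrt(5.0)) * 0.5;
  double ax = MU_LO, bx = MU_HI;
  double v = ax + c * (bx - ax);
  double w = v, x = v;
  double d = 0.0, e = 0.0;
  double fx = site_negll(x, obs), fv = fx, fw = fx;
  const double eps = std::sqrt(DBL_EPSILON);
  for (int iter = 0; iter < 200; ++iter) {
    double xm = 0.5 * (ax + bx);
    double tol1 = eps * std::fabs(x) + MU_TOL;
    double tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (bx - ax)) break;
    double p = 0.0, q = 0.0, r = 0.0;
    bool golden = true;
    if (std::fabs(e) > tol1) {
      r = (x - w) * (fx - fv);
      q = (x - v) * (fx - fw);
      p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      double etemp = e;
      e = d;
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) && p > q * (ax - x) &&
          p < q * (bx - x)) {
        d = p / q;
        double u = x + d;
        if (u - ax < tol2 || bx - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        golden = false;
      }
    }
    if (golden) {
      e = (x >= xm) ? ax - x : bx - x;
      d = c * e;
    }
    double u = (std::fabs(d) >= tol1) ? x + d : x + ((d > 0.0) ? tol1 : -tol1);
    double fu = site_negll(u, obs);
    if (fu <= fx) {
      if (u >= x) ax = x; else bx = x;
      v = w; fv = fw;
      w = x; fw = fx;
      x = u; fx = fu;
    } else {
      if (u < x) ax = u; else bx = u;
      if (fu <= fw || w == x) {
        v = w; fv = fw;
        w = u; fw = fu;
      } else if (fu <= fv || v == x || v == w) {
        v = u; fv = fu;
      }
    }
  }
  return -fx;  // maximised log-likelihood (constants dropped)
}

// background block alone (one shared error mean over both strands' obs)
static double max_ll_bg(const double *k, const double *n, int m, double rho) {
  SiteObs obs;
  obs.k = k; obs.n = n; obs.m = m;
  obs.n_extra = 0;
  obs.rho = rho;
  return brent_max_ll(obs);
}

// the tested sample alone: its two strand observations share one variant mean
static double max_ll_sample(double kf, double nf, double kr, double nr,
                            double rho) {
  SiteObs obs;
  obs.k = nullptr; obs.n = nullptr; obs.m = 0;
  obs.n_extra = 2;
  obs.xk[0] = kf; obs.xn[0] = nf;
  obs.xk[1] = kr; obs.xn[1] = nr;
  obs.rho = rho;
  return brent_max_ll(obs);
}

// null: background and sample share a single mean
static double max_ll_pooled(const double *k, const double *n, int m,
                            double kf, double nf, double kr, double nr,
                            double rho) {
  SiteObs obs;
  obs.k = k; obs.n = n; obs.m = m;
  obs.n_extra = 2;
  obs.xk[0] = kf; obs.xn[0] = nf;
  obs.xk[1] = kr; obs.xn[1] = nr;
  obs.rho = rho;
  return brent_max_ll(obs);
}

// One-sided LRT of a single shared elevation: H1 gives the sample's two
// strand observations their own common variant fraction (background keeps
// its own), H0 ties all observations to one fraction -- one extra parameter,
// so T = 2(l1 - l0) (clipped at 0) is referred to chi-square df = 1 with the
// one-sided halving p = 0.5 * P(chisq_1 >= T) when the sample's pooled
// fraction exceeds the background's pooled fraction, else p = 1. bg_ll may
// be passed precomputed (cached) or NA to compute here.
static void lrt_core(double skf, double snf, double skr, double snr,
                     const double *bk, const double *bn, int m2,
                     double fb, double bg_ll, double rho,
                     double *stat, double *p) {
  double sn = snf + snr;
  double fs = (sn > 0) ? (skf + skr) / sn : 0.0;
  if (!(fs > fb)) {
    *stat = 0.0; *p = 1.0;
    return;
  }
  if (ISNA(bg_ll)) bg_ll = max_ll_bg(bk, bn, m2, rho);
  double l1 = bg_ll + max_ll_sample(skf, snf, skr, snr, rho);
  double l0 = max_ll_pooled(bk, bn, m2, skf, snf, skr, snr, rho);
  double t = 2.0 * (l1 - l0);
  if (t < 0.0) t = 0.0;
  *stat = t;
  *p = 0.5 * R::pchisq(t, 1.0, 0, 0);
}

// [[Rcpp::export]]
List bb_lrt_site_cpp(double skf, double snf, double skr, double snr,
                     NumericVector bkf, NumericVector bnf, NumericVector bkr,
                     NumericVector bnr, double rho) {
  int m = bkf.size();
  std::vector<double> bk(2 * m), bn(2 * m);
  double bk_tot = 0, bn_tot = 0;
  for (int i = 0; i < m; ++i) {
    bk[i] = bkf[i]; bn[i] = bnf[i];
    bk[m + i] = bkr[i]; bn[m + i] = bnr[i];
    bk_tot += bkf[i] + bkr[i];
    bn_tot += bnf[i] + bnr[i];
  }
  double fb = (bn_tot > 0) ? bk_tot / bn_tot : 0.0;
  double stat, p;
  lrt_core(skf, snf, skr, snr, bk.data(), bn.data(), 2 * m, fb, NA_REAL,
           rho, &stat, &p);
  return List::create(Named("statistic") = stat, Named("p_value") = p);
}

// Batch LRT over positions (rows) and tested samples (columns) sharing one
// background per position. Background maximised likelihoods are computed
// lazily once per (position, strand) and reused across samples, which is what
// makes cohort-scale calling feasible.
// [[Rcpp::export]]
List bb_lrt_batch_cpp(NumericMatrix bkf, NumericMatrix bnf, NumericMatrix bkr,
                      NumericMatrix bnr, NumericMatrix skf, NumericMatrix snf,
                      NumericMatrix skr, NumericMatrix snr,
                      NumericVector rho) {
  int npos = bkf.nrow(), m = bkf.ncol(), ns = skf.ncol();
  NumericMatrix stat(npos, ns), pval(npos, ns);
  std::vector<double> bk(2 * m), bn(2 * m);
  for (int i = 0; i < npos; ++i) {
    double bk_tot = 0, bn_tot = 0;
    for (int j = 0; j < m; ++j) {
      bk[j] = bkf(i, j); bn[j] = bnf(i, j);
      bk[m + j] = bkr(i, j); bn[m + j] = bnr(i, j);
      bk_tot += bk[j] + bk[m + j];
      bn_tot += bn[j] + bn[m + j];
    }
    double fb = (bn_tot > 0) ? bk_tot / bn_tot : 0.0;
    double r = rho[i];
    double bg_ll = NA_REAL;
    for (int s = 0; s < ns; ++s) {
      double kfs = skf(i, s), nfs = snf(i, s);
      double krs = skr(i, s), nrs = snr(i, s);
      double sn = nfs + nrs;
      double fs = (sn > 0) ? (kfs + krs) / sn : 0.0;
      if (!(fs > fb)) {
        stat(i, s) = 0.0;
        pval(i, s) = 1.0;
        continue;
      }
      if (ISNA(bg_ll)) bg_ll = max_ll_bg(bk.data(), bn.data(), 2 * m, r);
      double t, p;
      lrt_core(kfs, nfs, krs, nrs, bk.data(), bn.data(), 2 * m, fb, bg_ll,
               r, &t, &p);
      stat(i, s) = t;
      pval(i, s) = p;
    }
  }
  return List::create(Named("statistic") = stat, Named("p_value") = pval);
}
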