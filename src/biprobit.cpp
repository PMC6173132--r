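#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Gauss-Legendre half-rules (positive abscissae) for the bivariate normal
// CDF quadrature; order chosen by |correlation| as in Genz's BVND scheme.
static const double GL6X[3] = {
  0.2386191860831971, 0.6612093864662647, 0.93246951420315194};
static const double GL6W[3] = {
  0.46791393457269048, 0.36076157304813938, 0.17132449237917025};
static const double GL12X[6] = {
  0.1252334085114698, 0.36783149899818013, 0.58731795428661759,
  0.76990267419430447, 0.90411725637047469, 0.98156063424671924};
static const double GL12W[6] = {
  0.24914704581340252, 0.23349253653835614, 0.20316742672306526,
  0.16007832854334608, 0.10693932599531807, 0.047175336386511696};
static const double GL20X[10] = {
  0.076526521133497782, 0.2277858511416454, 0.37370608871541966,
  0.51086700195082713, 0.63605368072651525, 0.74633190646015113,
  0.83911697182221889, 0.91223442825132606, 0.96397192727791381,
  0.993128599185095};
static const double GL20W[10] = {
  0.15275338713072575, 0.14917298647260305, 0.14209610931838021,
  0.13168863844917597, 0.1181945319615197, 0.10193011981724084,
  0.083276741576705129, 0.062672048334109318, 0.04060142980038714,
  0.017614007139152146};

static inline double phi1(double x) { return R::dnorm(x, 0.0, 1.0, 0); }
static inline double Phi1(double x) { return R::pnorm(x, 0.0, 1.0, 1, 0); }

// fast variants for the likelihood hot path (erfc is accurate to ~1 ulp and
// keeps denormal precision far into the tail)
static inline double Phi1f(double x) {
  return 0.5 * std::erfc(-x * M_SQRT1_2);
}
static inline double phi1f(double x) {
  return 0.3989422804014327 * std::exp(-0.5 * x * x);
}

// Upper-orthant probability P(X > h, Y > k) for a standard bivariate normal
// with correlation r.  Drezner-Wesolowsky/Genz scheme: Gauss-Legendre on the
// asin(r) integral for moderate |r|, and the high-correlation expansion with
// a transformed 20-point rule for |r| > 0.925.  Absolute error ~ 1e-15.
static double bvnu(double h, double k, double r) {
  if (ISNAN(h) || ISNAN(k) || ISNAN(r)) return NA_REAL;
  if (h == R_PosInf || k == R_PosInf) return 0.0;
  if (h == R_NegInf) return (k == R_NegInf) ? 1.0 : Phi1(-k);
  if (k == R_NegInf) return Phi1(-h);
  if (r >= 1.0 - 1e-15) return Phi1(-std::max(h, k));
  if (r <= -1.0 + 1e-15) return std::max(0.0, Phi1(-h) - Phi1(k));

  const double twopi = 2.0 * M_PI;
  double hk = h * k, bvn = 0.0;

  if (std::fabs(r) < 0.925) {
    if (r != 0.0) {
      const double *gx, *gw;
      int ng;
      if (std::fabs(r) < 0.3)       { gx = GL6X;  gw = GL6W;  ng = 3;  }
      else if (std::fabs(r) < 0.75) { gx = GL12X; gw = GL12W; ng = 6;  }
      else                          { gx = GL20X; gw = GL20W; ng = 10; }
      double hs = (h * h + k * k) / 2.0, asr = std::asin(r);
      for (int i = 0; i < ng; i++) {
        for (int is = -1; is <= 1; is += 2) {
          double sn = std::sin(asr * (1.0 + is * gx[i]) / 2.0);
          bvn += gw[i] * std::exp((sn * hk - hs) / (1.0 - sn * sn));
        }
      }
      bvn = bvn * asr / (2.0 * twopi);
    }
    bvn += Phi1(-h) * Phi1(-k);
  } else {
    if (r < 0.0) { k = -k; hk = -hk; }
    double as = (1.0 - r) * (1.0 + r), a = std::sqrt(as);
    double bs = (h - k) * (h - k);
    double c = (4.0 - hk) / 8.0, d = (12.0 - hk) / 16.0;
    double asr = -(bs / as + hk) / 2.0;
    if (asr > -100.0)
      bvn = a * std::exp(asr) *
            (1.0 - c * (bs - as) * (1.0 - d * bs / 5.0) / 3.0 +
             c * d * as * as / 5.0);
    if (-hk < 100.0) {
      double b = std::sqrt(bs);
      bvn -= std::exp(-hk / 2.0) * std::sqrt(twopi) * Phi1(-b / a) * b *
             (1.0 - c * bs * (1.0 - d * bs / 5.0) / 3.0);
    }
    a /= 2.0;
    for (int i = 0; i < 10; i++) {
      for (int is = -1; is <= 1; is += 2) {
        double xs = a * (1.0 + is * GL20X[i]);
        xs = xs * xs;
        double rs = std::sqrt(1.0 - xs);
        double asr2 = -(bs / xs + hk) / 2.0;
        if (asr2 > -100.0)
          bvn += a * GL20W[i] * std::exp(asr2) *
                 (std::exp(-hk * (1.0 - rs) / (2.0 * (1.0 + rs))) / rs -
                  (1.0 + c * xs * (1.0 + d * xs)));
      }
    }
    bvn = -bvn / twopi;
    if (r > 0.0) {
      bvn += Phi1(-std::max(h, k));
    } else {
      bvn = -bvn;
      if (k > h) bvn += Phi1(k) - Phi1(h);
    }
  }
  if (bvn < 0.0) bvn = 0.0;
  if (bvn > 1.0) bvn = 1.0;
  return bvn;
}

// P(X <= h, Y <= k) with correlation r.
static inline double bvn_cdf(double h, double k, double r) {
  return bvnu(-h, -k, r);
}

// [[Rcpp::export]]
NumericVector pbvnorm_cpp(NumericVector h, NumericVector k, NumericVector r) {
  R_xlen_t n = h.size();
  if (k.size() != n || (r.size() != n && r.size() != 1))
    stop("pbvnorm_cpp: incompatible lengths");
  NumericVector out(n);
  bool rscalar = (r.size() == 1);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = bvn_cdf(h[i], k[i], rscalar ? r[0] : r[i]);
  return out;
}

// Precomputed quadrature context for repeated Phi2 evaluations at a fixed
// correlation (the likelihood only ever needs +rho and -rho): caches the
// Gauss-Legendre sine table of the asin(r) integral. Order 6 is already
// accurate to ~1e-9 for |r| < 0.75, far below the statistical precision of
// the likelihood; larger |r| uses the 20-point rule, and |r| >= 0.925 falls
// back to the generic routine.
struct BvnCtx {
  double r, scale;
  int ng;
  const double *gw;
  double sn[20];
  bool direct;  // true: use the cached table; false: generic bvnu
  void init(double rr) {
    r = rr;
    direct = std::fabs(rr) < 0.925;
    if (!direct) return;
    const double *gx;
    if (std::fabs(rr) < 0.75) { gx = GL6X; gw = GL6W; ng = 3; }
    else                      { gx = GL20X; gw = GL20W; ng = 10; }
    double asr = std::asin(rr);
    for (int i = 0; i < ng; i++) {
      sn[2 * i]     = std::sin(asr * (1.0 - gx[i]) / 2.0);
      sn[2 * i + 1] = std::sin(asr * (1.0 + gx[i]) / 2.0);
    }
    scale = asr / (4.0 * M_PI);
  }
  // P(X <= u, Y <= v) at correlation r, given Phi(u), Phi(v)
  inline double cdf(double u, double v, double Pu, double Pv) const {
    if (!direct) return bvnu(-u, -v, r);
    double hk = u * v, hs = (u * u + v * v) / 2.0, s = 0.0;
    for (int i = 0; i < 2 * ng; i++) {
      double sni = sn[i];
      s += gw[i / 2] * std::exp((sni * hk - hs) / (1.0 - sni * sni));
    }
    return Pu * Pv + s * scale;
  }
};

struct ThetaView {
  int p;
  const double *bl, *br;
  double L11, L21, L22, rho;
  bool ok;
};

static ThetaView unpack(const NumericVector &theta, int p) {
  ThetaView tv;
  tv.p = p;
  tv.ok = true;
  for (R_xlen_t i = 0; i < theta.size(); i++)
    if (!R_finite(theta[i])) tv.ok = false;
  tv.bl = &theta[0];
  tv.br = &theta[p];
  tv.L11 = std::exp(theta[2 * p]);
  tv.L21 = theta[2 * p + 1];
  tv.L22 = std::exp(theta[2 * p + 2]);
  tv.rho = std::tanh(theta[2 * p + 3]);
  return tv;
}

// Record log-likelihood at given random-effect values, with optional partial
// derivatives wrt (eta_l, eta_r, rho).  Missing outcome coded as -1.
// ctx[0] holds the +rho quadrature context (concordant outcomes), ctx[1]
// the -rho one (discordant outcomes).
static inline double rec_loglik(double etal, double etar, int yl, int yr,
                                double rho, const BvnCtx *ctx, bool grad,
                                double *detal, double *detar, double *drho) {
  const double tiny = 1e-300;
  if (yl >= 0 && yr >= 0) {
    double sl = yl ? 1.0 : -1.0, sr = yr ? 1.0 : -1.0;
    double u = sl * etal, v = sr * etar, re = sl * sr * rho;
    double C = ctx[yl == yr ? 0 : 1].cdf(u, v, Phi1(u), Phi1(v));
    if (C < tiny) C = tiny;
    if (grad) {
      double s2 = 1.0 - re * re;
      double s = std::sqrt(s2 > 1e-24 ? s2 : 1e-24);
      double du = phi1(u) * Phi1((v - re * u) / s) / C;
      double dv = phi1(v) * Phi1((u - re * v) / s) / C;
      double dens = std::exp(-(u * u - 2.0 * re * u * v + v * v) /
                             (2.0 * s * s)) / (2.0 * M_PI * s);
      *detal = sl * du;
      *detar = sr * dv;
      *drho = sl * sr * dens / C;
    }
    return std::log(C);
  } else if (yl >= 0) {
    double sl = yl ? 1.0 : -1.0, u = sl * etal;
    double C = Phi1(u);
    if (C < tiny) C = tiny;
    if (grad) { *detal = sl * phi1(u) / C; *detar = 0.0; *drho = 0.0; }
    return std::log(C);
  } else {
    double sr = yr ? 1.0 : -1.0, v = sr * etar;
    double C = Phi1(v);
    if (C < tiny) C = tiny;
    if (grad) { *detal = 0.0; *detar = sr * phi1(v) / C; *drho = 0.0; }
    return std::log(C);
  }
}

// Negative log marginal likelihood of the random-intercept bivariate probit,
// integrated by tensor-product Gauss-Hermite quadrature (physicists' rule:
// weights for exp(-z^2), transformation b = sqrt(2) L z).  Optionally returns
// the analytic gradient wrt theta = (beta_l, beta_r, log L11, L21, log L22,
// atanh rho).  scan_ptr gives 0-based record offsets per scan (length
// n_scans + 1); records must be sorted by scan.
// [[Rcpp::export]]
List biprobit_nll_cpp(NumericVector theta, NumericMatrix X, IntegerVector yl,
                      IntegerVector yr, IntegerVector scan_ptr,
                      NumericVector gz, NumericVector gw, bool want_grad) {
  int n = X.nrow(), p = X.ncol();
  int npar = 2 * p + 4;
  if (theta.size() != npar) stop("theta has wrong length");
  ThetaView tv = unpack(theta, p);
  BvnCtx ctx[2];
  ctx[0].init(tv.rho);
  ctx[1].init(-tv.rho);
  NumericVector grad(npar);
  if (!tv.ok)
    return List::create(_["nll"] = 1e10, _["grad"] = grad);

  int K = gz.size();
  int T = K * K;
  int nscan = scan_ptr.size() - 1;
  const double s2 = M_SQRT2;

  // linear predictors
  std::vector<double> etal(n), etar(n);
  for (int i = 0; i < n; i++) {
    double al = 0.0, ar = 0.0;
    for (int m = 0; m < p; m++) {
      al += X(i, m) * tv.bl[m];
      ar += X(i, m) * tv.br[m];
    }
    etal[i] = al;
    etar[i] = ar;
  }

  // node offsets
  std::vector<double> bl(T), br(T), W(T);
  for (int j = 0; j < K; j++) {
    for (int kk = 0; kk < K; kk++) {
      int t = j * K + kk;
      bl[t] = s2 * tv.L11 * gz[j];
      br[t] = s2 * (tv.L21 * gz[j] + tv.L22 * gz[kk]);
      W[t] = gw[j] * gw[kk] / M_PI;
    }
  }

  std::vector<double> logP(T);
  std::vector<double> G;
  if (want_grad) G.resize((size_t)T * npar);

  double nll = 0.0;
  double drho_da = 1.0 - tv.rho * tv.rho;
  const double tiny = 1e-300;

  // per-(record, j) caches: the left-equation term u = s_l (eta_l + b_l)
  // depends on the first node index only
  int max_rec = 0;
  for (int s = 0; s < nscan; s++)
    max_rec = std::max(max_rec, scan_ptr[s + 1] - scan_ptr[s]);
  std::vector<double> cu((size_t)max_rec * K), cPu((size_t)max_rec * K),
      cpu((size_t)max_rec * K);

  for (int s = 0; s < nscan; s++) {
    int r0 = scan_ptr[s], r1 = scan_ptr[s + 1];
    int nrec = r1 - r0;
    for (int rec = r0; rec < r1; rec++) {
      if (yl[rec] < 0) continue;
      double sl = yl[rec] ? 1.0 : -1.0;
      for (int j = 0; j < K; j++) {
        size_t c = (size_t)(rec - r0) * K + j;
        double u = sl * (etal[rec] + s2 * tv.L11 * gz[j]);
        cu[c] = u;
        cPu[c] = Phi1f(u);
        cpu[c] = phi1f(u);
      }
    }
    (void)nrec;
    for (int t = 0; t < T; t++) {
      int j = t / K, kk = t % K;
      double lp = 0.0;
      double *g = want_grad ? &G[(size_t)t * npar] : (double *)0;
      if (want_grad) std::fill(g, g + npar, 0.0);
      for (int rec = r0; rec < r1; rec++) {
        double del = 0.0, der = 0.0, drh = 0.0;
        size_t c = (size_t)(rec - r0) * K + j;
        if (yl[rec] >= 0 && yr[rec] >= 0) {
          double sl = yl[rec] ? 1.0 : -1.0, sr = yr[rec] ? 1.0 : -1.0;
          double u = cu[c];
          double v = sr * (etar[rec] + br[t]);
          double re = sl * sr * tv.rho;
          double Pv = Phi1f(v);
          double C = ctx[yl[rec] == yr[rec] ? 0 : 1].cdf(u, v, cPu[c], Pv);
          if (C < tiny) C = tiny;
          lp += std::log(C);
          if (want_grad) {
            double ss = 1.0 - re * re;
            double sd = std::sqrt(ss > 1e-24 ? ss : 1e-24);
            double du = cpu[c] * Phi1f((v - re * u) / sd) / C;
            double dv = phi1f(v) * Phi1f((u - re * v) / sd) / C;
            double dens = std::exp(-(u * u - 2.0 * re * u * v + v * v) /
                                   (2.0 * sd * sd)) / (2.0 * M_PI * sd);
            del = sl * du;
            der = sr * dv;
            drh = sl * sr * dens / C;
          }
        } else if (yl[rec] >= 0) {
          double sl = yl[rec] ? 1.0 : -1.0;
          double C = cPu[c];
          if (C < tiny) C = tiny;
          lp += std::log(C);
          if (want_grad) del = sl * cpu[c] / C;
        } else {
          double sr = yr[rec] ? 1.0 : -1.0;
          double v = sr * (etar[rec] + br[t]);
          double C = Phi1f(v);
          if (C < tiny) C = tiny;
          lp += std::log(C);
          if (want_grad) der = sr * phi1f(v) / C;
        }
        if (want_grad) {
          for (int m = 0; m < p; m++) {
            g[m] += del * X(rec, m);
            g[p + m] += der * X(rec, m);
          }
          g[2 * p]     += del * s2 * tv.L11 * gz[j];
          g[2 * p + 1] += der * s2 * gz[j];
          g[2 * p + 2] += der * s2 * tv.L22 * gz[kk];
          g[2 * p + 3] += drh * drho_da;
        }
      }
      logP[t] = lp;
    }
    double M = logP[0];
    for (int t = 1; t < T; t++) if (logP[t] > M) M = logP[t];
    double Li = 0.0;
    for (int t = 0; t < T; t++) Li += W[t] * std::exp(logP[t] - M);
    if (Li < 1e-300) Li = 1e-300;
    nll -= std::log(Li) + M;
    if (want_grad) {
      for (int t = 0; t < T; t++) {
        double wq = W[t] * std::exp(logP[t] - M) / Li;
        if (wq == 0.0) continue;
        const double *g = &G[(size_t)t * npar];
        for (int q = 0; q < npar; q++) grad[q] -= wq * g[q];
      }
    }
  }
  return List::create(_["nll"] = nll, _["grad"] = grad);
}

// Adaptive variant: per-scan recentering of the quadrature grid at the mode
// of the integrand with curvature-based rescaling.  Value only (no gradient).
// [[Rcpp::export]]
double biprobit_nll_adaptive_cpp(NumericVector theta, NumericMatrix X,
                                 IntegerVector yl, IntegerVector yr,
                                 IntegerVector scan_ptr, NumericVector gz,
                                 NumericVector gw) {
  int n = X.nrow(), p = X.ncol();
  if (theta.size() != 2 * p + 4) stop("theta has wrong length");
  ThetaView tv = unpack(theta, p);
  if (!tv.ok) return 1e10;
  BvnCtx ctx[2];
  ctx[0].init(tv.rho);
  ctx[1].init(-tv.rho);

  int K = gz.size(), nscan = scan_ptr.size() - 1;
  const double s2 = M_SQRT2;

  std::vector<double> etal(n), etar(n);
  for (int i = 0; i < n; i++) {
    double al = 0.0, ar = 0.0;
    for (int m = 0; m < p; m++) {
      al += X(i, m) * tv.bl[m];
      ar += X(i, m) * tv.br[m];
    }
    etal[i] = al;
    etar[i] = ar;
  }

  // Sigma and its inverse from the Cholesky factor
  double s11 = tv.L11 * tv.L11;
  double s12 = tv.L11 * tv.L21;
  double s22 = tv.L21 * tv.L21 + tv.L22 * tv.L22;
  double det = s11 * s22 - s12 * s12;
  if (det < 1e-24) return 1e10;
  double i11 = s22 / det, i22 = s11 / det, i12 = -s12 / det;
  double ldet = std::log(det);

  double nll = 0.0;
  for (int s = 0; s < nscan; s++) {
    int r0 = scan_ptr[s], r1 = scan_ptr[s + 1];

    // log integrand g(b) = sum_r log l_r(b) + log phi2(b; Sigma)
    auto gval = [&](double b1, double b2) {
      double v = -std::log(2.0 * M_PI) - 0.5 * ldet -
                 0.5 * (i11 * b1 * b1 + 2.0 * i12 * b1 * b2 + i22 * b2 * b2);
      for (int rec = r0; rec < r1; rec++)
        v += rec_loglik(etal[rec] + b1, etar[rec] + b2, yl[rec], yr[rec],
                        tv.rho, ctx, false, 0, 0, 0);
      return v;
    };
    auto ggrad = [&](double b1, double b2, double *g1, double *g2) {
      *g1 = -(i11 * b1 + i12 * b2);
      *g2 = -(i12 * b1 + i22 * b2);
      for (int rec = r0; rec < r1; rec++) {
        double del, der, drh;
        rec_loglik(etal[rec] + b1, etar[rec] + b2, yl[rec], yr[rec], tv.rho,
                   ctx, true, &del, &der, &drh);
        *g1 += del;
        *g2 += der;
      }
    };

    // Newton search for the mode
    double m1 = 0.0, m2 = 0.0, g0 = gval(m1, m2);
    double h11 = 0, h12 = 0, h22 = 0;
    const double hstep = 1e-4;
    bool ok = true;
    for (int it = 0; it < 25; it++) {
      double g1, g2;
      ggrad(m1, m2, &g1, &g2);
      double a1, a2, c1, c2;
      ggrad(m1 + hstep, m2, &a1, &a2);
      ggrad(m1, m2 + hstep, &c1, &c2);
      h11 = (a1 - g1) / hstep;
      h12 = 0.5 * ((a2 - g2) / hstep + (c1 - g1) / hstep);
      h22 = (c2 - g2) / hstep;
      double hdet = h11 * h22 - h12 * h12;
      if (!(hdet > 0.0 && h11 < 0.0)) { ok = (it > 0); break; }
      double d1 = -(h22 * g1 - h12 * g2) / hdet;
      double d2 = -(-h12 * g1 + h11 * g2) / hdet;
      double step = 1.0;
      double gn = gval(m1 + d1, m2 + d2);
      int halv = 0;
      while (gn < g0 && halv < 20) {
        step /= 2.0;
        gn = gval(m1 + step * d1, m2 + step * d2);
        halv++;
      }
      if (halv >= 20) break;
      m1 += step * d1;
      m2 += step * d2;
      if (std::fabs(gn - g0) < 1e-10 && g1 * g1 + g2 * g2 < 1e-10) {
        g0 = gn;
        break;
      }
      g0 = gn;
    }

    // curvature H = -g''(mode); fall back to prior scale if not PD
    double hdet = h11 * h22 - h12 * h12;
    double C11, C21, C22;
    if (ok && hdet > 0.0 && h11 < 0.0) {
      double H11 = -h11, H12 = -h12, H22 = -h22, Hdet = hdet;
      // Cholesky of H^{-1} = [H22, -H12; -H12, H11]/Hdet
      double v11 = H22 / Hdet, v12 = -H12 / Hdet, v22 = H11 / Hdet;
      C11 = std::sqrt(v11);
      C21 = v12 / C11;
      double rem = v22 - C21 * C21;
      C22 = std::sqrt(rem > 1e-24 ? rem : 1e-24);
    } else {
      m1 = 0.0; m2 = 0.0;
      C11 = tv.L11; C21 = tv.L21; C22 = tv.L22;
    }

    double detC = C11 * C22;
    double M = R_NegInf;
    std::vector<double> lt(K * K);
    for (int j = 0; j < K; j++) {
      for (int kk = 0; kk < K; kk++) {
        double b1 = m1 + s2 * C11 * gz[j];
        double b2 = m2 + s2 * (C21 * gz[j] + C22 * gz[kk]);
        double v = gval(b1, b2) + gz[j] * gz[j] + gz[kk] * gz[kk];
        lt[j * K + kk] = v;
        if (v > M) M = v;
      }
    }
    double Li = 0.0;
    for (int j = 0; j < K; j++)
      for (int kk = 0; kk < K; kk++)
        Li += gw[j] * gw[kk] * std::exp(lt[j * K + kk] - M);
    Li *= 2.0 * detC;
    if (Li < 1e-300) Li = 1e-300;
    nll -= std::log(Li) + M;
  }
  return nll;
}

// Posterior (empirical Bayes) means of the scan random intercepts by
// Gauss-Hermite quadrature: E[b | y] per scan.
// [[Rcpp::export]]
NumericMatrix biprobit_eb_cpp(NumericVector theta, NumericMatrix X,
                              IntegerVector yl, IntegerVector yr,
                              IntegerVector scan_ptr, NumericVector gz,
                              NumericVector gw) {
  int n = X.nrow(), p = X.ncol();
  if (theta.size() != 2 * p + 4) stop("theta has wrong length");
  ThetaView tv = unpack(theta, p);
  if (!tv.ok) stop("non-finite parameters");
  BvnCtx ctx[2];
  ctx[0].init(tv.rho);
  ctx[1].init(-tv.rho);
  int K = gz.size(), T = K * K, nscan = scan_ptr.size() - 1;
  const double s2 = M_SQRT2;

  std::vector<double> etal(n), etar(n);
  for (int i = 0; i < n; i++) {
    double al = 0.0, ar = 0.0;
    for (int m = 0; m < p; m++) {
      al += X(i, m) * tv.bl[m];
      ar += X(i, m) * tv.br[m];
    }
    etal[i] = al;
    etar[i] = ar;
  }
  std::vector<double> bl(T), br(T), W(T);
  for (int j = 0; j < K; j++)
    for (int kk = 0; kk < K; kk++) {
      int t = j * K + kk;
      bl[t] = s2 * tv.L11 * gz[j];
      br[t] = s2 * (tv.L21 * gz[j] + tv.L22 * gz[kk]);
      W[t] = gw[j] * gw[kk] / M_PI;
    }

  NumericMatrix out(nscan, 2);
  std::vector<double> logP(T);
  for (int s = 0; s < nscan; s++) {
    int r0 = scan_ptr[s], r1 = scan_ptr[s + 1];
    for (int t = 0; t < T; t++) {
      double lp = 0.0;
      for (int rec = r0; rec < r1; rec++)
        lp += rec_loglik(etal[rec] + bl[t], etar[rec] + br[t], yl[rec],
                         yr[rec], tv.rho, ctx, false, 0, 0, 0);
      logP[t] = lp;
    }
    double M = logP[0];
    for (int t = 1; t < T; t++) if (logP[t] > M) M = logP[t];
    double den = 0.0, num1 = 0.0, num2 = 0.0;
    for (int t = 0; t < T; t++) {
      double w = W[t] * std::exp(logP[t] - M);
      den += w;
      num1 += w * bl[t];
      num2 += w * br[t];
    }
    out(s, 0) = num1 / den;
    out(s, 1) = num2 / den;
  }
  return out;
}
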