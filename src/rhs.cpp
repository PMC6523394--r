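// Method-of-lines right-hand sides for the front-fixed finite-volume scheme.
// These mirror the continuum model exactly as documented in R/swelling.R and
// R/release.R; the geometry list is precomputed once per solve in R.
#include <Rcpp.h>
using namespace Rcpp;

// glassy-core attenuation factor, clamped below phi0
static inline double ffac(double phi, double beta, double phi0, double phiG) {
  double p = phi < phi0 ? phi0 : phi;
  if (p >= phiG) return 1.0;
  return std::exp(-beta * (phiG - p) / (phiG - phi0));
}

// [[Rcpp::export]]
NumericVector swelling_rhs_cpp(NumericVector y, List geo, double Ds,
                               double beta, double phi0, double phiG,
                               double phieq, int flux_consistent) {
  NumericVector dxi = geo["dxi"], w = geo["w"], af = geo["af_int"],
                xf = geo["xf_int"], bg = geo["bg_coefs"];
  const int m = w.size();
  const double S = y[m];
  std::vector<double> Fd(m + 1, 0.0), Fa(m + 1, 0.0);
  for (int j = 0; j < m - 1; ++j) {
    const double pf = 0.5 * (y[j] + y[j + 1]);
    const double grad = (y[j + 1] - y[j]) / dxi[j];
    Fd[j + 1] = af[j] * Ds * ffac(pf, beta, phi0, phiG) * (1.0 - pf) * grad;
  }
  double gradb = bg[0] * phieq + bg[1] * y[m - 1] + bg[2] * y[m - 2];
  if (gradb < 0) gradb = 0;
  const double Fb = Ds * (1.0 - phieq) * gradb;
  double Sdot = Ds * gradb / S;
  if (flux_consistent) Sdot *= (1.0 - phieq);
  Fd[m] = Fb;
  for (int j = 0; j < m - 1; ++j)
    Fa[j + 1] = af[j] * (-xf[j] * Sdot) * y[j + 1]; // upwind from outside
  Fa[m] = -Sdot * phieq;
  const double S2 = S * S, S3 = S2 * S;
  NumericVector dy(m + 2);
  for (int i = 0; i < m; ++i)
    dy[i] = (S * (Fd[i + 1] - Fd[i]) - S2 * (Fa[i + 1] - Fa[i])) / (S3 * w[i])
            - 3.0 * (Sdot / S) * y[i];
  dy[m] = Sdot;
  dy[m + 1] = S * Fb + S2 * Sdot * phieq; // cumulative influx audit
  return dy;
}

// [[Rcpp::export]]
NumericVector release_rhs_cpp(NumericVector y, List geo, double Ds,
                              double beta, double phi0, double phiG,
                              double phieq, double Dd, double kbg,
                              double N_beads, double V_res, int static_bead) {
  NumericVector dxi = geo["dxi"], w = geo["w"], af = geo["af_int"],
                xf = geo["xf_int"], bg = geo["bg_coefs"];
  const int m = w.size();
  const double S = y[m];
  const double *phi = &y[0];
  const double *cd = &y[m + 1];
  const double *cb = &y[2 * m + 1];
  const double C = y[3 * m + 1];
  const double S2 = S * S, S3 = S2 * S;

  NumericVector dy(3 * m + 2);
  std::vector<double> vface(m - 1, 0.0), fface(m - 1, 1.0);
  double Sdot = 0.0;

  if (!static_bead) {
    std::vector<double> Fd(m + 1, 0.0), Fa(m + 1, 0.0);
    for (int j = 0; j < m - 1; ++j) {
      const double pf = 0.5 * (phi[j] + phi[j + 1]);
      const double grad = (phi[j + 1] - phi[j]) / dxi[j];
      const double fc = ffac(pf, beta, phi0, phiG);
      fface[j] = fc;
      Fd[j + 1] = af[j] * Ds * fc * (1.0 - pf) * grad;
      vface[j] = Ds * fc * grad / S;
    }
    double gradb = bg[0] * phieq + bg[1] * phi[m - 1] + bg[2] * phi[m - 2];
    if (gradb < 0) gradb = 0;
    Fd[m] = Ds * (1.0 - phieq) * gradb;
    Sdot = Ds * gradb / S;
    for (int j = 0; j < m - 1; ++j)
      Fa[j + 1] = af[j] * (-xf[j] * Sdot) * phi[j + 1];
    Fa[m] = -Sdot * phieq;
    for (int i = 0; i < m; ++i)
      dy[i] = (S * (Fd[i + 1] - Fd[i]) - S2 * (Fa[i + 1] - Fa[i])) /
              (S3 * w[i]) - 3.0 * (Sdot / S) * phi[i];
  }
  dy[m] = Sdot;

  // free drug: diffusion (one-sided boundary gradient against C_res) plus
  // mesh-relative advection; bound drug: advection and transfer only
  std::vector<double> Fdc(m + 1, 0.0), Fac(m + 1, 0.0), Fab(m + 1, 0.0);
  for (int j = 0; j < m - 1; ++j) {
    const double grad = (cd[j + 1] - cd[j]) / dxi[j];
    Fdc[j + 1] = af[j] * Dd * fface[j] * grad;
    const double u = vface[j] - xf[j] * Sdot;
    const double cdu = (u >= 0) ? cd[j] : cd[j + 1];
    const double cbu = (u >= 0) ? cb[j] : cb[j + 1];
    Fac[j + 1] = af[j] * u * cdu;
    Fab[j + 1] = af[j] * u * cbu;
  }
  const double gradcb = bg[0] * C + bg[1] * cd[m - 1] + bg[2] * cd[m - 2];
  const double Fb_cd = Dd * gradcb;
  Fdc[m] = Fb_cd; // boundary relative advective flux is zero
  for (int i = 0; i < m; ++i) {
    const double kloc =
        static_bead ? kbg : kbg * ffac(phi[i], beta, phi0, phiG);
    dy[m + 1 + i] =
        (S * (Fdc[i + 1] - Fdc[i]) - S2 * (Fac[i + 1] - Fac[i])) /
            (S3 * w[i]) -
        3.0 * (Sdot / S) * cd[i] + kloc * cb[i];
    dy[2 * m + 1 + i] = (-S2 * (Fab[i + 1] - Fab[i])) / (S3 * w[i]) -
                        3.0 * (Sdot / S) * cb[i] - kloc * cb[i];
  }
  // reservoir balance (1e6: m^3 of bead flux volume to mL)
  dy[3 * m + 1] = -N_beads * 4.0 * M_PI * S * Fb_cd * 1e6 / V_res;
  return dy;
}
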