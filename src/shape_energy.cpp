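// Discretized Helfrich energy of an axisymmetric fusion-pore profile.
//
// The profile is parameterized by its tangent angle phi at spline control
// nodes on two arc-length segments (remote boundary -> waist, waist -> disc
// rim); the R side precomputes the natural-spline value/derivative basis
// matrices mapping control values to quadrature nodes. This kernel only
// assembles geometry and energy; it is called thousands of times per solve
// inside the quasi-Newton minimization, which is why it is compiled.

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct EvalOut {
  double bending, tension, ring, energy, pen_geom;
  double c1, c2, c3, z_w, L1, L2, rho_end;
  std::vector<double> rho1, z1, rho2, z2, phi1, phi2, s1, s2, m1, m2;
};

inline void matvec(const NumericMatrix& M, const std::vector<double>& v,
                   std::vector<double>& out) {
  const int nr = M.nrow(), nc = M.ncol();
  out.assign(nr, 0.0);
  for (int j = 0; j < nc; ++j) {
    const double vj = v[j];
    const double* col = &M(0, j);
    for (int i = 0; i < nr; ++i) out[i] += col[i] * vj;
  }
}

void eval_core(const NumericVector& par, double r, double h,
               double kappa, double gamma, double c0,
               double R_out, double R_d,
               int hinged, int elastic, double ring_modulus,
               const NumericMatrix& S1, const NumericMatrix& D1,
               const NumericMatrix& S2, const NumericMatrix& D2,
               const NumericVector& t1, const NumericVector& t2,
               EvalOut& out) {
  const int nc = S1.ncol();
  const int nq1 = S1.nrow(), nq2 = S2.nrow();
  int i = 0;

  std::vector<double> phi1c(nc), phi2c(nc);
  phi1c[0] = M_PI;
  for (int k = 1; k < nc - 1; ++k) phi1c[k] = par[i++];
  phi1c[nc - 1] = M_PI / 2.0;
  double L1 = std::exp(std::min(std::max(par[i++], -7.0), 9.0));
  double phi2_end = 0.0;
  if (hinged) phi2_end = par[i++];
  phi2c[0] = M_PI / 2.0;
  for (int k = 1; k < nc - 1; ++k) phi2c[k] = par[i++];
  phi2c[nc - 1] = phi2_end;
  double L2 = std::exp(std::min(std::max(par[i++], -7.0), 9.0));
  double rho_end = R_d;
  if (elastic) rho_end = std::exp(std::min(std::max(par[i++], -7.0), 9.0));

  std::vector<double> phi1, dphi1, phi2, dphi2;
  matvec(S1, phi1c, phi1);
  matvec(D1, phi1c, dphi1);
  matvec(S2, phi2c, phi2);
  matvec(D2, phi2c, dphi2);
  for (int k = 0; k < nq1; ++k) dphi1[k] /= L1;
  for (int k = 0; k < nq2; ++k) dphi2[k] /= L2;

  std::vector<double> s1(nq1), s2(nq2);
  for (int k = 0; k < nq1; ++k) s1[k] = t1[k] * L1;
  for (int k = 0; k < nq2; ++k) s2[k] = t2[k] * L2;

  std::vector<double> rho1(nq1), z1(nq1), rho2(nq2), z2(nq2);
  rho1[0] = R_out; z1[0] = 0.0;
  for (int k = 1; k < nq1; ++k) {
    const double ds = s1[k] - s1[k - 1];
    rho1[k] = rho1[k - 1] + 0.5 * (std::cos(phi1[k]) + std::cos(phi1[k - 1])) * ds;
    z1[k] = z1[k - 1] + 0.5 * (std::sin(phi1[k]) + std::sin(phi1[k - 1])) * ds;
  }
  const double z_w = z1[nq1 - 1];
  rho2[0] = r; z2[0] = z_w;
  for (int k = 1; k < nq2; ++k) {
    const double ds = s2[k] - s2[k - 1];
    rho2[k] = rho2[k - 1] + 0.5 * (std::cos(phi2[k]) + std::cos(phi2[k - 1])) * ds;
    z2[k] = z2[k - 1] + 0.5 * (std::sin(phi2[k]) + std::sin(phi2[k - 1])) * ds;
  }

  std::vector<double> m1(nq1), m2(nq2);
  double eb1 = 0.0, eb2 = 0.0, area1 = 0.0, area2 = 0.0, pen = 0.0;
  for (int k = 0; k < nq1; ++k) {
    const double rs = std::max(rho1[k], 0.05);
    m1[k] = dphi1[k] + std::sin(phi1[k]) / rs - c0;
    const double dlow = std::min(rho1[k] - r, 0.0);
    const double dpos = std::min(rho1[k] - 0.05, 0.0);
    pen += dlow * dlow + 10.0 * dpos * dpos;
  }
  for (int k = 0; k < nq2; ++k) {
    const double rs = std::max(rho2[k], 0.05);
    m2[k] = dphi2[k] + std::sin(phi2[k]) / rs - c0;
    const double dlow = std::min(rho2[k] - r, 0.0);
    const double dpos = std::min(rho2[k] - 0.05, 0.0);
    pen += dlow * dlow + 10.0 * dpos * dpos;
  }
  for (int k = 1; k < nq1; ++k) {
    const double ds = s1[k] - s1[k - 1];
    const double f0 = m1[k - 1] * m1[k - 1] * std::max(rho1[k - 1], 0.05);
    const double f1 = m1[k] * m1[k] * std::max(rho1[k], 0.05);
    eb1 += 0.5 * (f0 + f1) * ds;
    area1 += 0.5 * (std::max(rho1[k - 1], 0.05) + std::max(rho1[k], 0.05)) * ds;
  }
  for (int k = 1; k < nq2; ++k) {
    const double ds = s2[k] - s2[k - 1];
    const double f0 = m2[k - 1] * m2[k - 1] * std::max(rho2[k - 1], 0.05);
    const double f1 = m2[k] * m2[k] * std::max(rho2[k], 0.05);
    eb2 += 0.5 * (f0 + f1) * ds;
    area2 += 0.5 * (std::max(rho2[k - 1], 0.05) + std::max(rho2[k], 0.05)) * ds;
  }
  eb1 *= M_PI * kappa;
  eb2 *= M_PI * kappa;

  // junction kink between the two spline segments
  const double ds_j = 0.5 * ((s1[nq1 - 1] - s1[nq1 - 2]) + (s2[1] - s2[0]));
  const double rw = std::max(r, 0.05);
  const double mj = (phi2[1] - phi1[nq1 - 2]) / (2.0 * ds_j) + 1.0 / rw - c0;
  const double ebj = M_PI * kappa * mj * mj * rw * ds_j;

  const double area = 2.0 * M_PI * (area1 + area2);
  const double a_proj = M_PI * (R_out * R_out - r * r) +
    M_PI * std::max(rho_end * rho_end - r * r, 0.0);
  const double et = gamma * (area - a_proj);
  const double er = elastic
    ? 0.5 * ring_modulus * (rho_end - R_d) * (rho_end - R_d) * 2.0 * M_PI * R_d
    : 0.0;

  out.bending = eb1 + eb2 + ebj;
  out.tension = et;
  out.ring = er;
  out.energy = out.bending + et + er;
  out.pen_geom = pen;
  out.c1 = rho1[nq1 - 1] - r;
  out.c2 = rho2[nq2 - 1] - rho_end;
  out.c3 = (z2[nq2 - 1] - z1[0]) - h;
  out.z_w = z_w;
  out.L1 = L1; out.L2 = L2; out.rho_end = rho_end;
  out.rho1.swap(rho1); out.z1.swap(z1);
  out.rho2.swap(rho2); out.z2.swap(z2);
  out.phi1.swap(phi1); out.phi2.swap(phi2);
  out.s1.swap(s1); out.s2.swap(s2);
  out.m1.swap(m1); out.m2.swap(m2);
}

}  // namespace

// [[Rcpp::export]]
double shape_objective_cpp(NumericVector par, double r, double h,
                           double kappa, double gamma, double c0,
                           double R_out, double R_d,
                           int hinged, int elastic, double ring_modulus,
                           NumericMatrix S1, NumericMatrix D1,
                           NumericMatrix S2, NumericMatrix D2,
                           NumericVector t1, NumericVector t2, double w) {
  EvalOut e;
  eval_core(par, r, h, kappa, gamma, c0, R_out, R_d, hinged, elastic,
            ring_modulus, S1, D1, S2, D2, t1, t2, e);
  const double cons = e.c1 * e.c1 + e.c2 * e.c2 + e.c3 * e.c3;
  const double val = e.energy + w * (cons + e.pen_geom);
  return R_finite(val) ? val : 1e10;
}

// [[Rcpp::export]]
List shape_eval_cpp(NumericVector par, double r, double h,
                    double kappa, double gamma, double c0,
                    double R_out, double R_d,
                    int hinged, int elastic, double ring_modulus,
                    NumericMatrix S1, NumericMatrix D1,
                    NumericMatrix S2, NumericMatrix D2,
                    NumericVector t1, NumericVector t2) {
  EvalOut e;
  eval_core(par, r, h, kappa, gamma, c0, R_out, R_d, hinged, elastic,
            ring_modulus, S1, D1, S2, D2, t1, t2, e);
  return List::create(
    _["bending"] = e.bending, _["tension"] = e.tension, _["ring"] = e.ring,
    _["energy"] = e.energy, _["pen_geom"] = e.pen_geom,
    _["constraints"] = NumericVector::create(e.c1, e.c2, e.c3),
    _["z_w"] = e.z_w, _["L1"] = e.L1, _["L2"] = e.L2,
    _["rho_end"] = e.rho_end,
    _["rho1"] = wrap(e.rho1), _["z1"] = wrap(e.z1),
    _["rho2"] = wrap(e.rho2), _["z2"] = wrap(e.z2),
    _["phi1"] = wrap(e.phi1), _["phi2"] = wrap(e.phi2),
    _["s1"] = wrap(e.s1), _["s2"] = wrap(e.s2),
    _["m1"] = wrap(e.m1), _["m2"] = wrap(e.m2));
}

// [[Rcpp::export]]
NumericVector shape_gradient_cpp(NumericVector par, double r, double h,
                                 double kappa, double gamma, double c0,
                                 double R_out, double R_d,
                                 int hinged, int elastic, double ring_modulus,
                                 NumericMatrix S1, NumericMatrix D1,
                                 NumericMatrix S2, NumericMatrix D2,
                                 NumericVector t1, NumericVector t2,
                                 double w) {
  const int n = par.size();
  NumericVector g(n);
  NumericVector p = clone(par);
  const double eps = 1e-6;
  for (int k = 0; k < n; ++k) {
    const double pk = p[k];
    p[k] = pk + eps;
    const double fp = shape_objective_cpp(p, r, h, kappa, gamma, c0, R_out,
                                          R_d, hinged, elastic, ring_modulus,
                                          S1, D1, S2, D2, t1, t2, w);
    p[k] = pk - eps;
    const double fm = shape_objective_cpp(p, r, h, kappa, gamma, c0, R_out,
                                          R_d, hinged, elastic, ring_modulus,
                                          S1, D1, S2, D2, t1, t2, w);
    p[k] = pk;
    g[k] = (fp - fm) / (2.0 * eps);
  }
  return g;
}
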