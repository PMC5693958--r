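// Condensed-history electron transport in water.
//
// Straightforward class-II-style stepping: deterministic collision energy
// loss per step (midpoint rule on the stopping power) and a Gaussian
// multiple-scattering deflection of Highland width applied in two orthogonal
// planes.  Radiative losses, straggling and secondaries are out of scope.
// Uses R's RNG stream so results are reproducible under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

// Berger-Seltzer collision stopping power for electrons in water,
// keV/um at unit density; T in keV, I = 75 eV.
static inline double scol_water(double T) {
  const double me = 511.0, I = 75.0e-3;
  double tau = T / me;
  double g = 1.0 + tau;
  double beta2 = 1.0 - 1.0 / (g * g);
  double F = 1.0 - beta2 +
    (tau * tau / 8.0 - (2.0 * tau + 1.0) * std::log(2.0)) / (g * g);
  double arg = tau * tau * (tau + 2.0) / 2.0 * (me / I) * (me / I);
  double S = 0.1535 * 0.5551 / beta2 * (std::log(arg) + F); // MeV cm^2/g
  return S * 0.1;                                           // keV/um in water
}

// power-law range-energy stopping power: S = E / (p * rr(E)),
// rr(E) = R0 * (E/E0)^p  (used to mirror the straight-line alpha model)
static inline double scol_powerlaw(double T, double E0, double R0, double p) {
  double rr = R0 * std::pow(T / E0, p);
  if (rr <= 0) return 1e30;
  return T / (p * rr);
}

// [[Rcpp::export]]
double cpp_scol_water(double T_keV) { return scol_water(T_keV); }

// [[Rcpp::export]]
List cpp_transport(NumericVector px, NumericVector py, NumericVector pz,
                   NumericVector dx, NumericVector dy, NumericVector dz,
                   NumericVector energy,
                   double zmax, double lat_half,
                   double step_max, double step_frac, double cutoff,
                   double X0_um, bool scatter, double max_path_factor,
                   int stopping_model, double pl_E0, double pl_R0,
                   double pl_p) {
  int n = px.size();
  IntegerVector status(n);      // 0 detected, 1 absorbed, 2 escaped
  NumericVector oxd(n), oyd(n), osx(n), osy(n), oE(n), opath(n);
  RNGScope rng;
  for (int i = 0; i < n; ++i) {
    double x = px[i], y = py[i], z = pz[i];
    double ux = dx[i], uy = dy[i], uz = dz[i];
    double E = energy[i], path = 0.0;
    double csda0 = (stopping_model == 1)
      ? pl_R0 * std::pow(E / pl_E0, pl_p)
      : E / scol_water(E);     // first-order range estimate for the guard
    double max_path = max_path_factor * (csda0 + 100.0);
    int st = 2;
    while (true) {
      if (E <= cutoff) { st = 1; break; }
      double S1 = (stopping_model == 1)
        ? scol_powerlaw(E, pl_E0, pl_R0, pl_p) : scol_water(E);
      double rr = (stopping_model == 1)
        ? pl_R0 * std::pow(E / pl_E0, pl_p) : E / S1;
      double ds = std::min(step_max, step_frac * rr);
      if (ds <= 0) { st = 1; break; }
      double Emid = E - 0.5 * ds * S1;
      double Smid = (Emid > cutoff)
        ? ((stopping_model == 1)
             ? scol_powerlaw(Emid, pl_E0, pl_R0, pl_p) : scol_water(Emid))
        : S1;
      double dE = ds * Smid;
      double nx = x + ux * ds, ny = y + uy * ds, nz = z + uz * ds;
      if (nz < 0.0) {                       // crossed the detector plane
        double f = z / (z - nz);
        double Ec = E - f * dE;
        oxd[i] = x + ux * ds * f;
        oyd[i] = y + uy * ds * f;
        osx[i] = ux; osy[i] = uy;
        oE[i] = (Ec > 0.0) ? Ec : 0.0;
        opath[i] = path + ds * f;
        st = 0; break;
      }
      x = nx; y = ny; z = nz; path += ds; E -= dE;
      if (E <= cutoff) { st = 1; break; }
      if (z > zmax || std::fabs(x) > lat_half || std::fabs(y) > lat_half ||
          path > max_path) { st = 2; break; }
      if (scatter) {
        double T = E / 1000.0, m = 0.511;          // MeV
        double pc = std::sqrt(T * (T + 2.0 * m));
        double betapc = pc * pc / (T + m);
        double th0 = 13.6e-3 / betapc * std::sqrt(ds / X0_um);
        double tx = th0 * norm_rand(), ty = th0 * norm_rand();
        double ax, ay, az;
        if (std::fabs(uz) < 0.9) { ax = 0; ay = 0; az = 1; }
        else { ax = 1; ay = 0; az = 0; }
        double e1x = uy * az - uz * ay, e1y = uz * ax - ux * az,
               e1z = ux * ay - uy * ax;
        double n1 = std::sqrt(e1x * e1x + e1y * e1y + e1z * e1z);
        e1x /= n1; e1y /= n1; e1z /= n1;
        double e2x = uy * e1z - uz * e1y, e2y = uz * e1x - ux * e1z,
               e2z = ux * e1y - uy * e1x;
        double al = std::sqrt(tx * tx + ty * ty);
        double ca = std::cos(al), sa = (al > 1e-12) ? std::sin(al) / al : 1.0;
        double vx = ux * ca + (e1x * tx + e2x * ty) * sa;
        double vy = uy * ca + (e1y * tx + e2y * ty) * sa;
        double vz = uz * ca + (e1z * tx + e2z * ty) * sa;
        double nn = std::sqrt(vx * vx + vy * vy + vz * vz);
        ux = vx / nn; uy = vy / nn; uz = vz / nn;
      }
    }
    status[i] = st;
  }
  return List::create(_["status"] = status, _["x_d"] = oxd, _["y_d"] = oyd,
                      _["s_x"] = osx, _["s_y"] = osy, _["E"] = oE,
                      _["path"] = opath);
}
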