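#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compartment layout (0-based):
//   idx = ((sex * B + band) * 8 + profile) * 2 + status
// with sex in {0 = male, 1 = female}, band in 0..B-1, profile bits
// {1 = obese, 2 = smoker, 4 = inactive}, status in {0 = nonDM, 1 = DM}.
// Auxiliary cumulative-flow states follow the 32B main states:
//   births per sex (2), deaths per sex (2), new T2DM cases per sex x band (2B).

struct ModelP {
  int B;
  double w;            // band width in years
  double aging;        // aging rate (usually 1/w; 0 in cohort diagnostics)
  double srb;          // male births per female birth
  double rr_mort;
  double rr[3];        // T2DM incidence RR: obesity, smoking, inactivity
  double trend_m2050[2];
  std::vector<double> cbr_t, cbr_v;
  std::vector<double> mort;                 // [2*B], per-year hazard
  std::vector<double> inc;                  // [2*B]
  std::vector<double> on[3], off[3];        // [2*B] each
};

static ModelP unpack(const List& parms) {
  ModelP P;
  P.B   = as<int>(parms["B"]);
  P.w   = as<double>(parms["band_width"]);
  P.aging = as<double>(parms["aging_rate"]);
  P.srb = as<double>(parms["sex_ratio_birth"]);
  P.rr_mort = as<double>(parms["rr_mortality"]);
  NumericVector rr = parms["rr_t2dm"];
  for (int f = 0; f < 3; ++f) P.rr[f] = rr[f];
  NumericVector tm = parms["trend_m2050"];
  P.trend_m2050[0] = tm[0]; P.trend_m2050[1] = tm[1];
  P.cbr_t = as<std::vector<double> >(parms["cbr_years"]);
  P.cbr_v = as<std::vector<double> >(parms["cbr_values"]);
  P.mort  = as<std::vector<double> >(parms["mort"]);
  P.inc   = as<std::vector<double> >(parms["inc"]);
  const char* onn[3]  = {"on_obesity", "on_smoking", "on_inactivity"};
  const char* offn[3] = {"off_obesity", "off_smoking", "off_inactivity"};
  for (int f = 0; f < 3; ++f) {
    P.on[f]  = as<std::vector<double> >(parms[onn[f]]);
    P.off[f] = as<std::vector<double> >(parms[offn[f]]);
  }
  return P;
}

static inline double interp_flat(const std::vector<double>& xs,
                                 const std::vector<double>& ys, double x) {
  int n = xs.size();
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int i = 1;
  while (xs[i] < x) ++i;
  double f = (x - xs[i - 1]) / (xs[i] - xs[i - 1]);
  return ys[i - 1] + f * (ys[i] - ys[i - 1]);
}

// obesity-onset multiplier: 1 up to 1990, linear to m2050 at 2050, flat after
static inline double ob_mult(double t, double m2050) {
  if (t <= 1990.0) return 1.0;
  if (t >= 2050.0) return m2050;
  return 1.0 + (m2050 - 1.0) * (t - 1990.0) / 60.0;
}

static void deriv(double t, const double* y, double* dy, const ModelP& P) {
  const int B = P.B, nmain = 32 * B;
  const int iB0 = nmain, iD0 = nmain + 2, iI0 = nmain + 4;
  const int ntot = nmain + 4 + 2 * B;
  for (int i = 0; i < ntot; ++i) dy[i] = 0.0;

  double total = 0.0;
  for (int i = 0; i < nmain; ++i) total += y[i];

  const double cbr = interp_flat(P.cbr_t, P.cbr_v, t);
  const double births = cbr * total;
  const double male_share = P.srb / (1.0 + P.srb);
  const double aging = P.aging;

  // births enter the youngest band, healthy profile, nonDM
  dy[((0 * B + 0) * 8 + 0) * 2 + 0] += births * male_share;
  dy[((1 * B + 0) * 8 + 0) * 2 + 0] += births * (1.0 - male_share);
  dy[iB0 + 0] += births * male_share;
  dy[iB0 + 1] += births * (1.0 - male_share);

  double mult[2];
  mult[0] = ob_mult(t, P.trend_m2050[0]);
  mult[1] = ob_mult(t, P.trend_m2050[1]);

  for (int s = 0; s < 2; ++s) {
    for (int b = 0; b < B; ++b) {
      const int sb = s * B + b;
      const double mu = P.mort[sb];
      for (int p = 0; p < 8; ++p) {
        const int base = ((sb) * 8 + p) * 2;
        for (int d = 0; d < 2; ++d) {
          const double v = y[base + d];
          if (v == 0.0) continue;
          const int self = base + d;

          // aging; leaving the oldest band counts as mortality
          if (aging > 0.0) {
            double out = aging * v;
            dy[self] -= out;
            if (b < B - 1) dy[self + 16] += out;  // next band, same p, d
            else dy[iD0 + s] += out;
          }

          // background mortality, with DM excess
          double m = mu * (d == 1 ? P.rr_mort : 1.0) * v;
          dy[self] -= m;
          dy[iD0 + s] += m;

          // risk-factor onset / reversal (identical in DM and nonDM)
          for (int f = 0; f < 3; ++f) {
            const int bit = 1 << f;
            if (!(p & bit)) {
              double a = P.on[f][sb];
              if (f == 0) a *= mult[s];
              if (a > 0.0) {
                double fl = a * v;
                dy[self] -= fl;
                dy[((sb * 8 + (p | bit)) * 2) + d] += fl;
              }
            } else {
              double bb = P.off[f][sb];
              if (bb > 0.0) {
                double fl = bb * v;
                dy[self] -= fl;
                dy[((sb * 8 + (p & ~bit)) * 2) + d] += fl;
              }
            }
          }

          // T2DM incidence (absorbing; same-profile DM compartment)
          if (d == 0) {
            double lam = P.inc[sb];
            if (lam > 0.0) {
              if (p & 1) lam *= P.rr[0];
              if (p & 2) lam *= P.rr[1];
              if (p & 4) lam *= P.rr[2];
              double fl = lam * v;
              dy[self] -= fl;
              dy[base + 1] += fl;
              dy[iI0 + sb] += fl;
            }
          }
        }
      }
    }
  }
}

//' @noRd
// [[Rcpp::export]]
NumericVector rhs_cpp(double t, NumericVector y, List parms) {
  ModelP P = unpack(parms);
  int ntot = 32 * P.B + 4 + 2 * P.B;
  if ((int)y.size() != ntot)
    stop("state vector has length %d, expected %d", (int)y.size(), ntot);
  for (int i = 0; i < ntot; ++i)
    if (!R_finite(y[i])) stop("non-finite state entry at position %d", i + 1);
  NumericVector dy(ntot);
  deriv(t, REAL(y), REAL(dy), P);
  return dy;
}

// Dormand-Prince 5(4) adaptive integrator with output at prescribed times.
// [[Rcpp::export]]
NumericMatrix integrate_cpp(NumericVector y0, NumericVector times, List parms,
                            double rtol, double atol) {
  ModelP P = unpack(parms);
  const int n = y0.size();
  const int nt = times.size();
  NumericMatrix out(nt, n);

  static const double c2 = 1.0/5, c3 = 3.0/10, c4 = 4.0/5, c5 = 8.0/9;
  static const double a21 = 1.0/5;
  static const double a31 = 3.0/40, a32 = 9.0/40;
  static const double a41 = 44.0/45, a42 = -56.0/15, a43 = 32.0/9;
  static const double a51 = 19372.0/6561, a52 = -25360.0/2187,
                      a53 = 64448.0/6561, a54 = -212.0/729;
  static const double a61 = 9017.0/3168, a62 = -355.0/33, a63 = 46732.0/5247,
                      a64 = 49.0/176, a65 = -5103.0/18656;
  static const double b1 = 35.0/384, b3 = 500.0/1113, b4 = 125.0/192,
                      b5 = -2187.0/6784, b6 = 11.0/84;
  static const double e1 = 71.0/57600, e3 = -71.0/16695, e4 = 71.0/1920,
                      e5 = -17253.0/339200, e6 = 22.0/525, e7 = -1.0/40;

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), k7(n),
      ytmp(n), y5(n);

  double t = times[0];
  for (int j = 0; j < n; ++j) out(0, j) = y[j];

  double h = 1e-2;
  bool have_k1 = false;
  long nstep = 0;
  const long max_steps = 5000000;

  for (int it = 1; it < nt; ++it) {
    const double tend = times[it];
    while (t < tend) {
      if (++nstep > max_steps)
        stop("integration failure: step limit reached at t = %f", t);
      if (h > tend - t) h = tend - t;
      if (!have_k1) { deriv(t, y.data(), k1.data(), P); have_k1 = true; }

      for (int j = 0; j < n; ++j) ytmp[j] = y[j] + h * a21 * k1[j];
      deriv(t + c2 * h, ytmp.data(), k2.data(), P);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a31 * k1[j] + a32 * k2[j]);
      deriv(t + c3 * h, ytmp.data(), k3.data(), P);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a41 * k1[j] + a42 * k2[j] + a43 * k3[j]);
      deriv(t + c4 * h, ytmp.data(), k4.data(), P);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a51 * k1[j] + a52 * k2[j] + a53 * k3[j] +
                              a54 * k4[j]);
      deriv(t + c5 * h, ytmp.data(), k5.data(), P);
      for (int j = 0; j < n; ++j)
        ytmp[j] = y[j] + h * (a61 * k1[j] + a62 * k2[j] + a63 * k3[j] +
                              a64 * k4[j] + a65 * k5[j]);
      deriv(t + h, ytmp.data(), k6.data(), P);
      for (int j = 0; j < n; ++j)
        y5[j] = y[j] + h * (b1 * k1[j] + b3 * k3[j] + b4 * k4[j] +
                            b5 * k5[j] + b6 * k6[j]);
      deriv(t + h, y5.data(), k7.data(), P);

      double errsum = 0.0;
      for (int j = 0; j < n; ++j) {
        double e = h * (e1 * k1[j] + e3 * k3[j] + e4 * k4[j] + e5 * k5[j] +
                        e6 * k6[j] + e7 * k7[j]);
        double sc = atol + rtol * std::max(std::fabs(y[j]), std::fabs(y5[j]));
        double r = e / sc;
        errsum += r * r;
      }
      double err = std::sqrt(errsum / n);
      if (!R_finite(err))
        stop("integration failure: non-finite error estimate at t = %f", t);

      if (err <= 1.0) {
        t += h;
        y.swap(y5);
        k1.swap(k7);  // FSAL
        double fac = (err == 0.0) ? 5.0
                     : std::min(5.0, std::max(0.2, 0.9 * std::pow(err, -0.2)));
        h *= fac;
      } else {
        h *= std::max(0.1, 0.9 * std::pow(err, -0.2));
        have_k1 = true;  // k1 still valid at unchanged (t, y)
      }
      if (h < 1e-12)
        stop("integration failure: step size underflow at t = %f", t);
    }
    for (int j = 0; j < n; ++j) out(it, j) = y[j];
  }
  return out;
}
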