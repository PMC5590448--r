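// Fast simulator for the three-reaction overflow-metabolism SBR model.
//
// State vector (canonical order): X, Xd, G, Gn, L, MAb
// Parameter vector (canonical order):
//   mu_max1, mu_max2, K_G, K_Gn, K_Gd, K_Gnd, mu_dmax,
//   k31, k32, k41, k42, k52, k61, k63
//
// Integration: Dormand-Prince RK45 with adaptive step control, restarted at
// each medium-renewal event (L, MAb -> 0; G, Gn -> renewal values; X, Xd kept).
// Monod factors clip negative concentrations at zero so that tiny solver
// undershoots cannot produce NaN.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 6;

static inline void model_rhs(const double* y, const double* p, const bool reduced,
                             double* dy) {
  const double X  = y[0] > 0.0 ? y[0] : 0.0;
  const double G  = y[2] > 0.0 ? y[2] : 0.0;
  const double Gn = y[3] > 0.0 ? y[3] : 0.0;

  double phiG = p[0] * Gn / (p[3] + Gn) * X;
  if (!reduced) phiG *= G / (p[2] + G);
  const double phimax = p[1] * X;
  const double phi1 = std::min(phiG, phimax);
  const double phi2 = std::max(0.0, phiG - phimax);
  const double phi3 = p[6] * p[4] / (p[4] + G) * p[5] / (p[5] + Gn) * X;

  dy[0] = phi1 + phi2 - phi3;
  dy[1] = phi3;
  dy[2] = -p[7] * phi1 - p[8] * phi2;
  dy[3] = -p[9] * phi1 - p[10] * phi2;
  dy[4] = p[11] * phi2;
  dy[5] = p[12] * phi1 + p[13] * phi3;

  // project onto the nonnegative orthant: consumption of an exhausted pool
  // stops (the reduced model's glucose demand is otherwise G-independent)
  for (int i = 0; i < NSTATE; ++i)
    if (y[i] <= 0.0 && dy[i] < 0.0) dy[i] = 0.0;
}

// [[Rcpp::export]]
NumericVector rhs_cpp(NumericVector state, NumericVector params, bool reduced) {
  NumericVector out(NSTATE);
  model_rhs(REAL(state), REAL(params), reduced, REAL(out));
  return out;
}

// Dormand-Prince 5(4) coefficients
static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5, c5 = 8.0 / 9;
static const double a21 = 1.0 / 5;
static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
                    a53 = 64448.0 / 6561, a54 = -212.0 / 729;
static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33, a63 = 46732.0 / 5247,
                    a64 = 49.0 / 176, a65 = -5103.0 / 18656;
static const double b1 = 35.0 / 384, b3 = 500.0 / 1113, b4 = 125.0 / 192,
                    b5 = -2187.0 / 6784, b6 = 11.0 / 84;
// embedded 4th-order weights
static const double e1 = 5179.0 / 57600, e3 = 7571.0 / 16695, e4 = 393.0 / 640,
                    e5 = -92097.0 / 339200, e6 = 187.0 / 2100, e7 = 1.0 / 40;

struct RKState {
  double y[NSTATE];
  double t;
  double h;
  double undershoot;  // most negative value seen before clipping
  bool failed;
};

// integrate from rk.t to tend, clamping steps so tend is hit exactly
static void integrate_to(RKState& rk, double tend, const double* p, bool reduced,
                         double rtol, double atol) {
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE], k6[NSTATE],
      k7[NSTATE], ytmp[NSTATE], ynew[NSTATE];
  const double hmin = 1e-12;
  int nstep = 0;
  while (rk.t < tend - 1e-12) {
    if (++nstep > 2000000) { rk.failed = true; return; }
    double h = std::min(rk.h, tend - rk.t);
    model_rhs(rk.y, p, reduced, k1);
    for (;;) {
      for (int i = 0; i < NSTATE; ++i) ytmp[i] = rk.y[i] + h * a21 * k1[i];
      model_rhs(ytmp, p, reduced, k2);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = rk.y[i] + h * (a31 * k1[i] + a32 * k2[i]);
      model_rhs(ytmp, p, reduced, k3);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = rk.y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
      model_rhs(ytmp, p, reduced, k4);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = rk.y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] + a54 * k4[i]);
      model_rhs(ytmp, p, reduced, k5);
      for (int i = 0; i < NSTATE; ++i)
        ytmp[i] = rk.y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                 a64 * k4[i] + a65 * k5[i]);
      model_rhs(ytmp, p, reduced, k6);
      for (int i = 0; i < NSTATE; ++i)
        ynew[i] = rk.y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                 b5 * k5[i] + b6 * k6[i]);
      model_rhs(ynew, p, reduced, k7);

      double errnorm = 0.0;
      for (int i = 0; i < NSTATE; ++i) {
        const double y4 = rk.y[i] + h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                                         e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
        const double sc = atol + rtol * std::max(std::fabs(rk.y[i]), std::fabs(ynew[i]));
        const double e = (ynew[i] - y4) / sc;
        errnorm += e * e;
      }
      errnorm = std::sqrt(errnorm / NSTATE);

      // force resolution of steep substrate-depletion crossings: a step that
      // dives visibly below zero is rejected and retried shorter
      double worst = 0.0;
      for (int i = 0; i < NSTATE; ++i)
        if (ynew[i] < worst) worst = ynew[i];
      if (worst < -1e-6 && h > 1e-8) {
        h *= 0.5;
        continue;
      }

      if (errnorm <= 1.0 || h <= hmin) {
        rk.t += h;
        for (int i = 0; i < NSTATE; ++i) {
          if (ynew[i] < 0.0) {
            if (ynew[i] < rk.undershoot) rk.undershoot = ynew[i];
            ynew[i] = 0.0;
          }
          rk.y[i] = ynew[i];
        }
        double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
        fac = std::min(5.0, std::max(0.2, fac));
        rk.h = std::min(h * fac, tend > rk.t ? (tend - rk.t) * 4.0 + 1.0 : 1.0);
        if (rk.h < hmin) rk.h = hmin;
        break;
      }
      double fac = 0.9 * std::pow(errnorm, -0.2);
      fac = std::min(1.0, std::max(0.1, fac));
      h *= fac;
      if (h <= hmin) { rk.failed = true; return; }
    }
    if (rk.failed) return;
  }
  rk.t = tend;
}

// [[Rcpp::export]]
List sim_sbr_cpp(NumericVector init, NumericVector params, bool reduced,
                 NumericMatrix events, NumericVector times,
                 double rtol = 1e-8, double atol = 1e-10) {
  const int nt = times.size();
  const int ne = events.nrow();
  if (nt < 1) stop("at least one output time is required");
  NumericMatrix out(nt, NSTATE);
  NumericMatrix pre(ne, NSTATE), post(ne, NSTATE);

  RKState rk;
  for (int i = 0; i < NSTATE; ++i) rk.y[i] = init[i];
  rk.t = times[0];
  rk.h = 1e-3;
  rk.undershoot = 0.0;
  rk.failed = false;

  const double* p = REAL(params);
  int it = 0;
  // record initial time point
  if (nt > 0) {
    for (int i = 0; i < NSTATE; ++i) out(0, i) = rk.y[i];
    it = 1;
  }

  int iev = 0;
  while (it < nt || iev < ne) {
    // next stop: min(next output time, next event time)
    double tnext;
    bool is_event;
    const double tout = it < nt ? times[it] : R_PosInf;
    const double tev = iev < ne ? events(iev, 0) : R_PosInf;
    if (tev <= tout) { tnext = tev; is_event = true; }
    else             { tnext = tout; is_event = false; }
    if (!R_FINITE(tnext)) break;

    integrate_to(rk, tnext, p, reduced, rtol, atol);
    if (rk.failed) {
      return List::create(_["ok"] = false, _["t_fail"] = rk.t,
                          _["segment"] = iev + 1);
    }
    if (is_event) {
      for (int i = 0; i < NSTATE; ++i) pre(iev, i) = rk.y[i];
      // renewal: substrates set, metabolites withdrawn, biomass kept
      rk.y[2] = events(iev, 1);
      rk.y[3] = events(iev, 2);
      rk.y[4] = 0.0;
      rk.y[5] = 0.0;
      for (int i = 0; i < NSTATE; ++i) post(iev, i) = rk.y[i];
      rk.h = 1e-3;  // restart step-size control across the discontinuity
      ++iev;
      // an output time equal to the event time records the post-event state
    }
    while (it < nt && times[it] <= rk.t + 1e-12) {
      for (int i = 0; i < NSTATE; ++i) out(it, i) = rk.y[i];
      ++it;
    }
  }

  return List::create(_["ok"] = true, _["trajectory"] = out,
                      _["event_pre"] = pre, _["event_post"] = post,
                      _["undershoot"] = rk.undershoot);
}
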