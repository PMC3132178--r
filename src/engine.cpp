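// Streaming stimulus->response engine: per time step, bilinear image
// sampling under horizontal motion, Naka-Rushton transduction, LMC
// band-pass, variant-specific input-line transform, correlator
// half-detectors over the closed azimuthal ring, and gain-control
// integration for every receptive field. State is per receptor channel;
// nothing per-site is stored over time. The pure-R pipeline in R/ is the
// reference implementation this file is tested against.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double lp_alpha_c(double tau, double dt) {
  return tau <= 0.0 ? 1.0 : 1.0 - std::exp(-dt / tau);
}

// Bilinear azimuthal sampling positions at one time step (shared by all
// rows: the elevation blend is precomputed in the row profiles).
static void az_index(const NumericVector& az, double shift_deg, double dpp,
                     int W, std::vector<int>& i0, std::vector<int>& i1,
                     std::vector<double>& f) {
  const int n = az.size();
  for (int k = 0; k < n; ++k) {
    double x = (az[k] - shift_deg) / dpp;
    x -= W * std::floor(x / W);   // wrap into [0, W)
    if (x >= W) x -= W;           // guard the floor round-off edge case
    int a = (int)std::floor(x);
    f[k] = x - a;
    i0[k] = a % W;
    i1[k] = (a + 1) % W;
  }
}

// [[Rcpp::export]]
List cpp_frontend_calib(NumericMatrix prof, double dpp, NumericVector az,
                        double v, double dt, int n_steps, int stride,
                        double I0, double a_nr, double tauL, double tauH,
                        double tauLp, double tauS) {
  const int nr = prof.nrow(), W = prof.ncol(), na = az.size();
  const int nch = nr * na;
  const double aL = lp_alpha_c(tauL, dt), aH = lp_alpha_c(tauH, dt);
  const double aLp = lp_alpha_c(tauLp, dt), aS = lp_alpha_c(tauS, dt);
  const double I0a = std::pow(I0, a_nr);

  std::vector<double> u(nch), lpL(nch), lpH(nch), bp(nch), D(nch), S(nch);
  std::vector<int> i0(na), i1(na);
  std::vector<double> f(na);

  const int nsamp = (n_steps + stride - 1) / stride;
  NumericMatrix abs_bp(nsamp, nch), Sout(nsamp, nch);
  int srow = 0;

  for (int t = 0; t < n_steps; ++t) {
    az_index(az, v * t * dt / 1000.0, dpp, W, i0, i1, f);
    for (int k = 0; k < na; ++k) {
      const double w1 = 1.0 - f[k], w2 = f[k];
      for (int r = 0; r < nr; ++r) {
        const double I = prof(r, i0[k]) * w1 + prof(r, i1[k]) * w2;
        const double Ia = std::pow(I, a_nr);
        u[r + nr * k] = Ia / (Ia + I0a);
      }
    }
    if (t == 0) {
      for (int c = 0; c < nch; ++c) {
        lpL[c] = u[c]; lpH[c] = u[c]; bp[c] = 0.0; D[c] = 0.0; S[c] = 0.0;
      }
    } else {
      for (int c = 0; c < nch; ++c) {
        lpL[c] += aL * (u[c] - lpL[c]);
        lpH[c] += aH * (lpL[c] - lpH[c]);
        bp[c] = lpL[c] - lpH[c];
        const double Dprev = D[c];
        D[c] += aLp * (bp[c] - D[c]);
        S[c] += aS * (std::fabs(D[c] - Dprev) / dt - S[c]);
      }
    }
    if (t % stride == 0) {
      for (int c = 0; c < nch; ++c) {
        abs_bp(srow, c) = std::fabs(bp[c]);
        Sout(srow, c) = S[c];
      }
      ++srow;
    }
  }
  return List::create(_["abs_bp"] = abs_bp, _["S"] = Sout);
}

// [[Rcpp::export]]
NumericMatrix cpp_run_engine(NumericMatrix prof, double dpp,
                             NumericVector az, double v, double dt,
                             int n_steps, double I0, double a_nr,
                             double tauL, double tauH, double tauLp,
                             int variant, double a_sat, double eps_gain,
                             double tauA, double minTh, double maxTh,
                             double K, double g, double tauS,
                             List weights, double Ep, double Em,
                             double G0) {
  const int nr = prof.nrow(), W = prof.ncol(), na = az.size();
  const int nch = nr * na;
  const double aL = lp_alpha_c(tauL, dt), aH = lp_alpha_c(tauH, dt);
  const double aLp = lp_alpha_c(tauLp, dt), aS = lp_alpha_c(tauS, dt);
  const double aA = lp_alpha_c(tauA, dt);
  const double I0a = std::pow(I0, a_nr);

  // sparse receptive fields: nonzero site indices and weights
  const int nrf = weights.size();
  std::vector<std::vector<int>> rf_idx(nrf);
  std::vector<std::vector<double>> rf_w(nrf);
  for (int fi = 0; fi < nrf; ++fi) {
    NumericMatrix wm = weights[fi];
    if (wm.nrow() != nr || wm.ncol() != na)
      stop("weight matrix does not match the receptor grid");
    for (int k = 0; k < na; ++k)
      for (int r = 0; r < nr; ++r)
        if (wm(r, k) != 0.0) {
          rf_idx[fi].push_back(r + nr * k);
          rf_w[fi].push_back(wm(r, k));
        }
  }

  std::vector<double> u(nch), lpL(nch), lpH(nch), bp(nch), s(nch),
      D(nch), Dprev(nch), mad(nch), Sd(nch), tauh(nch), lpXp(nch),
      lpXm(nch), Pp(nch), Pm(nch);
  std::vector<int> i0(na), i1(na);
  std::vector<double> f(na);

  NumericMatrix Z(n_steps, nrf);

  for (int t = 0; t < n_steps; ++t) {
    az_index(az, v * t * dt / 1000.0, dpp, W, i0, i1, f);
    for (int k = 0; k < na; ++k) {
      const double w1 = 1.0 - f[k], w2 = f[k];
      for (int r = 0; r < nr; ++r) {
        const double I = prof(r, i0[k]) * w1 + prof(r, i1[k]) * w2;
        const double Ia = std::pow(I, a_nr);
        u[r + nr * k] = Ia / (Ia + I0a);
      }
    }

    if (t == 0) {
      for (int c = 0; c < nch; ++c) {
        lpL[c] = u[c]; lpH[c] = u[c]; bp[c] = 0.0;
      }
    } else {
      for (int c = 0; c < nch; ++c) {
        lpL[c] += aL * (u[c] - lpL[c]);
        lpH[c] += aH * (lpL[c] - lpH[c]);
        bp[c] = lpL[c] - lpH[c];
      }
    }

    // variant-specific input-line transform
    switch (variant) {
    case 2:  // contrast saturation
      for (int c = 0; c < nch; ++c) s[c] = std::tanh(a_sat * bp[c]);
      break;
    case 3:  // input-line gain control
      if (t == 0)
        for (int c = 0; c < nch; ++c) mad[c] = std::fabs(bp[c]);
      else
        for (int c = 0; c < nch; ++c)
          mad[c] += aA * (std::fabs(bp[c]) - mad[c]);
      for (int c = 0; c < nch; ++c) s[c] = bp[c] / (mad[c] + eps_gain);
      break;
    default:
      for (int c = 0; c < nch; ++c) s[c] = bp[c];
    }

    // delay arm, adaptation state
    if (t == 0) {
      for (int c = 0; c < nch; ++c) {
        D[c] = s[c]; Dprev[c] = s[c]; Sd[c] = 0.0; tauh[c] = maxTh;
      }
    } else {
      for (int c = 0; c < nch; ++c) {
        Dprev[c] = D[c];
        D[c] += aLp * (s[c] - D[c]);
      }
    }
    if (variant == 1) {
      if (t > 0)
        for (int c = 0; c < nch; ++c) {
          Sd[c] += aS * (std::fabs(D[c] - Dprev[c]) / dt - Sd[c]);
          // exact integration of d tauh/dt = K(max-tauh) - gS(tauh-min)
          const double B = K + g * Sd[c];
          const double fp = (K * maxTh + g * Sd[c] * minTh) / B;
          double th = fp + (tauh[c] - fp) * std::exp(-B * dt);
          tauh[c] = th < minTh ? minTh : (th > maxTh ? maxTh : th);
        }
      else
        for (int c = 0; c < nch; ++c)
          tauh[c] = maxTh;  // S = 0 at onset: relaxation fixed point
    }

    // correlator: site k pairs receptor columns k and k+1 (ring closure)
    for (int k = 0; k < na; ++k) {
      const int kr = (k + 1) % na;
      for (int r = 0; r < nr; ++r) {
        const int cl = r + nr * k, cr = r + nr * kr;
        double xr = s[cr], xl = s[cl];
        if (variant == 1) {
          if (t == 0) { lpXp[cl] = xr; lpXm[cl] = xl; }
          const double ap = lp_alpha_c(tauh[cl], dt);
          lpXp[cl] += ap * (xr - lpXp[cl]);
          xr -= lpXp[cl];
          const double am = lp_alpha_c(tauh[cr], dt);
          lpXm[cl] += am * (xl - lpXm[cl]);
          xl -= lpXm[cl];
        }
        const double pp = D[cl] * xr, pm = xl * D[cr];
        Pp[cl] = pp > 0 ? pp : 0;
        Pm[cl] = pm > 0 ? pm : 0;
      }
    }

    // gain-control integration per receptive field
    for (int fi = 0; fi < nrf; ++fi) {
      double Sp = 0.0, Sm = 0.0;
      const std::vector<int>& idx = rf_idx[fi];
      const std::vector<double>& w = rf_w[fi];
      for (size_t q = 0; q < idx.size(); ++q) {
        Sp += w[q] * Pp[idx[q]];
        Sm += w[q] * Pm[idx[q]];
      }
      Z(t, fi) = (Sp * Ep - Sm * Em) / (G0 + Sp + Sm);
    }
  }
  return Z;
}
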