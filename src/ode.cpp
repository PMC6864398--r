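// Compiled numerical core: candidate-model ODE right-hand sides, an adaptive
// Dormand-Prince RK45 integrator with exact restarts at pulse edges, the
// Gaussian log-likelihood over population-average ratio curves, and the
// dynamic-time-warping recursions.
//
// Full parameter vector layout (length 39, fixed across topologies; pruned
// entries are held at neutral values by the R layer):
//   0 k1   1 k_1   2 k2   3 k_2   4 k3   5 k_3   6 HSPG_tot 7 FGFR_tot 8 w_FR
//   9..20  cascade (k_act, Km, d) for Ras, Raf, MEK, ERK
//  21 NFB_tot 22 k_nfb 23 d_nfb 24 K_inh 25 h_nfb
//  26 K_hfr 27 h_hfr 28 K_fgfr 29 h_fgfr
//  30 k_f 31 Km_f 32 k_r 33 Km_r 34 rho 35 sigma
//  36 a_pf 37 K_pf 38 h_pf
//
// State vector (length 9): HF, HFR, FR, Ras*, Raf*, MEK*, ERK*, NFB*, EKARp.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int NSTATE = 9;

static inline double hillf(double x, double K, double h) {
  if (x <= 0.0) return 0.0;
  double xh = std::pow(x, h), Kh = std::pow(K, h);
  return xh / (Kh + xh);
}

// Michaelis-Menten activation of a normalized pool with first-order decay.
static inline double mm_tier(double act, double x, double k, double Km, double d) {
  double avail = 1.0 - x;
  if (avail < 0.0) avail = 0.0;
  return k * act * avail / (Km + avail) - d * x;
}

static void rhs(double u, const double* y, double* dy, const double* p,
                int receptor, int feedback, int pf) {
  const double HF = y[0], HFR = y[1], FR = y[2];
  const double Ras = y[3], Raf = y[4], MEK = y[5], ERK = y[6];
  const double NFB = y[7], EK = y[8];
  const bool has_fr = receptor >= 2;

  double HSPG_free = p[6] - HF - HFR; if (HSPG_free < 0.0) HSPG_free = 0.0;
  double FGFR_free = p[7] - HFR - FR; if (FGFR_free < 0.0) FGFR_free = 0.0;

  dy[0] = p[0] * u * HSPG_free - p[1] * HF - p[2] * HF * FGFR_free + p[3] * HFR;
  dy[1] = p[2] * HF * FGFR_free - p[3] * HFR;
  dy[2] = has_fr ? (p[4] * u * FGFR_free - p[5] * FR) : 0.0;

  double S = HFR + (receptor == 3 ? p[8] * FR : 0.0);

  double I_nfb = 1.0;
  if (feedback >= 1 && NFB > 0.0)
    I_nfb = 1.0 / (1.0 + std::pow(NFB / p[24], p[25]));
  double P_pf = 1.0;
  if (pf) P_pf = 1.0 + p[36] * hillf(ERK, p[37], p[38]);

  dy[3] = mm_tier(S, Ras, p[9], p[10], p[11]);
  {
    double avail = 1.0 - Raf; if (avail < 0.0) avail = 0.0;
    dy[4] = p[12] * Ras * I_nfb * P_pf * avail / (p[13] + avail) - p[14] * Raf;
  }
  dy[5] = mm_tier(Raf, MEK, p[15], p[16], p[17]);
  dy[6] = mm_tier(MEK, ERK, p[18], p[19], p[20]);

  if (feedback >= 1) {
    double A;
    if (feedback == 1) {
      A = p[22] * ERK;
    } else {
      A = hillf(HFR, p[26], p[27]);
      if (has_fr) A += hillf(FR, p[28], p[29]);
      A *= p[22];
      if (feedback == 3) A *= ERK;
    }
    double avail = p[21] - NFB; if (avail < 0.0) avail = 0.0;
    dy[7] = A * avail - p[23] * NFB;
  } else {
    dy[7] = 0.0;
  }

  {
    double avail = 1.0 - EK; if (avail < 0.0) avail = 0.0;
    dy[8] = p[30] * ERK * avail / (p[31] + avail) - p[32] * EK / (p[33] + EK);
  }
}

// ---- linear algebra helpers for the Rosenbrock stepper ----

// LU factorization with partial pivoting of an NSTATE x NSTATE matrix.
static bool lu_factor(double* A, int* piv) {
  for (int k = 0; k < NSTATE; ++k) {
    int p = k;
    double amax = std::fabs(A[k * NSTATE + k]);
    for (int i = k + 1; i < NSTATE; ++i) {
      double v = std::fabs(A[i * NSTATE + k]);
      if (v > amax) { amax = v; p = i; }
    }
    if (amax < 1e-300) return false;
    piv[k] = p;
    if (p != k)
      for (int j = 0; j < NSTATE; ++j)
        std::swap(A[k * NSTATE + j], A[p * NSTATE + j]);
    double pivval = A[k * NSTATE + k];
    for (int i = k + 1; i < NSTATE; ++i) {
      double m = A[i * NSTATE + k] / pivval;
      A[i * NSTATE + k] = m;
      for (int j = k + 1; j < NSTATE; ++j)
        A[i * NSTATE + j] -= m * A[k * NSTATE + j];
    }
  }
  return true;
}

static void lu_solve(const double* A, const int* piv, double* b) {
  for (int k = 0; k < NSTATE; ++k) {
    if (piv[k] != k) std::swap(b[k], b[piv[k]]);
    for (int i = k + 1; i < NSTATE; ++i) b[i] -= A[i * NSTATE + k] * b[k];
  }
  for (int i = NSTATE - 1; i >= 0; --i) {
    for (int j = i + 1; j < NSTATE; ++j) b[i] -= A[i * NSTATE + j] * b[j];
    b[i] /= A[i * NSTATE + i];
  }
}

// Dormand-Prince 5(4) coefficients.
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

struct StepCtx {
  const double* p;
  int receptor, feedback, pf;
  double u;
};

// One adaptive segment [t0,t1] under constant input u, integrated with an
// L-stable Rosenbrock 2(3) pair (the ode23s scheme of Shampine & Reichelt)
// and a finite-difference Jacobian: receptor binding under high ligand doses
// makes the system stiff, where explicit Runge-Kutta steps would be
// stability-limited. Returns false on failure (step underflow, NaN, or step
// budget exhausted).
static bool integrate_segment(StepCtx& cx, double t0, double t1, double* y,
                              double rtol, double atol, long max_steps,
                              long* steps_used, double* hguess) {
  if (t1 <= t0) return true;
  const double gam = 1.0 / (2.0 + std::sqrt(2.0));
  const double e32 = 6.0 + std::sqrt(2.0);
  double t = t0;
  double h = *hguess;
  if (h <= 0.0 || h > (t1 - t0)) h = std::min(0.5, t1 - t0);
  double f0[NSTATE], f1[NSTATE], f2[NSTATE], k1[NSTATE], k2[NSTATE],
      k3[NSTATE], ytmp[NSTATE], ynew[NSTATE], J[NSTATE * NSTATE],
      W[NSTATE * NSTATE], yp[NSTATE], fp[NSTATE];
  int piv[NSTATE];
  rhs(cx.u, y, f0, cx.p, cx.receptor, cx.feedback, cx.pf);
  bool have_jac = false;
  int jac_age = 0;
  while (t < t1) {
    if (++(*steps_used) > max_steps) return false;
    if (h > t1 - t) h = t1 - t;
    if (h < 1e-12) return false;

    if (!have_jac || jac_age > 10) {  // forward-difference Jacobian at (t, y)
      for (int j = 0; j < NSTATE; ++j) {
        double dy = 1e-7 * std::max(std::fabs(y[j]), 1e-5);
        for (int i = 0; i < NSTATE; ++i) yp[i] = y[i];
        yp[j] += dy;
        rhs(cx.u, yp, fp, cx.p, cx.receptor, cx.feedback, cx.pf);
        for (int i = 0; i < NSTATE; ++i)
          J[i * NSTATE + j] = (fp[i] - f0[i]) / dy;
      }
      have_jac = true;
      jac_age = 0;
    }
    // W = I - h*gam*J, factorized
    for (int i = 0; i < NSTATE; ++i)
      for (int j = 0; j < NSTATE; ++j)
        W[i * NSTATE + j] = (i == j ? 1.0 : 0.0) - h * gam * J[i * NSTATE + j];
    if (!lu_factor(W, piv)) { h *= 0.5; continue; }

    for (int i = 0; i < NSTATE; ++i) k1[i] = f0[i];
    lu_solve(W, piv, k1);
    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + 0.5 * h * k1[i];
    rhs(cx.u, ytmp, f1, cx.p, cx.receptor, cx.feedback, cx.pf);
    for (int i = 0; i < NSTATE; ++i) k2[i] = f1[i] - k1[i];
    lu_solve(W, piv, k2);
    for (int i = 0; i < NSTATE; ++i) k2[i] += k1[i];
    for (int i = 0; i < NSTATE; ++i) ynew[i] = y[i] + h * k2[i];
    rhs(cx.u, ynew, f2, cx.p, cx.receptor, cx.feedback, cx.pf);
    for (int i = 0; i < NSTATE; ++i)
      k3[i] = f2[i] - e32 * (k2[i] - f1[i]) - 2.0 * (k1[i] - f0[i]);
    lu_solve(W, piv, k3);

    double errnorm = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double e = (h / 6.0) * (k1[i] - 2.0 * k2[i] + k3[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NSTATE);
    if (!std::isfinite(errnorm)) { h *= 0.25; continue; }
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < NSTATE; ++i) {
        y[i] = (ynew[i] < 0.0 && ynew[i] > -1e-9) ? 0.0 : ynew[i];
        if (!std::isfinite(y[i])) return false;
        f0[i] = f2[i];
      }
      ++jac_age;  // keep the (approximate) Jacobian while steps succeed
      double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -1.0 / 3.0) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errnorm, -1.0 / 3.0);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      have_jac = false;  // refresh the Jacobian after a rejection
    }
  }
  *hguess = h;
  return true;
}

// Explicit Dormand-Prince 5(4) segment integrator, kept as an independent
// cross-check of the Rosenbrock path (used by the dual-route tests).
static bool integrate_segment_rk45(StepCtx& cx, double t0, double t1, double* y,
                                   double rtol, double atol, long max_steps,
                                   long* steps_used, double* hguess) {
  if (t1 <= t0) return true;
  double t = t0;
  double h = *hguess;
  if (h <= 0.0 || h > (t1 - t0)) h = t1 - t0;
  double k1[NSTATE], k2[NSTATE], k3[NSTATE], k4[NSTATE], k5[NSTATE],
      k6[NSTATE], k7[NSTATE], ytmp[NSTATE], ynew[NSTATE];
  rhs(cx.u, y, k1, cx.p, cx.receptor, cx.feedback, cx.pf);
  while (t < t1) {
    if (++(*steps_used) > max_steps) return false;
    if (h > t1 - t) h = t1 - t;
    if (h < 1e-12) return false;

    for (int i = 0; i < NSTATE; ++i) ytmp[i] = y[i] + h * A21 * k1[i];
    rhs(cx.u, ytmp, k2, cx.p, cx.receptor, cx.feedback, cx.pf);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (A31 * k1[i] + A32 * k2[i]);
    rhs(cx.u, ytmp, k3, cx.p, cx.receptor, cx.feedback, cx.pf);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (A41 * k1[i] + A42 * k2[i] + A43 * k3[i]);
    rhs(cx.u, ytmp, k4, cx.p, cx.receptor, cx.feedback, cx.pf);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (A51 * k1[i] + A52 * k2[i] + A53 * k3[i] + A54 * k4[i]);
    rhs(cx.u, ytmp, k5, cx.p, cx.receptor, cx.feedback, cx.pf);
    for (int i = 0; i < NSTATE; ++i)
      ytmp[i] = y[i] + h * (A61 * k1[i] + A62 * k2[i] + A63 * k3[i] +
                            A64 * k4[i] + A65 * k5[i]);
    rhs(cx.u, ytmp, k6, cx.p, cx.receptor, cx.feedback, cx.pf);
    for (int i = 0; i < NSTATE; ++i)
      ynew[i] = y[i] + h * (B1 * k1[i] + B3 * k3[i] + B4 * k4[i] +
                            B5 * k5[i] + B6 * k6[i]);
    rhs(cx.u, ynew, k7, cx.p, cx.receptor, cx.feedback, cx.pf);

    double errnorm = 0.0;
    for (int i = 0; i < NSTATE; ++i) {
      double e = h * (E1 * k1[i] + E3 * k3[i] + E4 * k4[i] + E5 * k5[i] +
                      E6 * k6[i] + E7 * k7[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double r = e / sc;
      errnorm += r * r;
    }
    errnorm = std::sqrt(errnorm / NSTATE);
    if (!std::isfinite(errnorm)) {
      h *= 0.25;
      rhs(cx.u, y, k1, cx.p, cx.receptor, cx.feedback, cx.pf);
      continue;
    }
    if (errnorm <= 1.0) {
      t += h;
      for (int i = 0; i < NSTATE; ++i) {
        // clamp tiny negative excursions; true invariants are tested separately
        y[i] = (ynew[i] < 0.0 && ynew[i] > -1e-9) ? 0.0 : ynew[i];
        k1[i] = k7[i];  // FSAL
        if (!std::isfinite(y[i])) return false;
      }
      double fac = errnorm > 0.0 ? 0.9 * std::pow(errnorm, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errnorm, -0.2);
      if (fac < 0.2) fac = 0.2;
      h *= fac;
      rhs(cx.u, y, k1, cx.p, cx.receptor, cx.feedback, cx.pf);
    }
  }
  *hguess = h;
  return true;
}

static double dose_at(const NumericMatrix& episodes, double t) {
  for (int i = 0; i < episodes.nrow(); ++i)
    if (t >= episodes(i, 0) && t < episodes(i, 1)) return episodes(i, 2);
  return 0.0;
}

// Integrate a model over [0, max(tout)] with restarts at episode boundaries;
// fill `states` (length(tout) x 9) at the requested output times.
static int simulate_core(const double* p, int receptor, int feedback, int pf,
                         const NumericMatrix& episodes,
                         const NumericVector& tout, NumericMatrix& states,
                         double rtol, double atol, long max_steps,
                         int use_rk45 = 0) {
  int nt = tout.size();
  // assemble sorted breakpoints: output times plus episode edges
  std::vector<double> brk(tout.begin(), tout.end());
  for (int i = 0; i < episodes.nrow(); ++i) {
    brk.push_back(episodes(i, 0));
    brk.push_back(episodes(i, 1));
  }
  brk.push_back(0.0);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end(),
                        [](double a, double b) { return std::fabs(a - b) < 1e-12; }),
            brk.end());
  double tmax = tout[nt - 1];

  double y[NSTATE];
  for (int i = 0; i < NSTATE; ++i) y[i] = 0.0;
  StepCtx cx;
  cx.p = p; cx.receptor = receptor; cx.feedback = feedback; cx.pf = pf;
  long steps = 0;
  double hguess = 0.0;
  int iout = 0;
  // record any outputs at t == 0 (or before the first breakpoint)
  double tcur = 0.0;
  while (iout < nt && tout[iout] <= tcur + 1e-12) {
    for (int j = 0; j < NSTATE; ++j) states(iout, j) = y[j];
    ++iout;
  }
  for (size_t b = 0; b + 1 < brk.size(); ++b) {
    double ta = brk[b], tb = brk[b + 1];
    if (tb <= tcur + 1e-12) continue;
    if (ta > tmax) break;
    cx.u = dose_at(episodes, 0.5 * (ta + tb));
    bool ok = use_rk45
      ? integrate_segment_rk45(cx, ta, tb, y, rtol, atol, max_steps, &steps,
                               &hguess)
      : integrate_segment(cx, ta, tb, y, rtol, atol, max_steps, &steps,
                          &hguess);
    if (!ok) return 1;
    tcur = tb;
    while (iout < nt && tout[iout] <= tcur + 1e-12) {
      for (int j = 0; j < NSTATE; ++j) states(iout, j) = y[j];
      ++iout;
    }
  }
  return iout == nt ? 0 : 1;
}

// [[Rcpp::export(name = ".simulate_cpp")]]
List simulate_cpp(NumericVector params, int receptor, int feedback, int pf,
                  NumericMatrix episodes, NumericVector tout,
                  double rtol = 1e-6, double atol = 1e-8,
                  double max_steps = 50000, int use_rk45 = 0) {
  if (params.size() != 39) stop("parameter vector must have length 39");
  NumericMatrix states(tout.size(), NSTATE);
  int status = simulate_core(REAL(params), receptor, feedback, pf, episodes,
                             tout, states, rtol, atol, (long)max_steps,
                             use_rk45);
  NumericVector readout(tout.size());
  double rho = params[34];
  for (int i = 0; i < tout.size(); ++i) readout[i] = 1.0 + rho * states(i, 8);
  return List::create(_["states"] = states, _["readout"] = readout,
                      _["status"] = status);
}

// Joint Gaussian log-likelihood over several population-average datasets.
// Each dataset: list(episodes, times, values, weight). Returns -Inf on any
// integration failure.
// [[Rcpp::export(name = ".loglik_cpp")]]
double loglik_cpp(NumericVector params, int receptor, int feedback, int pf,
                  List datasets, double rtol = 1e-6, double atol = 1e-8,
                  double max_steps = 50000) {
  if (params.size() != 39) stop("parameter vector must have length 39");
  double sigma = params[35];
  if (!(sigma > 0.0)) return R_NegInf;
  double rho = params[34];
  double ll = 0.0;
  for (int d = 0; d < datasets.size(); ++d) {
    List ds = datasets[d];
    NumericMatrix episodes = ds["episodes"];
    NumericVector times = ds["times"];
    NumericVector values = ds["values"];
    double w = as<double>(ds["weight"]);
    NumericMatrix states(times.size(), NSTATE);
    int status = simulate_core(REAL(params), receptor, feedback, pf, episodes,
                               times, states, rtol, atol, (long)max_steps);
    if (status != 0) return R_NegInf;
    double ss = 0.0;
    for (int i = 0; i < times.size(); ++i) {
      double r = 1.0 + rho * states(i, 8);
      double res = values[i] - r;
      ss += res * res;
    }
    int n = times.size();
    ll += w * (-0.5 * n * std::log(2.0 * M_PI * sigma * sigma) -
               0.5 * ss / (sigma * sigma));
    if (!std::isfinite(ll)) return R_NegInf;
  }
  return ll;
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(NumericVector params, int receptor, int feedback, int pf,
                      double u, NumericVector state) {
  if (params.size() != 39) stop("parameter vector must have length 39");
  if (state.size() != NSTATE) stop("state vector must have length 9");
  NumericVector dy(NSTATE);
  rhs(u, REAL(state), REAL(dy), REAL(params), receptor, feedback, pf);
  return dy;
}

// Dynamic time warping, absolute-difference local cost, boundary-anchored,
// unconstrained. symmetric2 doubles the local cost on diagonal steps.
// [[Rcpp::export(name = ".dtw_cpp")]]
double dtw_cpp(NumericVector x, NumericVector y, bool symmetric2 = false) {
  int n = x.size(), m = y.size();
  if (n == 0 || m == 0) stop("empty series");
  std::vector<double> prev(m), cur(m);
  const double wdiag = symmetric2 ? 2.0 : 1.0;
  // the (1,1) cell has no incoming step, so its local cost counts once
  // under either pattern
  prev[0] = std::fabs(x[0] - y[0]);
  for (int j = 1; j < m; ++j) prev[j] = prev[j - 1] + std::fabs(x[0] - y[j]);
  for (int i = 1; i < n; ++i) {
    cur[0] = prev[0] + std::fabs(x[i] - y[0]);
    for (int j = 1; j < m; ++j) {
      double d = std::fabs(x[i] - y[j]);
      double best = prev[j - 1] + wdiag * d;                 // diagonal
      double up = prev[j] + d, left = cur[j - 1] + d;
      if (up < best) best = up;
      if (left < best) best = left;
      cur[j] = best;
    }
    std::swap(prev, cur);
  }
  return prev[m - 1];
}

// [[Rcpp::export(name = ".dtw_pairwise_cpp")]]
NumericMatrix dtw_pairwise_cpp(NumericMatrix mat, bool symmetric2 = false) {
  int n = mat.nrow();
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    NumericVector xi = mat(i, _);
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_cpp(xi, mat(j, _), symmetric2);
      out(i, j) = d;
      out(j, i) = d;
    }
  }
  return out;
}
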