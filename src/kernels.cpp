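#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Core integrator for the guided reaction-diffusion system.
//
// State: a (H x N) branching density, c (H x N) connection density on a
// hexagonal lattice with neighbour table nbr (H x 6, 0-based, -1 = outside
// the domain). Static inputs per projection: guidance vector field (gx, gy),
// its lattice divergence divg, and the competition coefficient
// epsN1[i] = eps * m_i / (N - 1).
//
// Flux divergence, five terms:
//   divJ_i = D lap(a_i) - a_i divg_i - g_i . grad(a_i)
//            + epsN1_i a_i lap(ahat_i) + epsN1_i grad(ahat_i) . grad(a_i)
// with ahat_i = sum_{j != i} a_j. Ghost cells: scalar ghost = centre value
// (no-flux), guidance ghost = 0 (fall-off contract).
//
// dc_i/dt = -alpha c_i + beta (1 - sum_j c_j) a_i^k
// da_i/dt = divJ_i - dc_i/dt

static const double COSJ[6] = {1.0, 0.5, -0.5, -1.0, -0.5, 0.5};
static double SINJ[6];
static bool sin_init = false;
static void init_dirs() {
  if (!sin_init) {
    for (int j = 0; j < 6; ++j) SINJ[j] = std::sin(M_PI * j / 3.0);
    sin_init = true;
  }
}

// sign-preserving power: integer k by repeated multiplication
static inline double powk(double x, double k, int ki, bool k_is_int) {
  if (k_is_int) {
    double r = 1.0;
    double b = x;
    int n = ki;
    while (n > 0) {
      if (n & 1) r *= b;
      b *= b;
      n >>= 1;
    }
    return r;
  }
  return std::pow(x, k);
}

struct Work {
  int H, N;
  const int* nbr;           // H x 6, column-major
  double d;
  std::vector<double> Atot, Ctot, lapA, gxA, gyA;
  Work(int H_, int N_, const int* nbr_, double d_)
    : H(H_), N(N_), nbr(nbr_), d(d_),
      Atot(H_), Ctot(H_), lapA(H_), gxA(H_), gyA(H_) {}
};

// lap, gradx, grady of one scalar column f at hex h
static inline void hex_ops(const double* f, const int* nbr, int H, int h,
                           double inv3d2_times2, double inv3d,
                           double& lap, double& gx, double& gy) {
  const double f0 = f[h];
  double s = 0.0, sx = 0.0, sy = 0.0;
  for (int j = 0; j < 6; ++j) {
    const int q = nbr[h + j * H];
    if (q >= 0) {
      const double df = f[q] - f0;
      s += df;
      sx += df * COSJ[j];
      sy += df * SINJ[j];
    }
  }
  lap = inv3d2_times2 * s;
  gx = inv3d * sx;
  gy = inv3d * sy;
}

static void deriv(const double* a, const double* c,
                  const double* gx, const double* gy, const double* divg,
                  const double* epsN1, Work& w,
                  double D, double alpha, double beta, double k,
                  int ki, bool k_is_int,
                  double* da, double* dc) {
  const int H = w.H, N = w.N;
  const int* nbr = w.nbr;
  const double inv3d2_times2 = 2.0 / (3.0 * w.d * w.d);
  const double inv3d = 1.0 / (3.0 * w.d);

  for (int h = 0; h < H; ++h) { w.Atot[h] = 0.0; w.Ctot[h] = 0.0; }
  for (int i = 0; i < N; ++i) {
    const double* ai = a + (size_t)i * H;
    const double* ci = c + (size_t)i * H;
    for (int h = 0; h < H; ++h) { w.Atot[h] += ai[h]; w.Ctot[h] += ci[h]; }
  }
  for (int h = 0; h < H; ++h) {
    hex_ops(w.Atot.data(), nbr, H, h, inv3d2_times2, inv3d,
            w.lapA[h], w.gxA[h], w.gyA[h]);
  }

  for (int i = 0; i < N; ++i) {
    const size_t off = (size_t)i * H;
    const double* ai = a + off;
    const double* ci = c + off;
    const double* gxi = gx + off;
    const double* gyi = gy + off;
    const double* dgi = divg + off;
    double* dai = da + off;
    double* dci = dc + off;
    const double e = epsN1[i];
    for (int h = 0; h < H; ++h) {
      double lap_a, gax, gay;
      hex_ops(ai, nbr, H, h, inv3d2_times2, inv3d, lap_a, gax, gay);
      const double lap_ah = w.lapA[h] - lap_a;
      const double ghx = w.gxA[h] - gax;
      const double ghy = w.gyA[h] - gay;
      const double divJ = D * lap_a
        - ai[h] * dgi[h]
        - (gxi[h] * gax + gyi[h] * gay)
        + e * (ai[h] * lap_ah + ghx * gax + ghy * gay);
      const double dcdt = -alpha * ci[h]
        + beta * (1.0 - w.Ctot[h]) * powk(ai[h], k, ki, k_is_int);
      dci[h] = dcdt;
      dai[h] = divJ - dcdt;
    }
  }
}

// [[Rcpp::export]]
List cpp_run(NumericMatrix a0, NumericMatrix c0,
             NumericMatrix gx, NumericMatrix gy, NumericMatrix divg,
             IntegerMatrix nbr0, double d,
             double D, double alpha, double beta, double k,
             NumericVector epsN1, double dt, int n_steps) {
  init_dirs();
  const int H = a0.nrow(), N = a0.ncol();
  const size_t M = (size_t)H * N;
  Work w(H, N, nbr0.begin(), d);
  const int ki = (int)std::lround(k);
  const bool k_is_int = std::fabs(k - ki) < 1e-12 && ki >= 0 && ki < 64;

  NumericMatrix a(H, N), c(H, N);
  std::copy(a0.begin(), a0.end(), a.begin());
  std::copy(c0.begin(), c0.end(), c.begin());

  std::vector<double> ka(M), kc(M), at(M), ct(M), suma(M), sumc(M);
  bool stable = true;
  int done = 0;

  for (int s = 0; s < n_steps; ++s) {
    // classical RK4 on y' = f(y), y = (a, c)
    deriv(a.begin(), c.begin(), gx.begin(), gy.begin(), divg.begin(),
          epsN1.begin(), w, D, alpha, beta, k, ki, k_is_int,
          ka.data(), kc.data());
    for (size_t m = 0; m < M; ++m) {
      suma[m] = ka[m];
      sumc[m] = kc[m];
      at[m] = a[m] + 0.5 * dt * ka[m];
      ct[m] = c[m] + 0.5 * dt * kc[m];
    }
    deriv(at.data(), ct.data(), gx.begin(), gy.begin(), divg.begin(),
          epsN1.begin(), w, D, alpha, beta, k, ki, k_is_int,
          ka.data(), kc.data());
    for (size_t m = 0; m < M; ++m) {
      suma[m] += 2.0 * ka[m];
      sumc[m] += 2.0 * kc[m];
      at[m] = a[m] + 0.5 * dt * ka[m];
      ct[m] = c[m] + 0.5 * dt * kc[m];
    }
    deriv(at.data(), ct.data(), gx.begin(), gy.begin(), divg.begin(),
          epsN1.begin(), w, D, alpha, beta, k, ki, k_is_int,
          ka.data(), kc.data());
    for (size_t m = 0; m < M; ++m) {
      suma[m] += 2.0 * ka[m];
      sumc[m] += 2.0 * kc[m];
      at[m] = a[m] + dt * ka[m];
      ct[m] = c[m] + dt * kc[m];
    }
    deriv(at.data(), ct.data(), gx.begin(), gy.begin(), divg.begin(),
          epsN1.begin(), w, D, alpha, beta, k, ki, k_is_int,
          ka.data(), kc.data());
    const double w6 = dt / 6.0;
    double amax = 0.0;
    bool finite = true;
    for (size_t m = 0; m < M; ++m) {
      a[m] += w6 * (suma[m] + ka[m]);
      c[m] += w6 * (sumc[m] + kc[m]);
      const double av = std::fabs(a[m]);
      if (av > amax) amax = av;
      if (!std::isfinite(a[m]) || !std::isfinite(c[m])) finite = false;
    }
    done = s + 1;
    if (!finite || amax > 1e6) { stable = false; break; }
    if ((s & 127) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["a"] = a, _["c"] = c,
                      _["stable"] = stable, _["steps_done"] = done);
}

// Derivative evaluation only (exposed for cross-checks against the R
// operator implementations).
// [[Rcpp::export]]
List cpp_deriv(NumericMatrix a, NumericMatrix c,
               NumericMatrix gx, NumericMatrix gy, NumericMatrix divg,
               IntegerMatrix nbr0, double d,
               double D, double alpha, double beta, double k,
               NumericVector epsN1) {
  init_dirs();
  const int H = a.nrow(), N = a.ncol();
  Work w(H, N, nbr0.begin(), d);
  const int ki = (int)std::lround(k);
  const bool k_is_int = std::fabs(k - ki) < 1e-12 && ki >= 0 && ki < 64;
  NumericMatrix da(H, N), dc(H, N);
  deriv(a.begin(), c.begin(), gx.begin(), gy.begin(), divg.begin(),
        epsN1.begin(), w, D, alpha, beta, k, ki, k_is_int,
        da.begin(), dc.begin());
  return List::create(_["da"] = da, _["dc"] = dc);
}

// Gaussian smoothing over an irregular set of hex centres with per-point
// kernel renormalization (no padding beyond the domain). Cutoff at 4 sigma.
// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericMatrix centres, NumericVector rho,
                               double sigma) {
  const int H = centres.nrow();
  NumericVector out(H);
  if (sigma <= 0) { std::copy(rho.begin(), rho.end(), out.begin()); return out; }
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  const double cut2 = 16.0 * sigma * sigma;
  const double* X = &centres(0, 0);
  const double* Y = &centres(0, 1);
  for (int p = 0; p < H; ++p) {
    double num = 0.0, den = 0.0;
    for (int q = 0; q < H; ++q) {
      const double dx = X[p] - X[q], dy = Y[p] - Y[q];
      const double r2 = dx * dx + dy * dy;
      if (r2 <= cut2) {
        const double wgt = std::exp(-r2 * inv2s2);
        num += wgt * rho[q];
        den += wgt;
      }
    }
    out[p] = num / den;
  }
  return out;
}
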