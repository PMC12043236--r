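#include <Rcpp.h>
using namespace Rcpp;

// Epileptor network integrator (explicit Euler / Euler-Maruyama).
//
// State layout: one column per state variable, one row per region.
// Base model: x1, y1, x2, y2, z, g (6 variables).
// Stimulation variant: adds m as a 7th variable; f1 and the Heaviside
// shift in zdot then use the dynamic m instead of the constant parameter.
//
// Coupling is the linear permittivity approximation
//   c_i = K * sum_j W_ij * (x1_j - x1_i)
// entering zdot (scaled by r together with the rest of the slow equation).
//
// Noise: additive Gaussian increments, per-variable amplitude, applied as
// sigma * sqrt(dt) * N(0,1) after the deterministic Euler update. Draws go
// through R's RNG so set.seed() on the R side governs reproducibility.

static inline double f2_of(double x2, double a2) {
  return (x2 < -0.25) ? 0.0 : a2 * (x2 + 0.25);
}

static inline double f3_of(double z) {
  return (z < 0.0) ? -0.1 * std::pow(z, 7.0) : 0.0;
}

// [[Rcpp::export]]
List integrate_epileptor_cpp(NumericMatrix y0,
                             NumericMatrix W,
                             double K,
                             NumericVector x0,
                             NumericVector iext1,
                             NumericVector mthresh,
                             double r, double tau, double iext2,
                             double a, double a2, double b,
                             double c, double d, double m_param,
                             double k_gain, double r2, double n_gain,
                             double dt, int n_steps,
                             NumericVector noise,
                             Nullable<NumericMatrix> istim_,
                             int record_every,
                             bool stim_variant,
                             bool heaviside_ge) {
  const int R = y0.nrow();
  const int nv = y0.ncol();
  if (nv != (stim_variant ? 7 : 6))
    stop("state has %d columns; expected %d for this variant", nv,
         stim_variant ? 7 : 6);
  if (W.nrow() != R || W.ncol() != R) stop("connectome must be R x R");
  if ((int)x0.size() != R) stop("x0 must have length R");
  if ((int)iext1.size() != R) stop("iext1 must have length R");
  if (stim_variant && (int)mthresh.size() != R)
    stop("mthresh must have length R");
  if ((int)noise.size() != nv) stop("noise must have one amplitude per variable");
  if (record_every < 1) stop("record_every must be >= 1");

  bool have_stim = istim_.isNotNull();
  NumericMatrix istim;
  if (have_stim) {
    istim = NumericMatrix(istim_);
    if (istim.nrow() != R || istim.ncol() < n_steps)
      stop("istim must be R x n_steps");
  }

  bool any_noise = false;
  for (int v = 0; v < nv; ++v) if (noise[v] > 0.0) any_noise = true;

  // per-region row sums of W for the coupling difference term
  std::vector<double> wsum(R, 0.0);
  for (int i = 0; i < R; ++i)
    for (int j = 0; j < R; ++j) wsum[i] += W(i, j);

  const int n_rec = n_steps / record_every + 1;
  List out(nv);
  std::vector<NumericMatrix> rec;
  rec.reserve(nv);
  for (int v = 0; v < nv; ++v) rec.push_back(NumericMatrix(R, n_rec));

  std::vector<double> cur((size_t)R * nv), nxt((size_t)R * nv);
  for (int v = 0; v < nv; ++v)
    for (int i = 0; i < R; ++i) cur[(size_t)v * R + i] = y0(i, v);

  double *x1 = &cur[0], *y1 = &cur[(size_t)R], *x2 = &cur[(size_t)2 * R],
         *y2 = &cur[(size_t)3 * R], *z = &cur[(size_t)4 * R],
         *g = &cur[(size_t)5 * R];
  double *m = stim_variant ? &cur[(size_t)6 * R] : nullptr;

  // record initial state
  for (int v = 0; v < nv; ++v)
    for (int i = 0; i < R; ++i) rec[v](i, 0) = cur[(size_t)v * R + i];

  const double sqdt = std::sqrt(dt);
  RNGScope scope;
  int rec_idx = 1;

  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < R; ++i) {
      // coupling on x1, entering zdot
      double acc = 0.0;
      for (int j = 0; j < R; ++j) acc += W(i, j) * x1[j];
      double ci = K * (acc - x1[i] * wsum[i]);

      double Is = have_stim ? istim(i, s) : 0.0;
      double mi = stim_variant ? m[i] : m_param;

      double f1 = (x1[i] < 0.0)
                      ? a * x1[i] * x1[i] * x1[i] - b * x1[i] * x1[i]
                      : -(mi - x2[i] + 0.6 * (z[i] - 4.0) * (z[i] - 4.0)) * x1[i];
      double H = 0.0;
      if (stim_variant) {
        double dm = mi - mthresh[i];
        H = heaviside_ge ? (dm >= 0.0 ? 1.0 : 0.0) : (dm > 0.0 ? 1.0 : 0.0);
      }

      double dx1 = y1[i] - f1 - z[i] + iext1[i] + (stim_variant ? n_gain * Is : 0.0);
      double dy1 = c - d * x1[i] * x1[i] - y1[i];
      double dx2 = -y2[i] + x2[i] - x2[i] * x2[i] * x2[i] + iext2 +
                   0.002 * g[i] - 0.3 * (z[i] - 3.5);
      double dy2 = (-y2[i] + f2_of(x2[i], a2)) / tau;
      double dz = r * (4.0 * (x1[i] - x0[i] - H) - z[i] + f3_of(z[i]) + ci);
      double dg = -0.01 * (g[i] - 0.1 * x1[i]);

      nxt[i] = x1[i] + dt * dx1;
      nxt[(size_t)R + i] = y1[i] + dt * dy1;
      nxt[(size_t)2 * R + i] = x2[i] + dt * dx2;
      nxt[(size_t)3 * R + i] = y2[i] + dt * dy2;
      nxt[(size_t)4 * R + i] = z[i] + dt * dz;
      nxt[(size_t)5 * R + i] = g[i] + dt * dg;
      if (stim_variant) {
        double dm_dt = r2 * (k_gain * std::fabs(Is) - 0.3 * mi);
        nxt[(size_t)6 * R + i] = mi + dt * dm_dt;
      }
    }

    if (any_noise) {
      for (int v = 0; v < nv; ++v) {
        if (noise[v] <= 0.0) continue;
        double amp = noise[v] * sqdt;
        for (int i = 0; i < R; ++i)
          nxt[(size_t)v * R + i] += amp * R::norm_rand();
      }
    }

    std::swap(cur, nxt);
    x1 = &cur[0]; y1 = &cur[(size_t)R]; x2 = &cur[(size_t)2 * R];
    y2 = &cur[(size_t)3 * R]; z = &cur[(size_t)4 * R]; g = &cur[(size_t)5 * R];
    if (stim_variant) m = &cur[(size_t)6 * R];

    if ((s + 1) % record_every == 0) {
      for (int v = 0; v < nv; ++v)
        for (int i = 0; i < R; ++i) rec[v](i, rec_idx) = cur[(size_t)v * R + i];
      ++rec_idx;
    }

    if ((s & 1023) == 0) {
      for (int i = 0; i < R; ++i)
        if (!std::isfinite(x1[i]) || !std::isfinite(z[i]))
          stop("state diverged (non-finite) at step %d", s + 1);
    }
  }
  for (int i = 0; i < R; ++i)
    if (!std::isfinite(x1[i]) || !std::isfinite(z[i]))
      stop("state diverged (non-finite) at step %d", n_steps);

  for (int v = 0; v < nv; ++v) out[v] = rec[v];
  CharacterVector nm = stim_variant
      ? CharacterVector::create("x1", "y1", "x2", "y2", "z", "g", "m")
      : CharacterVector::create("x1", "y1", "x2", "y2", "z", "g");
  out.names() = nm;
  return out;
}
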