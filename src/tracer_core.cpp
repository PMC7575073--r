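#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Finite-volume tracer integration on a masked regular grid.
//
// One substep applies, in order: first-order upwind advection from the
// streamfunction-derived face transports, explicit centered diffusion,
// a constant volumetric source tendency, then point injections integrated
// with the exact exponential relaxation toward the source temperature
// (unconditionally monotone for any dt).
//
// Land cells carry NaN and are never read: land faces have zero transport
// by construction and are guarded here; diffusive conductances across land
// are zero. Domain-edge faces are open for advection (inflow carries the
// ambient boundary value, outflow is zero-gradient) and closed for
// diffusion.
//
// Stability (Courant/diffusion numbers) is enforced by the R caller, which
// chooses dt from the envelope-maximum transports.

// [[Rcpp::export]]
List run_tracer_core(NumericMatrix depth, double dx, double dy,
                     NumericMatrix FxC, NumericMatrix FxS, NumericMatrix FxR,
                     NumericMatrix FyC, NumericMatrix FyS, NumericMatrix FyR,
                     double omega, double sn_omega, double sn_mod,
                     NumericMatrix K, NumericMatrix init,
                     double t0, double dt, int nsub, int nsamples,
                     double bnd_mean, double bnd_amp, double bnd_peak_hour,
                     NumericMatrix source_rate,
                     IntegerVector site_i, IntegerVector site_j,
                     NumericVector site_Q, NumericVector site_T,
                     NumericVector sched_lo, NumericVector sched_hi) {
  const int nx = depth.nrow(), ny = depth.ncol();
  const int nsite = site_i.size();

  std::vector<double> vol(nx * ny), cur(nx * ny), nxt(nx * ny);
  std::vector<char> wet(nx * ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      int c = j * nx + i;
      wet[c] = depth(i, j) > 0.0;
      vol[c] = dx * dy * depth(i, j);
      cur[c] = wet[c] ? init(i, j) : NA_REAL;
    }

  // diffusive conductances on interior faces [m^3/s per unit tracer diff]
  std::vector<double> condx((nx + 1) * ny, 0.0), condy(nx * (ny + 1), 0.0);
  for (int j = 0; j < ny; ++j)
    for (int i = 1; i < nx; ++i)
      if (wet[j * nx + i - 1] && wet[j * nx + i]) {
        double kf = 0.5 * (K(i - 1, j) + K(i, j));
        double hf = std::min(depth(i - 1, j), depth(i, j));
        condx[j * (nx + 1) + i] = kf * hf * dy / dx;
      }
  for (int j = 1; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (wet[(j - 1) * nx + i] && wet[j * nx + i]) {
        double kf = 0.5 * (K(i, j - 1) + K(i, j));
        double hf = std::min(depth(i, j - 1), depth(i, j));
        condy[j * nx + i] = kf * hf * dx / dy;
      }

  NumericVector samples(static_cast<R_xlen_t>(nx) * ny * (nsamples + 1));
  NumericVector stimes(nsamples + 1);
  for (int c = 0; c < nx * ny; ++c) samples[c] = cur[c];
  stimes[0] = t0;

  double t = t0;
  for (int s = 1; s <= nsamples; ++s) {
    for (int sub = 0; sub < nsub; ++sub) {
      const double env = 1.0 + sn_mod * std::cos(sn_omega * t);
      const double cc = env * std::cos(omega * t);
      const double cs = env * std::sin(omega * t);
      const double tday = t / 86400.0;
      double hour = 24.0 * (tday - std::floor(tday));
      const double bval = bnd_mean + bnd_amp *
        std::cos(2.0 * M_PI * (hour - bnd_peak_hour) / 24.0);

      // --- advection (upwind) ---
      for (int c = 0; c < nx * ny; ++c) nxt[c] = cur[c];
      for (int j = 0; j < ny; ++j) {
        for (int i = 0; i <= nx; ++i) {   // x-face between cells i-1 and i
          const double F = FxC(i, j) * cc + FxS(i, j) * cs + FxR(i, j);
          if (F == 0.0) continue;
          const bool hasL = i > 0, hasR = i < nx;
          const int cl = j * nx + i - 1, cr = j * nx + i;
          const bool wl = hasL && wet[cl], wr = hasR && wet[cr];
          if ((hasL && !wl) || (hasR && !wr)) continue;  // land face guard
          double up;
          if (F > 0.0) up = hasL ? cur[cl] : bval;       // from the west
          else         up = hasR ? cur[cr] : bval;       // from the east
          if (wl) nxt[cl] -= dt * F * up / vol[cl];
          if (wr) nxt[cr] += dt * F * up / vol[cr];
        }
      }
      for (int j = 0; j <= ny; ++j) {     // y-face between cells j-1 and j
        for (int i = 0; i < nx; ++i) {
          const double F = FyC(i, j) * cc + FyS(i, j) * cs + FyR(i, j);
          if (F == 0.0) continue;
          const bool hasS = j > 0, hasN = j < ny;
          const int cs_ = (j - 1) * nx + i, cn = j * nx + i;
          const bool ws = hasS && wet[cs_], wn = hasN && wet[cn];
          if ((hasS && !ws) || (hasN && !wn)) continue;
          double up;
          if (F > 0.0) up = hasS ? cur[cs_] : bval;
          else         up = hasN ? cur[cn] : bval;
          if (ws) nxt[cs_] -= dt * F * up / vol[cs_];
          if (wn) nxt[cn] += dt * F * up / vol[cn];
        }
      }
      std::swap(cur, nxt);

      // --- diffusion (explicit centered) ---
      for (int c = 0; c < nx * ny; ++c) nxt[c] = cur[c];
      for (int j = 0; j < ny; ++j)
        for (int i = 1; i < nx; ++i) {
          const double D = condx[j * (nx + 1) + i];
          if (D == 0.0) continue;
          const int cl = j * nx + i - 1, cr = j * nx + i;
          const double flux = dt * D * (cur[cr] - cur[cl]);
          nxt[cl] += flux / vol[cl];
          nxt[cr] -= flux / vol[cr];
        }
      for (int j = 1; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const double D = condy[j * nx + i];
          if (D == 0.0) continue;
          const int cs_ = (j - 1) * nx + i, cn = j * nx + i;
          const double flux = dt * D * (cur[cn] - cur[cs_]);
          nxt[cs_] += flux / vol[cs_];
          nxt[cn] -= flux / vol[cn];
        }
      std::swap(cur, nxt);

      // --- constant source tendency (reef-age accumulation) ---
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const double r = source_rate(i, j);
          if (r != 0.0 && wet[j * nx + i]) cur[j * nx + i] += dt * r;
        }

      // --- point injections: exact relaxation toward source temperature ---
      for (int k = 0; k < nsite; ++k) {
        const bool active = (sched_lo[k] <= 0.0 && sched_hi[k] >= 24.0) ||
          (hour >= sched_lo[k] && hour < sched_hi[k]);
        if (!active || site_Q[k] <= 0.0) continue;
        const int c = site_j[k] * nx + site_i[k];
        const double a = std::exp(-site_Q[k] * dt / vol[c]);
        cur[c] = site_T[k] + (cur[c] - site_T[k]) * a;
      }

      t += dt;
    }
    const R_xlen_t off = static_cast<R_xlen_t>(s) * nx * ny;
    for (int c = 0; c < nx * ny; ++c) samples[off + c] = cur[c];
    stimes[s] = t;
  }

  samples.attr("dim") = IntegerVector::create(nx, ny, nsamples + 1);
  return List::create(_["values"] = samples, _["times"] = stimes);
}
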