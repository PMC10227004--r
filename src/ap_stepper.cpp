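#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Two-variable phenomenological excitable-medium model (Aliev-Panfilov class)
// with isotropic diffusion and no-flux boundaries, integrated by explicit
// forward Euler on a regular grid.
//
// State: u (normalized transmembrane variable, ~[0,1]), v (recovery).
//   du/dt = D lap(u) + [ -k u (u - a)(u - 1) - u v ] / t_scale + I_stim
//   dv/dt = repol_rate [ eps0 + mu1 v / (u + mu2) ] [ -v - k u (u - a - 1) ] / t_scale
//
// t_scale converts the dimensionless model clock to milliseconds; repol_rate
// scales the recovery rate (smaller -> longer action potential). The
// excitation threshold a is supplied per cell so callers can impose smooth
// spatial heterogeneity.
//
// I_stim is a constant source (1/ms units) applied to the cells listed in
// stim_idx (0-based, column-major) while any stimulus pulse is active.
//
// Frames of u are recorded every steps_per_frame steps (frame 0 is the
// initial state). Integration aborts with an R error on non-finite state.

// [[Rcpp::export]]
List ap_integrate(NumericMatrix a_field,
                  double D, double k, double eps0, double mu1, double mu2,
                  double t_scale, double repol_rate,
                  double h, double dt,
                  int n_frames, int steps_per_frame,
                  NumericVector stim_times, double stim_dur,
                  double stim_strength, IntegerVector stim_idx,
                  NumericMatrix u0, NumericMatrix v0) {
  const int nr = a_field.nrow(), nc = a_field.ncol();
  const int n = nr * nc;
  const double rh2 = D / (h * h);

  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> un(n);

  NumericVector frames((R_xlen_t)n * n_frames);
  // frame 0: initial state
  for (int i = 0; i < n; ++i) frames[i] = u[i];

  const int n_stim = stim_times.size();
  int stim_ptr = 0;

  for (int f = 1; f < n_frames; ++f) {
    for (int s = 0; s < steps_per_frame; ++s) {
      const double t = ((double)(f - 1) * steps_per_frame + s) * dt;

      // is a stimulus pulse active at time t?
      while (stim_ptr < n_stim && t >= stim_times[stim_ptr] + stim_dur) ++stim_ptr;
      const bool stim_on = stim_ptr < n_stim &&
        t >= stim_times[stim_ptr] && t < stim_times[stim_ptr] + stim_dur;

      // fused 5-point Laplacian (mirrored no-flux edges) + reaction update
      const double inv_ts = dt / t_scale;
      const double dr = dt * rh2;
      for (int c = 0; c < nc; ++c) {
        const double *uc = &u[(size_t)nr * c];
        const double *ul = &u[(size_t)nr * ((c == 0) ? 1 : c - 1)];
        const double *ur = &u[(size_t)nr * ((c == nc - 1) ? nc - 2 : c + 1)];
        double *unc = &un[(size_t)nr * c];
        double *vc = &v[(size_t)nr * c];
        const double *ac = &a_field[(size_t)nr * c];
        for (int r = 0; r < nr; ++r) {
          const int rl = (r == 0) ? 1 : r - 1;
          const int rr = (r == nr - 1) ? nr - 2 : r + 1;
          const double ui = uc[r], vi = vc[r], ai = ac[r];
          const double lap = uc[rl] + uc[rr] + ul[r] + ur[r] - 4.0 * ui;
          const double fu = -k * ui * (ui - ai) * (ui - 1.0) - ui * vi;
          const double eps = repol_rate * (eps0 + mu1 * vi / std::max(ui + mu2, 0.05));
          const double fv = eps * (-vi - k * ui * (ui - ai - 1.0));
          unc[r] = ui + dr * lap + inv_ts * fu;
          vc[r] = vi + inv_ts * fv;
        }
      }
      if (stim_on) {
        const double add = dt * stim_strength;
        for (int j = 0; j < stim_idx.size(); ++j) un[stim_idx[j]] += add;
      }
      u.swap(un);
    }

    double acc = 0.0;
    R_xlen_t off = (R_xlen_t)n * f;
    for (int i = 0; i < n; ++i) { frames[off + i] = u[i]; acc += u[i]; }
    if (!std::isfinite(acc))
      stop("numerical blow-up: non-finite state at frame %d (try a smaller time step)", f);
    if (f % 50 == 0) Rcpp::checkUserInterrupt();
  }

  frames.attr("dim") = IntegerVector::create(nr, nc, n_frames);
  NumericMatrix uf(nr, nc), vf(nr, nc);
  for (int i = 0; i < n; ++i) { uf[i] = u[i]; vf[i] = v[i]; }
  return List::create(_["frames"] = frames, _["u"] = uf, _["v"] = vf);
}
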