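#include <Rcpp.h>
using namespace Rcpp;

// Mirror v into [0, limit] (closed form, period-2*limit triangle wave).
static inline double fold(double v, double limit) {
  double p = 2.0 * limit;
  double w = v - std::floor(v / p) * p;  // reduce into [0, p)
  return (w > limit) ? p - w : w;
}

// Index of the square containing (x, y), or -1. Squares are closed sets and
// pairwise disjoint up to boundaries; ties resolve to the lowest index.
static inline int synapse_at(double x, double y, const double* cx,
                             const double* cy, const double* h, int ns) {
  for (int s = 0; s < ns; ++s) {
    if (std::fabs(x - cx[s]) <= h[s] && std::fabs(y - cy[s]) <= h[s]) return s;
  }
  return -1;
}

// One full trajectory. Per step, receptors are updated in index order; for
// each receptor the RNG draw order is: binding/unbinding uniform (only when
// the receptor is bound, or free inside a synapse), then the two normal
// displacement deviates, then the crossing uniform (only for a free receptor
// whose proposed move changes synapse membership and is gated by the mode).
// Uses R's RNG so a set.seed() call before entry fixes the trajectory.
// [[Rcpp::export(name = ".engine_run")]]
List engine_run(NumericVector x0, NumericVector y0, IntegerVector boundSyn0,
                NumericVector syn_cx, NumericVector syn_cy,
                NumericVector syn_half, double L, double W, double D_out,
                double D_in, double D_trap, double p_cross, int crossing_mode,
                int bound_edge, double dt, NumericVector p_bind,
                NumericVector p_unbind, IntegerVector sample_steps,
                bool do_occ, int occ_nx, int occ_ny, double occ_bin,
                int occ_from, int occ_to) {
  const int n = x0.size();
  const int ns = syn_cx.size();
  const int n_steps = p_bind.size();
  const int n_samp = sample_steps.size();

  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<int> bsyn(boundSyn0.begin(), boundSyn0.end());  // -1 = free

  const double* cx = syn_cx.begin();
  const double* cy = syn_cy.begin();
  const double* hh = syn_half.begin();

  const double sd_out = std::sqrt(2.0 * D_out * dt);
  const double sd_in = std::sqrt(2.0 * D_in * dt);
  const double sd_trap = std::sqrt(2.0 * D_trap * dt);

  IntegerMatrix bound_counts(n_samp, ns);
  IntegerMatrix total_counts(n_samp, ns);
  IntegerVector extra_counts(n_samp);
  NumericMatrix occ;
  if (do_occ) occ = NumericMatrix(occ_ny, occ_nx);
  long occ_steps = 0;

  int samp_i = 0;
  RNGScope scope;

  // sample index 0 = the initial state, before any step
  auto record = [&](int si) {
    std::vector<int> bc(ns, 0), tc(ns, 0);
    for (int i = 0; i < n; ++i) {
      int s = synapse_at(x[i], y[i], cx, cy, hh, ns);
      if (s >= 0) {
        tc[s]++;
        if (bsyn[i] >= 0) bc[s]++;
      }
    }
    int tot = 0;
    for (int s = 0; s < ns; ++s) {
      bound_counts(si, s) = bc[s];
      total_counts(si, s) = tc[s];
      tot += tc[s];
    }
    extra_counts[si] = n - tot;
  };

  while (samp_i < n_samp && sample_steps[samp_i] == 0) record(samp_i++);

  for (int k = 1; k <= n_steps; ++k) {
    const double pb = p_bind[k - 1];
    const double pu = p_unbind[k - 1];
    for (int i = 0; i < n; ++i) {
      double xi = x[i], yi = y[i];
      int s_here = synapse_at(xi, yi, cx, cy, hh, ns);

      // (1) kinetics, using the start-of-step position
      if (bsyn[i] >= 0) {
        if (unif_rand() < pu) bsyn[i] = -1;
      } else if (s_here >= 0) {
        if (unif_rand() < pb) bsyn[i] = s_here;
      }
      const bool bound = bsyn[i] >= 0;

      // (2) displacement with the state-dependent coefficient
      const double sd = bound ? sd_trap : (s_here >= 0 ? sd_in : sd_out);
      double nx = xi + sd * norm_rand();
      double ny = yi + sd * norm_rand();

      // (3) closed system: mirror at the region contour
      if (nx < 0 || nx > L) nx = fold(nx, L);
      if (ny < 0 || ny > W) ny = fold(ny, W);

      if (bound) {
        // (5) confinement in the PSD
        const int s = bsyn[i];
        if (std::fabs(nx - cx[s]) <= hh[s] && std::fabs(ny - cy[s]) <= hh[s]) {
          x[i] = nx;
          y[i] = ny;
        } else if (bound_edge == 1) {
          x[i] = cx[s] + fold(nx - cx[s] + hh[s], 2.0 * hh[s]) - hh[s];
          y[i] = cy[s] + fold(ny - cy[s] + hh[s], 2.0 * hh[s]) - hh[s];
        }  // else hold the previous position
      } else {
        // (4) border-crossing barrier for free receptors
        const int s_new = synapse_at(nx, ny, cx, cy, hh, ns);
        bool accept = true;
        if (s_new != s_here) {
          bool gated;
          switch (crossing_mode) {
            case 1: gated = s_new >= 0; break;   // entry-only
            case 2: gated = s_here >= 0; break;  // exit-only
            default: gated = true;               // symmetric
          }
          if (gated) accept = unif_rand() < p_cross;
        }
        if (accept) {
          x[i] = nx;
          y[i] = ny;
        }
      }
    }

    if (do_occ && k >= occ_from && k <= occ_to) {
      for (int i = 0; i < n; ++i) {
        int ix = (int)(x[i] / occ_bin);
        int iy = (int)(y[i] / occ_bin);
        if (ix >= occ_nx) ix = occ_nx - 1;
        if (iy >= occ_ny) iy = occ_ny - 1;
        occ(iy, ix) += 1.0;
      }
      ++occ_steps;
    }

    while (samp_i < n_samp && sample_steps[samp_i] == k) record(samp_i++);
  }

  if (do_occ && occ_steps > 0) {
    for (int j = 0; j < occ.size(); ++j) occ[j] /= (double)occ_steps;
  }

  return List::create(
    _["bound"] = bound_counts, _["total"] = total_counts,
    _["extra"] = extra_counts, _["x"] = NumericVector(x.begin(), x.end()),
    _["y"] = NumericVector(y.begin(), y.end()),
    _["bound_synapse"] = IntegerVector(bsyn.begin(), bsyn.end()),
    _["occupancy"] = do_occ ? (SEXP)occ : R_NilValue);
}
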