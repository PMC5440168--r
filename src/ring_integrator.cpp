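#include <Rcpp.h>
using namespace Rcpp;

// Exponential-Euler integrator for the E-PG / P-EN firing-rate loop.
//
// State layout: E has 54 units (27 per bridge side, left block first), the
// P-EN populations have 9 units per side.  W_left / W_right are the 27 x 9
// P-EN -> E-PG weight matrices (excitatory gain and synaptic efficacy already
// folded in); every E-PG receives both.  Each left E-PG i belongs to
// glomerulus i / 3 and excites the left P-EN of that glomerulus with gain
// alpha/3; global inhibition is w_inhib times the summed E-PG activity
// (strong uniform inhibition: w_inhib exceeds the local excitation, so the
// net E-PG -> P-EN weight is negative and the bias keeps P-ENs active).
// The velocity drive enters
// the P-EN equations already rectified and converted to model units
// (drive_plus -> left side, drive_minus -> right side), sampled on the
// recording grid and held constant over the sub-steps in between.
//
// [[Rcpp::export(name = ".ring_integrate")]]
List ring_integrate(NumericMatrix W_left, NumericMatrix W_right,
                    NumericVector E0, NumericVector Pl0, NumericVector Pr0,
                    NumericVector drive_plus, NumericVector drive_minus,
                    int steps_per_sample, int settle_steps,
                    double tau_e, double tau_p,
                    double alpha, double w_inhib, double bias,
                    double dt, double rate_ceiling, bool record_full) {
  const int n_side = W_left.nrow();     // 27
  const int n_pen  = W_left.ncol();     // 9
  const int n_e    = 2 * n_side;        // 54
  const int n_rec  = drive_plus.size();
  const int n_per_glom = n_side / n_pen;

  std::vector<double> E(n_e), Pl(n_pen), Pr(n_pen);
  for (int i = 0; i < n_e; ++i) E[i] = E0[i];
  for (int k = 0; k < n_pen; ++k) { Pl[k] = Pl0[k]; Pr[k] = Pr0[k]; }

  const double dec_e = std::exp(-dt / tau_e);
  const double dec_p = std::exp(-dt / tau_p);
  const double g_e   = 1.0 - dec_e;
  const double g_p   = 1.0 - dec_p;
  const double a3    = alpha / n_per_glom;

  NumericMatrix recE(record_full ? n_rec : 0, record_full ? n_e : 0);
  NumericMatrix recPl(record_full ? n_rec : 0, record_full ? n_pen : 0);
  NumericMatrix recPr(record_full ? n_rec : 0, record_full ? n_pen : 0);
  NumericVector rec_cos(n_rec), rec_sin(n_rec), rec_sum(n_rec);

  // unit angles for the bump readout (both sides tile [0, 2pi))
  std::vector<double> ucos(n_e), usin(n_e);
  for (int i = 0; i < n_e; ++i) {
    double th = 2.0 * M_PI * (i % n_side) / n_side;
    ucos[i] = std::cos(th);
    usin[i] = std::sin(th);
  }

  std::vector<double> inE(n_e), inPl(n_pen), inPr(n_pen);

  long total_steps = (long)settle_steps + (long)n_rec * steps_per_sample;
  int rec_idx = -1;            // recording starts after the settle window
  long step_in_sample = 0;
  double dplus = 0.0, dminus = 0.0;

  for (long s = 0; s < total_steps; ++s) {
    if (s >= settle_steps) {
      if (step_in_sample == 0) {
        ++rec_idx;
        dplus = drive_plus[rec_idx];
        dminus = drive_minus[rec_idx];
      }
    }
    double Esum = 0.0;
    for (int i = 0; i < n_e; ++i) Esum += E[i];
    const double inhib = w_inhib * Esum;

    // every E-PG receives from both P-EN populations (the left population
    // through the +shift kernel, the right through the -shift kernel); the
    // two bridge-side E-PG blocks obey identical equations
    for (int i = 0; i < n_side; ++i) {
      double acc = 0.0;
      for (int k = 0; k < n_pen; ++k)
        acc += W_left(i, k) * Pl[k] + W_right(i, k) * Pr[k];
      inE[i] = acc > 0.0 ? acc : 0.0;
      inE[n_side + i] = inE[i];
    }
    for (int k = 0; k < n_pen; ++k) {
      double exc_l = 0.0, exc_r = 0.0;
      for (int m = 0; m < n_per_glom; ++m) {
        exc_l += E[k * n_per_glom + m];
        exc_r += E[n_side + k * n_per_glom + m];
      }
      double dl = a3 * exc_l - inhib + bias + dplus;
      double dr = a3 * exc_r - inhib + bias + dminus;
      inPl[k] = dl > 0.0 ? dl : 0.0;
      inPr[k] = dr > 0.0 ? dr : 0.0;
    }
    for (int i = 0; i < n_e; ++i) E[i] = E[i] * dec_e + g_e * inE[i];
    for (int k = 0; k < n_pen; ++k) {
      Pl[k] = Pl[k] * dec_p + g_p * inPl[k];
      Pr[k] = Pr[k] * dec_p + g_p * inPr[k];
    }

    if (s >= settle_steps) {
      ++step_in_sample;
      if (step_in_sample == steps_per_sample) {
        step_in_sample = 0;
        // record at the end of each sample interval
        double cs = 0.0, sn = 0.0, sm = 0.0;
        for (int i = 0; i < n_e; ++i) {
          cs += E[i] * ucos[i];
          sn += E[i] * usin[i];
          sm += E[i];
        }
        rec_cos[rec_idx] = cs;
        rec_sin[rec_idx] = sn;
        rec_sum[rec_idx] = sm;
        if (record_full) {
          for (int i = 0; i < n_e; ++i) recE(rec_idx, i) = E[i];
          for (int k = 0; k < n_pen; ++k) {
            recPl(rec_idx, k) = Pl[k];
            recPr(rec_idx, k) = Pr[k];
          }
        }
        if (!(rec_sum[rec_idx] < rate_ceiling * n_e) ||
            ISNAN(rec_sum[rec_idx])) {
          stop("firing rates diverged (ceiling %g reached) at sample %d; "
               "check alpha/beta/dt", rate_ceiling, rec_idx + 1);
        }
      }
    }
  }

  return List::create(_["E"] = recE, _["P_left"] = recPl, _["P_right"] = recPr,
                      _["bump_cos"] = rec_cos, _["bump_sin"] = rec_sin,
                      _["rate_sum"] = rec_sum);
}
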