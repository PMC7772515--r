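#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire with Dirac-delta synaptic input.
//
// Between events the membrane relaxes exponentially towards v_rest; each
// event adds its weight instantaneously.  A spike is emitted on V > theta
// (strict), after which V -> v_reset and a `refractory` ms lockout starts.
// Jumps arriving during the lockout are still applied to the membrane; the
// threshold is re-examined when the lockout expires, because the membrane
// can still sit above theta at that instant.

// [[Rcpp::export]]
NumericVector lif_event_cpp(NumericVector times, NumericVector weights,
                            double v_rest, double v_reset, double theta,
                            double tau, double refractory, double duration) {
  const R_xlen_t n = times.size();
  if (weights.size() != n)
    stop("times and weights must have equal length");
  std::vector<double> spikes;
  double v = v_rest;
  double t_prev = 0.0;
  double last_spike = R_NegInf;

  for (R_xlen_t k = 0; k < n; ++k) {
    double t = times[k];
    // threshold re-check at refractory expiry instants that precede t
    while (R_FINITE(last_spike)) {
      double expiry = last_spike + refractory;
      if (!(expiry > t_prev && expiry < t)) break;
      double v_e = v_rest + (v - v_rest) * std::exp(-(expiry - t_prev) / tau);
      t_prev = expiry;
      v = v_e;
      if (v_e > theta) {
        spikes.push_back(expiry);
        v = v_reset;
        last_spike = expiry;
      } else {
        break;  // membrane only decays further until the next event
      }
    }
    v = v_rest + (v - v_rest) * std::exp(-(t - t_prev) / tau);
    v += weights[k];
    t_prev = t;
    if (v > theta && (t - last_spike) >= refractory) {
      spikes.push_back(t);
      v = v_reset;
      last_spike = t;
    }
  }
  // trailing refractory expiry before the end of the record
  while (R_FINITE(last_spike)) {
    double expiry = last_spike + refractory;
    if (!(expiry > t_prev && expiry < duration)) break;
    double v_e = v_rest + (v - v_rest) * std::exp(-(expiry - t_prev) / tau);
    t_prev = expiry;
    v = v_e;
    if (v_e > theta) {
      spikes.push_back(expiry);
      v = v_reset;
      last_spike = expiry;
    } else {
      break;
    }
  }
  return wrap(spikes);
}

// Fixed-step grid integrator used as an independent cross-check.  The
// membrane is advanced on a regular dt grid with the exact per-step decay
// factor; an event in (t_end - dt, t_end] is applied at the grid point
// t_end and the threshold is examined at every grid point.  Spike times
// are grid times, so agreement with the event-driven path is expected to
// within one step (and is exact when event times lie on the grid).

// [[Rcpp::export]]
NumericVector lif_grid_cpp(NumericVector times, NumericVector weights,
                           double v_rest, double v_reset, double theta,
                           double tau, double refractory, double duration,
                           double dt) {
  const R_xlen_t n = times.size();
  if (weights.size() != n)
    stop("times and weights must have equal length");
  const double decay = std::exp(-dt / tau);
  const R_xlen_t nstep = (R_xlen_t) std::ceil(duration / dt);
  std::vector<double> spikes;
  double v = v_rest;
  double last_spike = R_NegInf;
  R_xlen_t k = 0;  // next unapplied event

  for (R_xlen_t s = 1; s <= nstep; ++s) {
    double t_end = s * dt;
    v = v_rest + (v - v_rest) * decay;
    while (k < n && times[k] <= t_end) {
      v += weights[k];
      ++k;
    }
    if (v > theta && (t_end - last_spike) >= refractory - 1e-9) {
      spikes.push_back(t_end);
      v = v_reset;
      last_spike = t_end;
    }
  }
  return wrap(spikes);
}
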