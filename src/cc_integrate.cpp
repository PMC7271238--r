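#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of the single-compartment membrane equation
//   C dV/dt = -G_leak (V - E_leak) - G_pic m(V)(V - E_pic) + I_inj + noise
// with an integrate-and-fire spike mechanism: on V >= V_T (outside the
// refractory period, with spike availability >= avail_min) the sample is set
// to the stylized spike peak, the next sample is reset to V_reset and held
// there for t_ref, and the availability is multiplied by (1 - avail_use).
// Availability recovers towards 1 with time constant tau_avail. Units:
// ms, mV, pA, nS, pF.
//
// [[Rcpp::export(name = ".cc_integrate")]]
List cc_integrate(NumericVector I, NumericVector noise, double dt,
                  double C, double G_leak, double E_leak,
                  double G_pic, double V_half, double k_act, double E_pic,
                  double V_T, double V_reset, double t_ref, double ap_peak,
                  double avail_use, double avail_min, double tau_avail,
                  double V0) {
  const R_xlen_t n = I.size();
  if (noise.size() != n) stop("noise and command must have equal length");
  NumericVector V(n);
  std::vector<int> spikes;
  double v = V0;
  double avail = 1.0;
  double refr_left = 0.0;               // ms of refractory hold remaining
  const bool deplete = avail_use > 0.0;

  for (R_xlen_t i = 0; i < n; ++i) {
    if (refr_left > 0.0) {
      v = V_reset;
      V[i] = v;
      refr_left -= dt;
    } else {
      double m = 1.0 / (1.0 + std::exp((V_half - v) / k_act));
      double ipic = G_pic * m * (v - E_pic);
      double dv = (-(G_leak) * (v - E_leak) - ipic + I[i] + noise[i]) * dt / C;
      v += dv;
      if (!std::isfinite(v))
        stop("simulation error: non-finite membrane voltage at step %d (t = %.3f ms)",
             (int)(i + 1), (double)i * dt);
      if (v >= V_T && (!deplete || avail >= avail_min)) {
        spikes.push_back((int)(i + 1));   // 1-based sample index
        V[i] = ap_peak;
        v = V_reset;
        refr_left = t_ref;
        if (deplete) avail *= (1.0 - avail_use);
      } else {
        V[i] = v;
      }
    }
    if (deplete) avail += dt * (1.0 - avail) / tau_avail;
  }
  return List::create(_["V"] = V, _["spike_idx"] = wrap(spikes));
}
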