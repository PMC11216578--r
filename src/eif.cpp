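#include <Rcpp.h>
using namespace Rcpp;

// Exponential integrate-and-fire membrane with one non-inactivating,
// Boltzmann-gated K+ conductance (the dendrotoxin-sensitive component).
//
// Units: V mV, t ms, C pF, g nS, I pA.  dV/dt then comes out in mV/ms.
// The exponential spike-initiation drive is capped at `upstroke_cap_pa`
// so the upstroke has a finite, conductance-sensitive peak dV/dt.
// The K+ gate relaxes towards its Boltzmann steady state with time
// constant `kv_tau_ms`; because its half-activation sits above threshold,
// activation builds up only when the cell fires, producing a brake that
// grows with firing rate (hypoexcitability at large current injections)
// while leaving passive properties and rheobase untouched.
// Spikes are stylised: once V crosses v_peak the trace descends linearly
// to an after-hyperpolarisation level over `down_ms`, then the
// subthreshold dynamics resume.
//
// [[Rcpp::export]]
List eif_integrate(NumericVector current_pa, double dt_ms,
                   double c_pf, double gl_ns, double el_mv,
                   double vt_mv, double deltat_mv,
                   double v_peak_mv, double v_reset_mv, double ahp_mv,
                   double down_ms, double refr_ms,
                   double gkv_ns, double vh_mv, double k_mv, double ek_mv,
                   double kv_tau_ms, double upstroke_cap_pa,
                   double noise_sd_mv, double v0_mv) {
  int n = current_pa.size();
  NumericVector v(n);
  std::vector<double> spikes;
  double vm = v0_mv;
  double nk = 1.0 / (1.0 + std::exp(-(vm - vh_mv) / k_mv));
  int down_steps = std::max(1, (int)std::round(down_ms / dt_ms));
  int refr_steps = (int)std::round(refr_ms / dt_ms);
  int phase = 0;          // >0: remaining forced-downstroke steps
  int refr = 0;           // remaining absolute-refractory steps
  double down_slope = (v_peak_mv - (v_reset_mv - ahp_mv)) / down_steps;
  double sq_dt = std::sqrt(dt_ms);

  for (int i = 0; i < n; i++) {
    double nss = 1.0 / (1.0 + std::exp(-(vm - vh_mv) / k_mv));
    nk += (nss - nk) * dt_ms / kv_tau_ms;
    if (phase > 0) {
      vm -= down_slope;
      phase--;
      if (phase == 0) vm = v_reset_mv - ahp_mv;
    } else {
      double drive = gl_ns * deltat_mv *
        std::exp((vm - vt_mv) / deltat_mv);
      if (drive > upstroke_cap_pa) drive = upstroke_cap_pa;
      double dv = (-gl_ns * (vm - el_mv) + drive
                   - gkv_ns * nk * (vm - ek_mv)
                   + current_pa[i]) / c_pf;
      vm += dv * dt_ms;
      if (noise_sd_mv > 0) vm += R::rnorm(0.0, noise_sd_mv) * sq_dt;
      if (refr > 0) refr--;
      if (vm >= v_peak_mv && refr == 0) {
        vm = v_peak_mv;
        spikes.push_back(i * dt_ms);
        phase = down_steps;
        refr = refr_steps;
      }
    }
    v[i] = vm;
  }
  return List::create(_["v_mv"] = v, _["spike_ms"] = wrap(spikes));
}
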