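#include <Rcpp.h>
using namespace Rcpp;

// Minimal four-variable ventricular action potential model
// (Bueno-Orovio, Cherry & Fenton 2008), epicardial parameter set,
// integrated with fixed-step forward Euler. The three currents are
// fast inward (J_fi), slow outward (J_so) and slow inward (J_si).
// Conductance surrogates:
//   g_kr scales the supra-threshold (phase 2-3) component of J_so,
//   g_to scales the sub-threshold outward component of J_so,
//   g_cal scales J_si.

static inline double H(double x) { return x >= 0.0 ? 1.0 : 0.0; }

// [[Rcpp::export]]
List bocf_pace_cpp(double g_to, double g_kr, double g_cal,
                   double cl_ms, int n_beats, double dt,
                   double out_rate_hz,
                   double stim_amp = 0.5, double stim_dur = 1.0) {
  // epicardial parameters
  const double u_o = 0.0, u_u = 1.55, th_v = 0.3, th_w = 0.13;
  const double th_vm = 0.006, th_o = 0.006;
  const double tau_v1m = 60.0, tau_v2m = 1150.0, tau_vp = 1.4506;
  const double tau_w1m = 60.0, tau_w2m = 15.0, k_wm = 65.0, u_wm = 0.03;
  const double tau_wp = 200.0;
  const double tau_fi = 0.11, tau_o1 = 400.0, tau_o2 = 6.0;
  const double tau_so1 = 30.0181, tau_so2 = 0.9957, k_so = 2.0458, u_so = 0.65;
  const double tau_s1 = 2.7342, tau_s2 = 16.0, k_s = 2.0994, u_s = 0.9087;
  const double tau_si = 1.8875, tau_winf = 0.07, w_infs = 0.94;

  double u = 0.0, v = 1.0, w = 1.0, s = 0.0;

  const double total_ms = cl_ms * n_beats;
  const int n_steps = (int)std::round(total_ms / dt);
  const double out_dt = 1000.0 / out_rate_hz;
  const int n_out = (int)std::floor(total_ms / out_dt) + 1;
  NumericVector t_out(n_out), u_out(n_out);
  int k_out = 0;
  double next_out = 0.0;

  for (int i = 0; i <= n_steps; ++i) {
    double t = i * dt;
    if (k_out < n_out && t >= next_out - 1e-9) {
      t_out[k_out] = t;
      u_out[k_out] = u;
      ++k_out;
      next_out += out_dt;
    }
    // stimulus: at the start of each cycle
    double phase = t - cl_ms * std::floor(t / cl_ms);
    double J_stim = (phase < stim_dur) ? stim_amp : 0.0;

    double Huv = H(u - th_v), Huw = H(u - th_w), Huo = H(u - th_o);
    double tau_vm = (1.0 - H(u - th_vm)) * tau_v1m + H(u - th_vm) * tau_v2m;
    double tau_wm = tau_w1m + (tau_w2m - tau_w1m) *
                    (1.0 + std::tanh(k_wm * (u - u_wm))) / 2.0;
    double tau_so = tau_so1 + (tau_so2 - tau_so1) *
                    (1.0 + std::tanh(k_so * (u - u_so))) / 2.0;
    double tau_s  = (1.0 - Huw) * tau_s1 + Huw * tau_s2;
    double tau_o  = (1.0 - Huo) * tau_o1 + Huo * tau_o2;
    double v_inf  = (u < th_vm) ? 1.0 : 0.0;
    double w_inf  = (1.0 - Huo) * (1.0 - u / tau_winf) + Huo * w_infs;

    double J_fi = -v * Huv * (u - th_v) * (u_u - u) / tau_fi;
    double J_so = g_to * (u - u_o) * (1.0 - Huw) / tau_o + g_kr * Huw / tau_so;
    double J_si = -g_cal * Huw * w * s / tau_si;

    double du = -(J_fi + J_so + J_si) + J_stim;
    double dv = (1.0 - Huv) * (v_inf - v) / tau_vm - Huv * v / tau_vp;
    double dw = (1.0 - Huw) * (w_inf - w) / tau_wm - Huw * w / tau_wp;
    double ds = ((1.0 + std::tanh(k_s * (u - u_s))) / 2.0 - s) / tau_s;

    u += dt * du; v += dt * dv; w += dt * dw; s += dt * ds;
    if (!std::isfinite(u)) {
      stop("ionic model integration diverged at t = %f ms (u non-finite); "
           "reduce dt or check conductance scales", t);
    }
  }
  return List::create(_["time_ms"] = t_out[Range(0, k_out - 1)],
                      _["u"] = u_out[Range(0, k_out - 1)]);
}
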