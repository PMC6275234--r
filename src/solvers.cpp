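#include <Rcpp.h>
#include "solvers.h"

using namespace Rcpp;

// Single-neuron grid simulation under one solver configuration.
// Grid-point threshold variants report the spike at the grid entry time t;
// precise-threshold variants detect within (t, t+1] and emit at t+1.
// [[Rcpp::export]]
List cpp_simulate_neuron(double a, double b, double c, double d, double theta,
                         double I, int duration_ms, double v0, double u0,
                         int variant, int substeps, bool precise,
                         bool fxp, bool prescaled) {
  SolverCfg cfg; cfg.variant = variant; cfg.substeps = substeps;
  cfg.precise = precise; cfg.fxp = fxp; cfg.prescaled = prescaled;
  int T = duration_ms;
  NumericVector vv(T + 1), uu(T + 1);
  std::vector<int> spikes;
  long long wraps = 0;

  if (!fxp) {
    double v = v0, u = u0;
    vv[0] = v; uu[0] = u;
    for (int t = 0; t < T; t++) {
      bool sp = step_float(v, u, I, a, b, c, d, theta, cfg);
      if (sp) spikes.push_back((variant != 0 && precise) ? t + 1 : t);
      vv[t + 1] = v; uu[t + 1] = u;
    }
  } else {
    FxpConsts K = make_fxp_consts(a, b, c, d, theta, substeps, prescaled);
    long long dummy = 0;
    int64_t v = q_encode1(v0, 15, false, &dummy);
    int64_t u = q_encode1(u0, 15, false, &dummy);
    int64_t Iraw = q_encode1(I, 15, false, &dummy);
    vv[0] = (double)v / 32768.0; uu[0] = (double)u / 32768.0;
    for (int t = 0; t < T; t++) {
      bool sp = step_fxp(v, u, Iraw, K, cfg, &wraps);
      if (sp) spikes.push_back(precise ? t + 1 : t);
      vv[t + 1] = (double)v / 32768.0; uu[t + 1] = (double)u / 32768.0;
    }
  }
  return List::create(_["v"] = vv, _["u"] = uu,
                      _["spike_times"] = wrap(spikes),
                      _["wraps"] = (double)wraps);
}
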