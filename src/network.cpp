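// Grid-based (1 ms) simulation loop for the polychronization network:
// delayed spike delivery through a ring buffer, per-step single-neuron
// random stimulus, and the additive STDP rule with weight changes buffered
// and applied in batches of one biological second.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include "solvers.h"

using namespace Rcpp;

// targets/delays/weights: n x K matrices, row = source neuron (0-based ids).
// stim: one 0-based neuron index per ms (-1 = none), receiving i_ext.
// STDP is only supported in float64 arithmetic (fxp replay runs have it off).
// snapshot_ms must be sorted; snapshots are taken after any coincident batch
// weight update. Spikes are recorded at the grid step in which the solver
// reports them; a spike from source j reaches target k exactly D_jk steps
// later.
// [[Rcpp::export]]
List cpp_run_network(IntegerMatrix targets, IntegerMatrix delays,
                     NumericMatrix weights, int n_exc,
                     NumericVector a, NumericVector b,
                     NumericVector c, NumericVector d, double theta,
                     IntegerVector stim, double i_ext, int duration_ms,
                     int variant, int substeps, bool precise,
                     bool fxp, bool prescaled,
                     bool stdp, double a_plus, double a_minus,
                     double tau_plus, double tau_minus,
                     int batch_ms, double w_min, double w_max,
                     IntegerVector snapshot_ms,
                     NumericVector v0, NumericVector u0) {
  const int n = targets.nrow(), K = targets.ncol();
  const int depth = 32;            // > max conduction delay (20 ms)
  SolverCfg cfg; cfg.variant = variant; cfg.substeps = substeps;
  cfg.precise = precise; cfg.fxp = fxp; cfg.prescaled = prescaled;
  long long wraps = 0, dummy = 0;

  if (stdp && fxp)
    stop("STDP is not supported in fixed-point arithmetic");

  // flat synapse index s = src * K + k
  std::vector<double> w(n * K);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < K; k++) w[i * K + k] = weights(i, k);

  std::vector<std::vector<int> > ring(depth), incoming(n);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < K; k++)
      incoming[targets(i, k)].push_back(i * K + k);

  std::vector<double> cur(n, 0.0), dw(n * K, 0.0);
  std::vector<int> last_post(n, -1), last_arr(n * K, -1);

  std::vector<double> vf(n), uf(n);
  std::vector<int64_t> vq(n), uq(n), wq(n * K), curq(n, 0);
  std::vector<FxpConsts> Kq;
  int64_t i_ext_q = 0;
  if (!fxp) {
    for (int i = 0; i < n; i++) { vf[i] = v0[i]; uf[i] = u0[i]; }
  } else {
    Kq.reserve(n);
    for (int i = 0; i < n; i++) {
      vq[i] = q_encode1(v0[i], 15, false, &dummy);
      uq[i] = q_encode1(u0[i], 15, false, &dummy);
      Kq.push_back(make_fxp_consts(a[i], b[i], c[i], d[i], theta,
                                   substeps, prescaled));
    }
    for (size_t s = 0; s < w.size(); s++)
      wq[s] = q_encode1(w[s], 15, false, &dummy);
    i_ext_q = q_encode1(i_ext, 15, false, &dummy);
  }

  std::vector<int> spike_t, spike_id, fired;
  List snapshots(snapshot_ms.size());
  int next_snap = 0;
  while (next_snap < snapshot_ms.size() && snapshot_ms[next_snap] == 0) {
    NumericMatrix W0(n, K);
    for (int i = 0; i < n; i++)
      for (int k = 0; k < K; k++) W0(i, k) = w[i * K + k];
    snapshots[next_snap++] = W0;
  }

  for (int t = 0; t < duration_ms; t++) {
    // 1. deliver in-flight spikes; STDP depression at arrival time
    int slot = t % depth;
    std::vector<int>& arr = ring[slot];
    for (size_t q = 0; q < arr.size(); q++) {
      int s = arr[q];
      int tgt = targets(s / K, s % K);
      if (!fxp) cur[tgt] += w[s];
      else      curq[tgt] = wrap32(curq[tgt] + wq[s], &wraps);
      if (stdp) {
        if (last_post[tgt] >= 0)
          dw[s] -= a_minus * std::exp((double)(last_post[tgt] - t) / tau_minus);
        last_arr[s] = t;
      }
    }
    arr.clear();

    // 2. external stimulus into one randomly selected neuron
    if (stim[t] >= 0) {
      if (!fxp) cur[stim[t]] += i_ext;
      else      curq[stim[t]] = wrap32(curq[stim[t]] + i_ext_q, &wraps);
    }

    // 3. advance every neuron one grid step
    fired.clear();
    for (int i = 0; i < n; i++) {
      bool sp;
      if (!fxp)
        sp = step_float(vf[i], uf[i], cur[i], a[i], b[i], c[i], d[i],
                        theta, cfg);
      else
        sp = step_fxp(vq[i], uq[i], curq[i], Kq[i], cfg, &wraps);
      if (sp) fired.push_back(i);
      if (!fxp) cur[i] = 0.0; else curq[i] = 0;
    }

    // 4. record spikes, enqueue deliveries, STDP potentiation
    for (size_t q = 0; q < fired.size(); q++) {
      int i = fired[q];
      spike_t.push_back(t);
      spike_id.push_back(i);
      if (stdp) {
        const std::vector<int>& inc = incoming[i];
        for (size_t m = 0; m < inc.size(); m++) {
          int s = inc[m];
          if (last_arr[s] >= 0)
            dw[s] += a_plus * std::exp(-(double)(t - last_arr[s]) / tau_plus);
        }
        last_post[i] = t;
      }
      for (int k = 0; k < K; k++)
        ring[(t + delays(i, k)) % depth].push_back(i * K + k);
    }

    // 5. batched weight update (plastic = excitatory sources only)
    if (stdp && (t + 1) % batch_ms == 0) {
      for (int i = 0; i < n_exc; i++)
        for (int k = 0; k < K; k++) {
          int s = i * K + k;
          double nw = w[s] + dw[s];
          if (nw < w_min) nw = w_min;
          if (nw > w_max) nw = w_max;
          w[s] = nw;
          dw[s] = 0.0;
        }
    }
    while (next_snap < snapshot_ms.size() && snapshot_ms[next_snap] == t + 1) {
      NumericMatrix Wt(n, K);
      for (int i = 0; i < n; i++)
        for (int k = 0; k < K; k++) Wt(i, k) = w[i * K + k];
      snapshots[next_snap++] = Wt;
    }
  }

  NumericVector vfin(n), ufin(n);
  for (int i = 0; i < n; i++) {
    vfin[i] = fxp ? (double)vq[i] / 32768.0 : vf[i];
    ufin[i] = fxp ? (double)uq[i] / 32768.0 : uf[i];
  }
  NumericMatrix Wfin(n, K);
  for (int i = 0; i < n; i++)
    for (int k = 0; k < K; k++)
      Wfin(i, k) = fxp ? (double)wq[i * K + k] / 32768.0 : w[i * K + k];
  return List::create(_["spike_times"] = wrap(spike_t),
                      _["spike_ids"] = wrap(spike_id),
                      _["snapshots"] = snapshots,
                      _["weights"] = Wfin,
                      _["wraps"] = (double)wraps,
                      _["v"] = vfin, _["u"] = ufin);
}
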