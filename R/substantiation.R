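#' Full substantiation experiment at reduced scale
#'
#' Runs the complete model-comparison pipeline in one call: the default
#' 1000-neuron network is evolved with STDP under the float64
#' sixteen-substep solver for `duration_s` biological seconds, the final
#' weight matrix is frozen, and the frozen state is replayed for
#' `replay_s` seconds under two executable models -- the float64 pipeline
#' and the s16.15 fixed-point pipeline (pre-scaled quadratic coefficient,
#' precise threshold detection). The two spike recordings are then
#' compared measure by measure (FR, LV, CC) with Cohen's d.
#'
#' The default 600 s STDP phase is the package's scaled-down stand-in for
#' multi-hour network maturation; see the methods vignette for the
#' reasoning and for what this does and does not show.
#'
#' @param seed integer seed for topology and stimulus.
#' @param duration_s STDP phase length (s).
#' @param replay_s replay length (s); must not exceed `duration_s` or the
#'   recorded stimulus window (60 s).
#' @param snapshot_s when to freeze the weights (default: end of the run).
#' @return list with the [compare_spike_data()] `report`, both replays
#'   (`replay_float`, `replay_fxp`), the `states` object and the wrap
#'   count of the fixed-point replay.
#' @export
substantiation_run <- function(seed = 1L, duration_s = 600, replay_s = 60,
                               snapshot_s = duration_s) {
  stopifnot(replay_s <= 60, replay_s <= duration_s)
  states <- run_with_stdp(seed = seed, duration_s = duration_s,
                          snapshot_s = snapshot_s)
  Wi <- states$snapshots[[length(states$snapshots)]]
  top <- states$topology
  stim <- states$stimulus_60s
  rf <- replay_frozen(top, Wi, stim, duration_s = replay_s,
                      spec = solver_spec("euler16"))
  rq <- run_network(top, Wi, stim[seq_len(replay_s * 1000)],
                    as.integer(replay_s * 1000),
                    spec = solver_spec("euler16_fxp"))
  list(report = compare_spike_data(rf, rq$spikes),
       replay_float = rf, replay_fxp = rq$spikes,
       fxp_wraps = rq$wraps, states = states)
}
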