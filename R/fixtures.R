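#' Down-scaled 20-neuron test network
#'
#' The small functional-testing version of the polychronization network:
#' 16 excitatory and 4 inhibitory neurons with out-degree 5, built with the
#' same weight and delay rules as the full model. Small enough for manual
#' inspection, large enough to spike and to have a non-trivial connectivity
#' matrix. Regenerating with the same seed is bit-identical.
#'
#' @param seed integer seed.
#' @return A list of class `fixture_bundle` with `topology`, `weights`, a
#'   60 s `stimulus` series, the `seed` and a `name`.
#' @export
make_test_network <- function(seed = 42L) {
  topology <- build_topology(n_exc = 16, n_inh = 4, out_degree = 5,
                             seed = seed)
  structure(list(name = "test_network_20",
                 topology = topology,
                 weights = init_weights(topology),
                 stimulus = build_stimulus(topology$n, 60000L,
                                           seed = seed + 1L),
                 seed = as.integer(seed)),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("fixture_bundle '%s' (seed %d): %d neurons, %d synapses\n",
              x$name, x$seed, x$topology$n,
              x$topology$n * x$topology$out_degree))
  invisible(x)
}

#' Synthetic spike trains with known statistics
#'
#' `make_poisson_trains()` draws independent homogeneous Poisson trains
#' (expected LV of 1, expected pairwise correlation of 0);
#' `make_regular_trains()` builds constant-ISI trains (LV of 0, rate
#' `1/period`). Both are oracle inputs for the spike-train statistics.
#'
#' @param n number of trains.
#' @param rate Poisson rate (Hz).
#' @param duration duration (ms).
#' @param seed integer seed.
#' @param period regular inter-spike interval (ms).
#' @param phase offset of the first spike (ms).
#' @return A [spike_data()].
#' @export
make_poisson_trains <- function(n, rate, duration, seed = 1L) {
  stopifnot(rate > 0, duration > 0)
  trains <- with_seed(seed, lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, rate * duration / 1000)
    sort(stats::runif(k, 0, duration))
  }))
  spike_data(trains, duration, resolution = 0)
}

#' @rdname make_poisson_trains
#' @export
make_regular_trains <- function(n, period, duration, phase = 0) {
  stopifnot(period > 0, duration > 0)
  k <- floor((duration - phase) / period)
  if (phase + k * period >= duration) k <- k - 1
  tr <- phase + period * (0:k)
  spike_data(rep(list(tr), n), duration, resolution = 0)
}

#' Strong-drive overflow scenario
#'
#' A single-neuron drive profile under which the three-substep s16.15
#' solver without precise threshold detection lets the membrane potential
#' run far above threshold within a grid step, so that squaring it
#' overflows the fixed-point word (wrap events > 0, visible as spike
#' artifacts), while the sixteen-substep solver with precise threshold
#' detection keeps `v` within limits (0 wrap events). A float64 run of the
#' same profile cannot wrap by construction.
#'
#' @return list with the drive current `I` (pA), `duration` (ms) and the
#'   neuron `params`.
#' @export
make_overflow_scenario <- function() {
  list(I = 1000, duration = 100L, params = izh_params("rs"))
}

#' Run the overflow scenario under a given solver
#'
#' @param spec a [solver_spec()].
#' @param scenario a [make_overflow_scenario()] list.
#' @return The number of fixed-point wrap events recorded during the run.
#' @export
overflow_wrap_count <- function(spec, scenario = make_overflow_scenario()) {
  tr <- simulate_neuron(spec, scenario$params, I = scenario$I,
                        duration = scenario$duration)
  tr$wraps
}
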