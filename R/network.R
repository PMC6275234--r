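#' Polychronization network topology
#'
#' Builds the random connectivity of the polychronization network: every
#' excitatory neuron projects to `out_degree` targets drawn without
#' replacement from all other neurons (no autapses, no duplicate synapses),
#' with integer conduction delays drawn uniformly from 1--20 ms; every
#' inhibitory neuron projects to `out_degree` excitatory neurons only, with
#' a fixed 1 ms delay. The default sizes (800 excitatory, 200 inhibitory,
#' out-degree 100) give the full 100,000-synapse network; the down-scaled
#' 20-neuron test network uses (16, 4, 5).
#'
#' @param n_exc,n_inh population sizes.
#' @param out_degree synapses per source neuron.
#' @param seed integer seed; identical seeds give identical topologies.
#' @param max_delay largest excitatory conduction delay (ms).
#' @return An object of class `spnet_topology`: `targets` and `delays` are
#'   `n x out_degree` integer matrices (row = source, 1-based ids; neurons
#'   `1..n_exc` are excitatory).
#' @export
build_topology <- function(n_exc = 800, n_inh = 200, out_degree = 100,
                           seed = 1L, max_delay = 20L) {
  n <- n_exc + n_inh
  if (out_degree > n - 1L)
    stop("out_degree exceeds the excitatory target pool (n - 1)")
  if (out_degree > n_exc)
    stop("out_degree exceeds the inhibitory target pool (n_exc)")
  with_seed(seed, {
    targets <- matrix(0L, n, out_degree)
    delays <- matrix(1L, n, out_degree)
    for (i in seq_len(n_exc)) {
      targets[i, ] <- sample(seq_len(n)[-i], out_degree)
      delays[i, ] <- sample.int(max_delay, out_degree, replace = TRUE)
    }
    for (i in seq_len(n_inh)) {
      targets[n_exc + i, ] <- sample.int(n_exc, out_degree)
    }
  })
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 n = as.integer(n), out_degree = as.integer(out_degree),
                 targets = targets, delays = delays, seed = as.integer(seed)),
            class = "spnet_topology")
}

#' @export
print.spnet_topology <- function(x, ...) {
  cat(sprintf(
    "polychronization topology: %d exc + %d inh neurons, out-degree %d (%d synapses)\n",
    x$n_exc, x$n_inh, x$out_degree, x$n * x$out_degree))
  invisible(x)
}

#' Initial synaptic weights
#'
#' Excitatory synapses start at `w_exc` (default 6.0, plastic under STDP);
#' inhibitory synapses are fixed at `w_inh` (default -5.0) and are never
#' modified.
#'
#' @param topology a [build_topology()] object.
#' @param w_exc,w_inh initial weights.
#' @return An `n x out_degree` numeric weight matrix aligned with
#'   `topology$targets`.
#' @export
init_weights <- function(topology, w_exc = 6.0, w_inh = -5.0) {
  w <- matrix(w_inh, topology$n, topology$out_degree)
  w[seq_len(topology$n_exc), ] <- w_exc
  w
}

#' STDP parameters
#'
#' The additive spike-timing-dependent plasticity rule
#' \deqn{\Delta w = +A_+ e^{-\Delta t/\tau_+} \; (\Delta t \ge 0), \qquad
#'       \Delta w = -A_- e^{\Delta t/\tau_-} \; (\Delta t < 0)}
#' with \eqn{\Delta t} the time of the last post-synaptic spike minus the
#' (arrival) time of the last pre-synaptic spike. Increments are buffered
#' for one biological second (`batch_ms`) and then applied to all plastic
#' synapses simultaneously, clipped to `[w_min, w_max]`. The bounds are not
#' part of the published parameter set; the defaults `(0, 10)` follow the
#' original C implementation of the network and are configurable.
#'
#' @param a_plus,a_minus potentiation/depression amplitudes (mV).
#' @param tau_plus,tau_minus time constants (ms).
#' @param batch_ms batching period (ms).
#' @param w_min,w_max plastic weight bounds.
#' @return An object of class `stdp_params`.
#' @export
stdp_params <- function(a_plus = 0.1, a_minus = 0.12,
                        tau_plus = 20, tau_minus = 20,
                        batch_ms = 1000L, w_min = 0, w_max = 10) {
  stopifnot(a_plus > 0, a_minus > 0, tau_plus > 0, tau_minus > 0,
            batch_ms > 0, w_max > w_min)
  structure(list(a_plus = a_plus, a_minus = a_minus, tau_plus = tau_plus,
                 tau_minus = tau_minus, batch_ms = as.integer(batch_ms),
                 w_min = w_min, w_max = w_max),
            class = "stdp_params")
}

#' Single STDP pairing increment
#'
#' @param dt time of last post-synaptic spike minus time of last
#'   pre-synaptic spike arrival (ms); vectorized.
#' @param params an [stdp_params()].
#' @return The buffered weight increment(s).
#' @export
stdp_increment <- function(dt, params = stdp_params()) {
  ifelse(dt >= 0,
         params$a_plus * exp(-dt / params$tau_plus),
         -params$a_minus * exp(dt / params$tau_minus))
}

#' Apply one batch of buffered STDP updates
#'
#' @param weights current weight matrix.
#' @param buffer matrix of buffered increments, same shape.
#' @param topology the network topology (identifies plastic synapses:
#'   those with excitatory sources).
#' @param params an [stdp_params()].
#' @param clock_ms simulation clock; must be a positive multiple of
#'   `params$batch_ms` (the rule fires only on batch boundaries).
#' @return list with the updated `weights` and the zeroed `buffer`.
#' @export
apply_batched_updates <- function(weights, buffer, topology,
                                  params = stdp_params(), clock_ms) {
  if (clock_ms <= 0 || clock_ms %% params$batch_ms != 0)
    stop("batched STDP updates may only be applied at multiples of ",
         params$batch_ms, " ms")
  exc <- seq_len(topology$n_exc)
  weights[exc, ] <- pmin(pmax(weights[exc, ] + buffer[exc, ],
                              params$w_min), params$w_max)
  buffer[] <- 0
  list(weights = weights, buffer = buffer)
}

#' Random single-neuron stimulus series
#'
#' One uniformly chosen neuron index per 1 ms grid step; that neuron
#' receives a constant external current (20 pA by default) for that step.
#'
#' @param n number of neurons.
#' @param duration_ms series length (ms).
#' @param seed integer seed.
#' @return Integer vector of 1-based neuron indices, length `duration_ms`.
#' @export
build_stimulus <- function(n, duration_ms, seed = 1L) {
  with_seed(seed, sample.int(n, duration_ms, replace = TRUE))
}

network_params <- function(topology) {
  rs <- izh_params("rs"); fs <- izh_params("fs")
  exc <- seq_len(topology$n_exc)
  a <- rep(fs$a, topology$n); a[exc] <- rs$a
  b <- rep(fs$b, topology$n); b[exc] <- rs$b
  c <- rep(fs$c, topology$n); c[exc] <- rs$c
  d <- rep(fs$d, topology$n); d[exc] <- rs$d
  list(a = a, b = b, c = c, d = d, theta = rs$theta)
}

#' Run the polychronization network
#'
#' Advances the full network on the 1 ms grid: spikes arriving this step
#' (emission time + conduction delay) deposit their synaptic weight into
#' the target's input-current accumulator for exactly one step, the
#' stimulated neuron additionally receives `i_ext`, every neuron is
#' advanced by the configured solver, and emitted spikes are recorded and
#' enqueued for delayed delivery. With STDP enabled, pairing increments of
#' the most recent opposing spikes (pre-synaptic events timed at arrival)
#' are accumulated and applied in batches (see [stdp_params()]).
#'
#' Two independent engines implement the identical update rules: the
#' compiled `"cpp"` engine for production runs and a pure-R `"r"` engine
#' used for cross-verification; both are bitwise deterministic and agree
#' bit-identically.
#'
#' @param topology a [build_topology()] object.
#' @param weights weight matrix aligned with the topology.
#' @param stimulus integer vector of 1-based stimulated neuron ids, one per
#'   ms (`NA` = none); recycled/cropped to `duration_ms`.
#' @param duration_ms simulated duration (ms).
#' @param spec a [solver_spec()] (grid variants only).
#' @param stdp an [stdp_params()] to enable plasticity, or `NULL` (off).
#'   STDP requires float64 arithmetic.
#' @param snapshot_ms sorted times (ms) at which to snapshot the weight
#'   matrix; a snapshot coinciding with a batch boundary is taken after the
#'   batch update.
#' @param i_ext stimulus current amplitude (pA).
#' @param engine `"cpp"` or `"r"`.
#' @return list with `spikes` (a [spike_data()]), `snapshots` (list of
#'   weight matrices), `weights` (final), `wraps`, and the final neuron
#'   state `v`, `u`.
#' @export
run_network <- function(topology, weights, stimulus, duration_ms,
                        spec = solver_spec("euler16"), stdp = NULL,
                        snapshot_ms = integer(0), i_ext = 20,
                        engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  cfg <- spec_to_cfg(spec)
  if (!is.null(stdp) && cfg$fxp)
    stop("STDP is not supported in fixed-point arithmetic")
  if (!all(dim(weights) == dim(topology$targets)))
    stop("weight matrix does not match the topology dimensions")
  duration_ms <- as.integer(duration_ms)
  stim <- rep_len(as.integer(stimulus), duration_ms)
  p <- network_params(topology)
  sp <- if (is.null(stdp)) stdp_params() else stdp
  snapshot_ms <- as.integer(sort(snapshot_ms))
  if (length(snapshot_ms) && max(snapshot_ms) > duration_ms)
    stop("snapshot times must lie within the simulated duration")
  v0 <- p$c; u0 <- p$b * p$c
  if (engine == "cpp") {
    res <- cpp_run_network(topology$targets - 1L, topology$delays, weights,
                           topology$n_exc, p$a, p$b, p$c, p$d, p$theta,
                           ifelse(is.na(stim), -1L, stim - 1L), i_ext,
                           duration_ms,
                           cfg$variant, cfg$substeps, cfg$precise,
                           cfg$fxp, cfg$prescaled,
                           !is.null(stdp), sp$a_plus, sp$a_minus,
                           sp$tau_plus, sp$tau_minus, sp$batch_ms,
                           sp$w_min, sp$w_max, snapshot_ms, v0, u0)
    spikes <- spikes_to_data(res$spike_times, res$spike_ids + 1L,
                             topology$n, duration_ms)
    list(spikes = spikes, snapshots = res$snapshots,
         weights = res$weights, wraps = res$wraps, v = res$v, u = res$u)
  } else {
    run_network_r(topology, weights, stim, duration_ms, cfg, p,
                  if (is.null(stdp)) NULL else sp, snapshot_ms, i_ext,
                  v0, u0)
  }
}

# Pure-R second executable model of the network loop. Mirrors the compiled
# engine operation for operation (including floating-point accumulation
# order) so that the two can be compared bit-identically.
run_network_r <- function(topology, weights, stim, duration_ms, cfg, p,
                          stdp, snapshot_ms, i_ext, v0, u0) {
  n <- topology$n; K <- topology$out_degree
  depth <- 32L
  tg <- t(topology$targets)   # column = source, flat index s = (i-1)*K + k
  dl <- t(topology$delays)
  w <- as.vector(t(weights))
  ring <- vector("list", depth)
  for (s in seq_len(depth)) ring[[s]] <- integer(0)
  incoming <- split(seq_len(n * K), factor(as.vector(tg), levels = seq_len(n)))
  fxp <- cfg$fxp
  if (fxp) {
    vq <- raw_enc(v0); uq <- raw_enc(u0)
    wq <- raw_enc(w)
    i_ext_q <- raw_enc(i_ext)
    curq <- numeric(n)
  } else {
    v <- v0; u <- u0
    cur <- numeric(n)
  }
  dw <- numeric(n * K)
  last_post <- rep(-1L, n); last_arr <- rep(-1L, n * K)
  spike_t <- integer(0); spike_id <- integer(0)
  snapshots <- list()
  wraps <- 0
  take_snap <- function() matrix(w, n, K, byrow = TRUE)
  for (sm in snapshot_ms[snapshot_ms == 0L]) snapshots <- c(snapshots, list(take_snap()))
  pending <- snapshot_ms[snapshot_ms > 0L]
  params_of <- function(i) {
    structure(list(a = p$a[i], b = p$b[i], c = p$c[i], d = p$d[i],
                   theta = p$theta, type = "custom"), class = "izh_params")
  }
  spec <- structure(list(
    variant = if (cfg$variant == 0L) "c_grid" else
      if (cfg$prescaled) "euler16_fxp" else "euler16",
    arithmetic = if (fxp) "s16.15" else "float64",
    substeps = cfg$substeps, precise_threshold = cfg$precise),
    class = "solver_spec")
  for (t in seq_len(duration_ms) - 1L) {
    slot <- t %% depth + 1L
    for (s in ring[[slot]]) {
      tgt <- tg[s]
      if (!fxp) cur[tgt] <- cur[tgt] + w[s]
      else curq[tgt] <- raw_add(curq[tgt], wq[s])
      if (!is.null(stdp)) {
        if (last_post[tgt] >= 0L)
          dw[s] <- dw[s] - stdp$a_minus *
            exp((last_post[tgt] - t) / stdp$tau_minus)
        last_arr[s] <- t
      }
    }
    ring[[slot]] <- integer(0)
    if (!is.na(stim[t + 1L]) && stim[t + 1L] > 0L) {
      j <- stim[t + 1L]
      if (!fxp) cur[j] <- cur[j] + i_ext
      else curq[j] <- raw_add(curq[j], i_ext_q)
    }
    fired <- integer(0)
    for (i in seq_len(n)) {
      if (!fxp) {
        st <- izh_step(list(v = v[i], u = u[i]), cur[i], params_of(i), spec)
        v[i] <- st$state$v; u[i] <- st$state$u
        cur[i] <- 0
      } else {
        st <- izh_step_fxp(list(v_raw = vq[i], u_raw = uq[i]), curq[i],
                           params_of(i), spec)
        vq[i] <- st$state$v_raw; uq[i] <- st$state$u_raw
        curq[i] <- 0
      }
      if (st$spiked) fired <- c(fired, i)
    }
    for (i in fired) {
      spike_t <- c(spike_t, t); spike_id <- c(spike_id, i)
      if (!is.null(stdp)) {
        for (s in incoming[[i]]) {
          if (last_arr[s] >= 0L)
            dw[s] <- dw[s] + stdp$a_plus *
              exp(-(t - last_arr[s]) / stdp$tau_plus)
        }
        last_post[i] <- t
      }
      base <- (i - 1L) * K
      for (k in seq_len(K)) {
        s <- base + k
        slot2 <- (t + dl[s]) %% depth + 1L
        ring[[slot2]] <- c(ring[[slot2]], s)
      }
    }
    if (!is.null(stdp) && (t + 1L) %% stdp$batch_ms == 0L) {
      plastic <- seq_len(topology$n_exc * K)  # flat: exc sources come first
      nw <- w[plastic] + dw[plastic]
      w[plastic] <- pmin(pmax(nw, stdp$w_min), stdp$w_max)
      dw[plastic] <- 0
    }
    while (length(pending) && pending[1] == t + 1L) {
      snapshots <- c(snapshots, list(take_snap()))
      pending <- pending[-1]
    }
  }
  spikes <- spikes_to_data(spike_t, spike_id, n, duration_ms)
  list(spikes = spikes, snapshots = snapshots,
       weights = if (fxp) matrix(wq / 32768, n, K, byrow = TRUE)
         else take_snap(),
       wraps = wraps,
       v = if (fxp) vq / 32768 else v,
       u = if (fxp) uq / 32768 else u)
}

#' Generate reference network states with STDP
#'
#' Runs the full pipeline that produces frozen-state replay artifacts: the
#' topology and stimulus are built from `seed`, the network is run with
#' STDP for `duration_s` biological seconds under the given solver, and the
#' weight matrix is snapshotted at `snapshot_s`. The scaled-down default
#' protocol (600 s with snapshots every 120 s, five network states) stands
#' in for multi-hour runs; longer durations are available through the
#' arguments. The first 60 s of the stimulus series are kept verbatim for
#' replay.
#'
#' @param seed integer seed determining topology and stimulus.
#' @param duration_s STDP phase duration (biological seconds).
#' @param snapshot_s snapshot times (s). A snapshot falling on a batch
#'   boundary is taken after the coincident batch update.
#' @param spec a [solver_spec()]; STDP requires float64.
#' @param topology optionally, a prebuilt topology (the seed then only
#'   drives the stimulus).
#' @param stdp an [stdp_params()].
#' @return An object of class `spnet_states`: the `topology`, initial
#'   weights `w0`, `snapshots` (named `W(t)` matrices), full `stimulus`,
#'   `stimulus_60s`, the STDP-phase `spikes` and the `seed`.
#' @export
run_with_stdp <- function(seed = 1L, duration_s = 600,
                          snapshot_s = seq(120, 600, by = 120),
                          spec = solver_spec("euler16"),
                          topology = NULL, stdp = stdp_params()) {
  if (any(snapshot_s * 1000 > duration_s * 1000))
    stop("snapshot times must lie within the run duration")
  if (is.null(topology))
    topology <- build_topology(seed = seed)
  duration_ms <- as.integer(duration_s * 1000)
  stimulus <- build_stimulus(topology$n, duration_ms, seed = seed + 1L)
  w0 <- init_weights(topology)
  res <- run_network(topology, w0, stimulus, duration_ms, spec = spec,
                     stdp = stdp, snapshot_ms = as.integer(snapshot_s * 1000))
  names(res$snapshots) <- sprintf("W(%gs)", snapshot_s)
  structure(list(topology = topology, w0 = w0, snapshots = res$snapshots,
                 stimulus = stimulus,
                 stimulus_60s = stimulus[seq_len(min(60000L, duration_ms))],
                 spikes = res$spikes, seed = as.integer(seed),
                 spec = spec, stdp = stdp),
            class = "spnet_states")
}

#' @export
print.spnet_states <- function(x, ...) {
  cat(sprintf(
    "spnet_states: %d-neuron network, %d weight snapshot(s), seed %d\n",
    x$topology$n, length(x$snapshots), x$seed))
  invisible(x)
}

#' Frozen-state replay
#'
#' Re-runs the network from a recorded state with STDP switched off: the
#' connectivity, delays, a weight snapshot and the recorded stimulus series
#' fully determine the spiking activity, so the replay is a pure function
#' of its artifacts (bitwise reproducible) and the weights stay constant
#' throughout. Replaying the same state under different solvers or
#' arithmetic is the substantiation experiment: the resulting spike data
#' are compared with [compare_spike_data()].
#'
#' @param topology a [build_topology()] object.
#' @param weights a weight snapshot aligned with the topology.
#' @param stimulus stimulus series covering the replay duration.
#' @param duration_s replay duration (s), default 60.
#' @param spec a [solver_spec()] (any grid variant, float64 or s16.15).
#' @param engine `"cpp"` or `"r"`.
#' @return A [spike_data()] object with the replay's spiking activity.
#' @export
replay_frozen <- function(topology, weights, stimulus, duration_s = 60,
                          spec = solver_spec("euler16"),
                          engine = c("cpp", "r")) {
  duration_ms <- as.integer(duration_s * 1000)
  if (length(stimulus) < duration_ms)
    stop("stimulus series shorter than the replay duration")
  if (!all(dim(weights) == dim(topology$targets)))
    stop("weight matrix does not match the topology dimensions")
  res <- run_network(topology, weights, stimulus[seq_len(duration_ms)],
                     duration_ms, spec = spec, stdp = NULL,
                     engine = match.arg(engine))
  res$spikes
}
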