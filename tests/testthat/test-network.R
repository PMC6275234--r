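test_that("topology construction obeys the wiring rules", {
  top <- build_topology(n_exc = 800, n_inh = 200, out_degree = 100, seed = 7)
  expect_equal(top$n * top$out_degree, 100000)
  exc <- seq_len(800)
  # no autapses, no duplicate synapses
  for (i in c(1, 400, 800, 801, 1000)) {
    expect_false(i %in% top$targets[i, ])
    expect_equal(anyDuplicated(top$targets[i, ]), 0)
  }
  # inhibitory neurons target the excitatory population only, delay 1 ms
  expect_true(all(top$targets[801:1000, ] <= 800))
  expect_true(all(top$delays[801:1000, ] == 1L))
  # excitatory delays uniform over 1..20 ms
  expect_setequal(unique(as.vector(top$delays[exc, ])), 1:20)
  expect_true(all(top$delays[exc, ] >= 1 & top$delays[exc, ] <= 20))
  # determinism
  top2 <- build_topology(n_exc = 800, n_inh = 200, out_degree = 100, seed = 7)
  expect_identical(top$targets, top2$targets)
  expect_identical(top$delays, top2$delays)
  expect_error(build_topology(n_exc = 4, n_inh = 2, out_degree = 10),
               "out_degree")
})

test_that("initial weights are 6.0 excitatory / -5.0 inhibitory", {
  top <- build_topology(n_exc = 16, n_inh = 4, out_degree = 5, seed = 1)
  w <- init_weights(top)
  expect_true(all(w[1:16, ] == 6))
  expect_true(all(w[17:20, ] == -5))
  full <- build_topology(seed = 1)
  expect_equal(sum(init_weights(full)), 800 * 100 * 6 + 200 * 100 * -5)
})

test_that("the STDP window follows the additive exponential rule", {
  expect_identical(stdp_increment(0), 0.1)
  expect_equal(stdp_increment(20), 0.1 * exp(-1))
  expect_equal(stdp_increment(-20), -0.12 * exp(-1))
  # antisymmetric window shape around zero with the two amplitudes
  dt <- seq(-100, 100, by = 0.5)
  inc <- stdp_increment(dt)
  expect_true(all(inc[dt >= 0] > 0))
  expect_true(all(inc[dt < 0] < 0))
})

test_that("batched updates clip, zero the buffer, and respect the schedule", {
  top <- build_topology(n_exc = 16, n_inh = 4, out_degree = 5, seed = 1)
  w <- init_weights(top)
  buf <- matrix(0, top$n, top$out_degree)
  out <- apply_batched_updates(w, buf, top, clock_ms = 1000)
  expect_identical(out$weights, w)
  buf[1, 1] <- 0.1
  out <- apply_batched_updates(w, buf, top, clock_ms = 1000)
  expect_equal(out$weights[1, 1], 6.1)
  expect_true(all(out$buffer == 0))
  buf[1, 1] <- 100
  out <- apply_batched_updates(w, buf, top, clock_ms = 2000)
  expect_equal(out$weights[1, 1], 10)           # clipped to w_max
  buf[17, 1] <- 100                             # inhibitory: untouched
  out <- apply_batched_updates(w, buf, top, clock_ms = 1000)
  expect_equal(out$weights[17, 1], -5)
  expect_error(apply_batched_updates(w, buf, top, clock_ms = 1500),
               "multiples")
})

test_that("spikes are delivered once, to every target, after their delay", {
  # two neurons: 1 -> 2 with a 15 ms delay and a huge weight; drive neuron 1
  # over threshold with the stimulus and watch the arrival at neuron 2
  top <- structure(list(n_exc = 2L, n_inh = 0L, n = 2L, out_degree = 1L,
                        targets = matrix(c(2L, 1L), 2, 1),
                        delays = matrix(c(15L, 1L), 2, 1),
                        seed = 0L),
                   class = "spnet_topology")
  w <- matrix(c(200, 0), 2, 1)
  stim <- rep(NA_integer_, 40)
  stim[1:6] <- 1L                    # 20 pA into neuron 1 until it fires
  res <- run_network(top, w, stim, 40, spec = solver_spec("euler16"),
                     i_ext = 20, engine = "r")
  t1 <- res$spikes$trains[[1]][1]
  expect_false(is.na(t1))
  # neuron 2 receives w = 200 exactly at t1 + 15 (and at no earlier step)
  # and the delta-like current drives it over threshold that same step
  t2 <- res$spikes$trains[[2]][1]
  expect_identical(t2, t1 + 15)
})

test_that("both engines produce bit-identical runs on the 20-neuron fixture", {
  fx <- make_test_network(42)
  args <- list(fx$topology, fx$weights, fx$stimulus, 1000L,
               spec = solver_spec("euler16"), stdp = stdp_params(),
               snapshot_ms = c(0L, 1000L))
  a <- do.call(run_network, c(args, engine = "cpp"))
  b <- do.call(run_network, c(args, engine = "r"))
  expect_gt(sum(lengths(a$spikes$trains)), 0)
  expect_identical(a$spikes$trains, b$spikes$trains)
  expect_identical(a$weights, b$weights)
  expect_identical(a$snapshots[[1]], b$snapshots[[1]])
  expect_identical(a$snapshots[[2]], b$snapshots[[2]])
  # and for the fixed-point pipeline (STDP off)
  af <- run_network(fx$topology, fx$weights, fx$stimulus, 500L,
                    spec = solver_spec("euler16_fxp"), engine = "cpp")
  bf <- run_network(fx$topology, fx$weights, fx$stimulus, 500L,
                    spec = solver_spec("euler16_fxp"), engine = "r")
  expect_identical(af$spikes$trains, bf$spikes$trains)
})

test_that("run_with_stdp snapshots behave at the boundaries", {
  fx <- make_test_network(7)
  st <- run_with_stdp(seed = 7, duration_s = 3, snapshot_s = c(0, 1, 2, 3),
                      topology = fx$topology)
  expect_identical(st$snapshots[[1]], st$w0)
  expect_length(st$snapshots, 4)
  # plastic weights stay inside the bounds after every batch
  for (W in st$snapshots) {
    expect_true(all(W[1:16, ] >= 0 & W[1:16, ] <= 10))
    expect_true(all(W[17:20, ] == -5))
  }
  # with no STDP the weights never move
  frozen <- run_network(fx$topology, fx$weights, fx$stimulus, 2000L,
                        stdp = NULL, snapshot_ms = c(1000L, 2000L))
  expect_identical(frozen$snapshots[[1]], fx$weights)
  expect_identical(frozen$snapshots[[2]], fx$weights)
})

test_that("frozen-state replay is pure and weight-stationary", {
  fx <- make_test_network(9)
  st <- run_with_stdp(seed = 9, duration_s = 2, snapshot_s = 2,
                      topology = fx$topology)
  Wi <- st$snapshots[[1]]
  r1 <- replay_frozen(fx$topology, Wi, st$stimulus_60s, duration_s = 2)
  r2 <- replay_frozen(fx$topology, Wi, st$stimulus_60s, duration_s = 2)
  expect_identical(r1$trains, r2$trains)
  # weights constant throughout a replay
  chk <- run_network(fx$topology, Wi, st$stimulus_60s, 2000L,
                     snapshot_ms = c(1000L, 2000L))
  expect_identical(chk$snapshots[[1]], Wi)
  expect_identical(chk$snapshots[[2]], Wi)
  # float64 and s16.15 replays of one state generally differ
  ra <- replay_frozen(fx$topology, Wi, st$stimulus_60s, duration_s = 2,
                      spec = solver_spec("euler16"))
  rb <- replay_frozen(fx$topology, Wi, st$stimulus_60s, duration_s = 2,
                      spec = solver_spec("euler16_fxp"))
  expect_false(identical(ra$trains, rb$trains))
  # all-zero excitatory weights and no stimulus: silence
  W0 <- Wi; W0[1:16, ] <- 0
  silent <- replay_frozen(fx$topology, W0,
                          rep(NA_integer_, 2000), duration_s = 2)
  expect_identical(sum(lengths(silent$trains)), 0L)
})

test_that("dimension mismatches in replay artifacts are caught", {
  fx <- make_test_network(3)
  bad <- matrix(1, 5, 5)
  expect_error(replay_frozen(fx$topology, bad, fx$stimulus), "dimensions")
  expect_error(replay_frozen(fx$topology, fx$weights, fx$stimulus[1:100],
                             duration_s = 1), "shorter")
})
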