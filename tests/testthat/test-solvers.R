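rs <- izh_params("rs")
fs <- izh_params("fs")

test_that("right-hand sides and reset reproduce hand-evaluated points", {
  expect_identical(rhs_v(-75, 0, 0), -10)
  expect_identical(rhs_v(30, 0, 0), 326)
  expect_identical(rhs_v(-70, -14, 0), 0)
  expect_identical(rhs_u(-65, -13, rs), 0)
  expect_identical(rhs_u(-70, -14, rs), 0)
  expect_identical(rhs_u(0, 0, fs), 0)
  expect_identical(apply_reset(list(v = 31, u = 0), rs), list(v = -65, u = 8))
  expect_identical(apply_reset(list(v = 29.9, u = 0), rs),
                   list(v = 29.9, u = 0))
  expect_identical(apply_reset(list(v = 30, u = 5), fs), list(v = -65, u = 7))
})

test_that("the grid solver advances v in two half-steps and u in one", {
  st <- izh_step(list(v = -75, u = 0), 0, rs, solver_spec("c_grid"))
  expect_false(st$spiked)
  expect_identical(st$state$v, -82)
  expect_equal(st$state$u, -0.328)
  # above threshold at the grid point: spike, then integrate from the reset
  st2 <- izh_step(list(v = 31, u = 0), 0, rs, solver_spec("c_grid"))
  expect_true(st2$spiked)
  ref <- izh_step(list(v = -65, u = 8), 0, rs, solver_spec("c_grid"))
  expect_identical(st2$state, ref$state)
  # at the quiescent fixed point nothing moves
  st3 <- izh_step(list(v = -70, u = -14), 0, rs, solver_spec("c_grid"))
  expect_identical(st3$state, list(v = -70, u = -14))
})

test_that("sub-stepped solvers reduce correctly and respect fixed points", {
  # one substep == a single full Euler step of both equations
  spec1 <- solver_spec("euler16", substeps = 1)
  st <- izh_step(list(v = -60, u = -12), 3, rs, spec1)
  v1 <- -60 + rhs_v(-60, -12, 3)
  u1 <- -12 + rs$a * (rs$b * v1 - (-12))
  expect_equal(st$state$v, v1)
  expect_equal(st$state$u, u1)
  # the fixed point is preserved by every variant
  for (variant in c("euler3", "euler16", "euler16_fxp")) {
    st <- izh_step(if (variant == "euler16_fxp")
      list(v_raw = q_raw(q_encode(-70, q_s16_15())),
           u_raw = q_raw(q_encode(-14, q_s16_15())))
      else list(v = -70, u = -14),
      0, rs, solver_spec(variant))
    expect_false(st$spiked)
    if (variant == "euler16_fxp") {
      # fixed-point state stays within one truncation ulp of the nullcline
      expect_lt(abs(q_decode(q_encode(-70, q_s16_15())) -
                      st$state$v_raw / 2^15), 0.01)
    } else {
      expect_identical(st$state$v, -70)
    }
  }
})

test_that("fixed-point coefficient storage reproduces the worked derivatives", {
  # s16.15 constant: noticeably more negative than the exact -10
  e1 <- quadratic_coef_error(fmt = q_s16_15())
  expect_equal(e1$coef, 1310 / 32768)
  expect_equal(e1$value, -10.1236357, tolerance = 1e-4)
  # s8.23 constant (the pre-scaled 10.24 * 2^-8 form): much closer
  e2 <- quadratic_coef_error(fmt = q_s8_23())
  expect_equal(e2$coef, 335544 / 2^23)
  expect_equal(e2$value, -10.00021375, tolerance = 1e-4)
  # the error ordering: s16.15 < s8.23-equivalent < exact
  expect_lt(e1$value, e2$value)
  expect_lt(e2$value, -10)
  # v = 0: only the constant term remains
  expect_equal(quadratic_coef_error(v = 0)$value, 140, tolerance = 2^-15)
})

test_that("the adaptive reference integrator is converged and event-accurate", {
  init <- protocol_init(rs)
  ref <- reference_adaptive(rs, I = 5, duration = 500,
                            v0 = init$v0, u0 = init$u0)
  expect_length(ref$spike_times, 5)
  # tightening the error tolerance does not move the spikes
  ref8 <- reference_adaptive(rs, I = 5, duration = 500, abs_err = 1e-8,
                             v0 = init$v0, u0 = init$u0)
  expect_equal(ref$spike_times, ref8$spike_times, tolerance = 1e-3)
  # quiescent fixed point stays flat
  flat <- reference_adaptive(rs, I = 0, duration = 100, v0 = -70, u0 = -14)
  expect_length(flat$spike_times, 0)
  expect_true(all(abs(flat$v - (-70)) < 1e-6))
})

test_that("euler16 spikes lag the reference, with non-decreasing lag", {
  init <- protocol_init(rs)
  ref <- reference_adaptive(rs, I = 5, duration = 500,
                            v0 = init$v0, u0 = init$u0)
  eu <- simulate_neuron(solver_spec("euler16"), rs, I = 5, duration = 500,
                        v0 = init$v0, u0 = init$u0)
  lags <- spike_lag(eu$spike_times, ref$spike_times)
  expect_length(lags, 5)
  expect_true(all(lags >= 0))
  expect_true(all(diff(lags) >= 0))
})

test_that("first spike time matches a brute-force fine-step Euler oracle", {
  init <- protocol_init(rs)
  eu <- simulate_neuron(solver_spec("euler16"), rs, I = 5, duration = 200,
                        v0 = init$v0, u0 = init$u0)
  fine <- oracle_fine_euler(rs, I = 5, duration = 200, h = 1e-3,
                            v0 = init$v0, u0 = init$u0)
  expect_lt(abs(eu$spike_times[1] - fine[1]), 1)
})

test_that("refining the substeps moves spike times toward the reference", {
  init <- protocol_init(rs)
  ref <- reference_adaptive(rs, I = 5, duration = 500,
                            v0 = init$v0, u0 = init$u0)
  err <- sapply(c(16, 64), function(sub) {
    tr <- simulate_neuron(solver_spec("euler16", substeps = sub), rs,
                          I = 5, duration = 500,
                          v0 = init$v0, u0 = init$u0)
    max(abs(spike_lag(tr$spike_times, ref$spike_times)))
  })
  expect_lt(err[2], err[1])
})

test_that("precise threshold detection bounds the overshoot; grid detection does not", {
  sc <- make_overflow_scenario()
  grid <- simulate_neuron(solver_spec("euler3"), sc$params, I = sc$I,
                          duration = sc$duration)
  precise <- simulate_neuron(solver_spec("euler16"), sc$params, I = sc$I,
                             duration = sc$duration)
  expect_gt(max(grid$v), 100)            # runs far above theta = 30
  # one substep's growth from theta bounds the precise solver's samples
  bound <- 30 + 0.0625 * rhs_v(30, min(precise$u), sc$I)
  expect_lte(max(precise$v), bound)
})

test_that("solver variants are deterministic and fail loudly when unknown", {
  a <- simulate_neuron(solver_spec("euler16_fxp"), rs, I = 5, duration = 200)
  b <- simulate_neuron(solver_spec("euler16_fxp"), rs, I = 5, duration = 200)
  expect_identical(a$v, b$v)
  expect_identical(a$spike_times, b$spike_times)
  expect_error(simulate_neuron(solver_spec("esr"), rs, 5, 100),
               "not implemented")
})

test_that("compiled and R single-step kernels agree exactly", {
  spec <- solver_spec("euler16")
  v <- -65; u <- -13
  tr <- simulate_neuron(spec, rs, I = 7, duration = 50, v0 = v, u0 = u)
  st <- list(v = v, u = u)
  for (k in 1:50) st <- izh_step(st, 7, rs, spec)$state
  expect_identical(st$v, tr$v[51])
  expect_identical(st$u, tr$u[51])
  # fixed-point kernel
  spec2 <- solver_spec("euler16_fxp")
  tr2 <- simulate_neuron(spec2, rs, I = 7, duration = 50, v0 = v, u0 = u)
  st2 <- list(v_raw = q_raw(q_encode(v, q_s16_15())),
              u_raw = q_raw(q_encode(u, q_s16_15())))
  iraw <- q_raw(q_encode(7, q_s16_15()))
  for (k in 1:50) st2 <- izh_step_fxp(st2, iraw, rs, spec2)$state
  expect_identical(st2$v_raw / 2^15, tr2$v[51])
  expect_identical(st2$u_raw / 2^15, tr2$u[51])
})
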