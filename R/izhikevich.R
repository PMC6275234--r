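#' Izhikevich neuron parameters
#'
#' The two-variable Izhikevich model
#' \deqn{\dot v = 0.04 v^2 + 5 v + 140 - u + I}
#' \deqn{\dot u = a (b v - u)}
#' with hard reset \eqn{v \ge \theta: v \leftarrow c,\; u \leftarrow u + d}
#' at the spike threshold \eqn{\theta = 30} mV. The polychronization network
#' uses the regular-spiking parameterization
#' `(a, b, c, d) = (0.02, 0.2, -65, 8)` for excitatory neurons and the
#' fast-spiking one `(0.1, 0.2, -65, 2)` for inhibitory neurons.
#'
#' @param type `"rs"` (regular spiking) or `"fs"` (fast spiking), or
#'   `"custom"` with explicit values.
#' @param a recovery time scale (1/ms).
#' @param b recovery sensitivity.
#' @param c post-spike reset voltage (mV).
#' @param d post-spike recovery increment.
#' @param theta spike threshold (mV).
#' @return An object of class `izh_params`.
#' @export
izh_params <- function(type = c("rs", "fs", "custom"),
                       a = NULL, b = NULL, c = NULL, d = NULL, theta = 30) {
  type <- match.arg(type)
  preset <- switch(type,
    rs = list(a = 0.02, b = 0.2, c = -65.0, d = 8.0),
    fs = list(a = 0.1, b = 0.2, c = -65.0, d = 2.0),
    custom = {
      if (is.null(a) || is.null(b) || is.null(c) || is.null(d))
        stop("custom parameters require a, b, c and d")
      list(a = a, b = b, c = c, d = d)
    })
  structure(c(preset, list(theta = theta, type = type)),
            class = "izh_params")
}

#' @export
print.izh_params <- function(x, ...) {
  cat(sprintf(
    "Izhikevich parameters (%s): a = %g, b = %g, c = %g, d = %g, theta = %g mV\n",
    x$type, x$a, x$b, x$c, x$d, x$theta))
  invisible(x)
}

#' Model right-hand sides and reset
#'
#' `rhs_v()` and `rhs_u()` evaluate the two coupled rate equations of the
#' Izhikevich model; `apply_reset()` applies the hard reset when the
#' membrane potential has reached threshold, and leaves the state untouched
#' otherwise.
#'
#' @param v membrane potential (mV).
#' @param u recovery variable.
#' @param I input current (pA).
#' @param params an [izh_params()].
#' @param state a list with elements `v` and `u`.
#' @return `rhs_v()`/`rhs_u()` the derivative; `apply_reset()` the
#'   (possibly reset) state.
#' @export
rhs_v <- function(v, u, I) 0.04 * v^2 + 5 * v + 140 - u + I

#' @rdname rhs_v
#' @export
rhs_u <- function(v, u, params) params$a * (params$b * v - u)

#' @rdname rhs_v
#' @export
apply_reset <- function(state, params) {
  if (state$v >= params$theta) {
    state$v <- params$c
    state$u <- state$u + params$d
  }
  state
}

#' Solver configuration
#'
#' Selects the numerical scheme used to advance a neuron over one 1 ms grid
#' step:
#' \describe{
#'   \item{`c_grid`}{the original grid scheme: threshold tested at the grid
#'     point only, `v` advanced in two sequential 0.5 ms half-steps, `u` in
#'     one full step from the already-updated `v` (semi-implicit symplectic
#'     forward Euler).}
#'   \item{`euler3`}{three symplectic Euler substeps of h/3, threshold still
#'     tested only at the grid point. In s16.15 arithmetic this is the
#'     configuration that can overflow when `v` grows far above threshold.}
#'   \item{`euler16`}{sixteen substeps of h/16 = 0.0625 ms (applied as a
#'     multiplication by 0.0625, never a division), with precise threshold
#'     detection: `v >= theta` is tested after every substep and the reset
#'     applied immediately; the spike is still emitted on the 1 ms grid, and
#'     multiple within-step crossings merge into one event.}
#'   \item{`euler16_fxp`}{as `euler16`, but all state and constants held as
#'     s16.15 words, with the quadratic coefficient pre-scaled:
#'     `0.04 v^2` is evaluated as `((10.24 * v) * 2^-8) * v` in exactly that
#'     order, and the parameters `a`, `b` stored pre-scaled by `2^8` with a
#'     compensating 8-bit right shift at use.}
#'   \item{`reference`}{adaptive Runge-Kutta-Fehlberg 4(5) with bisection
#'     event localization (single-neuron use only; see
#'     [reference_adaptive()]).}
#'   \item{`esr`}{the Explicit Solver Reduction formulation used by the
#'     stock SpiNNaker software; named for completeness but intentionally
#'     not implemented here.}
#' }
#'
#' @param variant one of `"c_grid"`, `"euler3"`, `"euler16"`,
#'   `"euler16_fxp"`, `"reference"`, `"esr"`.
#' @param arithmetic `"float64"` or `"s16.15"`; defaults to the variant's
#'   natural arithmetic.
#' @param substeps override the number of substeps per 1 ms grid step
#'   (e.g. 1 or 64 for convergence checks).
#' @param precise_threshold override per-substep threshold testing.
#' @return An object of class `solver_spec`.
#' @export
solver_spec <- function(variant = c("euler16", "c_grid", "euler3",
                                    "euler16_fxp", "reference", "esr"),
                        arithmetic = NULL, substeps = NULL,
                        precise_threshold = NULL) {
  variant <- match.arg(variant)
  def <- switch(variant,
    c_grid      = list(arith = "float64", sub = 2L, precise = FALSE),
    euler3      = list(arith = "float64", sub = 3L, precise = FALSE),
    euler16     = list(arith = "float64", sub = 16L, precise = TRUE),
    euler16_fxp = list(arith = "s16.15", sub = 16L, precise = TRUE),
    reference   = list(arith = "float64", sub = NA_integer_, precise = TRUE),
    esr         = list(arith = "s16.15", sub = 1L, precise = FALSE))
  arith <- if (is.null(arithmetic)) def$arith else
    match.arg(arithmetic, c("float64", "s16.15"))
  if (variant %in% c("c_grid", "reference") && arith != "float64")
    stop("variant '", variant, "' supports float64 arithmetic only")
  sub <- if (is.null(substeps)) def$sub else as.integer(substeps)
  if (!is.na(sub) && sub < 1L) stop("substeps must be >= 1")
  precise <- if (is.null(precise_threshold)) def$precise else
    isTRUE(precise_threshold)
  structure(list(variant = variant, arithmetic = arith, substeps = sub,
                 precise_threshold = precise),
            class = "solver_spec")
}

#' @export
print.solver_spec <- function(x, ...) {
  cat(sprintf("solver_spec: %s (%s, %s substeps, precise threshold: %s)\n",
              x$variant, x$arithmetic,
              ifelse(is.na(x$substeps), "adaptive", x$substeps),
              x$precise_threshold))
  invisible(x)
}

# map a solver_spec onto the compiled kernel's arguments
spec_to_cfg <- function(spec) {
  if (spec$variant == "esr")
    stop("the ESR solver is a named variant only and is not implemented")
  if (spec$variant == "reference")
    stop("the reference solver is adaptive; use reference_adaptive()")
  list(variant = if (spec$variant == "c_grid") 0L else 1L,
       substeps = spec$substeps,
       precise = spec$precise_threshold,
       fxp = spec$arithmetic == "s16.15",
       prescaled = spec$variant == "euler16_fxp")
}

#' One grid step of the single-neuron dynamics (reference R implementation)
#'
#' Advances a neuron state over one 1 ms grid step under a [solver_spec()].
#' This pure-R implementation mirrors the compiled kernel and serves as the
#' second executable model in the package's own cross-verification tests.
#' For fixed-point variants the state carries raw s16.15 words (`v_raw`,
#' `u_raw`) and all arithmetic goes through [q_mul()]/[q_shr()]-equivalent
#' raw-word operations.
#'
#' @param state list with `v`, `u` (float64) or `v_raw`, `u_raw` (s16.15).
#' @param I input current (pA); for fixed-point states, a raw word.
#' @param params an [izh_params()].
#' @param spec a [solver_spec()].
#' @return list with the advanced `state` and a logical `spiked` flag.
#' @export
izh_step <- function(state, I, params, spec) {
  cfg <- spec_to_cfg(spec)
  if (cfg$fxp) return(izh_step_fxp(state, I, params, spec))
  v <- state$v; u <- state$u
  spiked <- FALSE
  if (cfg$variant == 0L) {
    if (v >= params$theta) { v <- params$c; u <- u + params$d; spiked <- TRUE }
    v <- v + 0.5 * rhs_v(v, u, I)
    v <- v + 0.5 * rhs_v(v, u, I)
    u <- u + params$a * (params$b * v - u)
  } else {
    h <- if (cfg$substeps == 16L) 0.0625 else 1 / cfg$substeps
    if (!cfg$precise && v >= params$theta) {
      v <- params$c; u <- u + params$d; spiked <- TRUE
    }
    for (k in seq_len(cfg$substeps)) {
      v <- v + h * rhs_v(v, u, I)
      u <- u + h * (params$a * (params$b * v - u))
      if (cfg$precise && v >= params$theta) {
        v <- params$c; u <- u + params$d; spiked <- TRUE
      }
    }
  }
  list(state = list(v = v, u = u), spiked = spiked)
}

# raw-word helpers for the R fixed-point path (f = 15 throughout)
raw_enc <- function(x) cpp_q_encode(x, 15L, FALSE)$raw
raw_mul <- function(a, b) cpp_q_mul(a, b, 15L)$raw
raw_add <- function(a, b) cpp_q_add(a, b)$raw
raw_shr <- function(a, n) cpp_q_shr(a, n)

fxp_consts <- function(params, substeps, prescaled) {
  list(h = raw_enc(1 / substeps),
       c04 = raw_enc(0.04), c1024 = raw_enc(10.24),
       five = raw_enc(5), c140 = raw_enc(140),
       theta = raw_enc(params$theta),
       c = raw_enc(params$c), d = raw_enc(params$d),
       a_ = if (prescaled) raw_enc(params$a * 256) else raw_enc(params$a),
       b_ = if (prescaled) raw_enc(params$b * 256) else raw_enc(params$b))
}

#' @rdname izh_step
#' @export
izh_step_fxp <- function(state, I, params, spec) {
  cfg <- spec_to_cfg(spec)
  stopifnot(cfg$fxp)
  K <- fxp_consts(params, cfg$substeps, cfg$prescaled)
  v <- state$v_raw; u <- state$u_raw
  spiked <- FALSE
  if (!cfg$precise && v >= K$theta) {
    v <- K$c; u <- raw_add(u, K$d); spiked <- TRUE
  }
  for (k in seq_len(cfg$substeps)) {
    quad <- if (cfg$prescaled)
      raw_mul(raw_shr(raw_mul(K$c1024, v), 8L), v)
    else
      raw_mul(raw_mul(K$c04, v), v)
    dv <- raw_add(quad, raw_mul(K$five, v))
    dv <- raw_add(dv, K$c140)
    dv <- raw_add(dv, -u)
    dv <- raw_add(dv, I)
    v <- raw_add(v, raw_mul(K$h, dv))
    bv <- if (cfg$prescaled) raw_shr(raw_mul(K$b_, v), 8L) else raw_mul(K$b_, v)
    diff <- raw_add(bv, -u)
    du <- if (cfg$prescaled) raw_shr(raw_mul(K$a_, diff), 8L) else raw_mul(K$a_, diff)
    u <- raw_add(u, raw_mul(K$h, du))
    if (cfg$precise && v >= K$theta) {
      v <- K$c; u <- raw_add(u, K$d); spiked <- TRUE
    }
  }
  list(state = list(v_raw = v, u_raw = u), spiked = spiked)
}

#' Quadratic-term coefficient error under fixed-point storage
#'
#' Demonstrates how storing the coefficient 0.04 of the quadratic membrane
#' term in fixed point perturbs the subthreshold derivative. The returned
#' value evaluates `coef * v^2 + 5 v + 140 - u + I` in double precision
#' with `coef` replaced by its fixed-point decoding: `1310 * 2^-15` for
#' s16.15 and `335544 * 2^-23` for s8.23 (the latter equals the pre-scaled
#' s16.15 constant `10.24 * 2^-8` used by the `euler16_fxp` solver).
#'
#' @param v,u,I evaluation point (defaults: the worked example at
#'   `v = -75`, `u = 0`, `I = 0`, where the exact derivative is -10).
#' @param fmt a [qformat()] in which the coefficient is stored.
#' @return list with the decoded `coef` and the derivative `value`.
#' @export
quadratic_coef_error <- function(v = -75, u = 0, I = 0, fmt = q_s16_15()) {
  coef <- q_decode(q_encode(0.04, fmt))
  list(coef = coef, value = coef * v^2 + 5 * v + 140 - u + I)
}
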