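---
title: "Verifying and substantiating spiking-network simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying and substantiating spiking-network simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeverify)
```

## The problem

When a spiking network model is re-implemented on a different platform --
in particular on integer-only neuromorphic hardware -- there is usually no
experimental ground truth against which either implementation could be
validated. What can be done instead is *substantiation*: running both
executable models under identical, frozen conditions and quantifying the
statistical agreement of their spiking activity. spikeverify implements
the complete apparatus for this exercise on the classic polychronization
network: the network model itself, a family of interchangeable numerical
schemes (including an emulation of 32-bit fixed-point arithmetic), a
frozen-state replay protocol, and the comparison statistics.

## The model

Every neuron follows the two-variable Izhikevich dynamics

$$\dot v = 0.04 v^2 + 5 v + 140 - u + I, \qquad \dot u = a (b v - u),$$

with the hard reset $v \leftarrow c$, $u \leftarrow u + d$ whenever
$v \ge \theta = 30$ mV. Excitatory neurons are regular spiking,
$(a,b,c,d) = (0.02, 0.2, -65, 8)$; inhibitory neurons fast spiking,
$(0.1, 0.2, -65, 2)$.

The network couples 800 excitatory and 200 inhibitory neurons with fixed
out-degree 100. Excitatory synapses start at $w = 6$, have integer
conduction delays uniform on 1--20 ms, and are plastic under an additive
STDP rule ($A_+ = 0.1$, $A_- = 0.12$, $\tau_\pm = 20$ ms) whose increments
are buffered and applied simultaneously once per biological second.
Inhibitory synapses are fixed at $w = -5$ with 1 ms delay and target the
excitatory population only. Each millisecond, one uniformly chosen neuron
receives a 20 pA current for that step. All spike emission and delivery is
locked to a 1 ms grid.

Two wiring details are deliberate design choices rather than published
facts: autapses and duplicate synapses are excluded (the historical C
implementation of this network excludes them), and excitatory delays are
drawn independently and uniformly from 1--20 ms (the historical code
instead partitions the 100 synapses evenly across delays; we follow the
published description of the distribution). Plastic weights are clipped to
$[0, 10]$ after each batch update -- these bounds come from the historical
implementation, not from the published parameter set, and both are
configurable through `stdp_params()`.

## Numerical schemes

`solver_spec()` selects how one 1 ms grid step is integrated:

* **`c_grid`** -- the historical scheme: threshold tested only at the grid
  point, then $v$ advanced in two sequential 0.5 ms half-steps and $u$ in
  one full step from the already-updated $v$ (semi-implicit symplectic
  forward Euler). Because the spike onset has a very steep slope, testing
  the threshold only at grid points lets $v$ overshoot $\theta$ by orders
  of magnitude under strong drive; the overshoot perturbs $u$ and delays
  every subsequent spike.
* **`euler3`** -- three substeps of $h/3$, threshold still at the grid
  point. In fixed-point arithmetic this configuration is the one that
  overflows: the overshooting $v$ enters the squared term and wraps.
* **`euler16`** -- sixteen substeps of $h/16 = 0.0625$ ms (applied as a
  multiplication by 0.0625, never a division, since $1/16$ is exact in
  binary), with *precise threshold detection*: $v \ge \theta$ is tested
  after every substep and the reset applied immediately. The spike is
  still emitted on the 1 ms grid; multiple within-step crossings merge
  into one event. Sixteen substeps is the compromise between cost and
  overshoot; being a power of two, the substep is exactly representable in
  s16.15.
* **`euler16_fxp`** -- the same scheme with every state variable and
  constant held as an s16.15 word (below).
* **`reference`** -- an adaptive embedded Runge-Kutta-Fehlberg 4(5)
  integration (via deSolve's `rk45f`) at absolute error $10^{-6}$, with
  threshold crossings localized by bisection to $10^{-6}$ ms, reset, and
  restart. Spike times are continuous, not grid-locked. The bisection
  tolerance is our choice; only the integration error is prescribed by the
  protocol we emulate.
* **`esr`** -- the Explicit Solver Reduction formulation shipped with the
  SpiNNaker toolchain is *named* for completeness but intentionally not
  implemented: its closed form is defined in its own publication and is
  not part of this package's scope. Selecting it raises an error.

The exact statement order inside the grid schemes (threshold-then-integrate
for the grid-threshold variants, integrate-then-test-per-substep for the
precise variants) is a reconstruction from the prose description of the
algorithms, since the original listings are figures; the package documents
it as such and pins it with tests.

## Fixed-point arithmetic

The `qformat` layer emulates 32-bit signed fixed-point words with $i$
integer bits, $f$ fraction bits and one sign bit, exactly as an
integer-only ARM core handles them: a value $x$ is stored as
$\mathrm{trunc}(x\,2^f)$, arithmetic is performed on the raw words, a
multiplication forms the exact 64-bit product and shifts it
arithmetically right by $f$, and overflow *wraps* -- it never saturates.
Two choices are ours where the emulated platform's behaviour is not
documented: conversion truncates toward zero (C cast semantics;
configurable to floor), and the multiply keeps a full 64-bit intermediate
before the single arithmetic shift. A package-level counter
(`q_wrap_counter()`) tallies wrap events so that overflow artifacts can be
demonstrated rather than silently produced.

The native format, s16.15, stores the coefficient 0.04 of the quadratic
term as $1310 \cdot 2^{-15} = 0.0399780\ldots$, which makes the
subthreshold derivative at $v = -75$ noticeably more negative than the
exact $-10$ and delays every spike. The remedy emulated here stores the
pre-scaled constant $10.24 = 0.04 \cdot 2^8$ and compensates with an
8-bit arithmetic right shift at use, achieving s8.23-level coefficient
precision inside an s16.15 word. Because truncated multiplication is not
associative, the quadratic term must then be evaluated in exactly the
order $((10.24 \cdot v) \cdot 2^{-8}) \cdot v$ -- evaluating
$10.24 \cdot v^2$ first would overflow. The neuron parameters $a$ and $b$
receive the same pre-scaling treatment; the scale factor $2^8$ mirrors the
treatment of 0.04 (the emulated platform's account does not state the
factor it used for $a$ and $b$).

```{r fxp}
q_decode(q_encode(0.04, q_s16_15()))
quadratic_coef_error(fmt = q_s16_15())$value   # exact value is -10
quadratic_coef_error(fmt = q_s8_23())$value
```

## Single-neuron verification protocol

The timing benchmark stimulates a regular-spiking neuron with a constant
5 pA for 500 ms and compares each solver against the adaptive reference.
The protocol we emulate does not state initial conditions. The package
default is the customary $(v_0, u_0) = (c, b c) = (-65, -13)$; under a
suprathreshold current, however, that state fires an additional spike
almost immediately at onset, giving six spikes in 500 ms and contaminating
the first lag estimate with grid quantization. Starting instead from the
post-reset state $(c, bc + d) = (-65, -5)$ -- the state a neuron actually
occupies right after a spike -- yields the canonical five reference spikes
in 500 ms and cleanly increasing solver lags, so the verification
protocol in the tests and the acceptance script uses the post-reset
initialization explicitly.

```{r neuron}
rs <- izh_params("rs")
ref <- simulate_neuron(solver_spec("reference"), rs, I = 5, duration = 500,
                       v0 = -65, u0 = -5)
eu <- simulate_neuron(solver_spec("euler16"), rs, I = 5, duration = 500,
                      v0 = -65, u0 = -5)
length(ref$spike_times)
spike_lag(eu$spike_times, ref$spike_times)
```

The lags are non-negative and non-decreasing: the residual overshoot of
the grid-locked solver accumulates through $u$ and postpones every later
spike. A worked example of this quantity appearing at its printed
precision is in the acceptance script.

## Comparison statistics

Three measures, computed through one shared code path for both inputs to
avoid analysis-side asymmetries:

* **FR** -- per-neuron firing rate, spike count over duration (Hz).
* **LV** -- the local coefficient of variation of Shinomoto et al. (2003),
  $\mathrm{LV} = \tfrac{3}{m-1}\sum_k \bigl(\tfrac{\mathrm{ISI}_k -
  \mathrm{ISI}_{k+1}}{\mathrm{ISI}_k + \mathrm{ISI}_{k+1}}\bigr)^2$: zero
  for perfectly regular trains, one in expectation for Poisson trains.
  The formula itself is pinned here because the protocol we emulate only
  cites it. Neurons with fewer than three spikes are excluded and counted.
* **CC** -- Pearson correlation of 2 ms-binned spike counts for every
  unordered neuron pair; pairs involving a zero-variance train are
  excluded and counted. All pairs enter by default (whether silent neurons
  should be dropped is left to the caller via the reported exclusions).

Distributions are summarized by 70-bin histograms on the union of both
samples' ranges and compared by Cohen's d with the pooled standard
deviation ("normalized difference of means" admits several denominators;
pooled SD is the conventional one and is documented as our choice). The
three measures probe different aspects -- counts, serial regularity,
coordination -- and deliberately need not agree; the test suite constructs
a pair of recordings with matched rates but different regularity to pin
this down.

## The substantiation experiment

`substantiation_run()` executes the full protocol at a reduced scale: the
network matures under STDP with the float64 `euler16` solver, the weight
matrix is frozen, and the frozen state (connectivity, delays, weights,
recorded stimulus) is replayed for 60 s with STDP off under both the
float64 and the s16.15 pipelines. The replay is a pure function of its
artifacts: reruns are bit-identical, and the weights do not move during a
replay. The default maturation length of 600 s with snapshots every 120 s
(five network states) stands in for the multi-hour maturation of the
original study; five hours of STDP are available through the arguments
but are not part of the default protocol. The package's own result, which
the acceptance script recomputes, is that the float64 and fixed-point
replays of a 600 s state agree with small-to-medium effect sizes
($|d| < 0.8$) on all three measures.

Two protocol ambiguities are resolved as follows and pinned in tests: a
weight snapshot that falls on a 1 s batch boundary is taken *after* the
coincident batch update, and the per-step stimulated neuron is drawn
independently each step (repeats allowed).

## Two engines, one model

The network loop exists twice: a compiled C++ engine used for production
runs, and a pure-R engine (`engine = "r"`) that mirrors it operation for
operation, including floating-point accumulation order. The test suite
runs both on the 20-neuron fixture and requires bit-identical spikes,
weights and snapshots -- the package applies to itself the methodology it
implements. To make this identity possible, the compiled code is built
with floating-point contraction disabled, and the C++ kernel mirrors R's
evaluation order for the quadratic term ($0.04 \cdot (v \cdot v)$).

STDP pairing uses the single most recent opposing spike per synapse, with
the pre-synaptic event timed at its *arrival* (emission plus conduction
delay); depression is applied when a spike arrives at a target that has
already fired, potentiation when a neuron fires after an arrival. This
arrival-timing convention follows the historical implementation of the
network and is noted here because the published rule leaves it implicit.

## Problem sizes and numerical choices

The default test and acceptance workloads are sized so that a complete
run fits comfortably on one CPU: the arithmetic oracle draws 10^4 random
word pairs; the Poisson LV anchor uses 250 trains of ~300 spikes
(sampling error of the mean ≈ 0.006, well inside the ±0.05 band); the
independence CC anchor uses 50 trains (1225 pairs); the substantiation
experiment matures the full 1000-neuron network for 600 biological
seconds and replays 60 s. Degenerate inputs are handled explicitly:
empty trains have rate zero, LV excludes trains with fewer than two ISIs,
CC excludes zero-variance binned trains, and Cohen's d of two zero-
variance samples is 0 for equal means and signed infinity otherwise.

## What the synthetic conditions do and do not show

All inputs are generated: there is no recorded biological data anywhere
in the pipeline, and the generators emulate exactly the published study
conditions (population sizes, out-degree, delay distribution, stimulus
protocol, STDP constants). Passing tests therefore demonstrate agreement
between two *implementations* under the model's own dynamics -- the
substantiation claim -- and say nothing about biological validity of the
network, nor about hardware effects the emulation does not model (event
loss, timer jitter, or the ESR solver's behaviour). The 600 s maturation
also yields a younger network state than multi-hour runs; effect sizes
for older states are obtainable with the same machinery and longer
`duration_s`, at proportional cost. Polychronous-group detection and
counting is out of scope throughout.
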