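---
title: "Simulation semantics and numerical methods in ratespike"
author: "ratespike authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation semantics and numerical methods in ratespike}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ratespike)
```

## The model

ratespike simulates networks built from two kinds of units on a fixed time
grid of step `dt` (milliseconds):

* **rate-coded neurons** carry a continuous instantaneous firing rate
  `r(t)` updated every step; projections deliver the weighted sum of
  delayed pre-synaptic rates as `sum(target)`;
* **spiking neurons** integrate membrane equations and emit discrete
  events when a boolean spike condition holds, followed by reset
  statements and an optional refractory period; incoming spikes increment
  per-target conductances `g_target`.

Both are described by the same plain-text language: a `parameters` block
(`name = value : flags`) and an `equations` block in which every variable
is either a regular assignment or a first-order ODE written with a
`dX/dt` term.  The left-hand side of an ODE may be affine
(`tau*dv/dt + v = E` is normalized symbolically to `dv/dt = (E - v)/tau`).
Conditionals use the Python-like `if c: a else: b` syntax and may nest;
`and`/`or`/`not` and the full set of relational operators are available,
as are the C math functions and the random terms `Uniform`, `Normal`,
`LogNormal`, `Exponential` and `Gamma` (drawn once per step and per unit,
constant within a step even when a scheme evaluates the gradient twice).
The flag vocabulary covers initial values (`init`), clamping bounds
(`min`, `max`), shared storage (`population` / `postsynaptic`: one value
per population or per post-synaptic neuron) and the per-variable
numerical method.

Synapse models add a per-synapse output `psp` (default `w * pre.r`)
aggregated with `sum`, `max`, `min` or `mean` for rate-coded
transmission, and `pre_spike` / `post_spike` statement blocks for
event-driven transmission (default `g_target += w`).  A synapse may only
modify its own variables, `w`, and — in `pre_spike` — `g_target`.
Declaring `psp` on a spiking projection switches to continuous
transmission, where `psp` is summed into `g_target` every step (the
non-linear NMDA synapse).

## Numerical methods

Four per-step schemes and an exact event-driven form are available; the
default is the explicit (forward) Euler method, and per-variable `method`
flags may mix schemes within one model.

* **explicit**: increments `dt * f(state)` evaluated at the current time;
* **implicit**: gradients evaluated at the next time.  The system must be
  linear in its ODE variables; the solver extracts the (possibly
  state-dependent) coefficients at each step by evaluating the gradients
  at basis points and solves `(I - dt A) x' = x + dt c`.  Non-linear
  systems are rejected at build time.
* **exponential**: each equation is canonized to
  `tau_eq * dx/dt + x = A_eq` with `tau_eq`, `A_eq` free of `x`, and
  advanced by `x += (1 - exp(-dt/tau_eq)) * (A_eq - x)`.  This is exact
  for uncoupled linear equations with piecewise-constant drive; a
  conductance-based term `g*(E - v)` yields the state-dependent
  equivalent time constant `tau/(1 + g)`.
* **midpoint**: a second-order Runge–Kutta step; the full gradient vector
  at `t` is used to estimate all variables jointly at `t + dt/2`.
* **event-driven** (synaptic variables only): for ODEs `dx/dt = a x + b`
  with coefficients constant over time, the closed form
  `x -> x_inf + (x - x_inf) exp(a e)` is applied only when a pre- or
  post-synaptic spike reaches the synapse, with `e` the elapsed time
  since the previous event.  State-dependent coefficients (such as the
  saturating NMDA conductance) are rejected at build time.

Two genuinely open points were fixed as follows.  First, `A_eq` (and any
coefficient of the implicit solver) is evaluated on *pre-update* values;
whether it may observe same-step updates of other variables is not
prescribed anywhere, and pre-update evaluation keeps all schemes
consistent with the simultaneous-increment contract below.  Second,
within one model, variables update in declaration order and each
assignment reads the already-updated values of earlier variables —
but consecutive ODEs sharing a method form a *block* whose increments
are all computed from the block's entry state before any member is
written.  This reproduces the standard coupled-system treatment (the
membrane/recovery pair of the quadratic adaptive neuron) while letting
auxiliary assignments (input currents, rate functions) feed the ODEs of
the same step.

Bounds are applied immediately after each variable (or block member) is
written, so later equations of the same step read clamped values.

## The simulation step

Every step executes seven stages in a fixed order:

1. **propagation** — previous-step outputs enter the network: weighted
   sums for rate-coded projections; for spiking projections, the
   pre-spike statements of spikes whose delay elapses now;
2. **neural update** — variable plans, then spike conditions, reset
   statements and entry into the refractory state.  During refractoriness
   only conductance variables (`g_*`) advance; everything else is frozen
   at its reset value and no spike can be emitted;
3. **delayed outputs** — the new rate (or spike flags) is pushed into the
   population's delay ring buffer, sized at compile time from the largest
   outgoing delay;
4. **synaptic updates** — continuous projection variables (learning
   rules, NMDA dynamics), postsynaptic-shared variables once per post
   neuron;
5. **post-synaptic events** — `post_spike` statements for projections
   whose post neuron fired this step;
6. **structural plasticity** — active creating/pruning rules at their
   check period;
7. **recording** — monitors sample at their period; then `t += dt`.

Cross-population reads therefore always observe previous-step outputs and
the minimal synaptic latency is one step (`dt`), which is also the
minimal delay; sub-step delays are raised to `dt` and off-grid delays are
rounded to the grid with a warning.  Only the pre-synaptic *output*
variable is delay-buffered; other `pre.X` references read current values.

Timing conventions for event-driven synapses: pre-synaptic events run at
spike *arrival* (stage 1, time `t`), post-synaptic events at the end of
the emitting step (stage 5, `t + dt`).  Event times are monotone under
this convention, and an isolated pre/post pair at nominal separation
`Δt` with the minimal delay sees exactly `Δt` of trace decay in both the
potentiation and the depression direction, so the recovered plasticity
window has the declared time constants.  Within one step, pre-synaptic
events precede post-synaptic ones (stage 1 before stage 5).  Spike events
are stamped with the start-of-step time, so a recorded raster fed back
into a `spike_source_array()` reproduces itself.

Conductances come in two flavours: a `g_target` that the neuron model
declares (usually with a decay ODE) accumulates increments into its
state; an undeclared (instantaneous) `g_target` exposes the summed
increments to the current update only and reads zero afterwards.
Referencing a target with no incoming projection yields 0, so models can
be built incrementally.

Every population and projection draws randomness (connectivity, initial
values, per-step noise, Poisson spikes, rule probabilities) from a
network-private RNG stream seeded at `network(seed = )`.  Hence a seed
fully determines a run; splitting one `simulate()` call into several is
bit-identical, and consuming randomness outside the network does not
perturb it.  NaN/overflow guards run every 100 steps (every step with
`debug = TRUE`) and abort naming the population and variable.

## Hybrid conversion

Rate-to-spike conversion uses Poisson populations: each unit fires with
per-step probability `rate * dt / 1000` (rate in Hz) — a Bernoulli
approximation of a Poisson process that is accurate while the
probability stays well below 1; a warning is emitted beyond 0.1.  The
rate may be fixed, a time expression, or the unit's weighted input sum,
so a rate-coded neuron at `r = 1.0` drives 1 Hz trains through weight
1.0 and 100 Hz trains through weight 100.0.

Spike-to-rate conversion uses a sliding-window decoding projection:

```
sum(target)(t) = weighted spikes received in (t - T, t] / (T[s] * N_syn)
```

with the window `T` in *seconds* in the denominator and `N_syn` the
number of incoming synapses.  A literal reading with `T` in milliseconds
would make unit-weight 1 Hz inputs decode to 0.001; the package
normalizes by seconds so that the stated calibration — 1 Hz inputs give
`sum(target) = 1.0` — holds, which is the convention all tests and the
acceptance script verify.  The default window is one step; a `T`-window
decode equals the `T/dt`-point moving average of the one-step decode,
and after a rate step the decoded value settles in exactly `T` ms.
Spikes are counted at their arrival (post-delay) time, the only point at
which the decoder observes them.

The relative decoding error reported by `decoding_error()` is the mean
normalized L1 distance `(1/H) Σ |r(t) - F| / F · dt` over a horizon `H`
(250 ms by default): 0 for a perfect trace, 1 for silence, `2/π` for a
full-swing sinusoid around `F`.

## Convolution and pooling

Weight-sharing projections serve rate-coded populations only, and are
non-plastic.  A convolution computes
`out(x) = Σ_i W(i) · pre.r(center(x) - i)` with odd-extent kernels; when
the shapes differ, post coordinate `c` maps to the pre center
`floor(c·ratio + ratio/2)` with `ratio = pre_d/post_d` per dimension.
Outside the population the input reads 0 (zero padding) or the clamped
border value (`padding = "edge"`).  A kernel with fewer dimensions than
the pre-synaptic geometry is applied separately along each trailing
(channel) coordinate; a list of kernels forms a filter bank indexed by an
extra trailing post dimension.  Kernels larger than the population are
rejected rather than silently truncated.

Pooling assigns post coordinate `c` the region starting at
`floor(c·ratio)` with extent `ceiling(ratio)` per dimension (a 200×200 to
100×100 projection gives 2×2 regions), truncated to valid coordinates at
the borders; mean-pooling divides by the actual region size.

## Structural plasticity

`create_synapse()` / `prune_synapse()` edit the connectivity directly,
preserving the per-post ordering; new synapses start their variables at
the declared initial values and participate in the very next propagation
stage.  Rule-based plasticity attaches boolean conditions to the synapse
model: pruning conditions see per-synapse state, creating conditions only
continuous pre/post variables (event-triggered creation is not defined).
Rules run once started (`start_creating()` / `start_pruning()`), at a
check period defaulting to every step — the expensive setting; a coarser
period is recommended and the default is kept only for fidelity to the
stated semantics.

## The reference networks

Three fixtures exercise the full engine and generate all synthetic test
inputs; none uses external data.

* **Pulse-coupled network**: 1000 quadratic adaptive (Izhikevich)
  neurons, 800 excitatory / 200 inhibitory, all-to-all with uniform
  random weights (`U(0, 0.5)` excitatory, `U(0, 1)` inhibitory) and
  per-neuron parameter heterogeneity from the original recipe
  (`c = -65 + 15e²`, `d = 8 - 6e²`; inhibitory `a = 0.02 + 0.08i`,
  `b = 0.25 - 0.05i`), per-step normal noise with amplitudes 5 and 2, at
  `dt = 1` ms.  It exhibits population oscillations in the 1–50 Hz band.
* **Conductance-based benchmark**: `4000·scale` integrate-and-fire
  neurons (80/20 split) with exponentially decaying conductances, random
  connectivity at probability 0.02, `dt = 0.1` ms and 0.1 ms delays.
  The physiological constants are not part of this package's claims and
  follow the standard benchmark description (leak 10 nS to −60 mV,
  C = 200 pF, threshold −50 mV, reset −60 mV, refractory 5 ms, reversal
  potentials 0/−80 mV, synaptic time constants 5/10 ms, weights
  6/67 nS); they live in one editable constant set (`coba_constants()`).
  Initial membrane potentials are uniform between reset and threshold
  and initial conductances are randomized, the usual kick into the
  self-sustained regime.  Scaled-down variants have few inputs per
  neuron, so a `weight_scale` (typically `1/scale`) keeps them active;
  tests assert structure and seeded bit-reproducibility, not rates.
* **Hybrid demo**: a rate source stepping through 0/10/50/100 Hz
  (250 ms each) drives a 1000-unit Poisson encoder through unit weights;
  a decoding projection (window 10 ms) reads the spikes back into one
  rate-coded neuron, and the per-level decoding error is measured.

## What the tests show — and what they do not

The synthetic fixtures probe the *simulator*: exactness of closed forms,
convergence orders, stage ordering, calibrations, reproducibility.  They
do not establish anything about biological data: Poisson encoders are
homogeneous and memoryless (no refractoriness or adaptation in the spike
trains), the benchmark constants are conventions, and the
pulse-coupled network's oscillations are a qualitative regime, not a fit
to recordings.  Problem sizes in the test-suite were chosen to keep each
check statistically decisive yet quick on one core: encoder calibrations
use 100–1000 units over 10–100 s (binomial 3σ bands), the
reproducibility check runs the quarter-scale benchmark for 100 ms, the
event-driven comparisons use a handful of spikes over a few hundred ms
against `dt = 0.001` ms dense integration, and the plasticity-window
scan uses isolated pairs at lags up to 50 ms.

## Known limitations

One clock per network; no stochastic differential equations (random
terms inside ODEs are per-step constants, not a diffusion); no
event-driven integration for *neural* equations (it would require
predicting threshold crossings); spiking weight-sharing and learning in
shared projections are not defined; augmented assignments are not
allowed on ODEs; physical units are implicit (only time is fixed, in
ms).  The implicit solver falls back to a per-unit dense solve for
blocks of more than two coupled ODEs, which is exact but slow for large
populations.  Performance targets correctness, not speed: this is a
single-threaded reference implementation whose value is that every
semantic rule above is explicit, tested, and independent of any compiled
backend.
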