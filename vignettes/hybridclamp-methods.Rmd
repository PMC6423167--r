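---
title: "Simulating dynamic-clamp hybrid circuits with hybridclamp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating dynamic-clamp hybrid circuits with hybridclamp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridclamp)
```

## The problem

Dynamic clamp closes a loop between a computer and a living neuron: every
sampling interval the cell's membrane potential is read, model equations are
advanced one step, and a computed current is injected back into the cell.
When the model side is a whole neuron coupled through model synapses, the
result is a *hybrid circuit* — a network in which biological and artificial
neurons interact on equal terms. Two things make such software demanding:
the loop must meet a hard timing budget (100 µs at 10 kHz), and the model
must be adapted automatically to the particular cell in front of the
electrode, whose amplitude range and burst rhythm are not known in advance.

`hybridclamp` reproduces this machinery at desk scale, with the hardware
and the real-time operating system abstracted behind a clock interface.
Everything else is the real thing: the neuron and synapse model library,
the calibration pipeline, the periodic loop with its latency accounting and
overrun recovery, and the control–coupled–control experiment protocol.  A
synthetic bursting preparation stands in for the biological cell, so full
experiments run and validate with no laboratory attached.

## Neuron models

The library covers the span from map-based to conductance-based dynamics:

* **Rulkov map** — a two-dimensional discrete map with a piecewise fast
  variable, `x' = alpha/(1-x) + y` below threshold, and a slow variable
  moving at rate `mu`.  One burst takes only tens of map points, so output
  must be *interpolated* up to the acquisition rate (below).
* **Izhikevich** — quadratic integrate-and-fire with recovery variable and
  a discrete reset (`v >= 30 mV` sets `v <- c`, `u <- u + d`; the boundary
  is inclusive so tie-breaking is deterministic).
* **Hindmarsh–Rose** — the classic three-variable polynomial burster.
* **Ghigliazza–Holmes-style conductance model** — a three-variable minimal
  burster: instantaneous Ca activation, a fast K gate and a slow KS gate,
  all with Boltzmann steady states, plus leak.  The shipped parameters put
  the fast subsystem in a bistable (rest/spiking) regime and let the slow
  gate sweep across it — square-wave bursting by fold ignition.  The slow
  gate's time constant is voltage dependent (1600 ms depolarised, 500 ms at
  rest): fast deinactivation at rest shortens the interburst interval
  without touching the burst, which is what lets the model combine a duty
  cycle suited to 1:1 coordination with a quiescent phase that stays below
  the graded-synapse threshold (see *Why the presets look the way they do*).
* **Wang-style conductance model** — a Hodgkin–Huxley-type spiker with the
  classic exponential rate functions plus a slow K adaptation gate.  The
  spiking core is bistable near its subcritical Hopf onset; the slow gate
  sweeping the effective drive across that window produces regular
  elliptic bursting.  It is the most expensive model in the library and the
  natural target for nonlinearity tabulation.

The paper trail for these model families fixes their *structure*, not a
unique parameter set, so the shipped presets (`inst/extdata/presets.yaml`,
`neuron_preset()`) are this package's own.  They were selected, once, by
four criteria and then frozen:

1. **Regular bursting** — the burst detector finds many bursts with a low
   duration CV in a free run;
2. **Step-size robustness** — the bursting orbit is unchanged across the
   integration steps the calibration may select (Hindmarsh–Rose in
   particular has period-adding multistabilities where a step-size change
   flips the orbit between spike counts; the preset sits away from those);
3. **Pyloric-compatible rhythm** — duty cycles such that, after
   burst-duration matching against a 1 burst/s preparation, the scaled
   period is commensurate with 1 s (duration matching fixes the period to
   duration/duty, so wildly different duty cycles produce incommensurate
   periods and no 1:1 coordination);
4. **Boundedness** — gating variables remain in [0, 1] at any accepted
   step.

`tabulate_fn()` implements the high-resolution lookup tables used to
cheapen exponential nonlinearities: linear interpolation on a uniform grid,
clamped at the domain edges; at 10^4 nodes the relative error against the
direct exponentials is below 10^-6.

## Synapse models

All synapses are computed in physiological units (µS × mV → nA).  The
graded chemical synapse — the workhorse of pyloric-circuit work, where
transmitter release follows the slow wave rather than spikes — has its
threshold and slope expressed as *percentages of the presynaptic amplitude
range*, resolved against the observed range at calibration time.  The
activation is a Boltzmann; the slow variant adds first-order kinetics
`dm/dt = k1 (1 - m) a - k2 m` (advanced by the exact exponential update, so
the gate cannot leave [0, 1] at any step size) with fixed point
`m* = k1 a / (k1 a + k2)`.  The standard validation wiring couples the
model to the living cell through a slow inhibitory graded synapse
(g = 0.2 µS, threshold 15%, slope 1%, k1 = 14 /s, k2 = 4 /s; 0.1 µS when
the model is Hindmarsh–Rose) and the living cell back through a fast
inhibitory one (threshold 50%, slope 5%; 0.8 µS for Izhikevich and the
Ghigliazza–Holmes-style model, 1.0 µS for Hindmarsh–Rose, 0.2 µS for
Rulkov).  An ohmic electrical synapse and a spike-triggered
transmitter-pulse chemical synapse complete the library.

Synaptic reversal potentials for the inhibitory graded synapses default to
the observed minimum of the postsynaptic signal, which guarantees an
inhibitory driving force whatever the calibrated range turns out to be.

## Calibration

`calibrate_model()` adapts a model to a target neuron in three steps:

1. a free run in the model's native time base, long enough for at least
   eight bursts, measured by the hysteresis burst detector
   (`detect_bursts()`: onset at an upward crossing of min + 0.25·range,
   offset at a downward crossing of min + 0.15·range, events closer than a
   minimum gap merged so intra-burst spikes do not fragment a burst);
2. a two-point affine **amplitude map** sending the observed model range
   onto the live mV range (with its exact inverse; streamed output
   saturates at the mapped bounds, as a DAC would);
3. a **time scale**: for ODE models, the model time to advance per
   acquisition interval so one burst spans the target duration, with the
   integration substep chosen by `select_step()` — the smallest substep
   count whose one-burst stability probe shows no blow-up and no gating
   escape; for map models, the interpolation ratio `r` (output samples per
   map point), realised by a phase accumulator whose long-run emission rate
   is exactly `r` even when `r` is irrational.

Calibration also returns a *warmed-up state* (the end state of the native
run): streams start on the bursting attractor rather than in the settling
transient, which for the Rulkov map would otherwise last ~10 s of scaled
time (its slow variable relaxes over ~1/mu map points).

Burst-duration matching (1 s per burst, or "match the living neuron") is
the convention used here, consistent with hybrid-circuit practice; the
virtual preparation itself is calibrated by burst *period*, since a
preparation is characterised by its rate.

## The periodic loop

`run_loop()` executes the canonical interval: wake, DAQ exchange, drift
compensation, synapse models, neuron model, enqueue to the writer channel,
sleep.  Deadlines form an anchored arithmetic sequence `t0 + k/fs` that is
*never re-based*: when an iteration overruns (the library's worst offender
is the Hodgkin–Huxley-type model, whose cost can spike to ~140 µs against
a 100 µs budget), the following iterations wake immediately, their sleep is
shortened or skipped, and the schedule is recovered within a couple of
periods — with the data cadence preserved, because every iteration index
executes even across multi-period overruns.

The clock is pluggable.  The **virtual clock** advances simulated time by
scripted per-operation durations, making the scheduling semantics exact and
testable (the overrun scenario above is reproduced to the microsecond).
The **wall clock** is best-effort OS timing: statistics are collected and
reported, but no hard bound is claimed — an unpatched desktop OS is a
soft-real-time platform at best, and R adds its own latencies on top.

`latency_stats()` summarises a run the standard way: min/max/mean ± sd,
jitter (max − min), a histogram presented with a log count axis, and a
failure count against the period (50 µs at 20 kHz, 100 µs at 10 kHz).
The `writer_channel()` decouples data output from the loop: an
amortised-constant-cost FIFO standing in for the inter-process queue that
feeds a writer thread in a real-time implementation.

Two engines can run an experiment.  The generic task loop above is the
reference; a fused single-function loop executes the same operations in the
same order with the bookkeeping hoisted out of the per-sample path, which
matters in R where closure dispatch dominates at 10 kHz.  The two are
verified against each other bit-for-bit in the test suite, and the wall
clock always uses the task loop.

## The virtual preparation

`virtual_preparation()` emulates the biological side: a Hindmarsh–Rose
cell calibrated to ~1 burst/s (the characteristic pyloric rate) on a
–60 to –25 mV range, behind the acquisition scaling conventions (input
voltage × 100 to recover mV; 10 nA per command volt on output).  Three
output-stage features model what an electrode actually delivers:

* **somatic filtering** — a one-pole low-pass (default tau 20 ms) standing
  for the electrotonic attenuation of distally generated spikes; somatic
  recordings of pyloric neurons are slow-wave dominated, and the graded
  synapses must see that waveform (without it, inhibition arrives as
  isolated spike-triggered pulses and cannot entrain a relaxation-type
  burster — coordination fails);
* **additive Gaussian noise** on the recorded sample (default 0.5 mV);
* **linear drift** (mV/min), the slow baseline wander of long recordings.

Noise and drift are output-stage effects only — no claim is made about
biological channel noise — and with all three disabled the preparation is
exactly the deterministic calibrated model trace, which the tests assert.
A two-column recorded trace can replace the model (replay mode).

Injected current maps into model units through the amplitude-map slope:
`I_model = I_nA / gain`.  This is the convention under which a synapse
computed in mapped mV coordinates acts on the model with the same effective
conductance it would have on the mapped side; the preparation applies the
same rule in reverse.

Drift compensation estimates the baseline from per-window signal floors
(a lower quantile rather than the raw minimum, which carries substantial
extreme-value noise), smoothed by a lag-cancelling pair of exponential
moving averages (`2·ema(tau) − ema(2 tau)` is exact on a linear ramp).
Constants — tau 3 s, 10% quantile, 3 burn-in windows — were fixed by a
design study across seeds before freezing.  The correction is subtracted
from the recorded signal before any threshold or range computation; it
acts on the recorded signal only, not on the injected current.

## The experiment protocol and the antiphase index

`run_experiment()` plays the full protocol: a pre-control phase records
the uncoupled preparation; calibration fits the model to the observed live
range and burst duration; the coupled phase runs both units inside the
loop with both graded synapses active; a post-control phase records both
uncoupled again.  Synaptic currents are exactly zero outside the coupled
phase.  Desk-scale defaults are 10 s controls around a 60 s coupled phase
(a scaled-down version of minute-controls around a five-minute
interaction; full lengths remain one configuration away).  Everything is
logged: model and synapse identities and parameters, calibration results,
and the latency summary.

Rhythm coordination is quantified by `antiphase_index()`: for each cycle
of the living neuron (burst midpoint to next burst midpoint), every model
burst midpoint inside the cycle contributes a phase in [0, 1); the summary
is the circular median and the circular dispersion `1 − R`.  Midpoints
rather than onsets anchor the phase because the onset-based index is
duty-cycle biased: two perfectly alternating bursters with duty `d` put
the partner's *onset* at phase `(1 + d)/2` (≈ 0.68 at the pyloric duty of
about one third), whereas the *midpoint* phase of exact alternation is 0.5
regardless of either duty.  For point events the midpoint reduces to the
onset, so the textbook arithmetic (live onsets 0, 1, 2 s; model onsets
0.5, 1.5 s; phase 0.5) is unchanged.

With the standard wiring and the virtual preparation, all four validation
models (Rulkov, Izhikevich, Hindmarsh–Rose, Ghigliazza–Holmes-style) lock
1:1 with the preparation with phase medians between 0.40 and 0.60 and
dispersions near zero, across seeds.  The mechanism is the classic
half-centre one: the fast inhibitory synapse vetoes model bursts while the
living cell is depolarised, and the slow inhibitory synapse reciprocally
shapes the living cell's window.

## Numerical choices

* Integrators: forward Euler, Heun, classic RK4, and a six-stage embedded
  Runge–Kutta pair (`"rk65"`, Fehlberg coefficients) advancing with its
  fifth-order solution and controlling the step with the embedded
  fourth-order error estimate (accept if the scaled error norm is ≤ 1,
  step factor `0.9·err^(-1/5)` clipped to [0.2, 5]).  Orders are verified
  empirically (1, 2, 4 ± 0.25; local order ~6 for the pair).
* The stability probe for substep selection runs one burst length and
  rejects non-finite values, |state| > 10^6, or gating outside [0, 1]
  beyond 1e-9.
* Ties and boundaries: the Izhikevich reset is inclusive; burst-detector
  hysteresis uses 0.25/0.15 of range with a 100 ms merge gap by default;
  zero-length phases are allowed everywhere except the pre-control window,
  which must contain at least 1 s (and in practice several bursts) for
  calibration.
* Determinism: a single integer seed fixes every random draw of a run;
  identical configurations give bit-identical traces, and fixed-step
  integration is bit-reproducible.

## Problem sizes and what the tests show

The shipped validation runs use 10 kHz sampling with 10 s + 60 s + 10 s
phases (800 000 loop intervals per experiment) and 30 s calibrated free
runs; scheduling checks run the full 3 × 10^6 intervals of a five-minute
10 kHz session on the virtual clock.  These sizes were chosen so the whole
suite completes in minutes on one core while still exercising every code
path at the study's native sampling rate.

Passing tests show that the machinery — models, calibration, scheduling
semantics, coordination — behaves as specified *against the synthetic
preparation*.  The preparation emulates the rhythm, amplitude, waveform,
noise and drift of a somatic pyloric recording, but not biological
variability between preparations, non-stationary rhythms, electrode
artifacts, or the continuum of real membrane dynamics; results on real
cells additionally depend on hardware timing that the virtual clock
deliberately abstracts away.  Wall-clock mode reports honest soft-real-time
statistics, nothing more.

## Known limitations

* Single-compartment models only; no network-scale circuits beyond the
  one model / one preparation pair.
* The living neuron's somatic waveform is emulated, not recorded; replay
  mode accepts real traces but then offers no closed-loop plasticity of
  the preparation side.
* Spike-level (intra-burst) waveform matching is out of scope for the
  calibration; only range and burst-duration are fitted.
* Hard real-time guarantees are out of scope by design: the wall clock is
  best-effort, and quantitative latency figures are only meaningful on a
  real-time OS with dedicated hardware.
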