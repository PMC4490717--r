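---
title: "Methods: simulated closed-loop optogenetic firing-rate control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated closed-loop optogenetic firing-rate control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optoclamp)
```

## The control problem

An "optoclamp" locks the firing rate of a neuronal population at a target
level by continuously adjusting bidirectional optical stimulation: blue
(465/470 nm) light excites channelrhodopsin-expressing cells, yellow
(590 nm) light recruits a hyperpolarizing chloride pump. The preparation —
a dissociated cortical culture on a microelectrode array, or a single
thalamocortical unit recorded in vivo — is noisy, adapting, and drifts in
excitability, which is precisely why open-loop stimulation fails and
feedback is required. This package reproduces that control stack in
simulation so that the estimator, control laws, stimulus mappings, and
evaluation metrics can be exercised, tested, and extended without
hardware.

## Rate estimation

Every `dt = 4` ms the population spike count is converted to an
instantaneous rate `r[t] = n_spikes / (n_units * dt)` (Hz/unit) and
blended into a first-order exponential average

```
f[t] = alpha * r[t] + (1 - alpha) * f[t - dt],    alpha = 1 - exp(-dt/tau)
```

with `tau = 2.5` s for population control and `tau = 0.8` s for
single-unit control, where the lower spike count forces a faster but
noisier estimate. `tau` is a genuine loop parameter: values below ~0.5 s
let measurement noise drive the actuators, values above ~10 s introduce
enough lag to cause slow oscillation; both directions are exercised by
`sweep_parameters()`.

## Control laws

The PI controller is the velocity-form recursion
`u[t] = u[t-1] + K (e[t] - e[t-1] + (Ts/Ti) e[t])` with error
`e = f* - f`, nominal gains `K = 0.1`, `Ti = 1` s, and control period
`Ts = 10` ms. Its scalar output is split into the two stimulus channels,
`U_C = clip(u + 0.25, 0, 1)` and `U_H = clip(-u + 0.25, 0, 1)`; the 0.25
offsets create an overlap region around `u = 0` in which mild excitation
and mild suppression coexist, giving a smooth hand-off between channels.

**Anti-windup.** Saturated actuators must not let the integrating state
accumulate, so the state itself is clipped: `u` is confined to
`[-0.25, 0.75]`, the interval beyond which both split outputs are pinned.
Clipping only the outputs would leave `u` free to wind far past
saturation and delay recovery; clipping the state is the choice that
actually bounds the integral.

The in vivo controller zeroes the proportional part
(`u[t] = u[t-1] + (Ts/Ti) e[t]`, `u` clipped to `[0, 1]`) and maps `u`
directly to fiber light power `G * u`, with `G` measured per fiber
(default 20 mW·mm⁻² per unit output).

The on-off (bang-bang) controllers act on the integrated error. The sum
in their definition is accumulated here as `I_f += e * dt` at the filter
step (4 ms) — a plain unweighted sum would be step-size dependent — and
`|I_f|` is capped at 10 Hz·s/unit so that the accumulator, like the PI
state, cannot wind up. The excitatory mode emits a fixed 5 ms,
13.4 mW·mm⁻², 465 nm pulse whenever `I_f > 0`, at most once every 100 ms
(the 10 Hz cap); the inhibitory mode gates continuous yellow light
(~11.8 mW·mm⁻²) on while `I_f < 0`. Controllers start neutral
(`u = 0`, `e_prev = 0`, `I_f = 0`) at control onset, and no state is
reset at target-segment switches — tracking a staircase of targets is
seamless, which the engine tests assert.

## Stimulus synthesis

A single excitatory variable `U_C` modulates pulse frequency
(`10 U_C + 10` Hz), width (`5 U_C` ms), and peak power (`13.2 U_C`
mW·mm⁻²) simultaneously; `U_H` is delivered as LED current (amperes) with
a linear current-to-power curve reaching 10.8 mW·mm⁻² at 1 A (the curve
is configurable; the linear default is a modeling choice). Two printed
peak-power coefficients coexist in the source material — 13.2 for the
pulse-train mapping, 13.4 for the alternative waveform family and the
on-off pulse — and the package follows each locally, with both
configurable. Note that at the widely cited operating point `U_C = 0.47`
the pulse-train mapping gives 6.204 mW·mm⁻² while the measured value is
reported as 6.9; the mapping is implemented literally, reading the 6.9 as
a calibrated measurement rather than a command.

`render_waveform()` produces the full waveform family at a fixed `U_C`:
square trains (energy-preserving fractional samples for sub-sample pulse
widths, so commanded energy per second equals `freq * width * power`),
triangles rising at 0.22 mW·ms⁻¹·mm⁻² (falling at the same slope; the
peak is limited to what fits in half a 10 Hz carrier period, since at
high `U_C` a full rise-and-fall no longer fits), half-wave-rectified
10 Hz sines (the defining sinusoid goes negative; light power cannot, so
negative lobes render as darkness), pseudorandom binary sequences redrawn
at 150 Hz from an order-15 maximal-length shift register (period 32767 ≫
any trial length at 150 Hz; the generator is unspecified in the source
and this is the standard choice), and constant light. In closed loop the
engine renders the same families with a phase-accumulator pulse train, so
a frequency change mid-train advances phase continuously instead of
piling pulses up.

The whisker stimulus is a train of punctate deflections with exponential
rising and falling phases: total excursion 8°, 99% rise and fall times of
5 ms. The exponential is normalized to reach the full 8° exactly at the
end of the 5 ms rise, which makes the average rising-phase velocity
exactly 8°/5 ms = 1600 °/s; without the normalization the trace tops out
at 99% of the excursion and both printed values are missed by 1%.

## The synthetic plants

The plants are **doubly-stochastic Poisson models, not synaptically
coupled networks**. The controllers only observe the population rate, so
the simplest plant family that reproduces every phenomenon the control
loop was validated against is the right one: spikes are drawn as an
inhomogeneous Poisson process whose intensity carries saturation,
suppression, adaptation, bursting, drift, and drug effects.

The network plant's per-unit intensity is

```
lambda_i = (spont * env + g_i * E * D(b) * a) * S(y) * x
```

* `b`, `y` — blue/yellow power passed through first-order opsin filters
  (80 ms and 30 ms). The resulting intensity additionally follows drive
  changes with a first-order *network recruitment lag* (`net_tau`,
  default 150 ms): a culture's population rate tracks optical input
  through synaptic integration and recurrent recruitment, not
  instantaneously. This lag is what gives aggressive controller settings
  something to be unstable against; without it a proportional gain of 2
  merely clamps harder.
* `D(b)` — Hill dose-response (exponent 2) on the commanded mean-power
  scale, half-point at the `U_C = 0.15` equivalent. With the pulse-train
  mapping this places saturation at the `U_C ≈ 0.47` drive, where the
  population rate reaches `dose_max = 12.5` Hz/unit;
  `E = max(dose_max - spont, 0)` scales the evoked component so the
  saturated *total* rate is `dose_max`.
* `S(y)` — monotone suppression (Hill exponent 3, half-point at the
  `U_H = 0.03` equivalent) descending to `suppress_floor / spont`
  (0.04/1.5 Hz/unit), so sustained yellow at the `U_H = 0.15` equivalent
  holds the population near the printed 0.04 Hz/unit floor. A slow
  efficacy fade with time-under-light (default time constant 2 h) models
  chloride accumulation and pump desensitization; it is negligible in
  60-s trials and matters only for multi-hour scenarios.
* `a` — multiplicative adaptation: first-order onset at rate 1/40 s⁻¹
  scaled by normalized drive, recovery with a 60 s time constant, floor
  `1 - adapt_depth = 0.7`. Under saturating drive `a` settles near 0.76
  with a ~20 s time constant, so open-loop stimuli visibly lose
  effectiveness across a 60-s trial while leaving enough headroom for the
  controller to hold an 8 Hz/unit target late in a trial. The adaptation
  magnitude is calibrated qualitatively (the source quantifies only its
  presence), and since all units share one optical drive the adaptation
  state is shared; heterogeneity enters through static log-normal unit
  gains `g_i` (CV 0.5).
* `env` — a two-state burst envelope (exponential dwell times, 8
  bursts/min of mean duration 0.2 s, in-burst multiplier 6, baseline
  chosen so the envelope has unit mean), giving the aperiodic population
  bursting typical of developing cultures.
* `x` — slow log-normal excitability drift: a within-trial
  Ornstein-Uhlenbeck process (log-sd 0.15, time constant 30 s) times a
  per-instance preparation factor (log-sd 0.1) drawn when the plant is
  seeded. The drift is what makes open-loop replay fail and control
  locking drift; the instance factor stands in for day-to-day and
  culture-to-culture variability.

Drug conditions are parameter modifiers (`apply_drug()`): CNQX scales the
spontaneous rate by 0.258 (−74.2%), AP5 by 0.334 (−66.6%), bicuculline by
4.57 (+357%) while capping the achievable driven rate at 5.1 Hz/unit;
burst amplitude is scaled down under glutamatergic blockade and up under
bicuculline (qualitative choices).

The thalamocortical-unit plant is a single-unit analogue: intensity
`(baseline * env + opsin_gain * a * b) * x + sensory`, a 2 ms absolute
refractory period, and a burstier spontaneous envelope (multiplier 8,
~7.5% duty) that pushes the spontaneous ISI coefficient of variation
above ~1.5, emulating anesthetized thalamic burst firing, while steady
optical drive produces near-Poisson intervals. Whisker deflection onsets
add a short-latency Gaussian rate kernel (5 ms latency, 1.5 ms SD, one
spike per deflection by default). The step function takes the kernel's
instantaneous intensity rather than raw whisker position: onset detection
from a position sample would smuggle state into an otherwise pure step,
so the engine detects onsets from the rendered deflection train and
passes the precomputed intensity.

## The closed-loop engine

Three clocks coexist: the published filter rate (4 ms) and control period
(10 ms) are both honored by running the simulation on a 1 ms master grid,
with the filter ticking every 4th step and the controllers every 10th.
The controller reads the rate estimate delayed by `loop_latency` (default
5 ms, the online spike-classification latency); the delay's position in
the loop is a modeling choice, and tests assert that changing only the
latency changes the outcome. Optional pre-pulse conditioning applies a
10-s train of `U_C = 1` stimuli starting 20 s before control onset, the
startup-stabilization protocol used with cultured networks.

`replay_open_loop()` drives a (re-seeded) plant with a recorded trial's
optical traces and no feedback; `lock_control()` freezes the control
signal mid-trial at its last value or its first-half mean;
`sweep_parameters()` varies exactly one of `K`, `Ti`, `tau` across seeded
trials and flags instability where the interquartile range of the binned
controlled rate (default 1-s bins) exceeds 3× the nominal value's IQR.
One timescale caveat: with this plant, rate-filter time constants below
~0.5 s produce ringing at a few hertz (the synthetic network's collective
dynamics are faster than a real culture's), so that instability is
visible in sub-second rate bins (`rate_bin = 0.2`) rather than 1-s bins,
whereas the slow oscillations at `tau` above ~10 s or `K` near 1 and
above appear directly in 1-s bins.

## Metrics

* RMS tracking error between the estimate and target over a window — for
  60-s trials the evaluation window is the final 30 s of the control
  epoch, where a trial counts as successful below 0.5 Hz/unit.
* Settling time: the rate trace is smoothed with LOWESS (`stats::lowess`,
  tri-cube weights, 2.5 s window) and the settling time is the first
  moment the smoothed trace enters `target ± 0.25` Hz/unit and never
  leaves.
* Cross-correlograms (5 ms bins, pair-averaged, normalized per reference
  spike and bin width to a conditional rate; raw-count normalization is
  also exposed since the source does not fix one) and the synchrony index
  `N_cc / sqrt((N_i² + N_j²)/2)` with `N_cc` the number of spike pairs
  within ±10 ms — each pair counted once, a spike free to participate in
  several pairs; an exhaustive O(N²) enumeration pins these semantics in
  the tests.
* `cv_isi()` uses the population (biased) SD by default (the estimator is
  unspecified in the source; the sample SD is available via an argument).
* Spike-triggered averages exclude spikes with truncated windows; for
  FWHM the baseline defaults to the mean of the first 10% of the curve
  (the start of the pre-window), and plateau maxima (e.g. rectangles) are
  measured by interpolating the half-crossings, with flat curves flagged
  `NA` rather than silently numeric.
* Burst detection is threshold-based (default 2× the median smoothed
  rate) with gap merging (<100 ms) and a 50 ms minimum duration to
  discard single-spike blips; the source names no algorithm, so the
  defaults are stated rather than inherited.

## Problem sizes, determinism, and numerical choices

All randomness flows through R's RNG from a single integer seed per
trial; identical seeds give byte-identical records, which is itself under
test. The test suite and the acceptance script size their simulations for
a desk machine: the headline closed-loop check runs twenty 60-s trials
(targets cycling 1–8 Hz/unit, 30 units, pre-pulse on) and evaluates the
final 30 s; replay and sweep properties use 20–30-s trials. Time steps
are exact in binary-friendly milliseconds; pulse onsets fire on phase
wraparound; fractional-width pulses are rendered energy-preserving; the
on-off minimum-interval comparison carries a 1 ns slack so grid-aligned
times fire exactly at 10 Hz.

## What the synthetic plants do and do not show

The plants reproduce the *response structure* the controllers face —
saturating drive, a suppression floor, within-trial adaptation, aperiodic
bursting, excitability drift, drug-induced excitability shifts,
stimulus-locked sensory spikes — and the package's passing tests show the
control stack behaves correctly against that structure. They do not
contain synapses, conduction delays, spatial light profiles, opsin
photocycles, or plasticity; higher-order correlation structure beyond
what the stimulus waveform imposes is not modeled. Quantities tied to
those mechanisms (e.g. exact correlation changes between waveform
families, homeostatic outcomes of multi-hour clamps) are outside what a
passing test here can claim about real preparations.
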