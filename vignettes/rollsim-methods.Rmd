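---
title: "Behavioral model of a reconfigurable spiking neuromorphic processor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral model of a reconfigurable spiking neuromorphic processor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rollsim)
```

`rollsim` is a behavioral (circuit-free) software model of a ROLLS-class
mixed-signal neuromorphic processor: 256 silicon neurons, a 256×256
array of bistable on-line-learning synapses, a 256×256 array of
programmable synapses with short-term depression, shared per-row linear
synapse integrators, per-row "virtual" synapses, a synapse
de-multiplexer, and symbolic address-event routing.  This vignette
documents the model equations, the parameter conventions, the numerical
scheme, and the design decisions taken where the hardware description
leaves the behavioral level open.

## Units

The hardware expresses every neuron and synapse parameter as a
subthreshold bias current; no SI values are attached to the membrane
variable.  The model therefore uses dimensionless normalized units:
resting level 0, spike peak 1, with time in seconds.  All default
parameter values are free choices constrained only by the orderings the
circuits impose (thresholds between rest and peak, calcium thresholds
ordered, weight bounds around the bistability threshold).

## Neuron model

The soma implements an adaptive exponential integrate-and-fire neuron.
With membrane capacitance normalized as $C = \tau_m g_L$,

$$C \frac{dV}{dt} = -g_L (V - V_\mathrm{rest})
 + g_L \Delta_T e^{(V - V_T)/\Delta_T} - I_\mathrm{ahp} + I_\mathrm{syn},$$

with spike detection at $V \ge V_\mathrm{peak}$, reset to a tunable
$V_\mathrm{reset}$, an absolute refractory clamp of duration
$t_\mathrm{ref}$ at the reset level, and a subtractive adaptation
current that jumps by $b$ at each spike and decays with
$\tau_\mathrm{ahp}$.  Two leak settings × two refractory settings give
at most four neuron types per configuration, mirroring the two latch
bits of the silicon soma.  Setting $\Delta_T = 0$ selects the
hard-threshold leaky integrate-and-fire limit; in that limit ignition at
$V_T$ is instantaneous, so the spike is detected at $V_T$ and the
closed-form rate
$f = 1/(t_\mathrm{ref} + \tau_m \ln \frac{I}{I - g_L V_T})$ serves as an
independent oracle for the integrator (`lif_rate()`; the simulated f–I
curve matches it to 2 % at $dt = 0.01$ ms).

The post-synaptic learning block keeps a calcium trace $Ca$ (exponential
decay $\tau_{Ca}$, jump $+ca_\mathrm{jump}$ at each spike of the neuron
itself) and compares $(V, Ca)$ with four thresholds to produce the
up/down learning-enable flags broadcast to the neuron's plastic-synapse
row.

An optional NMDA voltage gate multiplies the plastic-array row current
by $\mathbf{1}[V > \theta_\mathrm{NMDA}]$.  It is off by default: with a
purely recurrent NMDA drive the gate is self-defeating (after each reset
the membrane sits below the gate and the gated current can never lift it
back), so no packaged experiment uses it.

## Synapse dynamics

All temporal dynamics go through the differential-pair integrator (DPI)
modeled in its linear operating range: a first-order low-pass filter
whose output current decays as $e^{-t/\tau}$ and jumps by
$\mathrm{jump} \times w$ per spike.  The hardware pulse extender is
folded into the jump scale.  Because one DPI is shared per row and per
receptor class, simultaneous inputs superpose exactly and the
steady-state mean current is $\mathrm{jump}\, w\, \nu\, \tau$ — a
function of the rate × weight product only.  That identity is the basis
of virtual-synapse time multiplexing: one 10 kHz train is
indistinguishable at steady state from 1000 independent 10 Hz inputs of
equal weight (the package verifies the simulated ratio to 2 % over
10 s).  Default time constants: 100 ms for the plastic-array (NMDA-like)
row filters, 20 ms for the programmable-array excitatory/inhibitory
(AMPA/GABA-like) filters and the virtual synapses.

Each programmable-array element has a two-bit weight latch mapped to
four equidistant levels $\{0, \frac13, \frac23, 1\} \times w_\mathrm{unit}$
(the hardware states only "four possible weight values"), an
excitatory/inhibitory latch, and activation-mode latches.  The
excitatory branch carries short-term depression: an efficacy variable
$x \in [0, 1]$ scales the EPSC, is sampled *before* depression (the
first pulse of a rested burst is full-size), then reduced subtractively
by $d$ and recovered toward 1 with first-order kinetics
($\tau_\mathrm{rec}$).  The silicon recovery through a diode-connected
transistor is nonlinear but numerically unspecified; first-order
recovery was chosen for testability, and whether the depression is
subtractive in charge or multiplicative in efficacy is genuinely open —
the circuit description ("an amount of positive charge is removed")
points to the subtractive reading adopted here.  The inhibitory branch
has no depression circuit.  Depression is disabled by default and in
both packaged experiments.

## The bistable learning rule

On each pre-synaptic spike arriving at a plastic synapse the internal
weight $w$ updates against the *post-synaptic* state:

$$w \leftarrow \begin{cases}
 w + \Delta w^+ & V > \theta_\mathrm{mem},\ \theta_1 < Ca < \theta_3\\
 w - \Delta w^- & V < \theta_\mathrm{mem},\ \theta_1 < Ca < \theta_2\\
 w & \text{otherwise (stop-learning)}
\end{cases}$$

with clipping to $[w_\mathrm{min}, w_\mathrm{max}]$ and strict
inequalities as printed.  Between events $w$ drifts at a constant rate
toward $w_\mathrm{max}$ or $w_\mathrm{min}$ according to its side of
$\theta_w$; the efficacy delivered to the row integrator is the
thresholded read-out $J = J_\mathrm{max} f(w, \theta_J)$ with a hard
threshold by default (boundary inclusive, $w \ge \theta_J$) or a
logistic alternative.  Defaults
($\theta_1, \theta_2, \theta_3 = 0.1, 0.35, 0.9$;
$\theta_\mathrm{mem} = \theta_w = \theta_J = 0.5$;
$\Delta w^\pm = 0.1$; drift 0.5 s⁻¹ on $w \in [0,1]$) are free choices
satisfying the printed orderings.  All stochasticity of the updates
comes from input and membrane variability; no noise source is added.

Evaluation order at a pre-spike: (1) lazy drift of the synapse column to
the current time, (2) read the post-synaptic membrane and calcium (the
values from the end of the previous step, i.e. *before* this spike's
EPSC), (3) jump $w$, (4) deliver $J(w_\mathrm{after})$ to the row
integrator.  The hardware does not say whether the EPSC uses the pre- or
post-jump efficacy; post-jump was chosen because the current-converter
block reads the weight node continuously.

## Device architecture and the master loop

Both 256×256 arrays are modeled element-by-element; the simulator
exposes both (2 × 65,536 elements) and reports counts explicitly.  The
synapse de-multiplexer assigns, for factor $F \in \{1, 2, 4, \dots,
256\}$, the $F$ consecutive rows starting at neuron $kF$ to that neuron,
disconnecting the others; the element count per active neuron is
$F \times 512$ and the total is invariant in $F$.

Address events are symbolic (the 21-bit hardware encodings and the
1.2-million-pattern decode table are out of scope): a plain-text event
file carries `time_us,kind,arg1,arg2,arg3` records with kinds `DIR`
(direct synapse stimulation), `BCAST` (column broadcast to elements with
the broadcast latch set), `VIRT` (row virtual synapse), `CFG_L`/`CFG_G`
(local/global configuration writes), and `OUT` (neuron spikes).
Recurrent activation connects on-chip neuron $k$ to every synapse of
column $k$ whose recurrent latch is set, each delivering to its own
row's neuron.  The hardware text is ambiguous about the direction of
the recurrent wiring; the column-source/row-destination reading is
adopted consistently in the router and both experiment builders.

The master loop is clock-driven (forward Euler, default
$dt = 0.1$ ms) with a fixed within-step order: configuration events →
recurrent fan-out of the previous step's output spikes (a deliberate
one-step axonal delay that avoids same-step causal loops) → external
deliveries (plastic array, programmable array, virtual synapses) →
exponential decays (computed exactly, not by Euler) → neuron
integration and spike detection.  Simultaneous output spikes are
ordered by neuron index, standing in for the hardware output arbiter
(bus contention is not modeled).  The calcium jump of an output spike
is applied at the spike's step, hence visible to any pre-spike arriving
at the next step.  The simulation is deterministic: identical
configuration, events and step size give a byte-identical output
stream.  Drift and depression are applied lazily in closed form, which
equals per-step application exactly because both flows are
piecewise-linear or exponential and cannot cross their thresholds.

Numerical safeguards: the exponential spike-initiation term is clamped
(argument ≤ 16) so a step cannot overflow — the overshoot is discarded
by the reset; membrane states are checked for non-finite values and the
run aborts with the offending neuron addresses.  An integration
convergence check (f–I against the closed form at $dt = 0.01$ ms) is
part of the test suite.

## Synthetic stimuli

`poisson_train()` draws seeded homogeneous Poisson trains (count-then-
uniform construction).  `synth_dvs()` emulates what an event camera
viewing a jittered static image delivers to the chip: a binary edge
template is "displaced" at the jitter rate (default 10 Hz) and each
edge pixel emits a Poisson burst (mean
`event_rate_per_edge_pixel / jitter_rate`) within 10 ms of each
displacement, mapped through a collision-free channel map to
programmable-array columns; polarity is collapsed to a single event
type and nothing is emitted during the saccadic-suppression gap between
presentations.  It reproduces the *timing statistics* of edge-locked
event streams, not real scene content: no luminance model, no sensor
noise or refractoriness, no per-pixel polarity, and only two synthetic
silhouette classes (a ring and a box outline, 52 and 48 edge pixels,
packaged as text grids).  A passing classification experiment therefore
demonstrates that the learning dynamics can exploit class-specific
event statistics — not performance on natural images, which in the
hardware experiment depended on a physical sensor and a natural-image
dataset and is explicitly not reproduced here.

## The attractor experiment and its calibration

The builder realizes the printed architecture: three pools of 64
excitatory and three pools of 10 inhibitory neurons (222 of 256);
within-pool recurrence on the plastic array (excitatory pools with
probability 0.7, inhibitory pools 0.4) programmed to the high state with
learning frozen; between excitatory pools, excitatory and inhibitory
programmable contacts each with probability 0.2; inhibitory pool → its
excitatory pool with probability 0.4 (inhibitory); excitatory pool → its
inhibitory pool with probability 0.7.  Because one programmable element
exists per (row, column) pair, the two cross-pool classes are drawn
disjointly from a single uniform variable, preserving both marginal
probabilities.  External stimuli are per-neuron 100 Hz Poisson trains on
the virtual synapses for 0.5 s; the reset drives all inhibitory pools at
200 Hz.

The weight magnitudes are free parameters, and the packaged calibration
is a deliverable of the package.  Its design rationale: with linear
synapses and deterministic integrate-and-fire neurons, a purely
recurrent excitatory drive is a line through the origin in the
(rate, current) plane, and for the integrate-and-fire inverse f–I curve
the tangent/secant ratio is $x/(e^x - 1) < 1$ for all $x > 0$ — so such
a line always crosses the curve unstably below the refractory-limited
regime, and the network either dies or runs away.  The calibration
therefore pins the memory state with threshold-linear inhibitory
feedback: the inhibitory neuron type has a raised leak (0.15) so the
inhibitory pools are silent below an ignition point just above 15 Hz of
their excitatory pool; below the pin the recurrent excitation is
supra-threshold and the pool climbs, above it the inhibitory pool
ignites steeply and pulls the rate back.  The external gain is then an
almost independent knob for the driven rate.  Operating point
(`attractor_spec()` defaults, also packaged as
`extdata/attractor_calibration.yaml`): NMDA gain 0.00125, AMPA gain
0.0125, GABA gain 0.020, virtual gain 0.072, no adaptation.  Averaged
over connectivity seeds 1–5 at $dt = 0.1$ ms this yields a driven-window
rate of ≈ 49 Hz, a self-sustained rate of ≈ 16 Hz holding steady until
the next stimulus, memory switching when the second pool is driven, and
collapse below 2 Hz after the inhibitory reset.  Alternatives explored
and rejected: adaptation-based stabilization (any linear adaptation
shifts the balance and the instability identically, leaving only a
slowly decaying transient) and NMDA voltage gating (a trap, as above).

## The classification experiment and its calibration

The builder wires 128 hidden neurons, each to 64 distinct random input
columns with random sign (probability ½) and random nonzero weight
level, through the programmable array in broadcast mode; and 128 output
neurons (two class pools of 64) that receive all 128 hidden neurons
through plastic synapses in recurrent mode, weights initialized low,
learning on.  The teacher is a 250 Hz Poisson train into the
class-matching pool's virtual synapses during training; rates, counts
and schedule are unstated in the hardware experiment and are package
defaults (20 training presentations per class, 10 test presentations
per class, 0.5 s presentations with 0.1 s saccade gaps).

Three couplings make the stop-learning rule operate in its intended
regime.  (1) The per-spike calcium jump is lowered to 0.05 so that with
$\tau_{Ca} = 0.2$ s the depression window $(\theta_1, \theta_2)$ spans
roughly 10–35 Hz of output rate and the potentiation window reaches
90 Hz: a wrongly responding pool (tens of Hz with a mostly-low membrane)
is pruned, a silent pool is protected, and the teacher-driven pool
(≈ 60–70 Hz) potentiates without self-pruning.  (2) The plasticity jumps
are halved (0.05) so a synapse crosses the bistability threshold only
when its hidden neuron fires ≳ 30 Hz within one presentation — the drift
erases slower progress between presentations — which selects the
strongly class-driven hidden neurons.  (3) The plastic-row gain
(0.0012) puts the resulting test-time pool rates in the 3–30 Hz range
where the arg-max decision is meaningful.  With the packaged defaults
the pool decision is correct on 20/20 test presentations for each of
the wiring seeds 1–3, the taught pool's training rate exceeds the
untaught pool's by an order of magnitude, and the pool decision is at
least as accurate as the best single output neuron granted an optimal
threshold in hindsight (the population-coding comparison).

## Problem sizes used by the packaged checks

The test suite and the acceptance script run the attractor protocol for
4 s of simulated time per seed over 5 connectivity seeds, the
classification protocol once end-to-end (60 presentations, 36 s
simulated), the f–I oracle for 2 s per current at $dt = 0.01$ ms, and
the multiplexing comparison for 10 s of integrator time.  These sizes
give sampling errors comfortably inside the stated tolerances (e.g.
± ≈ 0.6 Hz on a 16 Hz pool-rate estimate from 64 neurons × 1 s).

## Known limitations

* The DPI is linear by construction; log-domain compression and
  saturation of the silicon integrator are not modeled, and the
  low-rate attractor stability that saturation would provide in
  hardware is instead provided by the inhibitory operating point.
* Address-event encodings are symbolic; four-phase handshake timing,
  arbiter serialization, and bus contention are not modeled.
* Device mismatch is available only as optional seeded log-normal
  parameter jitter (`mismatch_cv`), off by default; the packaged
  experiments run matched.
* Only depression is implemented on the programmable synapse, no
  facilitation, matching the hardware.
* Homeostatic synaptic scaling and the bias-generator/ADC periphery are
  out of scope.
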