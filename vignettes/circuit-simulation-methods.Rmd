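---
title: "Methods: integrate-and-fire circuit simulation in lifnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrate-and-fire circuit simulation in lifnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifnet)
```

## The model and its assumptions

`lifnet` simulates networks of leaky integrate-and-fire (LIF) point
neurons. The membrane is an RC circuit,

$$C_m \frac{dV}{dt} = I_\text{leak} + I_\text{syn} + I_\text{inj} - I_\text{adapt},
\qquad I_\text{leak} = -\frac{V - V_r}{R_m},$$

with threshold/reset spiking: when $V \ge V_\text{thres}$ the cell emits a
spike, $V$ is set to $V_\text{reset}$ and pinned there for the absolute
refractory period $\tau_r$. Spike-frequency adaptation, when enabled, adds
a conductance $g_\text{adapt}$ that jumps by $\Delta g_\text{adapt}$ at
each spike and decays exponentially with $\tau_\text{adapt}$; its current
$g_\text{adapt}(V - V_r)$ is *subtracted* in the membrane equation. Written
with a positive sign that term would depolarize an already-depolarized
cell; subtracting it makes it hyperpolarizing — the intended "harder to
fire after firing" effect — and is the convention we fixed for the whole
package.

Synapses are current-based and voltage-independent: every presynaptic spike
increments a per-edge current by `peak_current`, and the current decays as
$\exp(-t/\tau_\text{syn})$. Successive spikes **superpose linearly** on the
single decaying state variable rather than resetting it to the peak; this
preserves the linearity of the subthreshold dynamics (tested as a
superposition property) and matches standard practice for exponential
current-based synapses. The synapse stores a nonnegative magnitude; the
sign of the postsynaptic current is a property of the *presynaptic* node's
polarity, so flipping a cell or generator from excitatory to inhibitory
exactly mirrors its downstream effect.

Because current-based synapses place no physical bound on $V$, the
simulator clamps the membrane after every update to
$[-90, +60]$ mV by default — the K$^+$ and Na$^+$ reversal potentials. The
bounds are configurable and the clamp can be disabled (`clamp_policy()`).

## Integration scheme and the step contract

Integration is forward Euler with a fixed step, default
`dt = 1e-4` s. Euler was chosen over exact integration for transparency:
every update rule is a one-line function (`step_neuron()`,
`decay_synaptic_current()`, ...) that students can read, and the engine is
nothing more than those rules applied in a fixed order. The scheme is
first-order: the test suite verifies that halving `dt` at least halves the
maximum deviation from the closed-form subthreshold trajectory, and that
the simulated f–I curve of a non-adaptive cell under constant current
matches

$$f(I) = \Big(\tau_r + \tau_m \ln \frac{V_\infty - V_\text{reset}}
{V_\infty - V_\text{thres}}\Big)^{-1},
\qquad V_\infty = V_r + R_m I$$

to well within 2% at `dt = tau_m / 1000` (measured: ~0.03%).

Each engine step executes, in this order:

1. deliver due spike events as synaptic-current increments;
2. decay all edge currents;
3. evaluate stimulators at the step's start time;
4. integrate all neurons with the summed synaptic and injected currents;
5. enqueue the step's fires, each edge with a delivery offset of
   `max(1, round(delay / dt))` steps;
6. update sensors.

The ordering is observable only at $O(dt)$, but fixing it (and processing
simultaneous fires in ascending node order) makes runs bit-reproducible: an
identical network and `sim_config()` — including the seed, which governs a
single global random stream consumed in deterministic node order — yields
an identical recording, which the suite asserts with `identical()`.
Delivery offsets have a floor of one step, so causality (no effect at or
before the cause's step) holds for every edge, including zero-delay ones.

**Trace semantics.** The state at $t = 0$ is recorded before the first
step, so traces have `n_steps + 1` samples. The recorded voltage of a step
is the post-Euler, post-clamp, *pre-reset* value: an ordinary spiking trace
therefore touches threshold (never more than one Euler increment above it)
before snapping to $V_\text{reset}$, while a saturating input shows the
clamp bound itself. Spikes are recorded as event times, not as voltage
excursions — the action potential is not part of the membrane dynamics.

**Refractory semantics.** During $\tau_r$ the membrane is pinned at
$V_\text{reset}$ and integration is suspended, but synaptic currents and
the adaptation conductance keep decaying. Together with the one-step
delivery floor this guarantees every inter-spike interval is at least
$\tau_r + dt$.

Degenerate configurations fail loudly: `dt >= tau_syn` or
`dt >= tau_adapt` is rejected as an unstable Euler step before the run
starts, and a non-finite membrane potential aborts the run naming the
offending node.

## Default parameters

The defaults describe a generic cortical-style cell and are deliberately
round; every one can be overridden per node or per edge, in code or in the
JSON document.

| parameter | default | unit | rationale |
|---|---|---|---|
| `Rm` | 1e8 | ohm | 100 M$\Omega$ input resistance |
| `Cm` | 1e-9 | F | gives $\tau_m = R_m C_m = 100$ ms |
| `Vr`, `Vreset` | -0.065 | V | reset at rest |
| `Vthres` | -0.050 | V | 15 mV threshold gap |
| `tau_r` | 0.002 | s | typical absolute refractory period |
| `tau_syn` | 0.010 | s | fast current-based synapse |
| `peak_current` | 1e-9 | A | ~7.7 mV EPSP: several inputs needed to fire |
| `tau_adapt` | 0.250 | s | slow adaptation, spans several ISIs |
| `delta_g_adapt` | 1e-9 | S | ~10% rate reduction over a few spikes |
| `dt` | 1e-4 | s | $\tau_m / 1000$; f–I error ~0.03% |

Units are strict SI everywhere inside the package; millivolts and
milliseconds appear only in reports and documentation. The spike-threshold
demonstration circuit (`build_threshold_demo()`) is the one deliberate
exception to the resting potential: it uses an artificial $V_r = 0$ so the
classic textbook figure reads directly in millivolts above zero.

## Stimulators

DC and AC sources inject current directly into $I_\text{inj}$; they never
enter the spike queue. The AC source is
$A \sin(2\pi f t)$ with phase fixed at 0 and no offset. The regular
generator accumulates elapsed time and fires when it exceeds $1/\text{rate}$,
then resets its accumulator — so a 10 Hz generator at `dt = 1e-4` s
produces 9–10 spikes per second with ISIs constant to within one step, and
`rate = 0` is legal and silent.

The Poisson generator draws an independent Bernoulli variable with
$p = \text{rate} \cdot dt$ every step. This per-step construction has a
bias of order $\text{rate} \cdot dt$ relative to an exact exponential-
waiting-time process; the package warns above $p = 0.1$ and refuses
$p > 1$. At the default step a 100 Hz generator has $p = 0.01$: its ISI
coefficient of variation is $\sqrt{1 - p} \approx 0.995$, comfortably
inside the $1.00 \pm 0.05$ band the tests assert.

Touch input is headless here: an `event_source` carries a pre-declared
schedule of activation times, fires in the step whose half-open bin
$(t - dt, t]$ contains an activation (multiple activations in one bin
coalesce), and reaches its targets through an ordinary synapse. We chose
the synaptic route rather than forcing the target to fire because the
touch-gated inhibition circuit depends on inhibition being able to veto a
touch-driven spike — forced firing would make that impossible.

## Receptive fields

The visual-input node is a spike generator whose rate follows the
instantaneous inner product between a spatial kernel and a grayscale frame
(no temporal kernel; the response at $t$ depends only on the frame at $t$).
Three kernels are provided:

* **edge**: +1/-1 on two equal rectangular half-planes of the rotated
  axis; exactly zero-sum on even grids, within one pixel row on odd ones;
* **DoG**: difference of two isotropic Gaussians, *each normalized to unit
  discrete sum*, so the kernel is balanced and a uniform image yields a
  response of zero by construction (the OFF-center kernel is the ON-center
  kernel negated);
* **Gabor**: oriented Gaussian envelope times a cosine carrier with the
  standard five parameters. Its discrete integral is only approximately
  zero, with a residual DC response orders of magnitude below any grating
  response.

Responses are divided by the pixel count so that a gain chosen on a 16x16
grid means the same firing rate on a 64x64 grid. Spike conversion is
half-wave-rectified Bernoulli, $p = \min(1, \max(0, r)\,g\,dt)$, mirroring
the Poisson generator's construction; we considered a deterministic
regular-spiking alternative and left it out — a second conversion rule
doubles the configuration surface without changing anything the circuits
demonstrate.

## Sensors

The firing-rate meter places a *normalized* Gaussian of width
$\sigma_w$ at every spike (unit time-integral per spike, so a regular
$f$ Hz train reads $f$ Hz — the alternative, an unnormalized window, would
make the reading depend on $\sigma_w$) and averages — not sums — over the
connected neurons. The kernel is truncated at $\pm 5\sigma_w$; the
discarded mass is below $10^{-6}$ per spike. Since the window is symmetric
in time, the engine computes rate traces after the run from the recorded
spike trains; the values are identical to an on-line evaluation at the end
of the run. `rate_min`/`rate_max` are display bounds only and never clip
stored values.

Voltmeter rows and spike-raster rows are named by the node's label when one
is present, falling back to the id, and the raster supports a trailing
window. CSV writers emit one wide file for voltages, a two-column
(node, time) file for spikes, and one column per meter for rates.

## File format

Networks serialize to a four-key JSON envelope — `fileFormatVersion`
(integer 3), `edges`, `nodes`, `workspace` — with a canonical layout:
fixed key order, alphabetical property names, and only the properties that
differ from each kind's defaults (defaults fill omissions on load), so
`save -> load -> save` is byte-identical and saved files diff cleanly.
The property vocabulary is this package's own documented schema
(`inst/extdata/network-schema.json`), using snake_case names mirroring the
constructors; no byte-compatibility with any other tool's save files is
claimed. Versions other than 3 are rejected outright with an error naming
the found and supported versions — never silently misread. The `workspace`
object is free-form metadata: it is preserved verbatim across round trips,
ignored by the engine, and tagged with `"units": "SI"` on save.

## Reference circuits and their calibration

The five motif builders encode classic circuit motifs as testable
experiments. No published parameter values exist for them, so all weights
are implementer-chosen named constants (see `R/motifs.R`), calibrated once
against the closed-form EPSP peak: with the default membrane, a synaptic
transient of peak $I$ produces a depolarization of about
$I \times 7.7\times 10^6$ V/A. The load-bearing choices:

* **Touch transients** use a 2 ms synaptic time constant with a ~25 mV
  peak. A strong kick with the default 10 ms constant would leave enough
  residual current after the refractory hold to re-fire the target,
  turning one touch into a burst; the brief transient decays below the
  re-fire level first, giving the intended one activation, one spike.
* **Summation** weights (1e-9 A, ~7.7 mV) make one input subthreshold
  against the 15 mV gap and three near-simultaneous inputs suprathreshold.
* **Relay** weights (3e-9 A, ~23 mV) give reliable one-to-one
  transmission.
* **Direction selectivity**: relay-to-output weights (1.7e-9 A, ~13 mV)
  need two relay spikes within the 0.1 s sweep interval to fire the
  output, and the one-sided lateral inhibition (6e-9 A) still cancels a
  23 mV excitation arriving 0.1 s later. In the preferred (right-to-left)
  direction each inhibitory volley lands on a relay that has already
  fired; in the null direction it arrives just in time, so the output
  stays silent and the selectivity index is exactly 1.

Each contract has a dedicated test, and the spike counts of the default
builds are verified to be invariant under halving `dt`.

## What the tests do and do not show

All fixtures are generated in code under fixed seeds; there are no external
datasets. The study conditions are: default parameters as tabled above,
runs of 0.3–2 s at `dt = 1e-4` s for circuit behavior, 100 s x 5 seeds for
Poisson statistics, and 64x64 grids for receptive-field tuning. Passing
tests show that the *model* behaves as its equations and the closed-form
oracles predict under these conditions. They do not show that the
parameters fit any particular biological cell, that the motifs' behavior is
robust to heterogeneous parameters or background noise (every neuron in a
motif is identical and noiseless unless a generator is attached), or that
the first-order integrator is adequate for stiff regimes far from the
defaults.

Known limitations, deliberate and inherited from the model class: no
synaptic plasticity, no conductance-based synapses, no
Izhikevich/AdEx/Hodgkin–Huxley dynamics, no temporal receptive-field
component, no audio output (the loudspeaker concept is at most an event
hook), and no interactive/real-time stepping — runs are batch only.

## A complete round trip

```{r roundtrip, eval = FALSE}
net <- build_direction_selective(n_columns = 4, sweep = "right_to_left")
save_network(net, "ds.json")
rec <- run_network(load_network("ds.json"),
                   sim_config(duration = 0.85, seed = 1))
length(rec$spikes[[node_by_label(net, "output")]])  # >= 1 preferred-direction spikes
```
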