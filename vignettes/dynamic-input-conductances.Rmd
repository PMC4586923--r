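---
title: "Timescale decomposition of neuronal excitability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Timescale decomposition of neuronal excitability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model class and the quantity being computed

A conductance-based neuron model couples the membrane equation

$$C\,\dot V = -\sum_i \bar g_i\, m_i^{p_i} h_i^{q_i} (V - V_i)
  \;-\; g_L (V - E_L) \;+\; I_{app}$$

to first-order gating kinetics
$\tau_X(V)\,\dot X = X_\infty(V) - X$ for every activation and inactivation
variable, and (in calcium-gated cells) to an intracellular calcium pool
$\tau_{Ca}\,\dot{Ca} = -f \sum I_{Ca} - Ca + Ca_0$. Units are fixed
globally: mV, ms, mS/cm², µA/cm², µF/cm², µM.

The firing pattern of such a cell is a sequence of events in a few
characteristic timescales — the fast spike upstroke, the slow downstroke
and interspike interval, and (in bursters) an ultraslow adaptation and
interburst rhythm. The package reduces the local sensitivity structure of
the whole model to three voltage-dependent *dynamic input conductances*,
one per timescale:

$$g_j(V) \;=\; -\sum_{X}\; w_j^{X}(V)\,
  \frac{\partial I_{tot}}{\partial X}\,
  \frac{\partial X_\infty}{\partial V}, \qquad j \in \{f, s, u\},$$

evaluated at gating steady state, with
$g_f + g_s + g_u = g = -\,\partial I/\partial V$ the static input
conductance. Positive values are regenerative (positive feedback) in their
timescale, negative values restorative. The leak is excluded: its response
is instantaneous compared to any gating kinetics, so it shapes no dynamic
feedback loop. Capacitance is factored out, so every curve carries
conductance units.

Two sign conventions circulate for these quantities (the derivative of the
current, or its negative); this package uses $g = -\partial I/\partial V$
throughout, which makes the sodium-activation pathway positive — the
regenerative upstroke — and the delayed-rectifier pathway negative. The
simulated voltage clamp uses the matching convention
$g_j = -\Delta I_j/\Delta V$, so the two routes are directly comparable.

## Timescale references and weights

Three reference time constants anchor the decomposition
(`reference_timescales()`): $\tau_f(V)$, the activation time constant of
the fastest depolarizing current; $\tau_s(V)$, the activation time constant
of the fastest repolarizing current (the kinetics limiting fast spiking);
and $\tau_u(V)$, the time constant of the slowest gating variable. For the
bundled STG cell these are sodium activation, delayed-rectifier activation
and slow-calcium inactivation, and the same designations emerge from the
automatic rule. A model whose slowest gate is not separated from $\tau_s$
(geometric-mean ratio below 5 — the Hodgkin–Huxley cell) is treated as a
two-timescale model: no ultraslow reference, $g_u \equiv 0$.

Each variable's influence is split across timescales by logarithmic
distance between its $\tau_X(V)$ and the references: the weights are
piecewise log-linear,

$$w_{fs} = \mathrm{clamp}\!\left(
  \frac{\ln \tau_s - \ln \tau_X}{\ln \tau_s - \ln \tau_f}\right),\qquad
  w_{su} = \mathrm{clamp}\!\left(
  \frac{\ln \tau_u - \ln \tau_X}{\ln \tau_u - \ln \tau_s}\right),$$

and the three shares $w_{fs},\, w_{su} - w_{fs},\, 1 - w_{su}$ form a
non-negative partition of unity. This is the unique continuous rule that is
linear in $\ln \tau$, equals 1/0 at the flanking references, and clamps
sharply outside them; smoothing near the references would be an equally
defensible choice but was not adopted, and the sharp variant is what every
test and the acceptance analysis use. The intracellular calcium
concentration is treated as one more state variable with constant
$\tau_{Ca}$; with the STG constants it lands almost wholly in the ultraslow
timescale, and `dic_curves()` warns if a model's pool constant would place
appreciable calcium weight elsewhere.

A calcium-dependent gate (the K,Ca activation) contributes through two
pathways: its direct voltage dependence, weighted at its own $\tau_m$, and
an indirect pathway through $Ca_\infty(V)$, weighted at $\tau_{Ca}$
(ultraslow). This reproduces the ultraslow dynamical role of intracellular
calcium while keeping the decomposition additive per channel.

## The simulated voltage clamp

`run_clamp_step()` equilibrates the cell at a holding potential (the
analytic steady state; a simulated hold with a convergence flag is
available), applies a step $\Delta V$ (default 1 mV), and records the total
transmembrane current with V algebraically clamped. `extract_clamp()` reads
three values from the transient: the minimum within 2 ms of onset
($I_f$), the minimum between 10 and 100 ms ($I_s$; if the window has no
interior minimum the amplitude at 10 ms is taken and flagged), and the
minimal amplitude from 1 s to the end ($I_u$). The dynamic currents
telescope ($\Delta I_f = I_f - I_0$, $\Delta I_s = I_s - I_f$,
$\Delta I_u = I_u - I_s$), and $g_j(V^* + \Delta V/2) = -\Delta I_j/\Delta V$.
$I_0$ is the first sample *after* the step, so the instantaneous ohmic jump
through already-open channels is excluded — consistent with excluding the
passive membrane from the analytic curves.

Two-timescale models use the classical two-window readout instead (fast
minimum, then the steady-state current), since the 10 ms boundary would
otherwise split their slow transient and assign its tail to a nonexistent
ultraslow current.

Protocol defaults: step duration 5 s (the ultraslow window needs > 1 s),
sampling 0.05 ms up to 10 ms and 1 ms beyond, holds spanning the
subthreshold range (−75…−35 mV for the STG cell, −90…−70 mV for
Hodgkin–Huxley). The window protocol has an irreducible systematic error of
order (slow amplitude)/(timescale separation): near threshold the squid
axon separates $\tau_m$ from $\tau_h, \tau_n$ by barely a factor 20, and
the slow drift eats into the fast-window dip, so measured $g_f$ is biased
low there by roughly $|g_s| \cdot t_{min}/\tau_s$. The subthreshold hold
ranges keep this bias inside the comparison tolerance; the bias analysis is
why the defaults stop where they do.

## Voltage markers

Two potentials anchor the sensitivity analysis. The *up-state* $V_{osc}$ is
the most depolarized zero of the steady-state I/V curve at the reference
applied current — the unstable equilibrium around which intra-burst spikes
oscillate. The *spike threshold* $V_{th}$ is the potential of maximal
sensitivity, operationalized as a codimension-one degenerate equilibrium:
the maximal conductance of a calcium current (slow calcium by default) is
scaled until the steady-state I/V relation develops a double zero
($F = 0$, $\partial F/\partial V = 0$), found by bracketing the change in
equilibrium count over the scaling and polishing with a damped 2-D Newton
iteration (residuals below 1e-6 in native units; roots refined well below
the 0.1 mV bracketing grid, so the result does not depend on the grid).

Both markers are computed by default on the I/V curve with the calcium pool
held at its baseline concentration rather than at $Ca_\infty(V)$
(`calcium = "steady"` gives the fully equilibrated curve). The rationale:
these markers describe the fast–slow excitability structure, and the
voltage excursions they organize are too fast to recruit the ultraslow
calcium feedback, so the pool enters as a frozen parameter. The fully
equilibrated curve is dominated at depolarized potentials by the
calcium-activated potassium current and places the most depolarized zero
tens of mV away from the up-state the bursting trajectory actually orbits.
`static_iv()` itself reports the fully equilibrated curve — that is what a
long clamp step measures. The applied current is held at the reference
value during the threshold sweep.

## Sensitivities and compensation

`sensitivity_curves()` differentiates each dynamic input conductance with
respect to one maximal conductance. Because the curves are linear in every
$\bar g_i$ at a fixed calcium reference, the sensitivity is the per-unit
pathway term — independent of $\bar g_i$ itself — and matches central
finite differences of `dic_curves()` to first-order-exact accuracy. The
*frozen-calcium convention* applies throughout: the reference cell's
$Ca_\infty(V)$ is treated as fixed, so the indirect dependence of the K,Ca
channel on the calcium conductances is excluded from the calcium channels'
curves (the K,Ca channel's own curves keep the calcium pathway, which is
linear in its density). The residual this convention leaves when a calcium
density actually changes is measured and reported
(`residuals_full`), never hidden.

The compensation mechanism (`compensate()`) preserves four scalars chosen
on the reference cell: $g_s(V_{th})$, $g_s(V_{osc})$, $g_u(V_{th})$ and the
net static current at threshold. For a perturbed calcium density it solves
the 4×4 linear system $Ax = b$ for
$x = (I_{app}, \bar g_{K,d}, \bar g_A, \bar g_{K,Ca})$, with $A$ the
sensitivity values of the compensating parameters at the markers and $b$
the targets minus the fixed channels' (and leak's) contributions. Markers
and targets are computed once on the reference cell and held fixed across
perturbations; sodium is excluded from the compensating set because the
calcium channels barely touch the fast timescale. The solve is a direct
dense solve with a condition-number report (error above 1e10); no
non-negativity constraint is imposed — a negative solved conductance is a
finding about the cell's compensation capacity, flagged nonphysiological.
A three-unknown variant (`use_iapp = FALSE`) drops the static row for
users who want to probe compensation without current injection. Because
everything is linear at frozen calcium, each solution component is an
affine function of the perturbed density, and re-evaluating the four
quantities through the conductance machinery reproduces the targets to
solver round-off.

## The bundled fixtures and what they emulate

The fixtures are the package's study conditions, not random data: the
method itself is deterministic.

**STG cell** (`make_stg()`): a six-current crustacean stomatogastric
burster — Na, T-type and slow calcium, A-type, delayed-rectifier and
calcium-activated potassium — with kinetics transcribed from the
source-model lineage into `inst/extdata/stg_kinetics.yaml`, the single
reviewable transcription in the package. Reference densities (mS/cm²):
Na 700, Ca,T 2, Ca,S 4, A 50, K,d 70, K,Ca 40; calcium reversal fixed at
+120 mV; leak 0.01 mS/cm² at −50 mV; C = 1 µF/cm². The calcium pool uses
$\tau_{Ca} = 200$ ms, $Ca_0 = 0.05$ µM and a conversion of 9.4 µM per
µA/cm² (14.96 µM/nA over the 0.628·10⁻³ cm² membrane of the source cell).
The cell bursts spontaneously, so the reference applied current is 0. Two
derived conditions used by the tests: at a low slow-calcium density
($\bar g_{Ca,S} = 2$) the intraburst inter-spike intervals grow
monotonically; at a high density ($\bar g_{Ca,S} = 8$) they first shrink,
then grow — parabolic bursting driven by the localized ultraslow positive
feedback of the slow calcium channel at threshold.

**Hodgkin–Huxley** (`make_hh()`): the canonical squid-axon model (modern
convention, rest near −65 mV), the two-timescale validation case.

**Toys** (`make_toy()`): a passive membrane, a single-gate cell with
constant time constant (closed-form clamp response), and a minimal
fast/slow pair — the oracle instances for the unit tests.

What the fixtures do not emulate: channel noise, temperature dependence,
morphology, synaptic input, and measurement noise in clamp recordings.
Tests passing on these fixtures show the machinery is faithful to the
deterministic model class; they say nothing about estimating these curves
from noisy biological recordings, which the clamp module deliberately does
not attempt (traces can be imported, but no noise-robust estimation is
provided).

## Numerical choices

* Integration: `deSolve::ode` (lsoda), relative tolerance 1e-8 for free
  simulation, 1e-10 for clamped gating; failures raise an error naming the
  time of the stiff segment.
* Steady-state gating derivatives $dX_\infty/dV$: central differences with
  step 1e-3 mV (second-order; the curves are smooth sigmoids, so the
  truncation error is ~1e-8 of curve scale). The calcium chain rule uses
  the same scheme in V through $Ca_\infty(V)$.
* Curve grids: working range −80…+50 mV at 0.1 mV for all curve
  operations; roots and degenerate points are refined by bisection/Newton
  far below the grid.
* Spike detection: upward 0 mV crossings with 2 ms refractory tie-break;
  burst gap 5× the median inter-spike interval. These affect reporting
  only, never the method.
* Problem sizes in the test suite: bursting simulations run 6.5–12 s of
  model time (several burst cycles at the ~1.15 s reference period), clamp
  validation uses 17 STG and 11 HH holds with 5 s steps, and the weight
  property test draws 10⁴ random timescale triplets.

## Known limitations

* The fivefold slow-calcium *increase* is compensated exactly in the four
  preserved quantities, but the solved delayed-rectifier density crosses
  zero beyond roughly a 2.7-fold increase, and the rebuilt (nonphysiological)
  cell does not burst — its simulation diverges. The chain is intrinsic to
  the linear mechanism under this transcription: the calcium channels'
  slow-timescale sensitivity at threshold is ~19× the A-current's, so the
  A-density must rise steeply; the A-inactivation's ultraslow share then
  demands a large K,Ca increase, whose slow-timescale cost at the up-state
  is comparable per unit to the delayed rectifier's and drives it negative.
  The outcome is sensitive to the calcium pool conversion factor (a probe
  shows the solution stays positive for conversions about twice the
  transcribed value), which the source literature does not pin down in
  area-normalized units. Compensation demonstrably preserves bursting at
  0.5× and 2×, and the co-variation directions (K,Ca up, K,d down, A up)
  hold throughout.
* The clamp windows assume the model's slow kinetics are essentially
  settled by 10 ms and its ultraslow kinetics barely started by 100 ms;
  models outside that regime (or holds where separation collapses) incur
  the systematic errors analyzed above.
* Colocalization of sensitivity ranges is scored two ways
  (`overlap_score()`): the cosine of the curves and the distance between
  their peak potentials. For the A-type/slow-calcium/T-type triple the
  cosine is non-discriminative after the +4.5 mV A-shift (both pairs score
  ≈0.95 because the shifted curve remains highly similar to both), while
  the peak distance separates them cleanly; the swap test uses the peak
  score and the reference ordering uses the cosine.
* Sensitivities are available with respect to maximal conductances and
  activation shifts only; other parameters (half-activations, calcium
  handling) would need new pathway terms.
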