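# dicurves

Dynamic input conductance analysis of conductance-based neuron models.

Neuronal firing emerges from many ion channels whose gating spans a wide
range of voltage dependences and timescales, and the same firing pattern can
be produced by very different channel-density combinations. `dicurves`
reduces this complexity to three voltage-dependent curves — the **dynamic
input conductances** — that aggregate every channel's contribution to each
timescale of the activity: fast (spike upstroke), slow (downstroke and
interspike interval) and ultraslow (adaptation and interburst rhythm). For a
model with state variables $X_i$,

$$g_j(V) = -\sum_i w_j^{X_i}(V)\,
  \frac{\partial I}{\partial X_i}\frac{\partial X_{i,\infty}}{\partial V},
  \qquad j \in \{f, s, u\},\qquad g_f + g_s + g_u = g = -\frac{\partial I}{\partial V},$$

where the weights $w_j^{X_i}(V)$ split each variable's influence across
timescales by the logarithmic distance of its time constant from the fast,
slow and ultraslow references. Positive values are regenerative feedback in
that timescale, negative values restorative. On top of the decomposition the
package provides:

* a **simulated voltage-clamp protocol** that measures the same curves from
  the current transient after a small step ($g_j = -\Delta I_j/\Delta V$),
  with the three-window extraction for bursters and the classical two-window
  readout for spiking models;
* **voltage markers**: spike threshold $V_{th}$ (a degenerate-equilibrium
  point of the static I/V relation under a calcium-conductance sweep) and
  up-state $V_{osc}$ (most depolarized zero of the I/V curve);
* per-channel **sensitivity curves** $\partial g_{f,s,u}/\partial \bar g_i$
  and their colocalization along the voltage axis;
* the linear **compensation mechanism**: given a perturbed calcium-channel
  density, solve $Ax = b$ for $(I_{app}, \bar g_{K,d}, \bar g_A,
  \bar g_{K,Ca})$ so that $g_s(V_{th})$, $g_s(V_{osc})$, $g_u(V_{th})$ and
  the static current at threshold are preserved;
* fixtures: a six-current **STG burster** (printed reference densities,
  calcium reversal +120 mV), the classical **Hodgkin–Huxley** model, and
  analytic toys; declarative YAML model configs round-trip through
  `read_model_config()`/`write_model_config()`.

It is aimed at computational neuroscientists studying neuromodulation,
channel degeneracy and homeostatic compensation in conductance-based models.

## Worked example

```r
library(dicurves)

stg <- make_stg()          # reference six-current burster
mk  <- voltage_markers(stg)
dic_at(stg, mk$v_th)       # conductances at spike threshold
tg  <- make_targets(stg)
compensate(stg, "CaS", 8, tg)  # double the slow calcium density
```

```
V_th  = -50.37 mV   V_osc = -18.75 mV
    g_f     g_s     g_u g_total
 0.0155  0.0115  0.0003  0.0273
Compensation for CaS: 4 -> 8 mS/cm2
   i_app       Kd        A      KCa
 -0.0018  14.1938 125.8260  91.0264
  max |residual| (frozen Ca): 1.39e-17; (full): 0.116
  condition number: 1.21e+04
```

Reading this: the spike threshold of the reference cell sits near −50 mV and
the up-state near −19 mV. At threshold the slow conductance is *positive*
(+0.0115 mS/cm²) — the localized slow positive feedback that makes the cell
a burster. Doubling the slow-calcium density would normally reshape that
feedback; the solved compensation absorbs it by raising the A-type density
from 50 to 125.8 mS/cm² and the calcium-activated potassium density from 40
to 91.0 mS/cm² while dropping the delayed rectifier from 70 to
14.2 mS/cm², leaving all four preserved quantities at their reference values
to machine precision (the `full` residual is the measured cost of treating
the calcium pool as frozen during the solve).

`dic_curves()`, `measure_dics()`, `sensitivity_table()` and
`compensation_path()` give the corresponding whole-curve and whole-path
views; `simulate_model()` + `trace_statistics()` verify firing patterns. A
thin command-line front end lives at `inst/cli/dicurves`.

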