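---
title: "A closed-loop 0D-1D model of cardiovascular deconditioning in weightlessness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A closed-loop 0D-1D model of cardiovascular deconditioning in weightlessness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`cardiodecon` simulates the human circulation as a closed loop that couples
two descriptions of vascular mechanics:

* **1D arterial tree.** The large systemic arteries are one-dimensional
  distensible vessels governed by the cross-sectionally averaged mass and
  momentum balances
  \[
  \partial_t A + \partial_x Q = 0, \qquad
  \partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x p = -\,k_f\,\frac{Q}{A},
  \]
  with a Poiseuille-type dissipation term
  \(k_f = 2\pi(\zeta + 2)\mu/\rho\) (velocity-profile coefficient
  \(\zeta = 9\)), closed by a nonlinear viscoelastic tube law for the
  tapered wall,
  \[
  p = p_\mathrm{ext} + \frac{\beta(x)}{A_0(x)}\left(\sqrt{A} -
  \sqrt{A_0}\right) + \gamma(x)\,\partial_t A .
  \]
  The elastic coefficient is parameterized by the unstressed wave speed
  \(c_0\) through \(\beta = 2\rho\sqrt{A_0}\,c_0^2/k\) (with \(k\) the
  mmHg-to-CGS conversion), so the local wave speed is
  \(c = c_0 (A/A_0)^{1/4}\); \(\gamma\) is a Kelvin-Voigt wall viscosity.
* **0D compartments.** Arterioles, capillaries, venules, veins, venae
  cavae and the pulmonary circulation are lumped RLC elements obeying
  \(V = V_0 + C\,P\), with resistive (optionally inertial or
  flow-rectifying) outlets.
* **Heart.** All four chambers are contractile:
  \(P = E(t)\,(V - V_0)\) with \(E(t) = E_\mathrm{min} +
  E_\mathrm{amp}\,e(t/RR)\), where the normalized activation \(e\) is a
  raised-cosine pulse rising to 1 and returning to 0 within the beat. The
  atria activate in late diastole (onset at 85% of the beat), producing the
  atrial kick. Ventricles additionally carry an internal (source)
  resistance in series with their outflow valve, the standard
  flow-dependent pressure loss of elastance chambers during ejection.
* **Valves.** The opening fraction \(\xi \in [0,1]\) of each valve obeys a
  second-order dynamics driven by four effects: the transvalvular pressure
  difference and the dynamic motion of the blood on the leaflet (both with
  a lever arm \(\cos(\xi\pi/2)\) that vanishes at full opening), tissue
  friction damping, and a vortex term promoting closure under reverse
  flow. Flow through the open valve follows a semi-implicit RL law with
  effective resistance \(R_\mathrm{open}/\xi^2\); a closed valve passes
  exactly zero flow.
* **Baroreflex.** The afferent pressure is the average of the aortic root
  and carotid sinus pressures, low-pass filtered (\(\tau = 8\) s). Five
  effector multipliers (heart rate, ventricular elastance amplitude,
  peripheral arteriolar resistance, venous unstressed volume, venous
  compliance) relax with first-order lags towards sigmoidal static curves
  \(1 \pm G \tanh((P_\mathrm{set} - p)/S)\); all equal 1 at the setpoint,
  and the signs implement negative feedback.

### Interfaces and numerics

The domains are joined at two points: the **aortic valve** feeds the
ascending-aorta inlet (the valve RL law and the incoming Riemann invariant
are solved simultaneously each step; an explicitly staggered coupling is
unstable whenever the open-valve resistance is below the root
characteristic impedance), and each **terminal artery** couples to its
arteriolar bed through a characteristic impedance \(Z_c = \rho c/(A k)\)
plus an arteriolar access resistance in series.

The 1D equations are advanced by a two-step Lax-Wendroff (Richtmyer)
finite-volume scheme on a uniform per-segment grid
(\(\Delta x \le 0.25\) cm). Because boundary, junction and terminal faces
are closed with characteristic solves and used as face fluxes, the
discrete mass balance telescopes: whole-loop blood volume is conserved to
near machine precision (measured drift \(<10^{-13}\) per beat). Junctions
enforce mass conservation and total-pressure continuity via a Newton
iteration on the interface areas (mass residual below \(10^{-10}\) ml/s).
The viscoelastic wall term is applied by operator splitting as an implicit
diffusion in \(Q\); a curvature-sensor-scaled dissipative flux suppresses
grid-scale oscillations at steep fronts while leaving smooth pulses
untouched (measured convergence order \(\ge 2\)). The time step derives
from the CFL condition with a 200 cm/s velocity headroom; the core checks
\(\Delta t \le \Delta x/(|u|+c)\) every step and aborts (rather than
clamps) on violation or on collapse (\(A \le 0\)), since either signals a
parameterization error. The 0D network shares the global time step with
explicit staggered coupling; valve flows use semi-implicit updates. The
first three beats ramp the activation amplitude (and any prescribed
inflow) to avoid an unphysical cold-start transient; the steady state is
unaffected.

A 100-beat run at the default resolution takes on the order of a minute on
one core; transients are extinguished well before beat 100 (the
beat-to-beat relative L2 metric at the ascending aorta falls below
\(10^{-3}\), typically to a few \(10^{-4}\)).

## The supine baseline

The packaged 1g-supine network (`baseline_network_1g()`, serialized as
`inst/extdata/baseline_1g_supine.yaml`) is a reduced 28-segment arterial
tree covering the reporting sites of the analysis layer (aortic trunk,
carotid/vertebral/brachial branches, intercostal, celiac, gastric,
hepatosplenic, renal, mesenteric beds, pelvic and leg arteries down to the
tibials, with lumped right-side trunks), 16 terminal arteriolar beds, a
lumped venous return split at the volume indifference point (VIP) into
upper body (head-arms and thoracic venous return, SVC) and lower body
(abdominal and leg venous return, IVC), the pulmonary circulation, and the
four-chamber heart.

Because the full segment list and parameter values of a subject-specific
tree are not part of this package, the baseline is **calibrated**, not
transcribed: terminal access resistances and arteriolar outlet resistances
are derived in closed form from a target mean operating point (normal
supine adult: heart rate 75 bpm, cardiac output ~5.3 l/min, mean aortic
pressure ~93 mmHg, regional flow fractions and arteriolar/venous pressures
of the normal supine circulation), and compliances/unstressed volumes set
a ~5 l, predominantly venous, blood volume distribution. Wave speeds rise
from ~5.6 m/s at the aortic root to ~7-8 m/s in the leg arteries — the
lower end of the physiological range, chosen because a reduced tree lacks
the side branches that disperse the pressure pulse, and stiffer distal
vessels over-amplify peripheral pulse pressure. The baroreflex setpoint
equals the model's own 1g afferent equilibrium, so all effector
multipliers are 1 in the baseline steady state. Wherever a published mean
value exists for a site retained in the reduced tree, the calibrated
steady state reproduces it closely (central beat-averaged pressures within
~1 mmHg); the simulator's purpose is the *paired* comparison below, for
which both configurations share whatever bias the reduction introduces.

## The weightlessness configurator

`configure_0g()` transforms a 1g network into the long-term 0g adaptation
point by applying, in order:

1. **Blood shift** (zero-sum, ml): legs −235, lower abdomen −234,
   head-arms +133, cardiac-thoracic +202, upper abdomen +134. Within each
   region every zone's volume scales proportionally to its 1g share, and
   unstressed volumes rescale so \(V_0/V\) is preserved exactly. The
   alternative within-region weighting by distensibility and VIP distance
   is treated as the provenance of the regional totals, not as a second
   allocation rule; only the proportional rule is implemented, because the
   data the alternative weighting needs are not available to the package.
2. **Total volume reduction** by 11.5%: every zone scales by 0.885,
   again preserving \(V_0/V\).
3. **Cardiac changes**: ventricular elastance amplitudes ×0.73, minima
   ×1.03, pulmonary artery compliance ×1.04, pulmonary vein compliance
   ×1.05, all four chamber unstressed volumes ×0.10.
4. **Vascular changes**: leg venous compliance ×1.27; arteriolar
   resistances ×1.10 in the carotid and vertebral territories and ×0.90 in
   every lower-body territory. Characteristic impedances (wall properties)
   are untouched, and the ±10% is not applied to the 1D friction term —
   the change set names *arterial resistances*, which live in the terminal
   beds.
5. **Baroreflex re-baselining**: baseline heart rate ×1.13 and setpoint
   ×0.90; gains and time constants unchanged (long-term adaptation is a
   new operating point, not a change in reflex dynamics).

1D segments participate in shift and reduction through their lumen: radii
scale with \(\sqrt{f}\) so the vessel volume at any pressure scales by
exactly \(f\), while the unstressed wave speed (wall stiffness) is
preserved. Region membership where ambiguous: SVC is cardiac-thoracic,
IVC lower-abdomen, the intercostal bed cardiac-thoracic, the
celiac/gastric/hepatosplenic/renal beds upper-abdomen, the
mesenteric/pelvic beds lower-abdomen. The transform is deterministic,
order-enforced (reduction before shift is an error), idempotent-guarded,
and emits a complete before/after change report.

## Analysis layer

Beat statistics use trapezoidal quadrature on a 1000-point resampled grid;
standard deviations use the population (1/N) form. The waveform metric is
the normalized signal difference
\[
\mathrm{NSD} = \int_0^1 \left| y'_{1G}(t') - y'_{0G}(t') \right| \mathrm{d}t',
\qquad y' = (y - \mu_y)/\sigma_y,\; t' = t/RR \in [0,1],
\]
which is symmetric, lies in \([0, 2]\) (0 for overlapping shapes, 2 only
for complementary centred steps), and is bounded by
\(\sqrt{2(1-\rho)}\) with \(\rho\) the Pearson correlation of the
normalized beats. Cardiac indexes follow their textbook definitions;
systole for the tension-time index is the aortic-valve-open interval from
the valve model (internally exact, not a pressure-threshold heuristic);
stroke work is the shoelace area of the LV pressure-volume loop; CVP is
the mean of the beat-averaged SVC and IVC pressures; the augmentation
index locates the systolic inflection as the zero crossing of the smoothed
second derivative nearest the pressure peak within a configurable systolic
window (no standard algorithm exists; AI is by far the most
algorithm-sensitive index reported).

## What the fixtures emulate — and what they do not

`generate_fixture()` builds three analytic configurations: a single tube
terminated by a Windkessel (steady mean pressure \(\bar Q(Z+R) +
P_\mathrm{out}\)), a two-compartment closed ring (exact volume
conservation), and a mini-tree whose steady flows split as the inverse
terminal resistances. The test-suite verifies the numerical building
blocks against closed forms on these fixtures (RC decay, wave speed,
reflection coefficients, friction pressure drop, convergence order). These
fixtures — and the reduced baseline itself — emulate wave propagation and
volume redistribution, not microcirculatory autoregulation, gravity
gradients (there is no explicit gravity force term; weightlessness enters
only through the adaptation change set), interstitial fluid exchange, or
anatomical variability. Passing tests therefore certify the numerics and
the configurator mechanics, not subject-specific prediction.

## Design choices and limitations

* **Valve closure volume.** The dynamic valves close in finite time, so
  ~2% of the stroke volume regurgitates at closure (physiological). The
  LV-excursion stroke volume therefore exceeds the net ejected volume by
  that amount; net mitral and aortic throughputs per steady beat agree to
  <0.5%.
* **Paired-comparison fidelity.** With the independently calibrated
  baseline, the 0g-vs-1g relative variations reproduce the direction of
  every cardiac index (SV, EF, CO, MAP, pulse pressure, stroke work,
  tension-time index, rate-pressure product and CVP fall; end-systolic LV
  volume rises; heart rate rises by ~14%) and the spatial patterns
  (waveform alteration grows from proximal to distal sites and is larger
  for flow than for pressure). Magnitudes of the pressure-side variations
  agree within ~2 percentage points; the systolic cluster (SV, EF, CO,
  stroke work) declines ~5 pp more than the published figures — the
  reduced venous network mobilizes less reserve volume than the source
  model.
* **Pulmonary volumes.** Within \(V = V_0 + CP\), the near-cancellation
  of the thoracic blood shift (+13%) and the volume reduction (−11.5%)
  leaves pulmonary \(V_0\) almost unchanged, so with pulmonary pressures
  falling a double-digit *increase* in mean pulmonary volume is not
  attainable; the model yields +0.8% for the pulmonary veins (direction
  reproduced) and −0.04% for the pulmonary artery. The corresponding
  regression check is deliberately left failing rather than reinterpreted.
* **Augmentation index.** The inflection-point algorithm yields AI
  increasing in 0g, opposite to the published decline; with no published
  algorithm this index should be read qualitatively.
* **Problem sizes.** Default runs use \(\Delta x \le 0.25\) cm
  (~1100 grid cells), a CFL-derived \(\Delta t \approx 2\times10^{-4}\) s,
  and 100 beats per configuration; the test-suite exercises reduced
  configurations of the same code paths where a full run is unnecessary.
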