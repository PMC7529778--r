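# cardiodecon

Closed-loop 0D–1D multiscale hemodynamics with a weightlessness
(microgravity) deconditioning configurator.

Sustained spaceflight reshapes the circulation: roughly two liters of
blood shift from the legs toward the head, total blood volume falls by
about 11%, cardiac mass and contractility decline, leg veins become more
compliant, and the baroreflex re-baselines to a faster, lower-pressure
operating point. Direct measurements in orbit are scarce and mutually
inconsistent, which makes a mechanistic simulator the practical instrument
for studying the adapted state. `cardiodecon` is such a simulator, aimed
at computational physiologists and at modelers who need a compact,
fully-testable closed-loop circulation.

## The model

* **1D arterial tree** — cross-sectionally averaged mass and momentum
  balances

      ∂A/∂t + ∂Q/∂x = 0
      ∂Q/∂t + ∂(Q²/A)/∂x + (A/ρ) ∂p/∂x = −k_f Q/A

  closed by a nonlinear viscoelastic tube law for the tapered wall
  `p = p_ext + β(x)/A₀(x) (√A − √A₀) + γ ∂A/∂t`, solved with a two-step
  Lax–Wendroff finite-volume scheme; junctions enforce mass conservation
  and total-pressure continuity on Riemann invariants.
* **0D network** — RLC compartments (`V = V₀ + C·P`) for arterioles,
  capillaries, venous return, venae cavae and the pulmonary circulation;
  terminal arteries couple through a characteristic impedance placed
  before each arteriole.
* **Heart and valves** — four time-varying-elastance chambers
  (`P = E(t)(V − V₀)`, atrial kick included) and four dynamic valves whose
  opening obeys a four-effect ODE (pressure difference, tissue friction,
  blood motion, downstream vortex); the aortic valve feeds the
  ascending-aorta inlet.
* **Baroreflex** — filtered aortic–carotid pressure drives five effector
  multipliers (heart rate, ventricular elastance, peripheral resistance,
  venous unstressed volume and compliance) with sigmoidal statics and
  first-order lags.
* **Weightlessness configurator** — `configure_0g()` applies, in order:
  the regional blood shift (legs −235 ml, lower abdomen −234 ml,
  head-arms +133 ml, cardiac-thoracic +202 ml, upper abdomen +134 ml; the
  shifts sum to zero and preserve each zone's V₀/V), the −11.5% total
  volume reduction, the cardiac changes (ventricular elastance amplitude
  ×0.73, minima ×1.03, pulmonary compliances ×1.04/×1.05, chamber V₀
  ×0.10), the vascular changes (leg venous compliance ×1.27,
  carotid/vertebral resistances ×1.10, lower-body resistances ×0.90) and
  the baroreflex re-baselining (HR ×1.13, setpoint ×0.90).
* **Analysis** — beat statistics, cardiac indexes (SV, EF, CO, SW/min,
  TTI/min, RPP, CVP, MAP, pulse pressure, augmentation index) and the
  normalized signal difference

      NSD = ∫₀¹ |y′₁G(t′) − y′₀G(t′)| dt′ ∈ [0, 2]

  computed on amplitude- and time-normalized beats, quantifying waveform
  alteration beyond translation and scaling.

## Worked example

```r
library(cardiodecon)

net_1g <- baseline_network_1g()          # supine baseline (packaged YAML)
net_0g <- configure_0g(net_1g)           # long-term weightlessness

run_1g <- run_simulation(net_1g, n_beats = 100)
run_0g <- run_simulation(net_0g, n_beats = 100)

cardiac_indexes(run_1g)
#> Cardiac indexes (steady beat):
#>   HR              75.14 bpm
#>   V_lves          56.11 ml
#>   V_lved         122.34 ml
#>   SV              66.23 ml
#>   EF              54.14 %
#>   CO               4.98 l/min
#>   ...
#>   CVP              6.56 mmHg
#>   MAP             91.81 mmHg
#>   P_AA_syst      114.40 mmHg
#>   P_AA_dias       71.60 mmHg
#>   PP_AA           42.80 mmHg
```

The supine steady state is a normal adult at heart rate 75 bpm: mean
aortic pressure 91.8 mmHg, cardiac output 5.0 l/min, ejection fraction
54%, central venous pressure 6.6 mmHg. Comparing the two runs:

```r
rep <- comparison_report(run_1g, run_0g)
subset(rep$means, site == "ascending_aorta" & quantity == "P")
#>              site quantity      ref      alt variation_pct
#>   ascending_aorta        P 91.81099 80.94876     -11.83325

dc <- direction_checks(run_1g, run_0g)
```

In weightlessness the model's heart rate rises to 85.5 bpm (+13.8%) while
every load index falls: MAP −11.8%, pulse pressure −18.8%, ejection
fraction −15.6%, cardiac output −13.4%, stroke work −25.8%, tension-time
index −11.1%, rate-pressure product −1.0%, CVP −1.4%; the end-systolic LV
volume rises (+6.7%) — the hemodynamic picture of cardiac deconditioning,
a heart adapted to a less demanding environment. Waveform alteration (NSD)
grows from the aortic root (pressure 0.17) to the periphery (posterior
tibial pressure 0.41, flow 0.64) and reaches the capillary–venous level
(leg veins 0.33): the altered wave pattern propagates into exactly the
districts that set tissue perfusion.

`evaluate_targets(run_1g, run_0g)` scores the paired runs against the
packaged table of published spaceflight variations
(`inst/extdata/flight_targets.csv`), and `direction_checks()` runs the
qualitative checks that are independent of baseline calibration.

A command-line front end is included:

```sh
inst/cli/cardiodecon simulate --config inst/extdata/baseline_1g_supine.yaml \
    --gravity 0g --beats 100 --out runs/0g
inst/cli/cardiodecon compare --run-a runs/1g --run-b runs/0g --out report
```

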