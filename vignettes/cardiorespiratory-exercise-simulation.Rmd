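---
title: "Modelling exercise hemodynamics in heart failure with and without a continuous-flow VAD"
author: "cvrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling exercise hemodynamics in heart failure with and without a continuous-flow VAD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrsim)
```

## What the simulator is

`cvrsim` is a lumped-parameter (0-D) closed-loop model of the human
cardiovascular and respiratory systems built to study why exercise capacity
remains limited in severe heart failure (HF) even after implantation of a
continuous-flow left ventricular assist device (LVAD). Its two packaged
scenarios describe a severe dilated-cardiomyopathy patient (`"hf"`) and the
same class of patient supported by an axial-flow pump between the left
ventricular apex and the ascending aorta (`"hf_vad"`). Each scenario runs a
rest phase to steady state, ramps oxygen uptake to the population's peak
cycling workload, and (for the VAD scenario) finally steps the pump from its
baseline 9500 rpm to its 12000 rpm maximum.

## The model

### Heart

The four chambers are volume state variables. Ventricular pressure blends a
systolic time-varying elastance line with an exponential end-diastolic
pressure-volume relation through a dimensionless activation $v_c(t)$:

$$P_v(t) = v_c(t)\,E_{es}\,(V - V_0) + (1 - v_c(t))\,a\,e^{bV} + P_{intr}(t)$$

At $v_c = 1$ (end systole) this is the classical elastance model; at
$v_c = 0$ (diastole) it is exactly the exponential stiffness
$P = a e^{bV}$ in the form in which the coefficients $a, b$ are estimated
from end-diastolic pressure-volume points (see `fit_diastolic_stiffness()`).
Note that the exponent acts on the absolute volume, not on $V - V_0$; the
zero-pressure volume $V_0$ belongs to the systolic line only. The
intrathoracic pressure $P_{intr}$ adds to every intrathoracic compartment.

The activation rises as a squared half-sine from 0 at systole onset to 1 at
$T_{sys} = k_s\sqrt{RR}$ (default $k_s = 0.3\ \mathrm{s}^{1/2}$, the
classical systolic-interval relation), relaxes back to 0 over a short tail
($0.3\,T_{sys}$), and is zero for the rest of the cycle. Because systole
scales with $\sqrt{RR}$ while the cycle scales with $RR$, diastole shortens
disproportionately at high heart rate — a central limitation on ventricular
filling during tachycardic exercise. The exact activation waveform is a
modelling choice; the squared half-sine satisfies the 0-to-1 contract and
its half-time anchor, and a brief smooth relaxation tail avoids an
unphysical pressure jump at end systole.

Atria are linear compliances with a Gaussian active-elastance "kick" in the
last 15 % of the cycle, just before ventricular systole. The kick amplitude
is set so that atrial contraction contributes roughly 15-25 % of ventricular
filling at resting heart rate.

### Vasculature

The systemic tree is: ascending aorta (compliant, intrathoracic),
descending aorta (compliant, with an inertial-resistive connecting branch),
five parallel districts — upper body, kidneys, splanchnic bed, left and
right legs — each an arterial inflow resistance, a (mostly venous)
compliance and a venous outflow resistance, then a vena cava node and the
right atrium. The published district arterial resistances are used as
printed; the venous resistances are small constants. The pulmonary tree is
a compliant arterial node, the arteriolar resistance $R_{ap}$ (held at its
resting value during exercise), a compliant venous node and a small venous
resistance into the left atrium.

Venous compartments (upper body, splanchnic, legs, vena cava) carry a cubic
stiffening term on top of the linear law, so the pressure-volume relation
becomes nonlinear away from the working range: emptying a collapsing vein
or overdistending it both raise $|dP/dV|$ above $1/C$. The pulmonary
arterial compliance shrinks linearly once the (filtered) wedge pressure
exceeds 15 mmHg, floored at half its baseline — pulmonary vascular
stiffening with congestion.

The leg venous outflows are Starling resistors under the external muscular
pressure of pedalling: the effective downstream pressure is
$\max(P_{vc}, P_{muscle})$, the legs squeeze in antiphase at 0.9 Hz, and
the squeeze amplitude grows with exercise intensity. Valves are competent
diode resistors (`max(0, \Delta P)/R`): no regurgitation is modelled.

### Controls

The baroreflex senses filtered ascending-aortic pressure and drives a
saturating sigmoid $\sigma = \tanh((P_{set,eff} - \bar P_{as})/k_b)$. Two
first-order effector states (a fast one for heart rate, $\tau = 3$ s, and a
slow sympathetic one, $\tau = 8$ s, for contractility, arterial resistance
and venous unstressed volume) follow $\sigma$. During exercise the
set-point is reset upward linearly in oxygen uptake above rest. The
sympathovagal imbalance of heart failure is implemented as a ceiling on the
commanded heart rate: however strong the drive, HF peaks at 112 bpm (67 %
of the age-predicted 167 bpm) and the VAD population at 115 bpm.

The metabolic peripheral control is strictly local: each district compares
its venous oxygen concentration with a population-specific reference and
dilates its arterial resistance toward a floor as the deficit grows
(Gaussian decay in the deficit, first-order in time). Exercising legs
therefore dilate strongly while the kidney bed does not. No pulmonary
hypoxic vasoconstriction is modelled, and $R_{ap}$ stays at its resting
value throughout exercise.

### Ventilation and gas transport

Minute ventilation is commanded by a feed-forward term proportional to
whole-body CO$_2$ production (the dominant exercise hyperpnea signal) plus
small feedback corrections for arterial CO$_2$ deviation and for hypoxia,
and relaxes to the command with $\tau = 15$ s. Breathing frequency rises
linearly with ventilation and tidal volume is the quotient, so both grow
with demand; dead space is fixed per breath. Lung volume follows a
raised-cosine breath, pleural pressure swings with it around a negative
baseline, and the resulting intrathoracic pressure loads the heart and the
intrathoracic vessels.

Gas exchange uses a Hill oxyhemoglobin dissociation curve
($P_{50} = 26.6$ mmHg, $n = 2.7$) plus dissolved oxygen, and a linearised
CO$_2$ content law. Alveolar partial pressures evolve from the balance of
alveolar ventilation and blood-gas flux; end-capillary blood equilibrates
to alveolar tensions; each district's venous store obeys Fick dynamics
(oxygen extracted at the regional metabolic rate, CO$_2$ added at RQ times
that rate). Oxygen uptake and respiratory quotient are *inputs*: the
protocol ramps them between rest and peak values. If perfusion cannot cover
a region's demand the venous oxygen floors at zero and the run is flagged
as supply-limited.

### The pump

The VAD branch connects the left ventricle to the ascending aorta with a
quadratic axial-pump characteristic and cannula dynamics:

$$L_c \frac{dQ}{dt} = P_{lv} - P_{ao} + k_\omega \omega^2 - k_{q1} Q -
k_{q2} Q |Q| - R_c Q$$

Instantaneous backflow (an unpowered or heavily loaded pump) is permitted.
The coefficients are not published for this configuration;
`calibrate_vad()` fits them from operating-point anchors, and the packaged
values were calibrated once, in closed loop, to the three published
operating points (4.3 l/min at 9500 rpm at rest, 5.2 l/min at 9500 rpm at
peak exercise, 8.0 l/min at 12000 rpm). The resulting head-flow slope is
steeper than a bench characteristic of a clinical axial pump; it is the
slope the closed-loop operating points imply, and pump behaviour outside
the calibrated range should be interpreted cautiously. Suction is not
modelled mechanistically; a warning is raised whenever left ventricular
volume falls below 10 cm^3.

## Parameters

Parameters fall in three tiers, all visible in `scenario_params()` and the
YAML fixtures under `inst/extdata/`:

1. **Published patient characterisation** — heart rate, end-systolic
   elastances, diastolic stiffness coefficients, zero-pressure volumes,
   regional arterial resistances, pulmonary arteriolar resistance,
   baroreflex set-point, reference venous O$_2$ concentrations. These are
   used verbatim.
2. **Standard lumped-parameter constants** — compliances, unstressed
   volumes, valve and venous resistances, inertances, dissociation-curve
   constants, body weight (75 kg; with it the printed oxygen uptakes,
   cardiac outputs and arteriovenous differences are mutually consistent
   through the Fick principle).
3. **Closed-loop calibration constants** — control gains, pump
   coefficients, stressed blood volume. These were tuned once so that the
   resting state of each scenario reproduces the published resting
   hemodynamics and the exercise response reproduces the published peak
   values, and are shipped fixed.

Two calibration choices deserve explanation:

* **Separate LV and RV inotropic gains.** A single contractility effector
  cannot reproduce the published operating points: peak-exercise pulmonary
  pressures require the right ventricle (end-systolic elastance
  0.37 mmHg/cm^3) to roughly double its effective contractility, while the
  published left ventricular end-systolic volumes admit almost no LV
  inotropic response in the HF scenario. In the VAD scenario the balance
  reverses: the reverse-remodelled, unloaded LV must *resume ejecting*
  (2.1 l/min at peak exercise) while right atrial pressure climbing to
  15 mmHg implies a weak RV response. The packaged gains encode this
  population-specific sympathetic balance.
* **Scenario-specific resetting gains** (1.6 and 1.25 mmHg per ml/min/kg)
  anchor the peak-exercise arterial pressures of the two populations.

The respiratory quotient ramps from 0.8 at rest to 1.19 (HF) or 1.23
(HF+VAD) at peak — the values implied by the published peak CO$_2$ outputs
and ventilatory equivalents — reflecting the early anaerobic metabolism of
these patients.

## Numerics

The coupled system (44 states) is integrated by a compiled fixed-step
fourth-order Runge-Kutta scheme with a 0.25 ms step, well below the fastest
valve-compliance time constants (a few ms). A fixed step was chosen
deliberately: the model switches valve states several times per cardiac
cycle, which defeats the step-size heuristics of stiff adaptive solvers,
and a fixed grid makes runs bit-identical — the model contains no
randomness, and the test suite asserts exact reproducibility and that
halving the step changes 15-cycle summaries by well under 0.5 %. The
equations are written twice on purpose: a readable pure-R reference
(`network_derivatives()`) defines the semantics, and the test suite checks
the compiled engine against it at machine precision and against a
`deSolve::lsoda` integration of the reference over a cardiac cycle.

Heart rate is sampled from the baroreflex at each cycle boundary and held
within the cycle, so cardiac cycles remain crisp averaging units while the
controls move. Summaries average the last 15 complete cycles — long enough
to suppress the ventilatory modulation of the hemodynamic signals — with
wedge pressure defined as the mean left atrial pressure, and end-diastolic/
end-systolic volumes as per-cycle extrema. Steady state is declared when
consecutive 15-cycle windows change cardiac output, arterial pressure and
wedge pressure by less than 0.5 % each; phases abort with a diagnostic
error if they fail to settle within their maximum duration (300 s rest,
600 s exercise). Exercise begins with a 60 s linear ramp of oxygen uptake
(and RQ) to avoid control transients from a step input.

Degenerate situations are handled explicitly: valves and Starling resistors
clamp at zero flow; regional venous oxygen floors at zero with a
supply-limitation counter; left ventricular volumes below 10 cm^3 raise a
suction warning; non-finite states abort integration with a diagnostic.

## What the scenarios emulate — and what they do not

The protocols emulate supine-ergometer exercise of two literature-averaged
populations; each simulated steady state stands for the average
hemodynamics of that population, not an individual patient. Gravity and
posture are absent, so upright exercise (where venous pooling limits the
end-diastolic volume rise) is outside the model's reach. Heart valves are
competent — aortic insufficiency, common in VAD patients, is not modelled.
The lung is a single ventilated compartment (no ventilation-perfusion
mismatch), CO$_2$ chemistry is linearised, and there is no acid-base
module. The pump model has no pulsatility-index controller, motor model or
hemolysis index.

One documented inconsistency deserves note: the published end-diastolic
volumes cannot be reconciled exactly with the published wedge pressures
through the exponential stiffness law and its published coefficients (at a
wedge of 28 mmHg the HF law fills the ventricle to about 335 cm^3, not the
355 cm^3 reported). The simulator is faithful to the stiffness law, so its
steady-state volumes track the law and land within about 5-7 % of the
printed volumes. For the same reason the published diastolic tangent
slopes (0.26 and 0.48 mmHg/cm^3) correspond to working-point volumes
between the simulated and the printed end-diastolic volumes;
`linearize_stiffness()` therefore takes the working volume as an explicit
argument rather than assuming one.

Passing the packaged tests shows that the closed loop reproduces the
published population-average operating points and responds in the right
direction to workload and pump speed; it does not validate the model for
individual-patient prediction, for exercise modalities other than cycling,
or for pump speeds outside the calibrated 9500-12000 rpm range.

## Problem sizes used in tests

The test suite runs both full protocols once (about 25 simulated minutes of
physiology in a few seconds of computation) and shares the results across
test files; conservation is checked over 60 s of simulation, step-halving
convergence over 25 s, and the engine-versus-`deSolve` comparison over one
cardiac cycle. The acceptance script reruns both protocols from scratch and
reports the 15-cycle summary quantities.

## A worked example

```{r example, eval = FALSE}
library(cvrsim)
cfg <- load_config(scenario_fixture("hf"))
protocol <- run_protocol(cfg)
protocol$summaries$exercise
loops <- extract_pv_loops(protocol$results$exercise, "lv", n = 1)
plot(loops[[1]]$V, loops[[1]]$P, type = "l",
     xlab = "LV volume (cm^3)", ylab = "LV pressure (mmHg)")
```
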