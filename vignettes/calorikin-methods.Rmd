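---
title: "Kinetic analysis of irreversible DSC thermograms with calorikin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic analysis of irreversible DSC thermograms with calorikin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calorikin)
```

## The model

Many multidomain proteins denature irreversibly: each *calorimetric
domain* — a part of the molecule that unfolds cooperatively and
independently of the rest — converts from its native state N to a
denatured state D through a first-order (or pseudo-first-order)
reaction.  The rate constant follows the Arrhenius law, which calorikin
parameterises as

$$k(T) = \exp\!\left[\frac{E_a}{R}\left(\frac{1}{T^*} -
\frac{1}{T}\right)\right],$$

with $E_a$ the activation energy (kJ/mol), $R = 8.314\times10^{-3}$
kJ/(mol·K), and $T^*$ the *special temperature* at which $k = 1$
min⁻¹.  $T^*$ replaces the astronomically scaled pre-exponential
factor with a quantity on the temperature scale of the experiment,
which keeps the fits well conditioned.  All rate constants in the
package are per minute, all temperatures absolute.

During a constant-rate scan ($dT/dt = \nu$, default 1 K/min) the
surviving native fraction is
$x(T) = \exp[-\tfrac1\nu\int_{T_0}^{T} k\,dT']$ and the excess heat
capacity of a one-stage domain is
$C_p^{ex}(T) = \Delta H\,k(T)\,x(T)/\nu$; its area is the domain
enthalpy $\Delta H$.  A domain may instead denature in two sequential
irreversible stages N → I → D with rate constants $k_1, k_2$ and
positive stage enthalpies $\Delta H_1, \Delta H_2$; the state
fractions then obey the linear system
$dx_N/dT = -k_1 x_N/\nu$, $dx_I/dT = (k_1 x_N - k_2 x_I)/\nu$.
`simulate_two_stage()` integrates this system with a stiff ODE solver
(`deSolve::lsoda`, tolerances 1e-10/1e-12) rather than evaluating the
equivalent nested-integral solution: the double integral requires an
integrating factor that overflows at high temperature, while the ODE
route is stable on any grid.  The test suite checks the solver against
an independent quadrature evaluation of the nested-integral form to
1e-4 relative.

A multidomain thermogram is the algebraic sum of its domain curves,
and annealing (an isothermal pre-incubation at $T_{ann}$ for
$t_{ann}$ minutes) scales each one-stage contribution by
$x_i = e^{-k_i(T_{ann})t_{ann}}$ without changing its shape.  For a
two-stage domain the hold is propagated through the closed-form
solution of the sequential system, including the removable
$k_1 = k_2$ singularity (switched when $|k_1-k_2| < 10^{-10}k_1$).

## The W(T) diagnostic and recursive peeling

For a one-stage curve the function

$$W(T) = T\left(\ln\nu + \ln C_p^{ex}(T) -
\ln\!\int_T^{end} C_p^{ex}\,dT'\right)
= \frac{E_a}{R\,T^*}\,T - \frac{E_a}{R}$$

is exactly linear in $T$, so a linear fit of $W$ returns
$E_a = -R\cdot\mathrm{intercept}$ and
$T^* = E_a/(R\cdot\mathrm{slope})$, and curvature of $W$ rejects the
one-stage hypothesis.  At the high-temperature end of a
multi-transition curve only the most thermostable transition is left,
so the tail of $W$ is linear there; `peel_transitions()` estimates
that transition, subtracts its simulated curve, and recurses.

Several numerical choices here are the package's own, because the
qualitative criterion "W is linear" needs a rule:

* Points are masked where $C_p^{ex} \le 0$ or where the remaining tail
  area falls below 1% of the total — the log of a vanishing integral
  otherwise dominates the fit.  Masked points are never extrapolated.
* The linear tail window is the longest high-temperature window whose
  linear-fit residual SD stays below
  $\max(2\times\text{local noise}, 0.05)$; the local noise is the
  median residual SD of 15-point local fits, and the absolute floor of
  0.05 (in W units, i.e. about $5\times10^{-4}$ K of equivalent
  temperature shift) absorbs the trapezoid-quadrature bias near the
  mask edges, which otherwise vetoes perfectly clean curves.  Windows
  that fail even this test fall back to the shortest top window and
  are flagged `window_forced`: later peeling steps inherit subtraction
  error in the deep tail, and aborting there would hide the remaining
  transitions entirely.
* Each peeled triple is re-optimised by bounded Levenberg–Marquardt on
  its estimation window only, countering the accumulation of
  subtraction error, and is kept only if it improves the window
  residual.
* The recursion stops when the residual area drops below 3% of the
  total, and additionally discards (and stops at) a peeled transition
  whose enthalpy is below 5% of the total.  This *resolution floor* is
  deliberate: subtracting a one-stage approximation of what is really
  the second stage of a two-stage domain leaves a few percent of
  structured debris, and without the floor the recursion counts that
  debris as an extra transition.  Transitions smaller than 5% of the
  total heat are below what the annealing method can isolate anyway.

Peeled parameters are null approximations.  Their role is to count the
apparent transitions, to seed `plan_annealing()` and the joint fit —
not to be reported as final values.

## Annealing design and resolving power

To isolate transition $i$ the hold must satisfy
$x_{i-1} < 0.01$, $x_i > 0.1$ and $t_{ann} \ge 10$ min (shorter holds
are dominated by heat-up/cool-down transients).  Fixing the survival
ratio $A = x_{i-1}/x_i < 0.1$ gives the explicit hold time
$t_{ann} = |\ln A|/(k_{i-1} - k_{i})$, which is positive exactly where
the less stable transition denatures faster; `plan_annealing()`
evaluates this over a temperature grid and reports per-transition
survivals with full two-stage bookkeeping (stage 1 survives as $x_N$,
stage 2 as $x_N + x_I$).  `resolving_power()` inverts the feasibility
system by bisection over the parameter gap: at equal activation
energies (~300 kJ/mol, $T^*$ near 320 K) the smallest resolvable
$T^*$ separation comes out at just under 2 K.  At equal $T^*$ the
minimum $E_a$ gap is only finite if the hold time is bounded above;
the package exposes that bound (default 60 min) and reports the gap as
a function of it rather than asserting a single number.

Enthalpy measured after annealing is restored with
$\Delta H = \Delta H_{trans}\exp[t_{ann}k(T_{ann})]$.

## Chemical baseline

The recorded signal is
$C_p = C_p^N(1-\xi) + C_p^D\,\xi + C_p^{ex}$ with $\xi$ the degree of
completeness.  `fit_baseline()` takes four anchor temperatures
bounding a pre- and post-transition linear run (at least 3 points
each; `suggest_anchors()` offers a sliding-window heuristic, but the
choice is the user's), builds the null baseline (native line, straight
chord across the peak, denatured line), then alternates computing
$(\Delta H, \xi)$ by trapezoid integration and rebuilding the baseline
as $C_p^N(1-\xi) + C_p^D\xi$ until $\Delta H$ changes by less than
0.01% (default, configurable).  $\xi$ excursions outside [0, 1] from
noise are clipped for baseline construction but reported unclipped.
For multi-transition curves the same single-$\xi$ form is applied
under the assumption that each transition's heat-capacity jump is
proportional to its enthalpy share; when that assumption is violated
outright (the whole jump on one peak) the recovered total enthalpy is
still within a few percent on synthetic data, and the test suite pins
that bound at 5%.  The state lines are linear by design — polynomial
baselines are out of scope.

Anchor placement matters more than the iteration: a pre-peak run that
already contains a fraction of a percent of kinetic signal tilts the
native line and loses 1–2% of the enthalpy.  The vignette's advice is
to push $T_2$ to where the simulated (or visually flat) signal is
below ~0.1% of the peak.

## Joint multi-thermogram fitting

`fit_model()` fits one shared parameter vector (three parameters per
transition) to the native scan and every annealed scan
simultaneously, each observation's initial state fractions derived
from its annealing history through the isothermal solution — the
annealed curves are what make the Arrhenius parameters identifiable in
practice.  The optimiser is bounded Levenberg–Marquardt
(`minpack.lm::nls.lm`; bounds $E_a\in[50,1000]$ kJ/mol,
$T^*\in[280,360]$ K, $\Delta H\in(0,5000]$ kJ/mol) with multi-start:
the first start is the peeled null approximation, the remaining starts
(default 8 in total, seed 1234) jitter activation energies and
enthalpies by ±20% and special temperatures by ±2 K.  Temperatures get
an absolute jitter because a relative one would be ±64 K — far outside
any basin of attraction.  Residuals are unweighted, and all curves
share a common scale (no per-curve normalisation factor is fitted):
the synthetic generator emulates a single preparation scanned under
different histories, where the molar normalisation is common by
construction.

Model criticism follows two protocols.  `predict_holdout()` simulates
an annealing condition excluded from fitting and compares it with the
held-out curve.  `constrained_counterfit()` refits with one parameter
frozen at a hypothesised value and compares holdout residuals of the
constrained and unconstrained models — a prediction-based test used in
place of regression statistics, because `estimate_uncertainty()`
deliberately rejects covariance-based intervals: systematic error
(chiefly baseline placement) dominates random error in DSC, so the
uncertainty of each parameter is taken as the spread of single-curve
refits, floored at 0.4 K for $T^*$, 40 kJ/mol for $E_a$ and 10% for
enthalpies.

## Aggregation, fluorescence and inactivation probes

Isothermal DLS traces are fitted to
$R_h = R_{h0}\exp[\ln 2\,(t-t_0)/t_{2R}]$ for $t > t_0$.  The lag
$t_0$ (nucleation of start aggregates) is irreproducible between runs
and treated as a nuisance parameter: a geometric change-point start
(the growth line of the log-radius extrapolated back to the plateau
level) followed by a Levenberg–Marquardt polish of all three
parameters.  An earlier grid-profiling estimator was abandoned — the
SSE valley in $t_0$ narrows to a few sampling intervals on long slow
traces and a fixed grid misses it.  The growth rate entering the
Arrhenius fit is $k_{agg} = \ln 2/t_{2R}$, the convention consistent
with the half-life relation $t_{0.5} = \ln 2/k$, so that
$t_{2R}(T^*) = \ln 2$ min; with the alternative $1/t_{2R}$ convention
$E_a$ would be unchanged and $T^*$ shifted by about 0.9 K.
`compare_with_denaturation()` tabulates $t_{2R}$ against the
half-lives of every calorimetric transition to identify the
rate-limiting denaturation step, and `scan_growth_overlay()` measures
the temperature delay between radius growth during a ramp and each
transition's conversion midpoint — the signature of the nucleation
stage.

The fluorescence spectral parameter $A = I_{320}/I_{365}$ is analysed
two ways.  `compute_parameter_a()` normalises between the observed
extremes.  `parametric_plot()` segments the $(I_{320}, I_{365})$
phase plot by exact dynamic-programming change-point detection with an
*orthogonal* (principal-axis) residual cost and BIC model selection
(penalty 3 per segment, minimum 5 points).  The orthogonal cost
matters: both channels carry noise, and an ordinary regression of one
intensity on the other is attenuation-biased over short segments,
which systematically misclassifies true through-origin quenching
segments.  A segment is "through-origin" when the perpendicular
distance of its principal line from the origin is below
$\max(0.06\times\text{mean radius}, 3\times\text{orthogonal residual
SD})$.  Segment boundaries are resolved to a few scan steps, which is
why the package reports temperature ranges and classifications, not
kinetic parameters, from phase plots.  `overlay_with_dsc()` smooths
the normalised $A$ curve (5-point running mean, plateau-median
renormalisation) before locating its 5–95% rise window; without the
smoothing, channel noise fakes early threshold crossings.

Residual-activity time courses are mono-exponential decays
$a(t) = e^{-kt}$ with amplitude fixed at 1 by default (activities are
pre-normalised; a free-amplitude flag exists), $k \ge 0$ enforced and
flagged at the boundary.

## The synthetic generator

`make_thermogram_set()`, `make_dls_set()` and `make_probe_set()`
produce every input the analysis modules consume, with a
machine-readable truth record and bit-reproducible seeding.  The
defaults are the study conditions of the reference system — the
isolated myosin head at high ionic strength: a one-stage domain
(290 kJ/mol, 317.5 K, 200 kJ/mol) plus a two-stage domain (stage 1:
400 kJ/mol, 321.2 K, 1030 kJ/mol; stage 2: 340 kJ/mol, 324.5 K,
500 kJ/mol), scanned at 1 K/min on a 0.05 K grid over 288.15–358.15 K;
annealing conditions 319.15 K/15 min and 315.15 K/20 min plus a
317.15 K/17 min holdout; DLS growth with $E_a = 430$ kJ/mol,
$T^* = 320.8$ K at 39–47 °C with a 44 °C concentration series;
fluorescence plateaus $A$ = 1.06 → 1.32.  Values the study does not
state are fixed once at field-plausible levels and documented here:
additive thermogram noise 1% of peak height, heat-capacity jump 10% of
peak height on a gently sloped native line, start-aggregate radius
20 nm, lags drawn from 2–8 min, 2% multiplicative DLS noise, linear
fluorescence quenching of 1%/K, 2% additive activity noise.

The generator emulates clean first-order kinetics with stationary
Gaussian noise.  It does not emulate instrument response smearing,
scan-rate miscalibration, concentration normalisation error,
polydisperse DLS inversion artifacts, or temperature offsets between
instruments — so green tests demonstrate correctness of the estimators
under the model's own assumptions, not robustness to every artifact of
real data.

## Problem sizes and determinism

The test suite and the acceptance script run the full pipeline at the
default grid (1401 points per thermogram, three thermograms in the
joint fit), five DLS temperatures, and 20 random two-transition models
for the peeling property; everything is seeded and deterministic.
Noiseless recovery of the reference parameters by the joint fit is
exact to well below the conventional uncertainty floors; the

honest limits of the method surface elsewhere: peeled (null
approximation) parameters can be biased by several kJ/mol and a few
tenths of a kelvin, the apparent transition count relies on the 5%
resolution floor, and phase-plot boundaries are only a few scan steps
accurate.

## Known limitations

* Reversible (equilibrium) thermodynamics, non-Arrhenius rate laws
  and scan-rate-dependent instrument corrections are out of scope; the
  time-response correction is a user-pluggable hook.
* The single-$\xi$ baseline is an approximation for multi-transition
  curves with disproportionate heat-capacity jumps.
* `plan_annealing()` treats the hold with the independent-transition
  inequalities when solving for the hold time; the reported survivals,
  however, use the exact sequential solution.
* The joint fit assumes the fixed domain structure it is given; it
  does not select the number of domains (the peeling count and the
  counterfit protocol are the tools for that judgement).
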