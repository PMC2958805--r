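---
title: "A whole-body fuel model for endurance running"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A whole-body fuel model for endurance running}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runfuel)
```

## The model

runfuel treats a distance runner as an aerobic engine drawing on two fuel
reservoirs of very different size. Fat stores are effectively unlimited —
even a very lean runner carries enough fat energy for several marathons
(`fat_reserve_distance()`) — but carbohydrate stores (liver glycogen,
leg-muscle glycogen, and a negligible plasma glucose pool) are small enough
to be exhausted mid-race, the abrupt failure mode runners call *hitting the
wall*. Everything the package predicts follows from combining three simple
ingredients.

**Running energetics.** The net metabolic cost of level running is nearly
speed-independent, $C \approx 1\ \mathrm{kcal\,kg^{-1}\,km^{-1}}$, so power
is $P = C v M$ for speed $v$ and body mass $M$, and the energy of a race of
distance $d$ is $C M d$ regardless of pace. Basal metabolism is deliberately
folded into $C$ rather than modeled separately; because resting metabolism
draws essentially nothing from muscle glycogen, the error this introduces
into the *carbohydrate* accounting is below one percent.

**Substrate partitioning.** The fraction of aerobic energy supplied by
carbohydrate rises with relative intensity $i$ (fraction of VO2max). We
model it as a quadratic
$$f_{CHO}(i) = a + b\,i + c\,i^2, \qquad f_{fat} = 1 - f_{CHO},$$
interpolated exactly through three anchor measurements at $i =$ 0.25, 0.65,
0.85 — the intensities of the classic 1993 tracer/indirect-calorimetry
protocol in trained subjects. Those anchor values are plotted but not
printed in the literature, so the package ships a one-time digitization
(`romijn_anchors()`: $f_{CHO} =$ 0.28, 0.46, 0.67) as a documented,
auditable constants table with the oxidation rates and standard errors that
underlie them. The fitted curve, $f_{CHO}(i) = i^2 - 0.45\,i + 0.33$, is
convex and non-decreasing over the fit domain. Because any digitization of
a plotted figure is approximate, agreement with worked numbers quoted from
the literature is expected at the few-percent level, not exactly; the
tolerances used throughout the tests reflect that.

**Oxygen stoichiometry.** Complete oxidation of glucose (686 kcal/mol,
6 mol O2) yields $\rho_{CHO} = 686/6 \approx 114.3$ kcal per mole of
oxygen; palmitate oxidation (2398 kcal/mol, 23 mol O2) yields
$\rho_{fat} = 2398/23 \approx 104.3$. The mixture value
$\rho(i) = f_{CHO}(i)\rho_{CHO} + f_{fat}(i)\rho_{fat}$ converts oxygen
uptake to power (`aerobic_power()`), and inverting the chain converts an
observed speed and fractional maximum heart rate $h$ (used one-to-one as a
proxy for $i$) into a VO2max estimate (`estimate_vo2max()`). Gas volumes
are converted at 22.4 L/mol (standard temperature and pressure).

From these, the headline quantities:

* maximum aerobic speed $v_{max} = \dot{V}O_{2max}\,\rho(1) \cdot
  60/(1000\,V_m\,C)$, with intensity from speed as $i = v/v_{max}$;
* carbohydrate budget of a race, $E_{CHO} = C M d\, f_{CHO}(i)$;
* distance to the wall,
  $d_w = (f_{liver}\rho_{liver} + f_{legs}\rho_{muscle}) / (C f_{CHO}(i))$,
  mass-free because both stores and demand scale with body mass;
* minimum midrace carbohydrate,
  $m_{exo} = \max(0, E_{CHO} - M S)/\rho^{g}_{CHO}$ grams, zero exactly
  when $d_w \ge d$;
* maximal muscle-glycogen depletion
  $\Delta\rho_{muscle} = (C d f_{CHO}(i) - E_{exo}/M)/f_{legs}$, reported
  unclipped with a flag when it exceeds the stored density, because it is a
  deliberate upper bound (it attributes all carbohydrate burned to muscle
  glycogen).

## Parameters that matter

| parameter | unit | default | rationale |
|---|---|---|---|
| running cost $C$ | kcal/kg/km | 1 | classical net cost of level running; individual economy varies ~5–7% |
| $\rho_{CHO}$, $\rho_{fat}$ | kcal/mol O2 | 114.33, 104.26 | glucose and palmitate combustion chemistry |
| molar volume | L/mol | 22.4 | STP convention for VO2 volumes |
| carbohydrate energy density | kcal/g | 4 | reservoir accounting convention |
| glycosyl residue mass | g/mol | 180 | free-glucose mass; see below |
| liver fraction | — | 0.025 | liver mass is tightly regulated |
| liver glycogen | mmol/kg | 270 typical, 500 max | 500 mmol/kg ≡ 360 kcal/kg exactly |
| leg-muscle fraction | — | 0.214 | typical male value; population 14.0–27.5% (men), 18.0–22.5% (women) |
| muscle glycogen | mmol/kg | 110 typical, 200 max | trained vs supercompensated; 110 ≡ 79.2 kcal/kg, 200 ≡ 144 kcal/kg |
| fat energy density | kcal/g | 9.4 | adipose tissue energy density |

Two conventions deserve emphasis. Glycosyl residues are converted at
180 g/mol (free glucose), not the 162 g/mol anhydro-glucose residue mass,
because the canonical reservoir arithmetic (a 1.8-kg liver at 270 mmol/kg
storing roughly 88 g) only reproduces under 180 g/mol; with that choice the
maximal liver store computes to 162 g, which the literature rounds to 160.
And the maximum-aerobic-speed formula evaluates the fuel mixture at $i = 1$
(not at the running intensity), which makes $i = v/v_{max}$
self-consistent; consequently power computed at intensity $i$ and power
computed from the equivalent speed differ by exactly $\rho(i)/\rho(1)$, a
ratio the test suite pins down.

## Error propagation

Every derived quantity depends on $f_{CHO}$ to first order, directly or
through $\rho(i)$. Logarithmic differentiation gives, for a relative error
$\delta f/f$:

* power, the VO2max estimate, and $v_{max}$ respond through $\rho$, with
  attenuation factor $f(\rho_{CHO}-\rho_{fat})/\rho(i) < 1$ — they inherit
  *smaller* relative errors;
* the carbohydrate budget ($\propto f$) and the wall distance
  ($\propto 1/f$) carry $\delta f/f$ exactly, the latter with opposite
  sign.

`propagate_error()` reports these first-order bounds (second-order terms
are ignored) and `verify_by_perturbation()` checks them numerically by
re-evaluating each quantity with the whole partition curve scaled by
$1+\epsilon$. The measurement errors of the anchors themselves are
propagated from the underlying oxidation-rate standard errors with
partial-derivative weights combined in quadrature (`partition_error()`);
with the packaged table the largest anchor-level relative error is about
5%, within the 5.5% design bound, so no model output inherits more than a
~5% relative error from the partition.

## Numerical choices

* **Fitting.** Exactly three anchors are interpolated by a direct solve of
  the 3×3 Vandermonde system; more anchors fall back to least squares.
  Fewer than three anchors, or duplicate intensities, are hard errors.
* **Domain.** Intensities are valid on $(0, 1]$ only; supra-aerobic speeds
  raise an error rather than extrapolating into the anaerobic regime.
  Above the anchor domain (0.85–1.0) the same quadratic is used, as the
  model's own charts extend there; below it a warning marks the
  extrapolation (endurance-relevant intensities exceed it anyway). Output
  is clamped to $[0, 1]$.
* **Degenerate inputs.** $f_{CHO}(i) = 0$ makes the wall infinitely far;
  `distance_to_wall()` returns `Inf` as a documented sentinel. A zero
  leg-muscle fraction makes the per-kg-muscle depletion undefined and
  errors.
* **Pacing splits.** A two-speed strategy is parameterized by its two
  speeds; the fraction of distance at the slow speed follows from the
  total-time constraint, and a user-supplied fraction is validated against
  it (to 1e-6) rather than trusted. Convexity of the fitted quadratic
  makes every proper split strictly worse than even pacing.
* **Rounding.** Pace strings round half-up to the nearest second. A
  3:42:00 marathon computes to 8:28.0 per mile and renders as "8:28";
  quoted figures sometimes print "8:29" for the same pace, so tests accept
  either string while the 3:10:00 → "7:15" conversion is exact.

## The synthetic cohort

`sample_cohort()` draws runners uniformly (by default) within stated
population bands: leg-muscle fractions 14.0–27.5% of body mass in men and
18.0–22.5% in women (printed population ranges), VO2max 38–52 (men) and
30–44 (women) ml/kg/min as 10th–90th-percentile-style bands for adults in
their twenties, body mass 55–90 kg (men) and 45–75 kg (women), and muscle
glycogen 80–200 mmol/kg spanning trained through supercompensated states.
Uniform sampling is the honest choice when only ranges, not distributions,
are stated; a percentile-anchored normal option (`sampling = "normal"`,
range read as a 10th–90th percentile band, draws clamped to the range) is
available. Draws are a pure function of the spec's seed.

The generator emulates between-runner variation in build and capacity. It
does **not** emulate within-run physiology — day-to-day glycogen state,
running-economy differences between individuals, heart-rate drift,
gastrointestinal limits on fueling — so passing cohort tests demonstrates
the model's internal consistency across realistic parameter ranges, not
predictive accuracy for any individual runner.

## Problem sizes

The package's computations are closed-form, so the test suite runs
property checks at generous sizes chosen for statistical coverage rather
than cost: complement and pacing-convexity properties over 10^3 random
draws, cohort-range checks over 10^4 draws, finite-difference error checks
over a grid of intensities and three perturbation sizes. The whole suite
completes in a few seconds.

## Known limitations

* No time dependence of the substrate mix at constant intensity: evidence
  for such drift is weak, confounded with declining aerobic output, and it
  is modeled as absent.
* Heart rate maps to intensity one-to-one; no nonlinear HR–VO2 relation,
  cardiac drift, or temperature effects.
* No terrain: the energetic cost of inclines is real but outside scope.
* Fueling is an energy ledger only; gastric emptying and absorption
  kinetics are not modeled. As a practical rule, midrace carbohydrate must
  be ingested roughly 30 minutes before it is needed.
* Anaerobic contributions (phosphocreatine, glycolysis to lactate) are out
  of scope; the model stops at $i = 1$.
* Performance may begin to degrade before complete depletion; the wall
  distance marks exhaustion of the modeled reservoir, an upper bound on
  trouble-free distance.

## A worked walkthrough

```{r walkthrough}
runner <- runner_profile(mass = 75, vo2max = 55)
plan <- race_plan(42.195, finish_time = "3:42:00")
predict_race(runner, plan, with_errors = TRUE)
```

The resolved intensity, carbohydrate budget, wall distance, and fueling
requirement above are the quantities the figures tabulate
(`fig2_table()`, `fig3_table()`, `fig4_table()`), and
`scripts/acceptance.R` recomputes the same walkthrough from scratch.
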