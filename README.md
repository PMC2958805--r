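# runfuel

A whole-body metabolic model of endurance running: given a runner's
physiology and a race plan, runfuel predicts the substrate mix burned, the
maximum aerobic pace, the carbohydrate budget of the race, the distance at
which glycogen reserves run out ("hitting the wall"), and the minimum
midrace carbohydrate intake needed to avoid it — with first-order error
bounds on every derived quantity.

It is written for exercise physiologists, coaches, and quantitatively
minded endurance runners who want reservoir arithmetic and pacing advice
grounded in an explicit, auditable model rather than rules of thumb.

## The model in brief

Level running costs $C \approx 1\ \mathrm{kcal\,kg^{-1}\,km^{-1}}$
independent of speed, so a race of distance $d$ costs $C M d$ kcal. The
fraction supplied by carbohydrate rises with relative intensity $i$
(fraction of VO2max) along a convex quadratic fitted through three
tracer-study anchors,

$$f_{CHO}(i) = i^2 - 0.45\,i + 0.33, \qquad f_{fat} = 1 - f_{CHO},$$

and oxygen stoichiometry ($\rho_{CHO} = 686/6$, $\rho_{fat} = 2398/23$
kcal per mole O2) links oxygen uptake to power. The headline prediction is
the distance to glycogen depletion,

$$d_w = \frac{f_{liver}\,\rho_{liver} + f_{legs}\,\rho_{muscle}}{C\, f_{CHO}(i)},$$

the ratio of glycogen energy stored per kg body mass to carbohydrate
energy burned per kg per km — independent of body mass. When $d_w$ falls
short of the race distance, the deficit divided by 4 kcal/g is the minimum
carbohydrate to eat en route. See the methods vignette
(`vignettes/marathon-fuel-model.Rmd`) for the full model, conventions, and
limitations.

## Worked example

Can a 75-kg runner with a VO2max of 55 ml/kg/min finish a marathon in
3:42:00 without hitting the wall, on typical trained glycogen stores?

```r
library(runfuel)

runner <- runner_profile(mass = 75, vo2max = 55)
plan   <- race_plan(42.195, finish_time = "3:42:00")
predict_race(runner, plan)
#> # A tibble: 1 × 12
#>    mass vo2max intensity speed_kmh cho_kcal cho_kcal_per_kg distance_to_wall_km
#>   <dbl>  <dbl>     <dbl>     <dbl>    <dbl>           <dbl>               <dbl>
#> 1    75     55     0.684      11.4    1552.            20.7                52.9
#>   will_hit_wall min_exogenous_cho_g delta_kcal_per_kg_muscle
#>   <lgl>                       <dbl>                    <dbl>
#> 1 FALSE                           0                     96.7
#>   delta_mmol_per_kg_muscle exceeds_stored
#>                      <dbl> <lgl>
#> 1                     134. TRUE
```

Reading the row: the 3:42:00 pace (11.4 km/h) is 68% of this runner's
aerobic capacity; the race burns about 20.7 kcal of carbohydrate per kg of
body mass (~1550 kcal total); his wall sits at 52.9 km, comfortably past
the finish, so no midrace carbohydrate is strictly required. The last
columns are the *maximal* muscle-depletion estimate, which attributes all
carbohydrate to leg-muscle glycogen; its flag notes that typical unloaded
muscle alone (79.2 kcal/kg) could not cover the budget — the liver's share
is what makes the race safe.

The minimum builds that make the same race feasible under maximal glycogen
loading, for this runner and for a VO2max-45 runner:

```r
min_leg_fraction(c(55, 45), plan)
#> [1] 0.08117293 0.12887769
```

i.e. leg muscles of roughly 8% and 13% of body mass. No laboratory VO2max?
Estimate it from a treadmill heart rate:

```r
estimate_vo2max(data.frame(speed = 9, hr = 149, age = 30),
                speed_unit = "mph")$vo2max
#> [1] 61.13315
```

A command-line interface wraps the same functions
(`exec/runfuel estimate-vo2max --speed 9 --unit mph --hr 149 --age 30`,
`predict-wall`, `fueling-plan`, `make-figures`, `simulate-cohort`).

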