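#' Carbohydrate energy required for a race
#'
#' Of the total race energy \eqn{C M d}, the fraction supplied by
#' carbohydrate at intensity \eqn{i} is \eqn{f_{CHO}(i)}, so
#' \deqn{E_{CHO} = C M d\, f_{CHO}(i).}
#' For a runner of given mass and VO2max over a fixed distance this depends
#' only on pace.
#'
#' @param profile a [runner_profile()] tibble.
#' @param plan a [race_plan()].
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return A tibble with columns `intensity`, `speed_kmh`, `cho_kcal`, and
#'   `cho_kcal_per_kg`.
#' @examples
#' cho_energy_required(runner_profile(mass = 75, vo2max = 55),
#'                     race_plan(42.195, finish_time = "3:42:00"))
#' @export
cho_energy_required <- function(profile, plan, partition = default_partition(),
                                stoich = stoichiometry()) {
  res <- resolve_intensity(profile, plan, partition, stoich)
  per_kg <- stoich$running_cost * plan$distance_km *
    f_cho(partition, res$intensity)
  tibble(
    intensity = res$intensity,
    speed_kmh = res$speed_kmh,
    cho_kcal = per_kg * profile$mass,
    cho_kcal_per_kg = per_kg
  )
}

#' Distance to glycogen depletion ("the wall")
#'
#' The ratio of glycogen energy stored per kg body mass to carbohydrate
#' energy burned per kg per km at intensity \eqn{i}:
#' \deqn{d_w = \frac{f_{liver}\rho_{liver} + f_{legs}\rho_{muscle}}
#'       {C\, f_{CHO}(i)}.}
#' Decreasing in intensity, increasing in every reserve parameter, and
#' independent of body mass at fixed tissue fractions. When
#' \eqn{f_{CHO}(i) = 0} the carbohydrate drain vanishes and `Inf` is
#' returned.
#'
#' @param profile a [runner_profile()] tibble.
#' @param intensity relative intensity in (0, 1\] (scalar or one per runner).
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return Distance in km (numeric vector; `Inf` when no carbohydrate is
#'   burned).
#' @examples
#' distance_to_wall(runner_profile(mass = 70), intensity = 0.8)
#' @export
distance_to_wall <- function(profile, intensity,
                             partition = default_partition(),
                             stoich = stoichiometry()) {
  check_intensity(intensity, arg = "intensity")
  f <- f_cho(partition, intensity)
  out <- specific_reserve(profile, stoich) / (stoich$running_cost * f)
  out[rep_len(f == 0, length(out))] <- Inf
  out
}

#' Minimum leg-muscle fraction to finish without depletion
#'
#' Solves the depletion boundary `specific_reserve == cho_kcal_per_kg` for
#' the leg-muscle fraction, with the liver contribution fixed:
#' \deqn{f_{legs}^{min} = \max\!\left(0,\;
#'   \frac{C d\,f_{CHO}(i) - f_{liver}\rho_{liver}}{\rho_{muscle}}\right).}
#' Defaults assume maximal loading of both tissues (muscle 144 kcal/kg by
#' supercompensation, liver 2.5% of mass at 360 kcal/kg).
#'
#' @param vo2max aerobic capacity, ml/kg/min (vectorized).
#' @param plan a [race_plan()] with a time or speed target.
#' @param muscle_density_kcal_per_kg muscle glycogen density, kcal per kg
#'   muscle.
#' @param liver_fraction liver mass fraction of body mass.
#' @param liver_density_kcal_per_kg liver glycogen density, kcal per kg liver.
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return Minimum leg-muscle fraction of body mass (0 if the liver alone
#'   suffices).
#' @examples
#' min_leg_fraction(55, race_plan(42.195, finish_time = "3:42:00"))
#' @export
min_leg_fraction <- function(vo2max, plan, muscle_density_kcal_per_kg = 144,
                             liver_fraction = 0.025,
                             liver_density_kcal_per_kg = 360,
                             partition = default_partition(),
                             stoich = stoichiometry()) {
  check_positive(vo2max = vo2max,
                 muscle_density_kcal_per_kg = muscle_density_kcal_per_kg)
  prof <- runner_profile(mass = 1, vo2max = vo2max)
  res <- resolve_intensity(prof, plan, partition, stoich)
  e_per_kg <- stoich$running_cost * plan$distance_km *
    f_cho(partition, res$intensity)
  pmax(0, (e_per_kg - liver_fraction * liver_density_kcal_per_kg) /
         muscle_density_kcal_per_kg)
}

#' Maximal change in muscle glycogen density over a race
#'
#' Attributes all carbohydrate burned (net of exogenous intake) to leg-muscle
#' glycogen — a maximal depletion estimate:
#' \deqn{\Delta\rho_{muscle} = \frac{C d\, f_{CHO}(i) - E_{exo}/M}
#'       {f_{legs}} \quad [\mathrm{kcal/kg\ leg\ muscle}].}
#' The value is returned unclipped; `exceeds_stored` flags predictions larger
#' than the stored density (the runner would have hit the wall midrace).
#'
#' @param profile a [runner_profile()] tibble.
#' @param plan a [race_plan()].
#' @param fueling a [fueling_plan()]; defaults to no intake.
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return A tibble with columns `delta_kcal_per_kg_muscle`,
#'   `delta_mmol_per_kg_muscle`, and `exceeds_stored`.
#' @export
delta_muscle_glycogen <- function(profile, plan, fueling = fueling_plan(0),
                                  partition = default_partition(),
                                  stoich = stoichiometry()) {
  stopifnot(inherits(fueling, "fueling_plan"))
  if (any(profile$leg_muscle_fraction <= 0)) {
    abort("Leg-muscle fraction must be positive to express a per-kg-muscle change.",
          class = "runfuel_domain_error")
  }
  req <- cho_energy_required(profile, plan, partition, stoich)
  exo_kcal <- glycogen_energy(fueling$total_g, stoich)
  delta <- (req$cho_kcal_per_kg - exo_kcal / profile$mass) /
    profile$leg_muscle_fraction
  tibble(
    delta_kcal_per_kg_muscle = delta,
    delta_mmol_per_kg_muscle = delta / glycogen_kcal_per_mmol(stoich),
    exceeds_stored = delta >
      glycogen_density_kcal(profile$muscle_glycogen_density, stoich)
  )
}

#' Minimum exogenous carbohydrate to avoid the wall
#'
#' The deficit between the carbohydrate energy a race requires and the
#' energy stored as glycogen, expressed as grams of carbohydrate:
#' \deqn{m_{exo} = \frac{\max(0,\; C M d\, f_{CHO}(i) - M S)}
#'       {\rho_{CHO}}\quad [\mathrm{g}],}
#' with \eqn{S} the specific reserve (kcal/kg). Exactly zero when the
#' distance to the wall is at least the race distance.
#'
#' @inheritParams delta_muscle_glycogen
#' @return Grams of carbohydrate (numeric vector).
#' @examples
#' required_exogenous_cho(runner_profile(mass = 75, vo2max = 45),
#'                        race_plan(42.195, finish_time = "3:42:00"))
#' @export
required_exogenous_cho <- function(profile, plan,
                                   partition = default_partition(),
                                   stoich = stoichiometry()) {
  req <- cho_energy_required(profile, plan, partition, stoich)
  deficit <- pmax(0, req$cho_kcal - profile$mass *
                    specific_reserve(profile, stoich))
  deficit / stoich$cho_energy_density
}

#' Full race prediction for one or more runners
#'
#' Assembles the headline quantities into one row per runner: resolved
#' intensity, carbohydrate budget, distance to the wall, whether the wall
#' falls inside the race, the minimum exogenous carbohydrate to avoid it,
#' and the maximal muscle-glycogen depletion. With `with_errors = TRUE`,
#' first-order error bounds from the partition uncertainty (see
#' [propagate_error()]) are appended: the carbohydrate budget carries the
#' relative error in f_cho exactly, and the wall distance carries it with
#' opposite sign.
#'
#' @inheritParams delta_muscle_glycogen
#' @param fueling optional [fueling_plan()].
#' @param with_errors append error-bound columns.
#' @param delta_f_rel relative error in f_cho; defaults to the largest
#'   propagated anchor error of the packaged table.
#' @return A tibble, one row per runner.
#' @examples
#' predict_race(runner_profile(mass = 75, vo2max = 55),
#'              race_plan(42.195, finish_time = "3:42:00"))
#' @export
predict_race <- function(profile, plan, fueling = fueling_plan(0),
                         partition = default_partition(),
                         stoich = stoichiometry(),
                         with_errors = FALSE, delta_f_rel = NULL) {
  req <- cho_energy_required(profile, plan, partition, stoich)
  d_wall <- distance_to_wall(profile, req$intensity, partition, stoich)
  exo <- required_exogenous_cho(profile, plan, partition, stoich)
  depl <- delta_muscle_glycogen(profile, plan, fueling, partition, stoich)
  out <- dplyr::bind_cols(
    tibble(mass = profile$mass, vo2max = profile$vo2max),
    req,
    tibble(
      distance_to_wall_km = d_wall,
      will_hit_wall = d_wall < plan$distance_km,
      min_exogenous_cho_g = exo
    ),
    depl
  )
  if (with_errors) {
    delta <- delta_f_rel %||% max(anchor_errors(partition$anchors)$rel_error)
    out$rel_err_f_cho <- delta
    out$cho_kcal_lo <- out$cho_kcal * (1 - delta)
    out$cho_kcal_hi <- out$cho_kcal * (1 + delta)
    out$distance_to_wall_km_lo <- out$distance_to_wall_km * (1 - delta)
    out$distance_to_wall_km_hi <- out$distance_to_wall_km * (1 + delta)
  }
  out
}

#' Carbohydrate cost of uneven pacing
#'
#' A runner covering distance `d` in fixed total time can hold the mean
#' speed throughout, or split the race between a slower and a faster speed.
#' Because \eqn{f_{CHO}} rises supralinearly (convexly) with speed, any
#' proper split burns strictly more carbohydrate than the constant-pace
#' strategy; constant exertion is the carbohydrate-optimal pacing.
#'
#' The split runs a fraction of the distance at `speed_lo` and the rest at
#' `speed_hi`; the fraction is determined by the requirement that total time
#' equals `distance_km / mean_speed` (a time-weighted speed average equal to
#' the mean speed). If `fraction_lo` is supplied it is checked against that
#' requirement.
#'
#' @param profile a one-row [runner_profile()] (mass and vo2max used).
#' @param distance_km race distance, km.
#' @param mean_speed required overall mean speed, km/h.
#' @param speed_lo,speed_hi the two split speeds, `speed_lo <= mean_speed <=
#'   speed_hi`, both aerobic.
#' @param fraction_lo optional fraction of the *distance* run at `speed_lo`
#'   (validated, not used for the computation).
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return Excess carbohydrate energy of the split over the constant
#'   strategy, kcal (>= 0; 0 only for the degenerate split).
#' @examples
#' pacing_penalty(runner_profile(mass = 70, vo2max = 55), 42.195,
#'                mean_speed = 11.4, speed_lo = 10.5, speed_hi = 12.5)
#' @export
pacing_penalty <- function(profile, distance_km, mean_speed, speed_lo, speed_hi,
                           fraction_lo = NULL,
                           partition = default_partition(),
                           stoich = stoichiometry()) {
  check_positive(distance_km = distance_km, mean_speed = mean_speed,
                 speed_lo = speed_lo, speed_hi = speed_hi)
  if (!(speed_lo <= mean_speed && mean_speed <= speed_hi)) {
    abort("Need `speed_lo` <= `mean_speed` <= `speed_hi`.",
          class = "runfuel_plan_error")
  }
  if (speed_lo == speed_hi) return(rep(0, nrow(profile)))
  # distance fraction at the slow speed from the total-time constraint
  p <- (1 / mean_speed - 1 / speed_hi) / (1 / speed_lo - 1 / speed_hi)
  if (p < -1e-12 || p > 1 + 1e-12) {
    abort("Split cannot average to `mean_speed` over the distance.",
          class = "runfuel_plan_error")
  }
  p <- min(max(p, 0), 1)
  if (!is.null(fraction_lo) && abs(fraction_lo - p) > 1e-6) {
    abort(sprintf("`fraction_lo` inconsistent with the mean-speed constraint (expected %.8f).", p),
          class = "runfuel_plan_error")
  }
  i_lo <- intensity_from_speed(speed_lo, profile$vo2max, partition, stoich)
  i_hi <- intensity_from_speed(speed_hi, profile$vo2max, partition, stoich)
  i_mean <- intensity_from_speed(mean_speed, profile$vo2max, partition, stoich)
  split_f <- p * f_cho(partition, i_lo) + (1 - p) * f_cho(partition, i_hi)
  stoich$running_cost * profile$mass * distance_km *
    (split_f - f_cho(partition, i_mean))
}
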