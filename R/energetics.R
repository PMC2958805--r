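check_positive <- function(..., .arg_names = NULL) {
  vals <- list(...)
  nms <- .arg_names %||% names(vals)
  for (k in seq_along(vals)) {
    v <- vals[[k]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0)) {
      abort(paste0("`", nms[k], "` must be positive and finite."),
            class = "runfuel_domain_error")
    }
  }
  invisible(NULL)
}

#' Energy liberated per mole of oxygen for the fuel mixture at intensity i
#'
#' The convex combination \eqn{\rho(i) = f_{CHO}(i)\,\rho_{CHO} +
#' (1 - f_{CHO}(i))\,\rho_{fat}} of the pure-substrate energy-per-mole-O2
#' constants; it always lies between the fat and carbohydrate limits.
#'
#' @param partition a [fit_partition()] object.
#' @param i relative intensity in (0, 1\] (vectorized).
#' @param stoich a [stoichiometry()] object.
#' @param warn passed to [f_cho()].
#' @return kcal per mole O2.
#' @examples
#' mixture_energy_per_mol_o2(fit_partition(), 0.75)
#' @export
mixture_energy_per_mol_o2 <- function(partition = default_partition(), i,
                                      stoich = stoichiometry(), warn = TRUE) {
  f <- f_cho(partition, i, warn = warn)
  f * stoich$energy_per_mol_o2_cho + (1 - f) * stoich$energy_per_mol_o2_fat
}

#' Whole-body aerobic power output
#'
#' Converts an oxygen-uptake rate to metabolic power. At relative intensity
#' `i`, VO2 is `vo2max * i` ml/kg/min; converting to moles of O2 per hour via
#' the molar volume and multiplying by the fuel-mixture energy per mole of
#' oxygen at that intensity gives power in kcal per hour:
#' \deqn{P = \frac{\dot{V}O_{2max}\, i\, M \cdot 60}{1000\, V_m}\, \rho(i).}
#'
#' @param vo2max aerobic capacity, ml O2 per kg body mass per minute.
#' @param i relative intensity, fraction of VO2max in (0, 1\].
#' @param mass body mass, kg.
#' @inheritParams mixture_energy_per_mol_o2
#' @return Power in kcal per hour.
#' @examples
#' # 60-kg runner, VO2max 75, at 75% of capacity:
#' aerobic_power(75, 0.75, 60)
#' @export
aerobic_power <- function(vo2max, i, mass, partition = default_partition(),
                          stoich = stoichiometry(), warn = TRUE) {
  check_positive(vo2max = vo2max, mass = mass)
  check_intensity(i)
  mol_o2_per_h <- vo2max * i * mass * 60 / (1000 * stoich$molar_volume_l)
  mol_o2_per_h * mixture_energy_per_mol_o2(partition, i, stoich, warn = warn)
}

#' Interconvert running speed and metabolic power
#'
#' Level running costs `running_cost` (C, ~1 kcal/kg/km) regardless of speed,
#' so power and speed are proportional: \eqn{P = C v M}. The two functions
#' are exact mutual inverses.
#'
#' @param speed running speed, km/h.
#' @param power metabolic power, kcal/h.
#' @param mass body mass, kg.
#' @param stoich a [stoichiometry()] object.
#' @return `power_from_speed()`: kcal/h; `speed_from_power()`: km/h.
#' @examples
#' speed_from_power(1020, 60) # 17 km/h at C = 1
#' @export
power_from_speed <- function(speed, mass, stoich = stoichiometry()) {
  check_positive(speed = speed, mass = mass)
  stoich$running_cost * speed * mass
}

#' @rdname power_from_speed
#' @export
speed_from_power <- function(power, mass, stoich = stoichiometry()) {
  check_positive(power = power, mass = mass)
  power / (stoich$running_cost * mass)
}

#' Total metabolic energy of a race
#'
#' \eqn{E = C M d}: the energetic cost of running depends only on mass and
#' distance, not on speed (running faster costs proportionately more power
#' for proportionately less time).
#'
#' @param mass body mass, kg.
#' @param distance race distance, km.
#' @param stoich a [stoichiometry()] object.
#' @return Energy in kcal.
#' @examples
#' total_race_energy(70, 42.195) # ~2950 kcal for a 70-kg marathoner
#' @export
total_race_energy <- function(mass, distance, stoich = stoichiometry()) {
  check_positive(mass = mass)
  if (any(distance < 0)) {
    abort("`distance` must be nonnegative.", class = "runfuel_domain_error")
  }
  stoich$running_cost * mass * distance
}

#' Age-predicted maximum heart rate
#'
#' Two widely used formulas: Fox-Haskell (`220 - age`) and Tanaka
#' (`207 - 0.7 * age`, meta-analytically supported for active adults).
#'
#' @param age age in years, in (0, 120).
#' @param formula `"tanaka"` (default) or `"fox"`.
#' @return Maximum heart rate in beats per minute.
#' @examples
#' hr_max(30)          # 186 bpm (Tanaka)
#' hr_max(20, "fox")   # 200 bpm
#' @export
hr_max <- function(age, formula = c("tanaka", "fox")) {
  formula <- tryCatch(match.arg(formula),
                      error = function(e) {
                        abort("`formula` must be \"tanaka\" or \"fox\".",
                              class = "runfuel_config_error")
                      })
  if (!is.numeric(age) || any(age <= 0 | age >= 120)) {
    abort("`age` must be in (0, 120) years.", class = "runfuel_domain_error")
  }
  switch(formula, tanaka = 207 - 0.7 * age, fox = 220 - age)
}

#' Estimate VO2max from heart rate observed while running at a known speed
#'
#' Fractional maximum heart rate \eqn{h = HR / HR_{max}} is used one-to-one
#' as a proxy for relative aerobic intensity. Running at speed \eqn{v} costs
#' power \eqn{C v} per kg, which corresponds to an oxygen-uptake rate of
#' \eqn{C v / \rho(h)} mol O2 per kg per hour at the fuel mixture implied by
#' \eqn{h}; converting to ml/kg/min and dividing by \eqn{h} extrapolates to
#' maximal uptake:
#' \deqn{\dot{V}O_{2max} = \frac{C v}{h\,\rho(h)} \cdot
#'       \frac{1000\,V_m}{60}.}
#'
#' @param data data frame of observations with columns `speed` (in the unit
#'   named by `speed_unit`), `hr` (beats/min), and `age` (years); an optional
#'   `hr_max` column overrides the age formula, and an optional `mass` column
#'   (kg) adds absolute VO2max in ml/min.
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @param speed_unit `"kmh"` or `"mph"`.
#' @param formula maximum-heart-rate formula, see [hr_max()].
#' @return The input as a tibble with added columns `speed_kmh`, `hr_max`,
#'   `intensity` (= h), and `vo2max` (ml/kg/min; plus `vo2max_ml_min` if
#'   `mass` was supplied).
#' @examples
#' estimate_vo2max(data.frame(speed = 9, hr = 149, age = 30),
#'                 speed_unit = "mph")
#' @export
estimate_vo2max <- function(data, partition = default_partition(),
                            stoich = stoichiometry(),
                            speed_unit = c("kmh", "mph"),
                            formula = c("tanaka", "fox")) {
  speed_unit <- match.arg(speed_unit)
  if (!is.data.frame(data) || !all(c("speed", "hr", "age") %in% names(data))) {
    abort("`data` needs columns `speed`, `hr`, and `age`.",
          class = "runfuel_config_error")
  }
  out <- as_tibble(data)
  out$speed_kmh <- if (speed_unit == "mph") out$speed * stoich$mile_km else out$speed
  check_positive(speed = out$speed_kmh)
  hrm <- if ("hr_max" %in% names(out) && any(!is.na(out$hr_max))) {
    ifelse(is.na(out$hr_max), hr_max(out$age, formula), out$hr_max)
  } else {
    hr_max(out$age, formula)
  }
  h <- out$hr / hrm
  if (any(h <= 0 | h > 1)) {
    abort("Fractional heart rate hr/hr_max must lie in (0, 1].",
          class = "runfuel_domain_error")
  }
  rho <- mixture_energy_per_mol_o2(partition, h, stoich)
  vo2_ml_kg_min <- stoich$running_cost * out$speed_kmh / rho *
    1000 * stoich$molar_volume_l / 60
  out$hr_max <- hrm
  out$intensity <- h
  out$vo2max <- vo2_ml_kg_min / h
  if ("mass" %in% names(out)) out$vo2max_ml_min <- out$vo2max * out$mass
  out
}

#' Maximum aerobically sustainable running speed
#'
#' The speed at which the power required to run equals whole-body aerobic
#' power at full capacity (i = 1):
#' \deqn{v_{max} = \frac{\dot{V}O_{2max} \cdot 60}{1000\,V_m}\,
#'       \frac{\rho(1)}{C},}
#' where \eqn{\rho(1)} is the fuel-mixture energy per mole O2 at maximal
#' aerobic intensity. Body mass cancels: both required and available power
#' scale linearly with it.
#'
#' @inheritParams aerobic_power
#' @return Speed in km/h.
#' @examples
#' max_aerobic_speed(55)
#' @export
max_aerobic_speed <- function(vo2max, partition = default_partition(),
                              stoich = stoichiometry()) {
  check_positive(vo2max = vo2max)
  vo2max * 60 / (1000 * stoich$molar_volume_l) *
    mixture_energy_per_mol_o2(partition, 1, stoich) / stoich$running_cost
}

#' Relative intensity implied by a running speed
#'
#' For a runner of known VO2max, \eqn{i \approx v / v_{max}}. Speeds above
#' the maximum aerobic speed are a hard error: the anaerobic regime is out
#' of the model's scope.
#'
#' @param speed running speed, km/h.
#' @inheritParams aerobic_power
#' @return Intensity fraction in (0, 1\].
#' @examples
#' intensity_from_speed(42.195 / 3.7, 55) # 3:42:00 marathon at VO2max 55
#' @export
intensity_from_speed <- function(speed, vo2max, partition = default_partition(),
                                 stoich = stoichiometry()) {
  check_positive(speed = speed, vo2max = vo2max)
  i <- speed / max_aerobic_speed(vo2max, partition, stoich)
  if (any(i > 1 + 1e-9)) {
    abort("Speed exceeds the maximum aerobic speed for this VO2max (supra-aerobic).",
          class = "runfuel_supra_aerobic_error")
  }
  pmin(i, 1)
}
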