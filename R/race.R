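#' Define a race plan
#'
#' A race plan is a distance plus exactly one pacing target: a finish time
#' (numeric hours or `"h:mm:ss"`), a speed in km/h, or a relative intensity
#' (fraction of VO2max). Whichever is given, the implied intensity must
#' resolve into (0, 1\] for the runner it is applied to.
#'
#' @param distance_km race distance, km (> 0).
#' @param finish_time target finish time, hours or `"h:mm:ss"`.
#' @param speed_kmh target speed, km/h.
#' @param intensity target relative intensity in (0, 1\].
#' @return An object of class `"race_plan"`.
#' @examples
#' race_plan(42.195, finish_time = "3:42:00")
#' @export
race_plan <- function(distance_km, finish_time = NULL, speed_kmh = NULL,
                      intensity = NULL) {
  check_positive(distance_km = distance_km)
  given <- !vapply(list(finish_time, speed_kmh, intensity), is.null, logical(1))
  if (sum(given) != 1) {
    abort("Provide exactly one of `finish_time`, `speed_kmh`, `intensity`.",
          class = "runfuel_config_error")
  }
  if (!is.null(finish_time)) finish_time <- parse_hours(finish_time)
  if (!is.null(speed_kmh)) check_positive(speed_kmh = speed_kmh)
  if (!is.null(intensity)) check_intensity(intensity, arg = "intensity")
  structure(
    list(distance_km = distance_km, finish_time = finish_time,
         speed_kmh = speed_kmh, intensity = intensity),
    class = "race_plan"
  )
}

#' @export
print.race_plan <- function(x, ...) {
  tgt <- if (!is.null(x$finish_time)) {
    sprintf("finish time %.4g h", x$finish_time)
  } else if (!is.null(x$speed_kmh)) {
    sprintf("speed %.4g km/h", x$speed_kmh)
  } else {
    sprintf("intensity %.3g", x$intensity)
  }
  cat(sprintf("<race_plan> %g km at %s\n", x$distance_km, tgt))
  invisible(x)
}

#' Define a midrace fueling plan
#'
#' Total exogenous carbohydrate (grams), optionally broken into a schedule of
#' (distance, grams) stations. The schedule must sum to the total; absorption
#' timing is not modeled — as a rule of thumb, carbohydrate should be
#' ingested roughly 30 minutes before it is needed.
#'
#' @param total_g total grams of carbohydrate consumed en route (>= 0).
#' @param schedule optional data frame with columns `distance_km` and
#'   `grams`; if given without `total_g`, its sum is used.
#' @return An object of class `"fueling_plan"`.
#' @examples
#' fueling_plan(schedule = data.frame(distance_km = seq(4, 28, 4), grams = 20))
#' @export
fueling_plan <- function(total_g = NULL, schedule = NULL) {
  if (!is.null(schedule)) {
    if (!is.data.frame(schedule) ||
          !all(c("distance_km", "grams") %in% names(schedule))) {
      abort("`schedule` needs columns `distance_km` and `grams`.",
            class = "runfuel_config_error")
    }
    if (any(schedule$grams < 0) || any(schedule$distance_km <= 0)) {
      abort("Schedule grams must be >= 0 and distances > 0.",
            class = "runfuel_config_error")
    }
    sched_total <- sum(schedule$grams)
    if (is.null(total_g)) {
      total_g <- sched_total
    } else if (abs(total_g - sched_total) > 1e-9) {
      abort("`schedule` grams must sum to `total_g`.",
            class = "runfuel_config_error")
    }
  }
  total_g <- total_g %||% 0
  if (!is.numeric(total_g) || length(total_g) != 1 || total_g < 0) {
    abort("`total_g` must be a nonnegative scalar.",
          class = "runfuel_config_error")
  }
  structure(list(total_g = total_g, schedule = schedule),
            class = "fueling_plan")
}

#' Resolve a race plan to a relative intensity for each runner
#'
#' Resolution order: a finish time becomes a speed (`distance / time`); a
#' speed becomes an intensity via [intensity_from_speed()]; an explicit
#' intensity is used as is. Supra-aerobic paces are a hard error.
#'
#' @param profile a [runner_profile()] tibble.
#' @param plan a [race_plan()].
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return A tibble with columns `intensity` and `speed_kmh` (speed is `NA`
#'   when the plan fixes intensity directly, as it then depends only on the
#'   runner's maximum aerobic speed).
#' @export
resolve_intensity <- function(profile, plan, partition = default_partition(),
                              stoich = stoichiometry()) {
  stopifnot(inherits(plan, "race_plan"))
  if (!is.null(plan$intensity)) {
    v <- if (all(!is.na(profile$vo2max))) {
      plan$intensity * max_aerobic_speed(profile$vo2max, partition, stoich)
    } else {
      rep(NA_real_, nrow(profile))
    }
    return(tibble(intensity = rep(plan$intensity, nrow(profile)), speed_kmh = v))
  }
  v <- plan$speed_kmh %||% (plan$distance_km / plan$finish_time)
  if (any(is.na(profile$vo2max))) {
    abort("Resolving a time/speed target requires `vo2max` in the profile.",
          class = "runfuel_config_error")
  }
  i <- intensity_from_speed(v, profile$vo2max, partition, stoich)
  tibble(intensity = i, speed_kmh = rep(v, nrow(profile)))
}
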