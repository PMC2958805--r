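#' Pace and finishing-time formatting
#'
#' `pace_format()` renders a speed as a minutes:seconds-per-mile pace string,
#' rounding half-up to the nearest second. `marathon_time()` renders the time
#' to cover the marathon distance at a given speed as `h:mm:ss`.
#'
#' @param speed running speed, km/h (vectorized).
#' @param stoich a [stoichiometry()] object (supplies the mile and marathon
#'   constants).
#' @return Character vector.
#' @examples
#' pace_format(42.195 / (19 / 6)) # 3:10:00 marathon -> "7:15"
#' marathon_time(42.195 / 3.7)    # "3:42:00"
#' @export
pace_format <- function(speed, stoich = stoichiometry()) {
  check_positive(speed = speed)
  sec <- floor(60 * 60 * stoich$mile_km / speed + 0.5)
  sprintf("%d:%02d", sec %/% 60, sec %% 60)
}

#' @rdname pace_format
#' @export
marathon_time <- function(speed, stoich = stoichiometry()) {
  check_positive(speed = speed)
  sec <- floor(3600 * stoich$marathon_km / speed + 0.5)
  sprintf("%d:%02d:%02d", sec %/% 3600, (sec %% 3600) %/% 60, sec %% 60)
}

#' Parse a clock duration into hours
#'
#' Accepts numeric hours unchanged, or strings `"h:mm:ss"` / `"mm:ss"`.
#'
#' @param x numeric hours or a character duration.
#' @return Numeric hours.
#' @examples
#' parse_hours("3:42:00")
#' @export
parse_hours <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    p <- suppressWarnings(as.numeric(p))
    if (any(is.na(p)) || !length(p) %in% 2:3) {
      abort("Durations must be numeric hours, \"h:mm:ss\", or \"mm:ss\".",
            class = "runfuel_config_error")
    }
    if (length(p) == 2) p <- c(0, p)
    p[1] + p[2] / 60 + p[3] / 3600
  }, numeric(1))
}

#' Convert miles per hour to km/h
#'
#' @param mph speed in statute miles per hour.
#' @param stoich a [stoichiometry()] object.
#' @return Speed in km/h.
#' @export
mph_to_kmh <- function(mph, stoich = stoichiometry()) {
  mph * stoich$mile_km
}
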