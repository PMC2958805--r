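#' Specify a synthetic runner cohort
#'
#' Ranges default to sex-specific population bands: leg-muscle fractions
#' 14.0-27.5% of body mass in men and 18.0-22.5% in women; VO2max 38-52
#' (men) and 30-44 (women) ml/kg/min, 10th-90th-percentile-style bands for
#' adults in their twenties; body mass 55-90 kg (men) and 45-75 kg (women);
#' muscle glycogen 80-200 mmol/kg (trained through supercompensated).
#' Supplying a range overrides the sex-specific default for all runners.
#'
#' @param n number of runners (>= 0).
#' @param prop_male proportion of male runners in \[0, 1\].
#' @param vo2max_range,leg_fraction_range,muscle_density_range,mass_range
#'   optional length-2 numeric ranges overriding the defaults.
#' @param seed integer seed; a fixed seed reproduces the cohort exactly.
#' @param sampling `"uniform"` draws uniformly within each range;
#'   `"normal"` treats the range as a 10th-90th percentile band of a normal
#'   distribution (draws clamped to the range).
#' @return An object of class `"cohort_spec"`.
#' @examples
#' cohort_spec(10, seed = 1)
#' @export
cohort_spec <- function(n, prop_male = 1, vo2max_range = NULL,
                        leg_fraction_range = NULL,
                        muscle_density_range = NULL, mass_range = NULL,
                        seed = 1L, sampling = c("uniform", "normal")) {
  sampling <- match.arg(sampling)
  if (!is.numeric(n) || length(n) != 1 || n < 0 || n != floor(n)) {
    abort("`n` must be a nonnegative integer.", class = "runfuel_spec_error")
  }
  if (prop_male < 0 || prop_male > 1) {
    abort("`prop_male` must lie in [0, 1].", class = "runfuel_spec_error")
  }
  check_range <- function(r, nm, lo, hi) {
    if (is.null(r)) return(NULL)
    if (length(r) != 2 || r[1] >= r[2] || r[1] < lo || r[2] > hi) {
      abort(sprintf("`%s` must be an increasing range within [%g, %g].",
                    nm, lo, hi),
            class = "runfuel_spec_error")
    }
    r
  }
  structure(
    list(
      n = as.integer(n),
      prop_male = prop_male,
      vo2max_range = check_range(vo2max_range, "vo2max_range", 10, 95),
      leg_fraction_range = check_range(leg_fraction_range,
                                       "leg_fraction_range", 0.05, 0.35),
      muscle_density_range = check_range(muscle_density_range,
                                         "muscle_density_range", 0, 200),
      mass_range = check_range(mass_range, "mass_range", 30, 150),
      seed = as.integer(seed),
      sampling = sampling
    ),
    class = "cohort_spec"
  )
}

cohort_defaults <- list(
  male = list(vo2max = c(38, 52), legs = c(0.140, 0.275),
              mass = c(55, 90)),
  female = list(vo2max = c(30, 44), legs = c(0.180, 0.225),
                mass = c(45, 75))
)

draw_in_range <- function(n, range, sampling) {
  if (n == 0) return(numeric(0))
  if (sampling == "uniform") {
    runif(n, range[1], range[2])
  } else {
    mid <- mean(range)
    sd <- diff(range) / (2 * qnorm(0.9))
    pmin(pmax(rnorm(n, mid, sd), range[1]), range[2])
  }
}

#' Sample a synthetic cohort of runner profiles
#'
#' Draws are independent within the spec's ranges and fully reproducible
#' under the spec's seed (the global RNG state is left untouched).
#'
#' @param spec a [cohort_spec()].
#' @return A [runner_profile()] tibble with `spec$n` rows.
#' @examples
#' sample_cohort(cohort_spec(5, seed = 42))
#' @export
sample_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  if (n == 0) {
    return(runner_profile(mass = numeric(0), sex = character(0)))
  }
  withr::with_seed(spec$seed, {
    n_male <- rbinom(1, n, spec$prop_male)
    sex <- sample(c(rep("male", n_male), rep("female", n - n_male)))
    per_sex <- function(field, override) {
      if (!is.null(override)) return(draw_in_range(n, override, spec$sampling))
      out <- numeric(n)
      for (s in c("male", "female")) {
        idx <- which(sex == s)
        out[idx] <- draw_in_range(length(idx), cohort_defaults[[s]][[field]],
                                  spec$sampling)
      }
      out
    }
    vo2max <- per_sex("vo2max", spec$vo2max_range)
    legs <- per_sex("legs", spec$leg_fraction_range)
    mass <- per_sex("mass", spec$mass_range)
    muscle <- draw_in_range(n, spec$muscle_density_range %||% c(80, 200),
                            spec$sampling)
    runner_profile(
      mass = mass, vo2max = vo2max, sex = sex,
      leg_muscle_fraction = legs, muscle_glycogen_density = muscle
    )
  })
}
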