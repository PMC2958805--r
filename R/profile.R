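#' Construct runner profiles
#'
#' A runner profile collects the anthropometric and physiologic parameters of
#' one runner per row. All arguments are vectorized and recycle in the usual
#' tibble way, so a single call can build a whole cohort.
#'
#' Defaults describe a typical trained male endurance runner: leg muscles
#' 21.4% of body mass, liver 2.5% of body mass, trained-but-unloaded muscle
#' glycogen (110 mmol/kg == 79.2 kcal/kg), and maximally loaded liver
#' glycogen (500 mmol/kg == 360 kcal/kg) — the same baseline the wall-distance
#' figures assume. Glycogen densities are stored in mmol glycosyl residues
#' per kg tissue; convert with [glycogen_density_kcal()].
#'
#' @param mass body mass, kg.
#' @param vo2max aerobic capacity, ml O2/kg/min (`NA` allowed if only
#'   reservoir accounting is needed).
#' @param sex `"male"` or `"female"`.
#' @param age years (optional, used for heart-rate formulas).
#' @param leg_muscle_fraction leg muscle mass as a fraction of body mass;
#'   values outside \[0.10, 0.35\] draw a warning (population ranges are
#'   14.0-27.5% in men, 18.0-22.5% in women).
#' @param liver_fraction liver mass as a fraction of body mass (tightly
#'   regulated near 2.5%).
#' @param muscle_glycogen_density mmol glycosyl residues per kg muscle;
#'   physiologic maximum 200 (glycogen supercompensation).
#' @param liver_glycogen_density mmol glycosyl residues per kg liver;
#'   typical 270, physiologic maximum 500.
#' @param nonessential_fat_fraction nonessential body fat as a fraction of
#'   body mass.
#' @return A tibble (class `runner_profile`) with one row per runner.
#' @examples
#' runner_profile(mass = 75, vo2max = 55)
#' @export
runner_profile <- function(mass,
                           vo2max = NA_real_,
                           sex = "male",
                           age = NA_real_,
                           leg_muscle_fraction = 0.214,
                           liver_fraction = 0.025,
                           muscle_glycogen_density = 110,
                           liver_glycogen_density = 500,
                           nonessential_fat_fraction = 0.15) {
  out <- tibble(
    mass = as.numeric(mass),
    vo2max = as.numeric(vo2max),
    sex = as.character(sex),
    age = as.numeric(age),
    leg_muscle_fraction = as.numeric(leg_muscle_fraction),
    liver_fraction = as.numeric(liver_fraction),
    muscle_glycogen_density = as.numeric(muscle_glycogen_density),
    liver_glycogen_density = as.numeric(liver_glycogen_density),
    nonessential_fat_fraction = as.numeric(nonessential_fat_fraction)
  )
  validate_profile(out)
  class(out) <- c("runner_profile", class(out))
  out
}

validate_profile <- function(p) {
  if (any(!is.finite(p$mass) | p$mass <= 0)) {
    abort("`mass` must be positive.", class = "runfuel_domain_error")
  }
  if (any(!is.na(p$vo2max) & p$vo2max <= 0)) {
    abort("`vo2max` must be positive when given.", class = "runfuel_domain_error")
  }
  if (!all(p$sex %in% c("male", "female"))) {
    abort("`sex` must be \"male\" or \"female\".", class = "runfuel_config_error")
  }
  fracs <- c("leg_muscle_fraction", "liver_fraction", "nonessential_fat_fraction")
  for (f in fracs) {
    v <- p[[f]]
    if (any(!is.finite(v) | v < 0 | v >= 1)) {
      abort(paste0("`", f, "` must lie in [0, 1)."), class = "runfuel_domain_error")
    }
  }
  if (any(p$leg_muscle_fraction < 0.10 | p$leg_muscle_fraction > 0.35)) {
    warn("`leg_muscle_fraction` outside the physiologic band [0.10, 0.35].")
  }
  if (any(p$muscle_glycogen_density < 0 | p$muscle_glycogen_density > 200)) {
    abort("`muscle_glycogen_density` must be in [0, 200] mmol/kg (physiologic max).",
          class = "runfuel_domain_error")
  }
  if (any(p$liver_glycogen_density < 0 | p$liver_glycogen_density > 500)) {
    abort("`liver_glycogen_density` must be in [0, 500] mmol/kg (physiologic max).",
          class = "runfuel_domain_error")
  }
  invisible(p)
}

#' Read a runner profile from a YAML config file
#'
#' The file holds flat keys named exactly as the [runner_profile()] arguments
#' (SI units: kg, ml/kg/min, years, dimensionless fractions, mmol/kg).
#' Unknown keys are an error so unit typos fail loudly.
#'
#' @param path path to a YAML file.
#' @return A one-row `runner_profile` tibble.
#' @examples
#' tf <- tempfile(fileext = ".yml")
#' writeLines("mass: 75\nvo2max: 55", tf)
#' read_runner_profile(tf)
#' @export
read_runner_profile <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(runner_profile))
  extra <- setdiff(names(cfg), allowed)
  if (length(extra)) {
    abort(paste0("Unknown profile keys: ", paste(extra, collapse = ", ")),
          class = "runfuel_config_error")
  }
  do.call(runner_profile, cfg)
}
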