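#' Substrate-partition curve as a table
#'
#' Evaluates the fitted partition on an intensity grid, together with the
#' anchor points and their propagated errors.
#'
#' @param partition a [fit_partition()] object.
#' @param intensities intensity grid.
#' @return A tibble with columns `intensity`, `f_cho`, `f_fat`.
#' @export
fig1_table <- function(partition = default_partition(),
                       intensities = seq(0.25, 1, by = 0.005)) {
  f <- f_cho(partition, intensities)
  tibble(intensity = intensities, f_cho = f, f_fat = 1 - f)
}

#' Marathon carbohydrate cost versus speed, by aerobic capacity
#'
#' For each VO2max and each aerobic running speed, the carbohydrate energy
#' per kg body mass consumed over a marathon, alongside the glycogen-storage
#' thresholds of a typical male build (leg muscles 21.4% of body mass, liver
#' 2.5% at maximal density): `storage_typical_kcal_per_kg` for trained but
#' unloaded muscle (79.2 kcal/kg) and `storage_supercomp_kcal_per_kg` for
#' maximal supercompensation (144 kcal/kg). Speeds above a runner's maximum
#' aerobic speed are skipped (with a note).
#'
#' @param vo2max vector of aerobic capacities, ml/kg/min.
#' @param speeds running-speed grid, km/h.
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @param quiet suppress the skipped-rows note.
#' @return A tibble with one row per feasible (vo2max, speed) pair.
#' @examples
#' fig2_table(vo2max = 55, speeds = 42.195 / 3.7)
#' @export
fig2_table <- function(vo2max = seq(35, 90, by = 5),
                       speeds = seq(7, 21, by = 0.25),
                       partition = default_partition(),
                       stoich = stoichiometry(), quiet = FALSE) {
  if (!length(vo2max) || !length(speeds)) {
    abort("`vo2max` and `speeds` must be nonempty.", class = "runfuel_spec_error")
  }
  grid <- tidyr::expand_grid(vo2max = vo2max, speed_kmh = speeds)
  vmax <- max_aerobic_speed(grid$vo2max, partition, stoich)
  feasible <- grid$speed_kmh <= vmax
  if (!quiet && any(!feasible)) {
    inform(sprintf("Skipping %d supra-aerobic (vo2max, speed) pairs.",
                   sum(!feasible)))
  }
  grid <- grid[feasible, ]
  i <- grid$speed_kmh / vmax[feasible]
  per_kg <- stoich$running_cost * stoich$marathon_km * f_cho(partition, i)
  typical <- 0.214 * glycogen_density_kcal(110, stoich) +
    0.025 * glycogen_density_kcal(500, stoich)
  supercomp <- 0.214 * 144 + 0.025 * glycogen_density_kcal(500, stoich)
  dplyr::mutate(
    grid,
    finish_time = marathon_time(.data$speed_kmh, stoich),
    intensity = i,
    cho_kcal_per_kg = per_kg,
    storage_typical_kcal_per_kg = typical,
    storage_supercomp_kcal_per_kg = supercomp,
    min_leg_fraction_supercomp = pmax(0, (per_kg - 0.025 *
      glycogen_density_kcal(500, stoich)) / 144)
  )
}

#' Wall distance versus intensity, build, and glycogen loading
#'
#' Tabulates the distance to glycogen depletion over a grid of running
#' intensities, muscle glycogen densities (kcal per kg muscle, as the
#' figure-style labels use), and leg-muscle fractions; liver parameters are
#' held at 2.5% of body mass and maximal density (360 kcal/kg).
#' `hits_wall_marathon` marks combinations that deplete inside a marathon.
#'
#' @param intensities intensity grid (fractions of VO2max).
#' @param muscle_density_kcal_per_kg muscle glycogen densities, kcal/kg.
#' @param leg_fractions leg-muscle mass fractions of body mass.
#' @param liver_fraction,liver_density_kcal_per_kg liver assumptions.
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return A tibble with columns `intensity`, `muscle_density_kcal_per_kg`,
#'   `leg_fraction`, `d_wall_km`, `hits_wall_marathon`.
#' @examples
#' fig3_table(intensities = c(0.8, 0.95), muscle_density_kcal_per_kg = 80)
#' @export
fig3_table <- function(intensities = seq(0.55, 1, by = 0.005),
                       muscle_density_kcal_per_kg = c(40, 60, 80, 100, 120, 144),
                       leg_fractions = c(0.15, 0.214, 0.25),
                       liver_fraction = 0.025,
                       liver_density_kcal_per_kg = 360,
                       partition = default_partition(),
                       stoich = stoichiometry()) {
  if (!length(intensities) || !length(muscle_density_kcal_per_kg) ||
        !length(leg_fractions)) {
    abort("Grids must be nonempty.", class = "runfuel_spec_error")
  }
  check_intensity(intensities, arg = "intensities")
  grid <- tidyr::expand_grid(
    intensity = intensities,
    muscle_density_kcal_per_kg = muscle_density_kcal_per_kg,
    leg_fraction = leg_fractions
  )
  reserve <- liver_fraction * liver_density_kcal_per_kg +
    grid$leg_fraction * grid$muscle_density_kcal_per_kg
  f <- f_cho(partition, grid$intensity)
  d <- ifelse(f == 0, Inf, reserve / (stoich$running_cost * f))
  dplyr::mutate(grid, d_wall_km = d,
                hits_wall_marathon = d < stoich$marathon_km)
}

#' Estimated VO2max versus fractional maximum heart rate, by speed
#'
#' Evaluates the heart-rate extrapolation on a grid of running speeds (mph,
#' as the figure-style legend labels them) and fractional maximum heart
#' rates.
#'
#' @param speeds_mph running speeds, miles per hour.
#' @param hr_fractions fractional maximum heart rates in (0, 1\].
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return A tibble with columns `speed_mph`, `speed_kmh`, `hr_fraction`,
#'   `vo2max_est`.
#' @examples
#' fig4_table(speeds_mph = 9, hr_fractions = 0.8)
#' @export
fig4_table <- function(speeds_mph = 4:13,
                       hr_fractions = seq(0.5, 1, by = 0.005),
                       partition = default_partition(),
                       stoich = stoichiometry()) {
  if (any(hr_fractions <= 0 | hr_fractions > 1)) {
    abort("`hr_fractions` must lie in (0, 1].", class = "runfuel_domain_error")
  }
  grid <- tidyr::expand_grid(speed_mph = speeds_mph, hr_fraction = hr_fractions)
  v <- grid$speed_mph * stoich$mile_km
  rho <- mixture_energy_per_mol_o2(partition, grid$hr_fraction, stoich,
                                   warn = FALSE)
  vo2 <- stoich$running_cost * v / rho * 1000 * stoich$molar_volume_l / 60
  dplyr::mutate(grid, speed_kmh = v, vo2max_est = vo2 / .data$hr_fraction)
}

#' Write the figure tables as CSV files
#'
#' Writes `fig1.csv` (partition curve), `fig2.csv` (marathon carbohydrate
#' cost), `fig3.csv` (wall distance), and `fig4.csv` (VO2max estimation)
#' into a directory. The tables are pure functions of the packaged
#' constants, so repeated runs produce byte-identical files.
#'
#' @param dir output directory (created if needed).
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return Named character vector of file paths, invisibly.
#' @export
write_figure_tables <- function(dir, partition = default_partition(),
                                stoich = stoichiometry()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list(
    fig1 = fig1_table(partition),
    fig2 = fig2_table(partition = partition, stoich = stoich, quiet = TRUE),
    fig3 = fig3_table(partition = partition, stoich = stoich),
    fig4 = fig4_table(partition = partition, stoich = stoich)
  )
  paths <- vapply(names(tables), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tables[[nm]], path)
    path
  }, character(1))
  invisible(paths)
}
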