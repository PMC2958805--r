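#' Carbohydrate mass and energy stored as glycogen
#'
#' `glycogen_mass()` converts a tissue mass and glycogen density to grams of
#' carbohydrate, counting glycosyl residues at the free-glucose molar mass
#' (180 g/mol): `tissue_mass * density * 180 / 1000`. `glycogen_energy()`
#' converts grams of carbohydrate to kcal at 4 kcal/g.
#'
#' @param tissue_mass tissue mass, kg (nonnegative).
#' @param density_mmol_per_kg glycogen density, mmol glycosyl residues per kg.
#' @param grams grams of carbohydrate.
#' @param stoich a [stoichiometry()] object.
#' @return Grams of carbohydrate, or kcal.
#' @examples
#' glycogen_mass(1.8, 270)           # a typical 1.8-kg liver: ~88 g
#' glycogen_energy(glycogen_mass(1.8, 270)) # ~350 kcal
#' @export
glycogen_mass <- function(tissue_mass, density_mmol_per_kg,
                          stoich = stoichiometry()) {
  if (any(tissue_mass < 0) || any(density_mmol_per_kg < 0)) {
    abort("Tissue mass and glycogen density must be nonnegative.",
          class = "runfuel_domain_error")
  }
  tissue_mass * density_mmol_per_kg * stoich$glucose_molar_mass / 1000
}

#' @rdname glycogen_mass
#' @export
glycogen_energy <- function(grams, stoich = stoichiometry()) {
  if (any(grams < 0)) {
    abort("`grams` must be nonnegative.", class = "runfuel_domain_error")
  }
  grams * stoich$cho_energy_density
}

#' Leg-muscle glycogen reserve of a runner
#'
#' @param profile a [runner_profile()] tibble (one row per runner).
#' @param stoich a [stoichiometry()] object.
#' @return A tibble with columns `muscle_cho_g` and `muscle_kcal`.
#' @examples
#' leg_muscle_reserve(runner_profile(mass = 70, leg_muscle_fraction = 0.225))
#' @export
leg_muscle_reserve <- function(profile, stoich = stoichiometry()) {
  g <- glycogen_mass(profile$mass * profile$leg_muscle_fraction,
                     profile$muscle_glycogen_density, stoich)
  tibble(muscle_cho_g = g, muscle_kcal = glycogen_energy(g, stoich))
}

#' Plasma glucose reserve
#'
#' The bloodstream is a negligible carbohydrate reservoir: at typical blood
#' volume (~5 L) and plasma glucose (~5 mM) it stores well under 20 kcal.
#'
#' @param blood_volume_l blood volume, liters (nonnegative).
#' @param glucose_mmol_per_l plasma glucose concentration, mmol/L.
#' @param stoich a [stoichiometry()] object.
#' @return Energy in kcal.
#' @examples
#' plasma_reserve(5, 5)
#' @export
plasma_reserve <- function(blood_volume_l = 5, glucose_mmol_per_l = 5,
                           stoich = stoichiometry()) {
  if (any(blood_volume_l < 0) || any(glucose_mmol_per_l < 0)) {
    abort("Blood volume and glucose concentration must be nonnegative.",
          class = "runfuel_domain_error")
  }
  grams <- blood_volume_l * glucose_mmol_per_l * stoich$glucose_molar_mass / 1000
  glycogen_energy(grams, stoich)
}

#' Glycogen energy stored per kilogram of body mass
#'
#' The numerator of the wall-distance formula: liver and leg-muscle glycogen
#' densities (converted to kcal per kg of tissue) weighted by their tissue
#' fractions of total body mass,
#' \deqn{S = f_{liver}\,\rho_{liver} + f_{legs}\,\rho_{muscle}
#'       \quad [\mathrm{kcal/kg\ body\ mass}].}
#' Plasma glucose is excluded as negligible. Linear in every fraction and
#' density, and independent of body mass.
#'
#' @inheritParams leg_muscle_reserve
#' @return kcal of glycogen per kg body mass (numeric vector).
#' @examples
#' specific_reserve(runner_profile(mass = 75))
#' @export
specific_reserve <- function(profile, stoich = stoichiometry()) {
  profile$liver_fraction *
    glycogen_density_kcal(profile$liver_glycogen_density, stoich) +
    profile$leg_muscle_fraction *
      glycogen_density_kcal(profile$muscle_glycogen_density, stoich)
}

#' Distance fueled by nonessential body fat
#'
#' Fat reserves are effectively unlimited for running: a runner with
#' nonessential fat fraction \eqn{b} stores \eqn{b M \rho_{fat}} kcal, enough
#' for a distance \eqn{b\,\rho_{fat}/C} independent of mass — several
#' marathons even at the lower physiologic limit of body fat.
#'
#' @param nonessential_fat_fraction fraction of body mass in \[0, 1).
#' @param stoich a [stoichiometry()] object (fat energy density is per gram;
#'   kcal/kg is 1000x).
#' @return Distance in km.
#' @examples
#' fat_reserve_distance(0.02) # > 4 marathons
#' @export
fat_reserve_distance <- function(nonessential_fat_fraction,
                                 stoich = stoichiometry()) {
  if (any(nonessential_fat_fraction < 0 | nonessential_fat_fraction >= 1)) {
    abort("`nonessential_fat_fraction` must lie in [0, 1).",
          class = "runfuel_domain_error")
  }
  nonessential_fat_fraction * stoich$fat_energy_density * 1000 /
    stoich$running_cost
}

#' Summarize the carbohydrate reservoirs of a runner
#'
#' One row per runner: liver, leg-muscle, and plasma carbohydrate in grams
#' and kcal, their total, and the specific reserve (kcal per kg body mass,
#' plasma excluded as negligible).
#'
#' @inheritParams leg_muscle_reserve
#' @param blood_volume_l,glucose_mmol_per_l plasma-pool parameters.
#' @return A tibble with columns `liver_cho_g`, `muscle_cho_g`,
#'   `plasma_cho_g`, `liver_kcal`, `muscle_kcal`, `plasma_kcal`,
#'   `total_kcal`, `specific_reserve`.
#' @examples
#' reserve_summary(runner_profile(mass = 70, leg_muscle_fraction = 0.225,
#'                                liver_glycogen_density = 270))
#' @export
reserve_summary <- function(profile, blood_volume_l = 5, glucose_mmol_per_l = 5,
                            stoich = stoichiometry()) {
  liver_g <- glycogen_mass(profile$mass * profile$liver_fraction,
                           profile$liver_glycogen_density, stoich)
  muscle <- leg_muscle_reserve(profile, stoich)
  plasma_kcal <- plasma_reserve(blood_volume_l, glucose_mmol_per_l, stoich)
  plasma_g <- plasma_kcal / stoich$cho_energy_density
  tibble(
    liver_cho_g = liver_g,
    muscle_cho_g = muscle$muscle_cho_g,
    plasma_cho_g = plasma_g,
    liver_kcal = glycogen_energy(liver_g, stoich),
    muscle_kcal = muscle$muscle_kcal,
    plasma_kcal = plasma_kcal,
    total_kcal = glycogen_energy(liver_g, stoich) + muscle$muscle_kcal +
      plasma_kcal,
    specific_reserve = specific_reserve(profile, stoich)
  )
}

#' Write a reserve summary as CSV
#'
#' Column units are embedded in the header names (grams, kcal, kcal/kg).
#'
#' @param summary a [reserve_summary()] tibble.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reserve_csv <- function(summary, path) {
  readr::write_csv(summary, path)
  invisible(path)
}
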