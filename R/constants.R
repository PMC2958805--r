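#' Stoichiometric and biophysical constants of the running-fuel model
#'
#' Bundles the fixed conversion constants used throughout the model. The
#' defaults follow the standard combustion chemistry of the two aerobic fuel
#' substrates and the classical linear energetics of level running:
#'
#' * complete oxidation of glucose (\eqn{C_6H_{12}O_6}, 180 g/mol, 686
#'   kcal/mol) consumes 6 mol O2 per mole, so carbohydrate liberates
#'   \eqn{686/6 \approx 114.3} kcal per mole of respired oxygen;
#' * oxidation of palmitate (\eqn{C_{16}H_{32}O_2}, 2398 kcal/mol) consumes
#'   23 mol O2 per mole, so fat liberates \eqn{2398/23 \approx 104.3} kcal
#'   per mole of oxygen — carbohydrate is the more oxygen-efficient fuel;
#' * the net metabolic cost of level running is close to 1 kcal per kg body
#'   mass per km, independent of speed over the aerobic range, so the power
#'   expended by a runner of mass \eqn{M} at speed \eqn{v} is
#'   \eqn{P = C v M}. Basal metabolism is deliberately neglected (its
#'   contribution to the carbohydrate budget is under 1%).
#'
#' Two carbohydrate energy conventions coexist, both standard: oxidation
#' stoichiometry uses the per-mole-O2 constants above, while reservoir
#' accounting uses 4 kcal per gram of carbohydrate with glycosyl residues
#' counted at the free-glucose molar mass of 180 g/mol (so 1 mmol/kg of
#' glycogen is 0.18 g/kg = 0.72 kcal/kg of tissue).
#'
#' @param energy_per_mol_o2_cho kcal liberated per mole O2 when oxidizing
#'   carbohydrate.
#' @param energy_per_mol_o2_fat kcal liberated per mole O2 when oxidizing fat.
#' @param molar_volume_l liters of gas per mole at standard temperature and
#'   pressure, used to convert VO2 volumes to moles.
#' @param running_cost net energetic cost of running, kcal per kg body mass
#'   per km.
#' @param cho_energy_density kcal per gram of carbohydrate (reservoir
#'   accounting).
#' @param fat_energy_density kcal per gram of fat.
#' @param glucose_molar_mass grams per mole of glucose; glycosyl residues are
#'   converted at this mass.
#' @param marathon_km marathon distance in km.
#' @param mile_km kilometers per statute mile.
#'
#' @return An object of class `"stoichiometry"`: a named list of constants.
#' @examples
#' st <- stoichiometry()
#' st$energy_per_mol_o2_cho - st$energy_per_mol_o2_fat
#' @export
stoichiometry <- function(energy_per_mol_o2_cho = 686 / 6,
                          energy_per_mol_o2_fat = 2398 / 23,
                          molar_volume_l = 22.4,
                          running_cost = 1,
                          cho_energy_density = 4,
                          fat_energy_density = 9.4,
                          glucose_molar_mass = 180,
                          marathon_km = 42.195,
                          mile_km = 1.609344) {
  if (!(energy_per_mol_o2_cho > energy_per_mol_o2_fat &&
          energy_per_mol_o2_fat > 0)) {
    abort("`energy_per_mol_o2_cho` must exceed `energy_per_mol_o2_fat` > 0.",
          class = "runfuel_config_error")
  }
  vals <- list(
    energy_per_mol_o2_cho = energy_per_mol_o2_cho,
    energy_per_mol_o2_fat = energy_per_mol_o2_fat,
    molar_volume_l = molar_volume_l,
    running_cost = running_cost,
    cho_energy_density = cho_energy_density,
    fat_energy_density = fat_energy_density,
    glucose_molar_mass = glucose_molar_mass,
    marathon_km = marathon_km,
    mile_km = mile_km
  )
  bad <- names(vals)[!vapply(vals, function(x) is.numeric(x) && length(x) == 1 && x > 0, logical(1))]
  if (length(bad)) {
    abort(paste0("All stoichiometric constants must be positive scalars: ",
                 paste(bad, collapse = ", ")),
          class = "runfuel_config_error")
  }
  structure(vals, class = "stoichiometry")
}

#' @export
print.stoichiometry <- function(x, ...) {
  cat("<stoichiometry>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %g\n", nm, x[[nm]]))
  invisible(x)
}

# kcal of glycogen per kg tissue per (mmol glycosyl residue / kg tissue)
glycogen_kcal_per_mmol <- function(stoich = stoichiometry()) {
  stoich$glucose_molar_mass / 1000 * stoich$cho_energy_density
}

#' Convert a glycogen density from mmol/kg to kcal/kg
#'
#' Glycosyl residues are counted at the free-glucose molar mass (180 g/mol)
#' and 4 kcal/g, so 1 mmol/kg corresponds to 0.72 kcal/kg of tissue. Under
#' this convention the physiologic maximum liver density of 500 mmol/kg is
#' exactly 360 kcal/kg, and a typical trained muscle density of 110 mmol/kg
#' is 79.2 kcal/kg (the value figures round to 80).
#'
#' @param density_mmol_per_kg glycogen density, mmol glycosyl residues per kg
#'   of tissue.
#' @param stoich a [stoichiometry()] object.
#' @return kcal of glycogen per kg of tissue.
#' @examples
#' glycogen_density_kcal(c(110, 200, 500))
#' @export
glycogen_density_kcal <- function(density_mmol_per_kg, stoich = stoichiometry()) {
  density_mmol_per_kg * glycogen_kcal_per_mmol(stoich)
}

#' Packaged substrate-partition anchor points
#'
#' Reads the anchor table shipped with the package: fractional carbohydrate
#' use and whole-body fat/carbohydrate oxidation rates (with standard errors)
#' at the three exercise intensities of the classic 1993 tracer/calorimetry
#' protocol (25%, 65%, and 85% of VO2max). These anchors are a one-time
#' digitization of the published figures (see the file header in
#' `system.file("extdata", "romijn1993_anchors.tsv", package = "runfuel")`
#' for provenance); the column `f_cho` equals `x_cho / (x_cho + x_fat)`
#' exactly.
#'
#' @return A tibble with columns `intensity`, `f_cho`, `x_fat`, `x_cho`,
#'   `se_fat`, `se_cho`.
#' @seealso [fit_partition()], [anchor_errors()]
#' @examples
#' romijn_anchors()
#' @export
romijn_anchors <- function() {
  path <- system.file("extdata", "romijn1993_anchors.tsv", package = "runfuel")
  if (!nzchar(path)) {
    abort("Packaged anchor table not found; is runfuel installed?")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
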