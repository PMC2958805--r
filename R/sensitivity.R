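# multiply f_cho by a constant factor (coefficients scale linearly)
scale_partition <- function(partition, factor) {
  partition$coefficients <- partition$coefficients * factor
  partition
}

# attenuation factor g(i) = f(i) (rho_cho - rho_fat) / rho_mix(i) in [0, 1):
# the logarithmic derivative of the mixture energy-per-mole-O2 with respect
# to a relative change in f_cho
attenuation_factor <- function(partition, i, stoich = stoichiometry()) {
  f <- f_cho(partition, i, warn = FALSE)
  f * (stoich$energy_per_mol_o2_cho - stoich$energy_per_mol_o2_fat) /
    mixture_energy_per_mol_o2(partition, i, stoich, warn = FALSE)
}

#' Propagate a relative error in f_cho through the model
#'
#' Every headline quantity depends on the substrate partition \eqn{f_{CHO}}
#' to first order, either through the mixture energy per mole of oxygen
#' \eqn{\rho(i)} or directly. Logarithmic differentiation with respect to
#' \eqn{f_{CHO}} gives the relative error each quantity inherits from a
#' relative error \eqn{\delta f / f}:
#'
#' * power output and the VO2max estimate vary through \eqn{\rho(i)}, with
#'   attenuation factor \eqn{f(\rho_{CHO} - \rho_{fat})/\rho(i) < 1} — their
#'   errors are strictly *smaller* than \eqn{|\delta f/f|};
#' * the maximum aerobic speed varies the same way, evaluated at i = 1;
#' * the carbohydrate budget is proportional to \eqn{f} and carries
#'   \eqn{|\delta f/f|} exactly;
#' * the wall distance is proportional to \eqn{1/f} and carries it exactly
#'   with opposite sign.
#'
#' Bounds are first-order (linearized); second-order terms are ignored.
#'
#' @param i relative intensity at which power/VO2max bounds are evaluated.
#' @param delta_f_rel relative error in f_cho, |value| < 1.
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @return A tibble with columns `quantity` (`power`, `vo2max_estimate`,
#'   `v_max`, `cho_energy`, `distance_to_wall`), `rel_error_bound`
#'   (magnitude), and `sign` (direction of the first-order response to an
#'   increase in f_cho).
#' @examples
#' propagate_error(0.75, 0.055)
#' @export
propagate_error <- function(i, delta_f_rel, partition = default_partition(),
                            stoich = stoichiometry()) {
  check_intensity(i)
  if (!is.numeric(delta_f_rel) || abs(delta_f_rel) >= 1) {
    abort("`delta_f_rel` must have magnitude < 1.",
          class = "runfuel_domain_error")
  }
  d <- abs(delta_f_rel)
  g_i <- attenuation_factor(partition, i, stoich)
  g_1 <- attenuation_factor(partition, 1, stoich)
  tibble(
    quantity = c("power", "vo2max_estimate", "v_max", "cho_energy",
                 "distance_to_wall"),
    rel_error_bound = c(g_i * d, g_i * d, g_1 * d, d, d),
    sign = c(1, -1, 1, 1, -1)
  )
}

#' Verify an error bound by finite-difference perturbation
#'
#' Re-evaluates a model quantity with the whole partition curve scaled by
#' `(1 + epsilon)` and returns the observed relative change. To first order
#' in `epsilon` this must match the corresponding analytic bound from
#' [propagate_error()] (equality for the carbohydrate budget and wall
#' distance, attenuation below `epsilon` for the power-like quantities).
#'
#' @param quantity which quantity to perturb.
#' @param i relative intensity at which to evaluate.
#' @param epsilon relative perturbation of f_cho (small, <= 1e-3 advised).
#' @param partition a [fit_partition()] object.
#' @param stoich a [stoichiometry()] object.
#' @param vo2max,mass,profile evaluation context: VO2max and mass for
#'   power-like quantities, a one-row profile for the wall distance.
#' @return Observed signed relative change (numeric scalar).
#' @examples
#' verify_by_perturbation("cho_energy", i = 0.75, epsilon = 1e-4)
#' @export
verify_by_perturbation <- function(quantity = c("power", "vo2max_estimate",
                                                "v_max", "cho_energy",
                                                "distance_to_wall"),
                                   i, epsilon = 1e-4,
                                   partition = default_partition(),
                                   stoich = stoichiometry(),
                                   vo2max = 55, mass = 70,
                                   profile = NULL) {
  quantity <- match.arg(quantity)
  check_intensity(i)
  profile <- profile %||% runner_profile(mass = mass, vo2max = vo2max)
  evaluator <- switch(
    quantity,
    power = function(p) aerobic_power(vo2max, i, mass, p, stoich, warn = FALSE),
    vo2max_estimate = function(p) {
      # VO2max estimate at fixed observed speed and fractional heart rate h = i
      stoich$running_cost * 12 /
        mixture_energy_per_mol_o2(p, i, stoich, warn = FALSE) / i
    },
    v_max = function(p) max_aerobic_speed(vo2max, p, stoich),
    cho_energy = function(p) {
      stoich$running_cost * stoich$marathon_km * f_cho(p, i, warn = FALSE)
    },
    distance_to_wall = function(p) distance_to_wall(profile, i, p, stoich)
  )
  base <- evaluator(partition)
  pert <- evaluator(scale_partition(partition, 1 + epsilon))
  (pert - base) / base
}
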