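#' Fit the substrate partition curve f_cho(i)
#'
#' Working muscle burns a mixture of carbohydrate and fat whose composition
#' shifts toward carbohydrate as relative aerobic intensity \eqn{i} (fraction
#' of VO2max) rises. The fractional carbohydrate contribution to aerobic
#' energy expenditure, \eqn{f_{CHO}(i)}, is modeled as a quadratic
#' \eqn{f_{CHO}(i) = a + b i + c i^2}; the fat fraction is its complement
#' \eqn{f_{fat} = 1 - f_{CHO}} by construction. With exactly three anchors
#' the quadratic interpolates them exactly (a direct 3x3 linear solve); with
#' more it is fit by least squares.
#'
#' The default anchors ([romijn_anchors()]) span intensities 0.25-0.85.
#' Evaluation above the fit domain up to i = 1 extrapolates with the same
#' quadratic (clamped to \[0, 1\]), as the model itself is used up to maximal
#' aerobic intensity; evaluation below the fit domain extrapolates with a
#' warning, since endurance-race intensities exceed it in practice.
#'
#' @param anchors data frame with columns `intensity` (in (0, 1\], distinct)
#'   and `f_cho` (in \[0, 1\]); extra columns (oxidation rates, standard
#'   errors) are carried along.
#' @return An object of class `"substrate_partition"` with elements
#'   `coefficients` (named `intercept`, `linear`, `quadratic`), `fit_domain`,
#'   `clamp_bounds`, and `anchors`.
#' @examples
#' part <- fit_partition()
#' f_cho(part, c(0.65, 0.85))
#' tidy(part)
#' @export
fit_partition <- function(anchors = romijn_anchors()) {
  if (!is.data.frame(anchors) || !all(c("intensity", "f_cho") %in% names(anchors))) {
    abort("`anchors` must be a data frame with columns `intensity` and `f_cho`.",
          class = "runfuel_fit_error")
  }
  x <- anchors$intensity
  y <- anchors$f_cho
  if (length(x) < 3) {
    abort("At least 3 anchors are required to fit a quadratic partition.",
          class = "runfuel_fit_error")
  }
  if (anyDuplicated(x)) {
    abort("Anchor intensities must be distinct (degenerate fit).",
          class = "runfuel_fit_error")
  }
  if (any(x <= 0 | x > 1)) {
    abort("Anchor intensities must lie in (0, 1].", class = "runfuel_fit_error")
  }
  if (any(y < 0 | y > 1)) {
    abort("Anchor `f_cho` values must lie in [0, 1].", class = "runfuel_fit_error")
  }
  X <- cbind(1, x, x^2)
  coefs <- if (length(x) == 3) {
    drop(solve(X, y))
  } else {
    unname(lm.fit(X, y)$coefficients)
  }
  coefs[is.na(coefs)] <- 0
  names(coefs) <- c("intercept", "linear", "quadratic")

  obj <- structure(
    list(
      coefficients = coefs,
      fit_domain = range(x),
      clamp_bounds = c(0, 1),
      anchors = as_tibble(anchors)
    ),
    class = "substrate_partition"
  )
  # slope b + 2ci must be >= 0 across the anchor-supported domain
  slope <- coefs[["linear"]] + 2 * coefs[["quadratic"]] * obj$fit_domain
  if (any(slope < -1e-12)) {
    warn("Fitted f_cho(i) is not non-decreasing over the whole fit domain.")
  }
  obj
}

# raw (unclamped) quadratic evaluation
partition_eval <- function(partition, i) {
  co <- partition$coefficients
  co[["intercept"]] + co[["linear"]] * i + co[["quadratic"]] * i^2
}

check_intensity <- function(i, arg = "i") {
  if (!is.numeric(i) || any(!is.finite(i)) || any(i <= 0 | i > 1)) {
    abort(paste0("`", arg, "` must be in (0, 1]: the model covers aerobic ",
                 "exercise only (anaerobic regime out of scope)."),
          class = "runfuel_domain_error")
  }
  invisible(i)
}

#' Fractional carbohydrate and fat usage at a given intensity
#'
#' Evaluates the fitted quadratic at relative intensity `i`, clamped to
#' \[0, 1\]. `f_fat()` returns the exact complement `1 - f_cho()`.
#'
#' @param partition a [fit_partition()] object.
#' @param i relative aerobic intensity, fraction of VO2max in (0, 1\]
#'   (vectorized).
#' @param warn warn when `i` falls below the anchor-supported fit domain.
#' @return Numeric vector of fractions in \[0, 1\].
#' @examples
#' part <- fit_partition()
#' f_cho(part, 0.75) + f_fat(part, 0.75) # exactly 1
#' @export
f_cho <- function(partition, i, warn = TRUE) {
  stopifnot(inherits(partition, "substrate_partition"))
  check_intensity(i)
  if (warn && any(i < partition$fit_domain[1])) {
    warn("Evaluating f_cho below the anchor fit domain; extrapolating the quadratic.")
  }
  val <- partition_eval(partition, i)
  pmin(pmax(val, partition$clamp_bounds[1]), partition$clamp_bounds[2])
}

#' @rdname f_cho
#' @export
f_fat <- function(partition, i, warn = TRUE) {
  1 - f_cho(partition, i, warn = warn)
}

#' Measurement-error propagation into the substrate partition
#'
#' The partition is measured as \eqn{f = x_{cho} / (x_{cho} + x_{fat})},
#' where \eqn{x_{fat}} and \eqn{x_{cho}} are independently measured
#' whole-body fat and carbohydrate oxidation rates. Partial differentiation
#' gives the weights \eqn{\partial f/\partial x_{fat} = -x_{cho}/(x_{fat} +
#' x_{cho})^2} and \eqn{\partial f/\partial x_{cho} = x_{fat}/(x_{fat} +
#' x_{cho})^2}; the independent standard errors combine in quadrature, and
#' the result is reported as the relative error \eqn{|\delta f / f|}.
#'
#' @param se_fat,se_cho standard errors of the fat and carbohydrate oxidation
#'   rates (same units as the rates).
#' @param x_fat,x_cho whole-body fat and carbohydrate oxidation rates
#'   (both > 0; any common energy/time unit).
#' @return Relative error \eqn{|\delta f / f|} (dimensionless), vectorized.
#' @examples
#' partition_error(se_fat = 2.5, se_cho = 1.3, x_fat = 57.6, x_cho = 22.4)
#' @export
partition_error <- function(se_fat, se_cho, x_fat, x_cho) {
  if (any(x_fat < 0) || any(x_cho <= 0) || any(x_fat + x_cho <= 0)) {
    abort("Oxidation rates must be positive (undefined partition otherwise).",
          class = "runfuel_domain_error")
  }
  if (any(se_fat < 0) || any(se_cho < 0)) {
    abort("Standard errors must be nonnegative.", class = "runfuel_domain_error")
  }
  sqrt((x_fat * se_cho)^2 + (x_cho * se_fat)^2) / (x_cho * (x_fat + x_cho))
}

#' Relative partition error at each packaged anchor
#'
#' Applies [partition_error()] to every row of an anchor table, giving the
#' propagated relative error in f_cho at each measured intensity.
#'
#' @param anchors an anchor table; defaults to [romijn_anchors()].
#' @return The anchor tibble with an added `rel_error` column.
#' @examples
#' anchor_errors()
#' @export
anchor_errors <- function(anchors = romijn_anchors()) {
  dplyr::mutate(
    as_tibble(anchors),
    rel_error = partition_error(.data$se_fat, .data$se_cho,
                                .data$x_fat, .data$x_cho)
  )
}

#' The default fitted partition
#'
#' Fits (once per session, then caches) the quadratic partition through the
#' packaged anchors. Most model functions use this as their default.
#'
#' @return A `"substrate_partition"` object.
#' @export
default_partition <- function() {
  if (is.null(.runfuel_cache$partition)) {
    .runfuel_cache$partition <- fit_partition(romijn_anchors())
  }
  .runfuel_cache$partition
}

#' @export
print.substrate_partition <- function(x, ...) {
  co <- x$coefficients
  cat("<substrate_partition>\n")
  cat(sprintf("  f_cho(i) = %.6g + %.6g i + %.6g i^2\n",
              co[["intercept"]], co[["linear"]], co[["quadratic"]]))
  cat(sprintf("  fit domain: [%.3g, %.3g], %d anchors; clamp to [%g, %g]\n",
              x$fit_domain[1], x$fit_domain[2], nrow(x$anchors),
              x$clamp_bounds[1], x$clamp_bounds[2]))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.substrate_partition <- function(x, ...) {
  tibble(
    term = c("intercept", "linear", "quadratic"),
    estimate = unname(x$coefficients)
  )
}

#' @exportS3Method generics::glance
glance.substrate_partition <- function(x, ...) {
  has_se <- all(c("se_fat", "se_cho", "x_fat", "x_cho") %in% names(x$anchors))
  tibble(
    n_anchors = nrow(x$anchors),
    fit_domain_min = x$fit_domain[1],
    fit_domain_max = x$fit_domain[2],
    convex = unname(x$coefficients[["quadratic"]]) > 0,
    f_cho_at_max = f_cho(x, 1),
    max_anchor_rel_error = if (has_se) max(anchor_errors(x$anchors)$rel_error) else NA_real_
  )
}
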