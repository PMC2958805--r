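#' @exportS3Method ggplot2::autoplot
autoplot.substrate_partition <- function(object, ...) {
  curve <- fig1_table(object)
  long <- tidyr::pivot_longer(curve, c("f_cho", "f_fat"),
                              names_to = "substrate", values_to = "fraction")
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$intensity, .data$fraction,
                                          colour = .data$substrate)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(f_cho = "#2166ac", f_fat = "#b2182b"),
      labels = c(f_cho = "carbohydrate", f_fat = "fat")
    ) +
    ggplot2::labs(x = "relative intensity (fraction of VO2max)",
                  y = "fraction of aerobic energy", colour = NULL) +
    ggplot2::theme_minimal()
  anch <- object$anchors
  if (all(c("se_fat", "se_cho", "x_fat", "x_cho") %in% names(anch))) {
    anch <- anchor_errors(anch)
    p <- p +
      ggplot2::geom_pointrange(
        data = anch,
        ggplot2::aes(.data$intensity, .data$f_cho,
                     ymin = .data$f_cho * (1 - .data$rel_error),
                     ymax = .data$f_cho * (1 + .data$rel_error)),
        colour = "#2166ac", inherit.aes = FALSE
      )
  } else {
    p <- p + ggplot2::geom_point(
      data = anch, ggplot2::aes(.data$intensity, .data$f_cho),
      colour = "#2166ac", inherit.aes = FALSE
    )
  }
  p
}

#' Plot marathon carbohydrate cost against speed
#'
#' One curve per aerobic capacity, with horizontal storage-threshold lines
#' for the typical male build.
#'
#' @param tbl a [fig2_table()] tibble.
#' @return A ggplot object.
#' @export
plot_marathon_energy <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$speed_kmh, .data$cho_kcal_per_kg,
                                    colour = factor(.data$vo2max))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = unique(tbl$storage_typical_kcal_per_kg),
                        linetype = "dashed") +
    ggplot2::geom_hline(yintercept = unique(tbl$storage_supercomp_kcal_per_kg),
                        linetype = "dotted") +
    ggplot2::labs(x = "speed (km/h)",
                  y = "carbohydrate energy over a marathon (kcal/kg body mass)",
                  colour = "VO2max") +
    ggplot2::theme_minimal()
}

#' Plot wall distance against intensity
#'
#' One curve per muscle glycogen density and leg fraction; the marathon
#' distance is marked, below which a runner depletes midrace.
#'
#' @param tbl a [fig3_table()] tibble.
#' @return A ggplot object.
#' @export
plot_wall_distance <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(100 * .data$intensity, .data$d_wall_km,
                                    colour = factor(.data$muscle_density_kcal_per_kg),
                                    linetype = factor(.data$leg_fraction))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 42.195, linetype = "dashed") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = "intensity (% VO2max)", y = "distance to the wall (km)",
                  colour = "muscle glycogen\n(kcal/kg)",
                  linetype = "leg fraction") +
    ggplot2::theme_minimal()
}

#' Plot VO2max estimates against fractional maximum heart rate
#'
#' @param tbl a [fig4_table()] tibble.
#' @return A ggplot object.
#' @export
plot_vo2max_curves <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$hr_fraction, .data$vo2max_est,
                                    colour = factor(.data$speed_mph))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fraction of maximum heart rate",
                  y = "estimated VO2max (ml/kg/min)", colour = "speed (mph)") +
    ggplot2::theme_minimal()
}
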