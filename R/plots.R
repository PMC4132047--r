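# ggplot2 views of the pipeline's result objects.

#' @export
autoplot.silk_friction_dataset <- function(object, ...) {
  long <- object |>
    dplyr::select("velocity", "F_total", "F_water", "F_ac",
                  dplyr::ends_with("_sem")) |>
    tidyr::pivot_longer(c("F_total", "F_water", "F_ac"),
                        names_to = "component", values_to = "force")
  sems <- c(F_total = "F_total_sem", F_water = "F_water_sem", F_ac = "F_ac_sem")
  long$sem <- vapply(seq_len(nrow(long)), function(i) {
    as.numeric(long[i, sems[long$component[i]]])
  }, numeric(1))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$velocity, y = .data$force,
                                     colour = .data$component)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$force - .data$sem,
                                        ymax = .data$force + .data$sem),
                           width = 0.05) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(
      values = c(F_total = "red", F_water = "darkgreen", F_ac = "black"),
      labels = c(F_total = "total", F_water = "water", F_ac = "amorphous-crystalline")) +
    ggplot2::labs(x = "pulling velocity (m/s)", y = "peak force (pN)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.silk_bond_fit <- function(object, area_res = NULL, ...) {
  if (is.null(area_res)) {
    area_res <- if (!is.null(object$area) && !is.null(object$n_contact)) {
      object$area / object$n_contact
    } else 1.2
  }
  curve <- eta_of_stress(object, area_res = area_res)
  dat <- object$data
  dat$tau_MPa <- dat$f_res / area_res
  dat$eta_res <- (dat$f_res * 1e-12 / dat$velocity) *
    (object$d_shear / area_res) * 1e9
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$tau_MPa, y = .data$eta_res)) +
    ggplot2::geom_line(colour = "red") +
    ggplot2::geom_point(data = dat, colour = "black") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(tau ~ "(MPa)"),
                  y = expression(eta[res] ~ "(Ns/" * m^2 * ")")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.silk_slider_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("tau_interface", "vm_crystal", "vm_amorphous"),
                              names_to = "where", values_to = "stress")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$velocity,
                                     y = .data$stress / 1e6,
                                     colour = .data$where)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "relative velocity (m/s)", y = "steady stress (MPa)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.silk_slider_result <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history,
                              c("vm_crystal", "vm_amorphous", "tau_interface"),
                              names_to = "where", values_to = "stress")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time * 1e9,
                                     y = .data$stress / 1e6,
                                     colour = .data$where)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ns)", y = "stress (MPa)", colour = NULL) +
    ggplot2::theme_minimal()
}
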