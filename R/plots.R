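#' Plot de-mixed force and yank across stretch velocities
#'
#' Overlays the de-mixed force and yank estimates for every trial, coloured
#' by nominal ramp velocity, one panel per variable — the velocity-scaling
#' view of the de-mixing output.
#'
#' @param demix A `demix_result` from [demix_spindle()] carrying
#'   `velocity_label`.
#' @return A ggplot object.
#' @export
plot_velocity_scaling <- function(demix) {
  check_cols(demix, c("t", "F_est", "Y_est", "velocity_label"))
  long <- as_tibble(demix) %>%
    tidyr::pivot_longer(c("F_est", "Y_est"), names_to = "variable",
                        values_to = "value") %>%
    mutate(variable = factor(.data$variable, c("F_est", "Y_est"),
                             c("decoded force (N)", "decoded yank (N/s)")))
  grp <- if ("trial_id" %in% names(long)) "trial_id" else "velocity_label"
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value,
                                     colour = factor(.data$velocity_label),
                                     group = .data[[grp]])) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~variable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "velocity (mm/s)") +
    ggplot2::theme_minimal()
}

#' @rdname plot_velocity_scaling
#' @param object,... `autoplot` method arguments.
#' @export
autoplot.demix_result <- function(object, ...) plot_velocity_scaling(object)

#' Plot a contractile-force decomposition
#'
#' Traces of the estimated externally imposed (`F_EI`), total contractile
#' (`F_C`) and self-generated (`F_SG`) forces over time, faceted by velocity
#' when several are present.
#'
#' @param object A `force_decomposition` from [estimate_forces()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.force_decomposition <- function(object, ...) {
  check_cols(object, c("t", "F_EI_est", "F_C_est", "F_SG_est"))
  long <- as_tibble(object) %>%
    tidyr::pivot_longer(c("F_EI_est", "F_C_est", "F_SG_est"),
                        names_to = "component", values_to = "force") %>%
    mutate(component = factor(.data$component,
                              c("F_C_est", "F_EI_est", "F_SG_est"),
                              c("contractile (Ib)", "externally imposed (II)",
                                "self-generated (difference)")))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$force,
                                          colour = .data$component))
  if ("trial_id" %in% names(long)) {
    p <- p + ggplot2::aes(group = interaction(.data$trial_id, .data$component))
  }
  p <- p + ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "time (s)", y = "force (N)", colour = NULL) +
    ggplot2::theme_minimal()
  if ("velocity_label" %in% names(long) && n_distinct(long$velocity_label) > 1) {
    p <- p + ggplot2::facet_wrap(~velocity_label)
  }
  p
}

#' Plot simulated forces for stretch trials
#'
#' Total, contractile and non-contractile force per trial, faceted by
#' velocity.
#'
#' @param forces Forces tibble from [simulate_forces()].
#' @return A ggplot object.
#' @export
plot_forces <- function(forces) {
  check_cols(forces, c("t", "F_MTU", "F_C", "F_NC", "velocity_label"))
  long <- forces %>%
    tidyr::pivot_longer(c("F_MTU", "F_C", "F_NC"), names_to = "component",
                        values_to = "force")
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$force,
                                     colour = .data$component,
                                     group = interaction(.data$trial_id, .data$component))) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~velocity_label) +
    ggplot2::labs(x = "time (s)", y = "force (N)", colour = NULL) +
    ggplot2::theme_minimal()
}
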