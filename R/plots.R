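#' Plot the time course of a simulated wingstroke
#'
#' Panels of the global-frame aerodynamic force components (with the
#' inertial reaction force when available), the pitch moment, and the
#' aerodynamic power over one wingstroke.
#'
#' @param object A [simulate_wingstroke()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.wingstroke_result <- function(object, ...) {
  ser <- object$series
  keep <- intersect(c("Fx_N", "Fz_N", "Fin_x_N", "Fin_z_N", "My_Nm", "P_W"),
                    names(ser))
  long <- tidyr::pivot_longer(ser[, c("t_s", keep)], -"t_s",
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$t_s * object$config$f,
                                     y = .data$value)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "wingstroke fraction", y = NULL,
                  title = "Wingstroke force, moment and power") +
    ggplot2::theme_minimal()
}

#' Plot trim solutions within their search bounds
#'
#' Each solution's parameters are normalised to the bound interval
#' (0 = minimum, 1 = maximum) so the spread of the solution family is
#' visible at a glance.
#'
#' @param object A [search_trim()] result.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.trim_result <- function(object, ...) {
  sols <- object$solutions
  b <- object$bounds
  long <- tidyr::pivot_longer(sols[, TRIM_PARAMS], tidyr::everything(),
                              names_to = "parameter", values_to = "value")
  long$solution <- rep(seq_len(nrow(sols)), each = length(TRIM_PARAMS))
  long <- dplyr::left_join(long, b, by = "parameter")
  long$norm <- ifelse(long$max > long$min,
                      (long$value - long$min) / (long$max - long$min), 0.5)
  long$parameter <- factor(long$parameter, levels = TRIM_PARAMS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$parameter, y = .data$norm,
                                     group = .data$solution)) +
    ggplot2::geom_hline(yintercept = c(0, 1), linetype = 2,
                        colour = "grey50") +
    ggplot2::geom_line(alpha = 0.3, colour = "#2166ac") +
    ggplot2::geom_point(colour = "#2166ac") +
    ggplot2::labs(x = NULL, y = "position within bounds",
                  title = "Trim solutions (bound-normalised)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Compare variant force waveforms in one figure
#'
#' Overlays the vertical and fore-aft aerodynamic force of each
#' body-kinematics variant over the wingstroke.
#'
#' @param base A [moth_config()] (model 1).
#' @param tags Variants to draw.
#' @param n_steps Time resolution.
#' @return A ggplot object.
#' @export
plot_variant_forces <- function(base, tags = c("model1", "model2", "model3"),
                                n_steps = 500L) {
  long <- purrr::map_dfr(tags, function(tag) {
    cfg <- make_variant(base, tag)
    res <- simulate_wingstroke(cfg, n_steps = n_steps, detail = FALSE)
    tidyr::pivot_longer(res$series[, c("t_s", "Fx_N", "Fz_N")], -"t_s",
                        names_to = "component", values_to = "value") |>
      dplyr::mutate(variant = tag, frac = .data$t_s * cfg$f)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frac, y = .data$value,
                                     colour = .data$variant)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(model1 = "#b2182b",
                                            model2 = "#2166ac",
                                            model3 = "#762a83",
                                            model1a = "#1b7837",
                                            model1b = "#e08214")) +
    ggplot2::labs(x = "wingstroke fraction", y = "force (N)",
                  title = "Aerodynamic force by body-kinematics variant") +
    ggplot2::theme_minimal()
}
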