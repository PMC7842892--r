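# ggplot2 figure builders for the three result types: radial field/current
# profiles, membrane exposure with physiological bands, and the overlay of
# a model profile on transfection-efficiency data.

#' Plot radial profiles of field or current density
#'
#' One line per layer and component (vertical dotted, radial dash-dot,
#' mean solid) on a log scale versus radius.
#'
#' @param object A `radial_profile`.
#' @param quantity `"J"` (current density, A/m^2) or `"E"` (field, V/m).
#' @param layers Layers to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radial_profile <- function(object, quantity = c("J", "E"),
                                    layers = c("buffer", "membrane",
                                               "cytoplasm"), ...) {
  quantity <- match.arg(quantity)
  dat <- dplyr::filter(tibble::as_tibble(object), .data$layer %in% layers)
  dat <- tidyr::pivot_longer(
    dat,
    cols = dplyr::all_of(paste0(quantity, c("_vertical", "_radial", "_mean"))),
    names_to = "component", values_to = "value"
  )
  dat$component <- sub(paste0("^", quantity, "_"), "", dat$component)
  ylab <- if (quantity == "J") "current density (A/m², RMS)"
          else "electric field (V/m, RMS)"
  ggplot2::ggplot(dat, ggplot2::aes(.data$r_mm, .data$value,
                                    colour = .data$layer,
                                    linetype = .data$component)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::scale_y_log10() +
    ggplot2::scale_linetype_manual(
      values = c(mean = "solid", vertical = "dotted", radial = "dotdash")) +
    ggplot2::labs(x = "r (mm)", y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot membrane exposure with physiological bands
#'
#' Membrane voltage (with the ~0.1 V action-potential band and the 0.5–1 V
#' damage band) or per-cell current (with the ~1 nA ion-transport band)
#' versus radius, on a log scale.
#'
#' @param object An `exposure_profile`.
#' @param quantity `"V_m"` or `"I_cell"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.exposure_profile <- function(object, quantity = c("V_m", "I_cell"),
                                      ...) {
  quantity <- match.arg(quantity)
  bands <- attr(object, "bands")
  dat <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$r_mm, .data[[quantity]]))
  if (quantity == "V_m") {
    p <- p +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = 0, ymax = bands$action_potential_V,
                        fill = "steelblue", alpha = 0.2) +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = bands$damage_low_V, ymax = bands$damage_high_V,
                        fill = "firebrick", alpha = 0.2) +
      ggplot2::labs(y = "membrane voltage V_m (V, RMS)")
  } else {
    p <- p +
      ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                        ymin = 0, ymax = bands$ion_transport_A,
                        fill = "steelblue", alpha = 0.2) +
      ggplot2::labs(y = "per-cell current I_cell (A, RMS)")
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "r (mm)") +
    ggplot2::theme_minimal()
}

#' Overlay a model profile on an efficiency profile
#'
#' Draws the efficiency points and the model curve multiplied by the
#' least-squares overlay scale, with a secondary axis showing the model's
#' own units.
#'
#' @param model Model series (`r_mm` + value column).
#' @param efficiency Efficiency profile (`r_mm`, `eta`).
#' @param overlay An `overlay_result` from [overlay_scale()] for this pair.
#' @param value_col Model value column (default: first non-`r_mm` column).
#' @return A ggplot object.
#' @export
plot_overlay <- function(model, efficiency, overlay, value_col = NULL) {
  if (is.null(value_col))
    value_col <- setdiff(names(model), "r_mm")[1]
  s <- overlay$scale[1]
  mod <- tibble::tibble(r_mm = model$r_mm,
                        scaled = model[[value_col]] * s)
  ggplot2::ggplot() +
    ggplot2::geom_rect(ggplot2::aes(xmin = overlay$r_min[1],
                                    xmax = overlay$r_max[1],
                                    ymin = -Inf, ymax = Inf),
                       fill = "grey85", alpha = 0.5) +
    ggplot2::geom_point(data = efficiency,
                        ggplot2::aes(.data$r_mm, .data$eta),
                        colour = "darkgreen") +
    ggplot2::geom_line(data = mod,
                       ggplot2::aes(.data$r_mm, .data$scaled),
                       colour = "black") +
    ggplot2::scale_y_continuous(
      name = "normalized efficiency η",
      sec.axis = ggplot2::sec_axis(~ . / s, name = value_col)
    ) +
    ggplot2::labs(x = "r (mm)") +
    ggplot2::theme_minimal()
}
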