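# From branch phasors to radial profiles of field and current density, and
# to the physiological exposure quantities (membrane voltage, per-cell
# current).
#
# Per element: E = |V|/length, J = |I|/area (RMS magnitudes). Per segment
# and layer, the vertical component averages the segment's vertical
# elements (the upper/lower membrane pair, the two cytoplasm halves, the
# single buffer column), the radial component averages the incident radial
# branches on the inner and outer side (boundary segments have only one),
# and the reported mean is (vertical + radial)/2 — the spatial average of
# the flux through a spherical cell of diameter H_c, whose projected areas
# in r and z are equal.

#' Per-element field and current density
#'
#' Adds the RMS electric field `E = |V| / geom_length` (V/m) and current
#' density `J = |I| / geom_area` (A/m^2) to the solved element table. For a
#' membrane element `J / E` equals \eqn{\omega\varepsilon_m} (the membrane's
#' admittance per unit length and area); for conducting layers it equals the
#' layer conductivity.
#'
#' @param solution A `phasor_solution` of a network with geometry
#'   annotations.
#' @return The element tibble with columns `E` and `J` added.
#' @export
element_fields <- function(solution) {
  el <- solution$elements
  if (anyNA(el$geom_length) || anyNA(el$geom_area))
    stop("network elements lack geometry annotations", call. = FALSE)
  dplyr::mutate(el,
                E = Mod(.data$voltage) / .data$geom_length,
                J = Mod(.data$current) / .data$geom_area)
}

#' Radial profiles of field and current density per layer
#'
#' Collapses the solved network into per-segment, per-layer effective
#' values: `E_vertical`/`J_vertical` from the segment's vertical elements,
#' `E_radial`/`J_radial` from the radial branches incident on the segment
#' (inner and outer averaged; the innermost and outermost segments use
#' their single incident branch), and `E_mean`/`J_mean` as the average of
#' the two components. Layers reported: buffer, membrane, cytoplasm (the
#' grounded plate has no radial elements and is omitted).
#'
#' For the buffer, the radial resistor linking segments `n` and `n + 1` is
#' counted as incident on both.
#'
#' @param solution A `phasor_solution` from the default well topology.
#' @param params Model parameters (default: those stored in the network).
#' @return A tibble of class `radial_profile` with columns `segment`, `r`
#'   (m), `r_mm`, `layer`, `E_vertical`, `E_radial`, `E_mean` (V/m),
#'   `J_vertical`, `J_radial`, `J_mean` (A/m^2).
#' @examples
#' prof <- layer_profiles(solve_network(build_network(well_parameters())))
#' @export
layer_profiles <- function(solution, params = solution$network$params) {
  if (is.null(params))
    stop("network carries no parameters; pass `params`", call. = FALSE)
  ef <- element_fields(solution)
  nseg <- params$disc$n_segments
  r <- radial_positions(params)

  avg <- function(rows) {
    if (!nrow(rows)) return(c(E = NA_real_, J = NA_real_))
    c(E = mean(rows$E), J = mean(rows$J))
  }

  grid <- tidyr::expand_grid(segment = seq_len(nseg),
                             layer = c("buffer", "membrane", "cytoplasm"))
  out <- purrr::pmap_dfr(grid, function(segment, layer) {
    seg <- segment; lay <- layer  # plain values, distinct from ef's columns
    vert <- ef[ef$layer == lay & ef$orientation == "vertical" &
                 ef$segment == seg, ]
    rad_segs <- if (lay == "buffer") c(seg - 1L, seg) else seg
    # buffer radial resistors are labelled by their inner segment and are
    # incident on both segments they join
    rad <- ef[ef$layer == lay & ef$orientation == "radial" &
                ef$segment %in% rad_segs, ]
    v <- avg(vert); h <- avg(rad)
    rn <- r[seg]
    tibble::tibble(
      segment = as.integer(seg), r = rn, r_mm = rn * 1e3,
      layer = lay,
      E_vertical = v[["E"]], E_radial = h[["E"]],
      E_mean = (v[["E"]] + h[["E"]]) / 2,
      J_vertical = v[["J"]], J_radial = h[["J"]],
      J_mean = (v[["J"]] + h[["J"]]) / 2
    )
  })
  class(out) <- c("radial_profile", class(out))
  attr(out, "params") <- params
  out
}

#' Physiological reference bands
#'
#' Constants used when reporting membrane exposure: the action-potential
#' ceiling of normal cell activity (~0.1 V), the membrane-damage voltage
#' range (0.5–1 V, above which irreversible damage and cell death set in)
#' and the scale of ion-channel membrane-transport current (~1 nA).
#'
#' @return Named list with `action_potential_V`, `damage_low_V`,
#'   `damage_high_V`, `ion_transport_A`.
#' @export
exposure_bands <- function() {
  list(action_potential_V = 0.1,
       damage_low_V = 0.5,
       damage_high_V = 1,
       ion_transport_A = 1e-9)
}

#' Membrane voltage and per-cell current
#'
#' Converts the membrane-layer profile into the quantities a cell
#' experiences: the transmembrane voltage
#' \eqn{V_m(r) = E_\mathrm{mean}(\mathrm{membrane}) \cdot H_m} and the
#' current through one (spherical, diameter \eqn{H_c}) cell,
#' \eqn{I_\mathrm{cell}(r) = J_\mathrm{mean} \cdot \pi H_c^2}. The
#' physiological reference bands of [exposure_bands()] are attached as the
#' `"bands"` attribute.
#'
#' @param profile A `radial_profile` from [layer_profiles()].
#' @param params Model parameters (default: those stored on the profile).
#' @return A tibble of class `exposure_profile` with columns `segment`, `r`,
#'   `r_mm`, `V_m` (V), `I_cell` (A).
#' @export
membrane_exposure <- function(profile, params = attr(profile, "params")) {
  if (is.null(params))
    stop("profile carries no parameters; pass `params`", call. = FALSE)
  mem <- dplyr::filter(profile, .data$layer == "membrane")
  out <- tibble::tibble(
    segment = mem$segment, r = mem$r, r_mm = mem$r_mm,
    V_m = mem$E_mean * params$geometry$H_m,
    I_cell = mem$J_mean * pi * params$geometry$H_c^2
  )
  class(out) <- c("exposure_profile", class(out))
  attr(out, "params") <- params
  attr(out, "bands") <- exposure_bands()
  out
}

#' Admittance and impedance scales of the three materials
#'
#' The per-unit-length-and-area admittances that explain the current routing
#' in the well: the buffer conductivity \eqn{\sigma_b}, the membrane
#' admittance \eqn{\omega\varepsilon_m} (33.4 uS/m at the default 20 kHz
#' drive — five orders below the buffer, so the buffer carries the supplied
#' current and only a small part branches into the cells), and the plate
#' impedance \eqn{1/(\omega\varepsilon_w)} (374 kOhm m — far above the other
#' layers' impedances, so most of the source voltage drops across the plate
#' and the vertical current density is nearly radius-independent).
#'
#' @param params A [well_parameters()] object.
#' @return A tibble with columns `quantity`, `value` (SI), `unit`,
#'   `display_value` (3 significant figures in the display unit),
#'   `display_unit`.
#' @examples
#' admittance_summary(well_parameters())
#' @export
admittance_summary <- function(params) {
  validate_parameters(params)
  m <- params$materials
  omega <- params$drive$omega
  w_eps_m <- omega * m$eps_m_rel * m$eps0
  z_plate <- 1 / (omega * m$eps_w_rel * m$eps0)
  tibble::tibble(
    quantity = c("sigma_b", "omega_eps_m", "plate_impedance"),
    value = c(m$sigma_b, w_eps_m, z_plate),
    unit = c("S/m", "S/m", "Ohm m"),
    display_value = signif(c(m$sigma_b, w_eps_m * 1e6, z_plate / 1e3), 3),
    display_unit = c("S/m", "uS/m", "kOhm m")
  )
}
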