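# End-to-end runners tying configuration to written artifacts. These back
# the command-line dispatcher in inst/cli/plasmawell.R and are the
# recommended entry points for scripted use.

.flatten_params <- function(params) {
  c(params$materials,
    params$geometry,
    params$disc,
    params$drive)
}

#' Run the full circuit-model simulation and write its artifacts
#'
#' Builds the network, solves it, verifies the conservation diagnostics
#' (KCL residual and complex power balance must both be below `tol`), and
#' writes `profiles.csv`, `exposure.csv`, `admittance.csv` and
#' `summary.json` (resolved parameters — including the buffer-height
#' choice — plus diagnostics) to `out_dir`.
#'
#' @param params A [well_parameters()] object.
#' @param out_dir Output directory (created if needed).
#' @param tol Acceptance threshold for the conservation diagnostics.
#' @return Invisibly, a list with `solution`, `profile`, `exposure`,
#'   `admittance` and `summary`.
#' @export
run_simulation <- function(params = well_parameters(), out_dir = ".",
                           tol = 1e-9) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  network <- build_network(params)
  solution <- solve_network(network)
  kcl <- kcl_residual(solution)
  pb <- power_balance(solution)
  if (kcl >= tol)
    stop("KCL residual ", signif(kcl, 3), " exceeds ", tol, call. = FALSE)
  if (pb$relative_mismatch >= tol)
    stop("power-balance mismatch ", signif(pb$relative_mismatch, 3),
         " exceeds ", tol, call. = FALSE)

  profile <- layer_profiles(solution)
  exposure <- membrane_exposure(profile)
  adm <- admittance_summary(params)

  write_profiles(profile, file.path(out_dir, "profiles.csv"))
  write_exposure(exposure, file.path(out_dir, "exposure.csv"))
  readr::write_csv(adm, file.path(out_dir, "admittance.csv"))

  summary <- list(
    parameters = .flatten_params(params),
    n_elements = nrow(network$elements),
    n_nodes = length(network$nodes),
    kcl_residual = kcl,
    power_mismatch = pb$relative_mismatch,
    source_power_W = Re(pb$source),
    source_current_A = Mod(.node_outflow(solution$elements,
                                         network$source_node)),
    omega_eps_m_uS_per_m =
      adm$display_value[adm$quantity == "omega_eps_m"],
    plate_impedance_kOhm_m =
      adm$display_value[adm$quantity == "plate_impedance"]
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(solution = solution, profile = profile,
                 exposure = exposure, admittance = adm, summary = summary))
}

#' Run the uniform-medium reference solver and write its profile
#'
#' Solves the finite-difference model at the requested resolution and at
#' half resolution, writes `reference_profile.csv` (columns `r_mm`,
#' `J_b_A_per_m2`) and `reference_summary.json` with the conservation and
#' grid-convergence diagnostics (the maximum relative change of the buffer
#' profile between the two resolutions).
#'
#' @param params A [well_parameters()] object.
#' @param out_dir Output directory.
#' @param nr,nz Grid resolution of the fine run.
#' @param depth_frac Sampling depth within the buffer (fraction).
#' @return Invisibly, a list with `profile`, `coarse_profile` and
#'   `summary`.
#' @export
run_reference <- function(params = well_parameters(), out_dir = ".",
                          nr = 64, nz = 64, depth_frac = 0.5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fine <- solve_axisym_potential(build_axisym_grid(params, nr, nz))
  coarse <- solve_axisym_potential(
    build_axisym_grid(params, max(8, nr %/% 2), max(8, nz %/% 2)))
  prof <- buffer_current_profile(fine, depth_frac)
  prof_c <- buffer_current_profile(coarse, depth_frac)
  on_fine <- stats::approx(prof_c$r_mm, prof_c$J_b_A_per_m2,
                           xout = prof$r_mm, rule = 2)$y
  convergence <- max(abs(on_fine - prof$J_b_A_per_m2) /
                       max(prof$J_b_A_per_m2))

  readr::write_csv(prof, file.path(out_dir, "reference_profile.csv"))
  bal <- axisym_current_balance(fine)
  summary <- list(
    nr = nr, nz = nz, depth_frac = depth_frac,
    divergence_residual = axisym_divergence_residual(fine),
    current_balance_mismatch = bal$relative_mismatch,
    refinement_change = convergence
  )
  jsonlite::write_json(summary, file.path(out_dir,
                                          "reference_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(profile = prof, coarse_profile = prof_c,
                 summary = summary))
}

#' Overlay the model profiles on an efficiency profile
#'
#' Computes the least-squares overlay scale of (a) the cell (membrane-layer)
#' current-density profile, (b) the circuit-model buffer profile and, when
#' a reference profile is supplied, (c) the uniform-medium buffer profile,
#' each over its own comparison window, writes `overlays.json` and an
#' `overlay.png` figure for the cell profile.
#'
#' @param params A [well_parameters()] object.
#' @param efficiency An `efficiency_profile` (or path to its CSV).
#' @param out_dir Output directory.
#' @param windows Named list of `c(r_min, r_max)` windows in mm for
#'   `cell`, `buffer` and `reference`.
#' @param reference Optional reference profile tibble (`r_mm`,
#'   `J_b_A_per_m2`), e.g. from [run_reference()].
#' @return Invisibly, a named list of `overlay_result` rows.
#' @export
run_compare <- function(params = well_parameters(), efficiency,
                        out_dir = ".",
                        windows = list(cell = c(0, 1.6),
                                       buffer = c(0.2, 0.5),
                                       reference = c(0.4, 1.6)),
                        reference = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(efficiency)) efficiency <- read_efficiency(efficiency)
  profile <- layer_profiles(solve_network(build_network(params)))

  series <- function(lay) {
    dat <- dplyr::filter(tibble::as_tibble(profile), .data$layer == lay)
    tibble::tibble(r_mm = dat$r_mm, J = dat$J_mean)
  }
  cell <- series("membrane")
  buffer <- series("buffer")
  overlays <- list(
    cell = overlay_scale(cell, efficiency, windows$cell),
    buffer = overlay_scale(buffer, efficiency, windows$buffer)
  )
  if (!is.null(reference)) {
    ref <- tibble::tibble(r_mm = reference$r_mm,
                          J = reference$J_b_A_per_m2)
    overlays$reference <- overlay_scale(ref, efficiency, windows$reference)
  }

  jsonlite::write_json(
    purrr::map(overlays, ~ as.list(tibble::as_tibble(.x))),
    file.path(out_dir, "overlays.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  p <- plot_overlay(cell, efficiency, overlays$cell, value_col = "J")
  ggplot2::ggsave(file.path(out_dir, "overlay.png"), p,
                  width = 6, height = 4, dpi = 150)
  invisible(overlays)
}

#' Export the netlist with a round-trip self-check
#'
#' Writes the SPICE netlist for the configured network and re-reads it,
#' verifying that element values and connectivity survive the round trip.
#'
#' @param params A [well_parameters()] object.
#' @param path Netlist file path.
#' @return Invisibly, the netlist lines.
#' @export
run_netlist <- function(params = well_parameters(),
                        path = "well_network.cir") {
  network <- build_network(params)
  lines <- export_netlist(network, path)
  back <- read_netlist(path)
  a <- dplyr::arrange(network$elements, .data$id)
  b <- dplyr::arrange(back$elements, .data$id)
  same <- identical(a$id, b$id) &&
    identical(a$node_a, b$node_a) && identical(a$node_b, b$node_b) &&
    all(abs(a$value - b$value) <= 1e-12 * a$value)
  if (!same) stop("netlist round-trip self-check failed", call. = FALSE)
  invisible(lines)
}
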