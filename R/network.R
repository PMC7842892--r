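# Element-value formulas and assembly of the three-layer axisymmetric
# ladder network.
#
# Per radial segment n (ring at r_n = (n - 1/2) dr) the vertical stack is,
# from the grounded plate upward:
#
#   G --C0n-- D_n --Czon-- L_n --Rzon-- M_n --Rzin-- U_n --Czin-- T_n --R0n-- B_n
#
# (plate capacitor, lower membrane, lower cytoplasm half, upper cytoplasm
# half, upper membrane, buffer column). Radial links: the buffer resistor
# R1n joins B_n to B_{n+1}; the cell layer is joined by the four-element
# series branch M_n -Rron(n)- -Cron(n)- -Crin(n+1)- -Rrin(n+1)- M_{n+1}
# (current leaves cytoplasm n through its outer half-resistance and outer
# radial membrane, and enters segment n+1 through the inner radial membrane
# and inner half-resistance). Segment n_segments has no outward link: the
# well wall is insulating. The plasma column is an ideal sinusoidal source
# between ground and B_1.

#' Per-segment circuit element values
#'
#' Evaluates the constitutive formulas for all eleven element kinds of
#' segment `n` at its ring radius \eqn{r_n = (n - 1/2)\Delta r}: the buffer
#' resistances (vertical `R0n`, radial `R1n`), the membrane capacitances
#' (vertical `Czin`/`Czon`, radial `Crin`/`Cron`), the cytoplasm resistances
#' (vertical `Rzin`/`Rzon`, radial `Rrin`/`Rron`) and the plate capacitance
#' `C0n`. Each resistor is \eqn{\ell / (\sigma A)} and each capacitor
#' \eqn{\varepsilon A / \ell} for the geometric length and area of the slab
#' of material it lumps; the radial cell-layer elements use the reduced
#' radial extent \eqn{(\Delta r / H_c) H_m} (membrane) and
#' \eqn{(\Delta r/H_c)(H_c - 2H_m)/2} (cytoplasm half) that preserves the
#' membrane:cytoplasm height ratio within the ring.
#'
#' @param n Segment index (1-based).
#' @param params A [well_parameters()] object.
#' @return A tibble with one row per element name: `id`, `kind`
#'   (`"resistor"`/`"capacitor"`), `value` (Ohm or F), `layer`,
#'   `orientation`, `side` (`"in"`/`"out"` for the paired membrane and
#'   cytoplasm elements, `NA` otherwise), `segment`, `geom_length` (m) and
#'   `geom_area` (m^2).
#' @examples
#' element_values(1, well_parameters())
#' @export
element_values <- function(n, params) {
  validate_parameters(params)
  stopifnot(n >= 1, n <= params$disc$n_segments)
  m <- params$materials; g <- params$geometry
  dr <- params$disc$delta_r
  r_n <- (n - 0.5) * dr
  eps_m <- m$eps_m_rel * m$eps0
  eps_w <- m$eps_w_rel * m$eps0
  Hcyt <- g$H_c - 2 * g$H_m  # cytoplasm height

  # (length, area) pairs read off each formula
  geom <- tibble::tribble(
    ~id,    ~kind,       ~layer,      ~orientation, ~side,
      ~geom_length,                      ~geom_area,
    "R0n",  "resistor",  "buffer",    "vertical",   NA,
      g$H_b,                             2 * pi * r_n * dr,
    "R1n",  "resistor",  "buffer",    "radial",     NA,
      dr,                                2 * pi * r_n * g$H_b,
    "Czin", "capacitor", "membrane",  "vertical",   "in",
      g$H_m,                             2 * pi * r_n * dr,
    "Czon", "capacitor", "membrane",  "vertical",   "out",
      g$H_m,                             2 * pi * r_n * dr,
    "Crin", "capacitor", "membrane",  "radial",     "in",
      (dr / g$H_c) * g$H_m,              2 * pi * r_n * g$H_c,
    "Cron", "capacitor", "membrane",  "radial",     "out",
      (dr / g$H_c) * g$H_m,              2 * pi * r_n * g$H_c,
    "Rzin", "resistor",  "cytoplasm", "vertical",   "in",
      Hcyt / 2,                          2 * pi * r_n * (dr / g$H_c) * Hcyt,
    "Rzon", "resistor",  "cytoplasm", "vertical",   "out",
      Hcyt / 2,                          2 * pi * r_n * (dr / g$H_c) * Hcyt,
    "Rrin", "resistor",  "cytoplasm", "radial",     "in",
      (dr / g$H_c) * Hcyt / 2,           2 * pi * r_n * Hcyt,
    "Rron", "resistor",  "cytoplasm", "radial",     "out",
      (dr / g$H_c) * Hcyt / 2,           2 * pi * r_n * Hcyt,
    "C0n",  "capacitor", "plate",     "vertical",   NA,
      g$H_w,                             2 * pi * r_n * dr
  )

  material_const <- c(buffer = m$sigma_b, cytoplasm = m$sigma_c,
                      membrane = eps_m, plate = eps_w)
  dplyr::mutate(
    geom,
    id = paste0(.data$id, n),
    segment = as.integer(n),
    value = ifelse(
      .data$kind == "resistor",
      .data$geom_length / (material_const[.data$layer] * .data$geom_area),
      material_const[.data$layer] * .data$geom_area / .data$geom_length
    ),
    .after = "kind"
  )
}

#' Construct a circuit network object
#'
#' Low-level constructor used by [build_network()] and [read_netlist()];
#' also usable directly for hand-built test circuits. Elements are given as
#' a tibble with at least `id`, `kind` (`"resistor"`/`"capacitor"`),
#' `value`, `node_a`, `node_b`; optional annotation columns (`layer`,
#' `orientation`, `side`, `segment`, `geom_length`, `geom_area`) are kept if
#' present and filled with `NA` otherwise.
#'
#' The sign convention throughout the package: the branch voltage of an
#' element is `V(node_a) - V(node_b)` and its branch current flows from
#' `node_a` to `node_b`.
#'
#' @param elements Element tibble (see above).
#' @param source_node Node held at the source potential.
#' @param drive Drive list with `v_pp`, `frequency`, `omega`, `v_rms`
#'   (e.g. `well_parameters()$drive`).
#' @param ground Ground node label (potential 0).
#' @param params Optional `well_parameters` the network was built from.
#' @return An object of class `circuit_network`.
#' @export
circuit_network <- function(elements, source_node, drive, ground = "G",
                            params = NULL) {
  elements <- tibble::as_tibble(elements)
  need <- c("id", "kind", "value", "node_a", "node_b")
  miss <- setdiff(need, names(elements))
  if (length(miss))
    stop("element table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("layer", "orientation", "side"))
    if (!col %in% names(elements)) elements[[col]] <- NA_character_
  if (!"segment" %in% names(elements)) elements$segment <- NA_integer_
  for (col in c("geom_length", "geom_area"))
    if (!col %in% names(elements)) elements[[col]] <- NA_real_

  if (anyDuplicated(elements$id))
    stop("duplicated element ids", call. = FALSE)
  if (!all(elements$kind %in% c("resistor", "capacitor")))
    stop("element kind must be 'resistor' or 'capacitor'", call. = FALSE)
  if (!all(elements$value > 0))
    stop("element values must be > 0", call. = FALSE)

  nodes <- sort(unique(c(elements$node_a, elements$node_b,
                         ground, source_node)))
  structure(
    list(elements = elements, nodes = nodes, ground = ground,
         source_node = source_node, drive = drive, params = params),
    class = "circuit_network"
  )
}

#' Build the full well network
#'
#' Assembles the three-layer, `n_segments`-ring equivalent-circuit network:
#' per segment a six-element vertical stack from the grounded plate to the
#' buffer top, buffer radial resistors linking adjacent buffer nodes, and
#' four-element series cell-layer branches linking adjacent mid-cytoplasm
#' nodes; the outermost segment is left open (insulating well wall). The
#' ideal sinusoidal source acts between ground and the buffer node of
#' segment 1, where the plasma column (treated as a zero-resistance
#' conductor) touches the liquid.
#'
#' Node labels: `B`/`T`/`U`/`M`/`L`/`D` plus the segment index for the
#' buffer-top, upper-membrane-top, upper-cytoplasm, mid-cytoplasm,
#' lower-cytoplasm and plate-top nodes, `Q<n>_1..3` for the internal nodes
#' of the cell-radial branch between segments `n` and `n+1`, and `"G"` for
#' ground.
#'
#' @param params A [well_parameters()] object.
#' @return A `circuit_network` with `6 n + 5 (n - 1)` elements
#'   (171 for the default 16 segments).
#' @examples
#' nw <- build_network(well_parameters())
#' nrow(nw$elements)  # 171
#' @export
build_network <- function(params) {
  validate_parameters(params)
  nseg <- params$disc$n_segments
  vals <- purrr::map(seq_len(nseg), element_values, params = params)

  pick <- function(n, stem) {
    row <- vals[[n]][match(paste0(stem, n), vals[[n]]$id), ]
    stopifnot(nrow(row) == 1)
    row
  }
  with_nodes <- function(row, a, b)
    dplyr::mutate(row, node_a = a, node_b = b)

  vertical <- purrr::map(seq_len(nseg), function(n) {
    dplyr::bind_rows(
      with_nodes(pick(n, "C0n"),  "G",              paste0("D", n)),
      with_nodes(pick(n, "Czon"), paste0("D", n),   paste0("L", n)),
      with_nodes(pick(n, "Rzon"), paste0("L", n),   paste0("M", n)),
      with_nodes(pick(n, "Rzin"), paste0("M", n),   paste0("U", n)),
      with_nodes(pick(n, "Czin"), paste0("U", n),   paste0("T", n)),
      with_nodes(pick(n, "R0n"),  paste0("T", n),   paste0("B", n))
    )
  })

  radial <- purrr::map(seq_len(nseg - 1), function(n) {
    dplyr::bind_rows(
      with_nodes(pick(n, "R1n"), paste0("B", n), paste0("B", n + 1)),
      with_nodes(pick(n, "Rron"),     paste0("M", n),        paste0("Q", n, "_1")),
      with_nodes(pick(n, "Cron"),     paste0("Q", n, "_1"),  paste0("Q", n, "_2")),
      with_nodes(pick(n + 1, "Crin"), paste0("Q", n, "_2"),  paste0("Q", n, "_3")),
      with_nodes(pick(n + 1, "Rrin"), paste0("Q", n, "_3"),  paste0("M", n + 1))
    )
  })

  circuit_network(
    elements = dplyr::bind_rows(vertical, radial),
    source_node = "B1",
    drive = params$drive,
    ground = "G",
    params = params
  )
}

#' Geometry annotation of an element
#'
#' Returns the (length, area) pair implied by an element's constitutive
#' formula, as stored on the network at build time: for a resistor
#' `value = geom_length / (sigma * geom_area)`, for a capacitor
#' `value = eps * geom_area / geom_length`.
#'
#' @param element One or more element rows (a tibble slice from a built
#'   network's `elements`).
#' @return A tibble with columns `id`, `geom_length` (m), `geom_area` (m^2).
#' @export
element_geometry <- function(element) {
  element <- tibble::as_tibble(element)
  if (is.null(element$geom_length) || anyNA(element$geom_length) ||
      is.null(element$geom_area) || anyNA(element$geom_area))
    stop("element has no geometry annotation", call. = FALSE)
  bad <- is.na(element$layer) | is.na(element$orientation)
  if (any(bad))
    stop("unknown layer/orientation for element ",
         paste(element$id[bad], collapse = ", "), call. = FALSE)
  dplyr::select(element, "id", "geom_length", "geom_area")
}

#' @export
print.circuit_network <- function(x, ...) {
  cat("<circuit_network>\n")
  cat(sprintf("  %d elements over %d nodes (ground '%s', source '%s')\n",
              nrow(x$elements), length(x$nodes), x$ground, x$source_node))
  if (!is.null(x$params))
    cat(sprintf("  %d segments, drive %g kVpp at %g kHz\n",
                x$params$disc$n_segments, x$drive$v_pp / 1e3,
                x$drive$frequency / 1e3))
  invisible(x)
}

#' @rdname tidy-phasor
#' @export
tidy.circuit_network <- function(x, ...) x$elements
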