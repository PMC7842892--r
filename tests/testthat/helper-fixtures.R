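# Shared fixtures for the suite.

# the volume-derived buffer height (thin liquid film) alongside the
# printed 50 mm default
thin_params <- function(...) {
  well_parameters(H_b = buffer_height_from_volume(), ...)
}

# a hand-built two-resistor voltage divider: source (1 V RMS at `freq`)
# -- R1 -- mid -- R2 -- ground
divider_network <- function(R1 = 1, R2 = 1, v_pp = 2 * sqrt(2),
                            freq = 20e3) {
  elements <- tibble::tibble(
    id = c("Rtop", "Rbot"),
    kind = "resistor",
    value = c(R1, R2),
    node_a = c("S", "mid"),
    node_b = c("mid", "G")
  )
  circuit_network(elements, source_node = "S",
                  drive = list(v_pp = v_pp, frequency = freq,
                               omega = 2 * pi * freq,
                               v_rms = v_pp / (2 * sqrt(2))))
}

# degenerate single-segment vertical chain with the membrane layers
# shorted out (omitted, their nodes merged) and sigma_c = sigma_b:
# source B -- R0 -- T -- Rzi -- M -- Rzo -- D -- C0 -- G
single_segment_degenerate <- function(params) {
  ev <- element_values(1, params)
  val <- function(id) ev$value[ev$id == id]
  elements <- tibble::tibble(
    id = c("R0n1", "Rzin1", "Rzon1", "C0n1"),
    kind = c("resistor", "resistor", "resistor", "capacitor"),
    value = c(val("R0n1"), val("Rzin1"), val("Rzon1"), val("C0n1")),
    node_a = c("B1", "T1", "M1", "D1"),
    node_b = c("T1", "M1", "D1", "G")
  )
  circuit_network(elements, source_node = "B1", drive = params$drive,
                  params = params)
}

# maximum relative disagreement of node potentials between two solutions
# of the same network
max_node_diff <- function(sol_a, sol_b) {
  nodes <- intersect(names(sol_a$node_potentials),
                     names(sol_b$node_potentials))
  scale <- max(Mod(sol_b$node_potentials))
  max(Mod(sol_a$node_potentials[nodes] - sol_b$node_potentials[nodes])) /
    scale
}
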