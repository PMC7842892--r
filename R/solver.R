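# Complex-phasor nodal analysis of the well network at the drive frequency.
#
# Phasor convention: phasors carry RMS magnitude (the source phasor is
# v_pp/(2*sqrt(2)) + 0i), so the "effective values" plotted downstream are
# simply Mod(phasor). The ideal source is handled by eliminating the
# constrained node from the unknowns (substitution), never by a penalty
# conductance.
#
# The production solver first collapses every series chain (the degree-2
# internal nodes of the vertical stacks and of the four-element cell-radial
# branches) into a single branch impedance, solves the reduced nodal system
# by a direct dense complex solve, and then recovers per-element voltages,
# currents and internal node potentials by impedance division along each
# chain. solve_network_dense() is an independent brute-force route that
# assembles one unknown per node with no reduction; the two must agree to
# round-off and are compared in the test suite.

.element_admittance_vec <- function(kind, value, omega) {
  complex(
    real      = ifelse(kind == "resistor", 1 / value, 0),
    imaginary = ifelse(kind == "capacitor", omega * value, 0)
  )
}

#' Complex admittance of a circuit element
#'
#' Resistor: \eqn{1/R} (real). Capacitor: \eqn{j\omega C} (positive
#' imaginary).
#'
#' @param element A one-row element tibble (or list) with `kind` and
#'   `value`.
#' @param omega Angular frequency, rad/s (> 0).
#' @return A complex scalar in siemens.
#' @examples
#' element_admittance(list(kind = "resistor", value = 2), omega = 1)   # 0.5+0i
#' element_admittance(list(kind = "capacitor", value = 1e-6), 1e6)     # 0+1i
#' @export
element_admittance <- function(element, omega) {
  stopifnot(omega > 0)
  .element_admittance_vec(element$kind, element$value, omega)
}

.check_connected <- function(elements, roots) {
  nodes <- unique(c(elements$node_a, elements$node_b, roots))
  reached <- stats::setNames(nodes %in% roots, nodes)
  repeat {
    hit <- reached[elements$node_a] | reached[elements$node_b]
    newly <- unique(c(elements$node_a[hit], elements$node_b[hit]))
    newly <- newly[!reached[newly]]
    if (!length(newly)) break
    reached[newly] <- TRUE
  }
  if (!all(reached))
    stop("singular system: node(s) not connected to source/ground: ",
         paste(names(reached)[!reached], collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.flip_branch <- function(b) {
  list(na = b$nb, nb = b$na, Z = b$Z,
       members = rev(b$members), dirs = -rev(b$dirs))
}

# Collapse series chains through degree-2 nodes (never ground or source).
.series_reduce <- function(elements, Z, protected) {
  branches <- lapply(seq_len(nrow(elements)), function(k) {
    list(na = elements$node_a[k], nb = elements$node_b[k], Z = Z[k],
         members = k, dirs = 1L)
  })
  repeat {
    ends <- c(vapply(branches, `[[`, character(1), "na"),
              vapply(branches, `[[`, character(1), "nb"))
    deg <- table(ends)
    cand <- setdiff(names(deg)[deg == 2], protected)
    merged_any <- FALSE
    for (v in cand) {
      idx <- which(vapply(branches, function(b) v %in% c(b$na, b$nb),
                          logical(1)))
      if (length(idx) != 2) next  # self-loop or already merged this pass
      b1 <- branches[[idx[1]]]; b2 <- branches[[idx[2]]]
      if (b1$na == v) b1 <- .flip_branch(b1)
      if (b2$nb == v) b2 <- .flip_branch(b2)
      branches[[idx[1]]] <- list(
        na = b1$na, nb = b2$nb, Z = b1$Z + b2$Z,
        members = c(b1$members, b2$members), dirs = c(b1$dirs, b2$dirs)
      )
      branches <- branches[-idx[2]]
      merged_any <- TRUE
      break  # degree table is stale; recompute
    }
    if (!merged_any) break
  }
  branches
}

# Assemble the nodal admittance system for a set of two-terminal branches.
# known: named complex vector of fixed node potentials (ground, source).
.nodal_system <- function(na, nb, Y, known) {
  nodes <- unique(c(na, nb))
  unknown <- setdiff(nodes, names(known))
  m <- length(unknown)
  A <- matrix(0 + 0i, m, m, dimnames = list(unknown, unknown))
  rhs <- stats::setNames(rep(0 + 0i, m), unknown)
  for (b in seq_along(Y)) {
    p <- na[b]; q <- nb[b]; y <- Y[b]
    pu <- !(p %in% names(known)); qu <- !(q %in% names(known))
    if (pu) A[p, p] <- A[p, p] + y
    if (qu) A[q, q] <- A[q, q] + y
    if (pu && qu) {
      A[p, q] <- A[p, q] - y
      A[q, p] <- A[q, p] - y
    } else if (pu) {
      rhs[p] <- rhs[p] + y * known[[q]]
    } else if (qu) {
      rhs[q] <- rhs[q] + y * known[[p]]
    }
  }
  list(A = A, rhs = rhs, unknown = unknown)
}

.nodal_solve <- function(na, nb, Y, known) {
  sys <- .nodal_system(na, nb, Y, known)
  A <- sys$A; rhs <- sys$rhs; unknown <- sys$unknown
  if (!length(unknown)) return(complex(0))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    stop("singular nodal system: ", conditionMessage(e), call. = FALSE))
  # two steps of iterative refinement: the element admittances span ~9
  # orders of magnitude, so the raw LAPACK solve leaves a conditioned
  # residual well above round-off
  for (step in 1:2) {
    resid <- rhs - as.complex(A %*% sol)
    sol <- sol + solve(A, resid)
  }
  stats::setNames(as.complex(sol), unknown)
}

.finish_solution <- function(network, pot, voltage, current, Yel, method) {
  structure(
    list(
      node_potentials = pot,
      elements = dplyr::mutate(network$elements,
                               admittance = Yel,
                               voltage = voltage,
                               current = current),
      omega = network$drive$omega,
      network = network,
      method = method
    ),
    class = "phasor_solution"
  )
}

#' Solve the network at the drive frequency
#'
#' Complex-phasor nodal analysis with the source node constrained to
#' `v_rms + 0i` and ground to 0. Series chains are merged into single branch
#' impedances before the direct linear solve; per-element branch voltages,
#' currents and internal node potentials are recovered afterwards by
#' impedance division, so the returned solution covers every element and
#' node of the original network. The solve is direct and deterministic.
#'
#' @param network A `circuit_network`.
#' @return An object of class `phasor_solution`: `node_potentials` (named
#'   complex vector, RMS phasors, V), `elements` (the network's element
#'   tibble with complex `admittance`, `voltage`, `current` columns),
#'   `omega`, and the `network` itself. Branch voltage is
#'   `V(node_a) - V(node_b)`; branch current is `voltage * admittance`.
#' @examples
#' sol <- solve_network(build_network(well_parameters()))
#' kcl_residual(sol)  # ~1e-16
#' @export
solve_network <- function(network) {
  stopifnot(inherits(network, "circuit_network"))
  el <- network$elements
  omega <- network$drive$omega
  Yel <- .element_admittance_vec(el$kind, el$value, omega)
  Zel <- 1 / Yel
  gnd <- network$ground
  src <- network$source_node
  .check_connected(el, roots = c(gnd, src))

  branches <- .series_reduce(el, Zel, protected = c(gnd, src))
  na <- vapply(branches, `[[`, character(1), "na")
  nb <- vapply(branches, `[[`, character(1), "nb")
  Yb <- 1 / vapply(branches, `[[`, complex(1), "Z")
  # Solve in the source-referenced frame (u = V - v_rms): in this network
  # most node potentials sit within a fraction of a percent of the source
  # potential, and differencing absolute potentials would lose that many
  # digits of every branch voltage. In the shifted frame the large value
  # is carried by the exactly-known ground (-v_rms) and all unknowns are
  # small, so branch voltages come out at full precision.
  v_rms <- network$drive$v_rms
  known <- stats::setNames(c(-v_rms + 0i, 0 + 0i), c(gnd, src))
  pot_u <- c(known, .nodal_solve(na, nb, Yb, known))

  voltage <- current <- rep(NA_complex_, nrow(el))
  for (b in branches) {
    I <- (pot_u[[b$na]] - pot_u[[b$nb]]) / b$Z
    vcur <- pot_u[[b$na]]
    for (j in seq_along(b$members)) {
      k <- b$members[j]; d <- b$dirs[j]
      drop <- I * Zel[k]
      vnext <- vcur - drop
      exit_node <- if (d > 0) el$node_b[k] else el$node_a[k]
      pot_u[exit_node] <- vnext
      voltage[k] <- d * drop
      current[k] <- d * I
      vcur <- vnext
    }
  }
  pot <- pot_u[network$nodes] + v_rms
  pot[gnd] <- 0 + 0i
  pot[src] <- v_rms + 0i
  .finish_solution(network, pot, voltage, current, Yel, method = "reduced")
}

#' Brute-force dense nodal solve (reference route)
#'
#' Independent of [solve_network()]: assembles the full nodal admittance
#' system with one unknown per node (no series reduction) and solves it
#' densely. Used as the in-package oracle for solver verification; results
#' must agree with [solve_network()] to round-off.
#'
#' @inheritParams solve_network
#' @return A `phasor_solution` (see [solve_network()]).
#' @export
solve_network_dense <- function(network) {
  stopifnot(inherits(network, "circuit_network"))
  el <- network$elements
  omega <- network$drive$omega
  Yel <- .element_admittance_vec(el$kind, el$value, omega)
  gnd <- network$ground
  src <- network$source_node
  .check_connected(el, roots = c(gnd, src))

  # same source-referenced frame as solve_network (see comment there)
  v_rms <- network$drive$v_rms
  known <- stats::setNames(c(-v_rms + 0i, 0 + 0i), c(gnd, src))
  pot_u <- c(known, .nodal_solve(el$node_a, el$node_b, Yel, known))
  pot_u <- pot_u[network$nodes]
  voltage <- as.complex(pot_u[el$node_a] - pot_u[el$node_b])
  current <- voltage * Yel
  pot <- pot_u + v_rms
  pot[gnd] <- 0 + 0i
  pot[src] <- v_rms + 0i
  .finish_solution(network, pot, voltage, current, Yel, method = "dense")
}

# Net phasor current injected at `node` by the solved elements
# (positive = flowing out of the node into the network).
.node_outflow <- function(elements, node) {
  sum(elements$current[elements$node_a == node]) -
    sum(elements$current[elements$node_b == node])
}

#' Maximum relative Kirchhoff-current-law residual
#'
#' For every node other than the source and ground, sums the incident branch
#' currents (which must cancel) and reports the largest magnitude relative
#' to the total source current. A direct solve leaves this at round-off
#' (< 1e-9 by a wide margin).
#'
#' @param solution A `phasor_solution`.
#' @param network The network (defaults to the one stored in `solution`).
#' @return A non-negative number.
#' @export
kcl_residual <- function(solution, network = solution$network) {
  el <- solution$elements
  nodes <- setdiff(unique(c(el$node_a, el$node_b)),
                   c(network$ground, network$source_node))
  i_src <- Mod(.node_outflow(el, network$source_node))
  if (!length(nodes)) return(0)
  resid <- vapply(nodes, function(v) Mod(.node_outflow(el, v)), numeric(1))
  max(resid) / i_src
}

#' Complex power balance (Tellegen check)
#'
#' The complex power delivered by the source,
#' \eqn{S = V_\mathrm{src}\,\overline{I}_\mathrm{src}} (RMS phasors, so no
#' factor 1/2), must equal the sum of per-element complex powers
#' \eqn{\sum_e V_e \overline{I}_e}. Resistors absorb non-negative real
#' power; capacitors absorb none.
#'
#' @inheritParams kcl_residual
#' @return A list with `source` (complex VA), `elements` (complex VA) and
#'   `relative_mismatch`.
#' @export
power_balance <- function(solution, network = solution$network) {
  el <- solution$elements
  v_src <- solution$node_potentials[[network$source_node]]
  s_source <- v_src * Conj(.node_outflow(el, network$source_node))
  s_elements <- sum(el$voltage * Conj(el$current))
  list(
    source = s_source,
    elements = s_elements,
    relative_mismatch = Mod(s_source - s_elements) / Mod(s_source)
  )
}

#' @export
print.phasor_solution <- function(x, ...) {
  cat("<phasor_solution>\n")
  cat(sprintf("  %d nodes, %d elements at %g kHz (%s solve)\n",
              length(x$node_potentials), nrow(x$elements),
              x$omega / (2 * pi) / 1e3, x$method))
  pb <- power_balance(x)
  cat(sprintf("  KCL residual %.2e, power mismatch %.2e, source %.3g W\n",
              kcl_residual(x), pb$relative_mismatch, Re(pb$source)))
  invisible(x)
}

#' Tidy and summarize phasor solutions
#'
#' `tidy()` on a `phasor_solution` returns the per-element table with RMS
#' magnitudes `voltage_V` and `current_A` added; on a `circuit_network` it
#' returns the element table. `glance()` returns a one-row summary with the
#' conservation diagnostics.
#'
#' @param x A `phasor_solution` or `circuit_network`.
#' @param ... Unused.
#' @return A tibble.
#' @name tidy-phasor
NULL

#' @rdname tidy-phasor
#' @export
tidy.phasor_solution <- function(x, ...) {
  dplyr::mutate(x$elements,
                voltage_V = Mod(.data$voltage),
                current_A = Mod(.data$current))
}

#' @rdname tidy-phasor
#' @export
glance.phasor_solution <- function(x, ...) {
  pb <- power_balance(x)
  tibble::tibble(
    n_nodes = length(x$node_potentials),
    n_elements = nrow(x$elements),
    frequency_Hz = x$omega / (2 * pi),
    source_current_A = Mod(.node_outflow(x$elements,
                                         x$network$source_node)),
    source_power_W = Re(pb$source),
    kcl_residual = kcl_residual(x),
    power_mismatch = pb$relative_mismatch,
    method = x$method
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
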