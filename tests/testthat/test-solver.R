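test_that("element admittances follow the constitutive laws", {
  expect_equal(element_admittance(list(kind = "resistor", value = 2), 1),
               0.5 + 0i)
  expect_equal(element_admittance(list(kind = "capacitor", value = 1e-6),
                                  1e6), 0 + 1i)
  # vertical membrane capacitor of segment 1 at the 20 kHz drive
  C <- element_values(1, well_parameters())$value[3]  # Czin1
  Y <- element_admittance(list(kind = "capacitor", value = C), 2 * pi * 2e4)
  expect_equal(Re(Y), 0)
  expect_equal(Mod(Y), 2 * pi * 2e4 * C)
  expect_equal(Mod(Y), 8.39e-6, tolerance = 1e-3)
})

test_that("trivial circuits solve to Ohm's-law values", {
  one_r <- circuit_network(
    tibble::tibble(id = "R", kind = "resistor", value = 1,
                   node_a = "S", node_b = "G"),
    source_node = "S",
    drive = list(v_pp = 2 * sqrt(2), frequency = 20e3,
                 omega = 2 * pi * 20e3, v_rms = 1))
  sol <- solve_network(one_r)
  expect_equal(sol$elements$current, 1 + 0i)
  expect_equal(sol$node_potentials[["S"]], 1 + 0i)
  expect_equal(sol$node_potentials[["G"]], 0 + 0i)

  div <- divider_network(R1 = 1, R2 = 1)
  for (solver in list(solve_network, solve_network_dense)) {
    s <- solver(div)
    expect_equal(s$node_potentials[["mid"]], 0.5 + 0i)
    expect_equal(s$elements$current, c(0.5 + 0i, 0.5 + 0i))
    expect_lt(kcl_residual(s), 1e-12)
  }

  # hand-written nodal equation for an uneven divider: V_mid = R2/(R1+R2)
  div2 <- divider_network(R1 = 3, R2 = 1)
  s2 <- solve_network(div2)
  expect_equal(s2$node_potentials[["mid"]], 0.25 + 0i)
})

test_that("full network satisfies KCL and complex power balance", {
  for (p in list(well_parameters(), thin_params())) {
    sol <- solve_network(build_network(p))
    expect_lt(kcl_residual(sol), 1e-9)
    pb <- power_balance(sol)
    expect_lt(pb$relative_mismatch, 1e-9)
    # every resistor absorbs real power; every capacitor none
    el <- sol$elements
    s_el <- el$voltage * Conj(el$current)
    res <- el$kind == "resistor"
    expect_true(all(Re(s_el[res]) >= 0))
    expect_lt(max(abs(Re(s_el[!res]))) / Mod(pb$source), 1e-12)
  }
})

test_that("kcl_residual detects a perturbed branch current", {
  sol <- solve_network(build_network(well_parameters()))
  expect_lt(kcl_residual(sol), 1e-9)
  k <- which(sol$elements$id == "R1n8")
  sol$elements$current[k] <- sol$elements$current[k] * 1.01
  expect_gt(kcl_residual(sol), 1e-3)
})

test_that("reduced solver agrees with the dense brute-force oracle", {
  for (hb in c(50e-3, buffer_height_from_volume())) {
    for (n in c(2, 4, 16)) {
      p <- well_parameters(H_b = hb, n_segments = n)
      nw <- build_network(p)
      expect_lt(max_node_diff(solve_network(nw), solve_network_dense(nw)),
                1e-10)
    }
  }
})

test_that("branch quantities are exactly linear in the drive amplitude", {
  p1 <- well_parameters()
  p2 <- well_parameters(v_pp = 3 * p1$drive$v_pp)
  s1 <- solve_network(build_network(p1))
  s2 <- solve_network(build_network(p2))
  rel <- function(a, b) max(Mod(a - b)) / max(Mod(b))
  expect_lt(rel(s2$elements$current, 3 * s1$elements$current), 1e-11)
  expect_lt(rel(s2$elements$voltage, 3 * s1$elements$voltage), 1e-11)
  expect_lt(rel(s2$node_potentials, 3 * s1$node_potentials), 1e-11)
})

test_that("assembled nodal admittance matrix is symmetric (reciprocity)", {
  nw <- build_network(well_parameters(n_segments = 4))
  omega <- nw$drive$omega
  el <- nw$elements
  Y <- plasmawell:::.element_admittance_vec(el$kind, el$value, omega)
  sys <- plasmawell:::.nodal_system(
    el$node_a, el$node_b, Y,
    known = c(G = 0 + 0i, B1 = 1 + 0i))
  expect_identical(sys$A, t(sys$A))
})

test_that("degenerate single-segment chain matches the closed-form divider", {
  p <- well_parameters(sigma_c = 0.376)  # cytoplasm set to buffer
  nw <- single_segment_degenerate(p)
  omega <- p$drive$omega
  ev <- element_values(1, p)
  val <- function(id) ev$value[ev$id == id]
  Z <- val("R0n1") + val("Rzin1") + val("Rzon1") +
    1 / (1i * omega * val("C0n1"))
  I <- p$drive$v_rms / Z

  for (solver in list(solve_network, solve_network_dense)) {
    sol <- solver(nw)
    expect_lt(max(Mod(sol$elements$current - I)) / Mod(I), 1e-9)
    v_T <- p$drive$v_rms - I * val("R0n1")
    v_M <- v_T - I * val("Rzin1")
    v_D <- v_M - I * val("Rzon1")
    expect_lt(Mod(sol$node_potentials[["T1"]] - v_T) / Mod(v_T), 1e-9)
    expect_lt(Mod(sol$node_potentials[["M1"]] - v_M) / Mod(v_M), 1e-9)
    expect_lt(Mod(sol$node_potentials[["D1"]] - v_D) / Mod(v_D), 1e-9)
  }
})

test_that("disconnected nodes are reported by label", {
  el <- tibble::tibble(
    id = c("R1", "R2"),
    kind = "resistor", value = 1,
    node_a = c("S", "lost1"),
    node_b = c("G", "lost2"))
  nw <- circuit_network(el, source_node = "S",
                        drive = list(v_pp = 2 * sqrt(2), frequency = 1e3,
                                     omega = 2e3 * pi, v_rms = 1))
  expect_error(solve_network(nw), "lost1")
  expect_error(solve_network_dense(nw), "lost2")
})

test_that("tidy and glance expose the solution tables", {
  sol <- solve_network(build_network(well_parameters()))
  td <- tidy(sol)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 171)
  expect_true(all(c("voltage_V", "current_A") %in% names(td)))
  expect_equal(td$voltage_V, Mod(td$voltage))
  gl <- glance(sol)
  expect_equal(nrow(gl), 1)
  expect_lt(gl$kcl_residual, 1e-9)
  expect_equal(gl$n_elements, 171L)
  expect_equal(nrow(tidy(build_network(well_parameters()))), 171)
})
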