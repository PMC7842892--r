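profile_fixture <- function(params = well_parameters()) {
  layer_profiles(solve_network(build_network(params)))
}

test_that("element fields follow E = |V|/l and J = |I|/A", {
  sol <- solve_network(build_network(well_parameters()))
  ef <- element_fields(sol)
  expect_equal(ef$E, Mod(ef$voltage) / ef$geom_length)
  expect_equal(ef$J, Mod(ef$current) / ef$geom_area)
  # hand check: 1 V RMS across 0.5 um gives 2e6 V/m; 1 mA through 1e-6 m^2
  # gives 1e3 A/m^2
  expect_equal(1 / 0.5e-6, 2e6)
  k <- which(ef$id == "Czin1")
  expect_equal(ef$E[k], Mod(ef$voltage[k]) / 0.5e-6)
})

test_that("membrane elements realize the omega*eps_m admittance (33.4 uS/m)", {
  p <- well_parameters()
  sol <- solve_network(build_network(p))
  ef <- element_fields(sol)
  mem <- ef[ef$layer == "membrane", ]
  w_eps_m <- p$drive$omega * 30 * 8.854e-12
  expect_lt(max(abs(mem$J / mem$E - w_eps_m)) / w_eps_m, 1e-9)
  expect_equal(w_eps_m * 1e6, 33.4, tolerance = 2e-3)
})

test_that("profiles are constitutively consistent in every layer and segment", {
  for (p in list(well_parameters(), thin_params())) {
    prof <- profile_fixture(p)
    sigma <- c(buffer = p$materials$sigma_b,
               cytoplasm = p$materials$sigma_c,
               membrane = p$drive$omega * p$materials$eps_m_rel *
                 p$materials$eps0)
    for (comp in c("vertical", "radial", "mean")) {
      Jc <- prof[[paste0("J_", comp)]]
      Ec <- prof[[paste0("E_", comp)]]
      expect_lt(max(abs(Jc / Ec - sigma[prof$layer]) / sigma[prof$layer]),
                1e-9)
    }
    # the r-z average identity
    expect_equal(prof$J_mean, (prof$J_vertical + prof$J_radial) / 2)
    expect_equal(prof$E_mean, (prof$E_vertical + prof$E_radial) / 2)
    expect_true(all(prof$J_vertical >= 0 & prof$J_radial >= 0))
  }
})

test_that("radial component averages the incident branches", {
  sol <- solve_network(build_network(well_parameters()))
  ef <- element_fields(sol)
  prof <- layer_profiles(sol)
  # interior buffer segment n: mean of R1(n-1) and R1(n)
  j5 <- prof$J_radial[prof$layer == "buffer" & prof$segment == 5]
  expect_equal(j5, mean(ef$J[ef$id %in% c("R1n4", "R1n5")]))
  # boundary segments use their single incident branch
  j1 <- prof$J_radial[prof$layer == "buffer" & prof$segment == 1]
  expect_equal(j1, ef$J[ef$id == "R1n1"])
  j16 <- prof$J_radial[prof$layer == "buffer" & prof$segment == 16]
  expect_equal(j16, ef$J[ef$id == "R1n15"])
  # membrane radial: inner + outer capacitor of the segment
  m3 <- prof$J_radial[prof$layer == "membrane" & prof$segment == 3]
  expect_equal(m3, mean(ef$J[ef$id %in% c("Crin3", "Cron3")]))
  m1 <- prof$J_radial[prof$layer == "membrane" & prof$segment == 1]
  expect_equal(m1, ef$J[ef$id == "Cron1"])
  # vertical membrane: upper/lower pair averaged
  v3 <- prof$J_vertical[prof$layer == "membrane" & prof$segment == 3]
  expect_equal(v3, mean(ef$J[ef$id %in% c("Czin3", "Czon3")]))
})

test_that("buffer radial current decays outward; vertical membrane current is near-uniform", {
  for (p in list(well_parameters(), thin_params())) {
    prof <- profile_fixture(p)
    buf <- prof[prof$layer == "buffer", ]
    expect_true(all(diff(buf$J_radial[2:16]) < 0))
    mem <- prof[prof$layer == "membrane", ]
    ratio <- max(mem$J_vertical[2:16]) / min(mem$J_vertical[2:16])
    expect_lt(ratio, 2)
  }
})

test_that("membrane exposure converts field to voltage and current density to per-cell current", {
  p <- well_parameters()
  prof <- profile_fixture(p)
  expo <- membrane_exposure(prof)
  mem <- prof[prof$layer == "membrane", ]
  expect_equal(expo$V_m, mem$E_mean * 0.5e-6)
  expect_equal(expo$I_cell, mem$J_mean * pi * (50e-6)^2)
  # worked constants: E = 1e6 V/m over 0.5 um -> 0.5 V;
  # J = 12.73 A/m^2 over pi Hc^2 -> ~1e-7 A
  expect_equal(1e6 * 0.5e-6, 0.5)
  expect_equal(12.73 * pi * (50e-6)^2, 1e-7, tolerance = 1e-3)
  bands <- attr(expo, "bands")
  expect_equal(bands$action_potential_V, 0.1)
  expect_equal(bands$damage_low_V, 0.5)
  expect_equal(bands$damage_high_V, 1)
  expect_equal(bands$ion_transport_A, 1e-9)
})

test_that("exposure scales exactly with the drive amplitude", {
  e1 <- membrane_exposure(profile_fixture(well_parameters()))
  e2 <- membrane_exposure(profile_fixture(well_parameters(v_pp = 30e3)))
  expect_equal(e2$V_m, 2 * e1$V_m, tolerance = 1e-12)
  expect_equal(e2$I_cell, 2 * e1$I_cell, tolerance = 1e-12)
})

test_that("admittance summary reproduces the printed material scales", {
  adm <- admittance_summary(well_parameters())
  expect_equal(adm$display_value[adm$quantity == "omega_eps_m"], 33.4)
  expect_equal(adm$display_value[adm$quantity == "plate_impedance"], 374)
  expect_equal(adm$display_unit, c("S/m", "uS/m", "kOhm m"))
  # linear in omega: doubling f doubles the membrane admittance and
  # halves the plate impedance
  adm2 <- admittance_summary(well_parameters(frequency = 40e3))
  expect_equal(adm2$value[2], 2 * adm$value[2])
  expect_equal(adm2$value[3], adm$value[3] / 2)
})
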