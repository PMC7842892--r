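test_that("segment-1 element values match independent hand evaluation", {
  p <- well_parameters()
  ev <- element_values(1, p)
  val <- function(id) ev$value[ev$id == id]
  r1 <- 0.1e-3; dr <- 0.2e-3
  eps0 <- 8.854e-12

  # buffer column: (1/sigma_b) * H_b / (2 pi r1 dr)
  expect_equal(val("R0n1"), (1 / 0.376) * 0.05 / (2 * pi * r1 * dr))
  # buffer radial: (1/sigma_b) * dr / (2 pi r1 H_b)
  expect_equal(val("R1n1"), (1 / 0.376) * dr / (2 * pi * r1 * 0.05))
  # vertical membrane: eps_m * 2 pi r1 dr / H_m
  expect_equal(val("Czin1"), 30 * eps0 * 2 * pi * r1 * dr / 0.5e-6)
  expect_equal(val("Czin1"), val("Czon1"))
  # radial membrane: eps_m * 2 pi r1 H_c / ((dr/H_c) H_m)
  expect_equal(val("Crin1"),
               30 * eps0 * 2 * pi * r1 * 50e-6 / ((dr / 50e-6) * 0.5e-6))
  expect_equal(val("Crin1"), val("Cron1"))
  # cytoplasm vertical: (1/sigma_c) ((H_c-2H_m)/2) / (2 pi r1 (dr/H_c)(H_c-2H_m))
  hcy <- 50e-6 - 2 * 0.5e-6
  expect_equal(val("Rzin1"),
               (hcy / 2) / (2 * pi * r1 * (dr / 50e-6) * hcy))
  expect_equal(val("Rzin1"), val("Rzon1"))
  # cytoplasm radial
  expect_equal(val("Rrin1"),
               ((dr / 50e-6) * hcy / 2) / (2 * pi * r1 * hcy))
  expect_equal(val("Rrin1"), val("Rron1"))
  # plate: eps_w * 2 pi r1 dr / H_w
  expect_equal(val("C0n1"), 2.4 * eps0 * 2 * pi * r1 * dr / 1.5e-3)

  # magnitudes frozen from the hand evaluations above
  expect_equal(val("R0n1"), 1.058e6, tolerance = 1e-3)
  expect_equal(val("R1n1"), 16.93, tolerance = 1e-3)
  expect_equal(val("Czin1"), 6.68e-11, tolerance = 1e-3)
  expect_equal(val("C0n1"), 1.78e-15, tolerance = 2e-3)
  expect_equal(val("Rzin1"), 199, tolerance = 1e-3)
})

test_that("element values are consistent with their (length, area) geometry", {
  for (p in list(well_parameters(), thin_params(),
                 well_parameters(n_segments = 4, delta_r = 0.5e-3))) {
    nw <- build_network(p)
    el <- nw$elements
    const <- c(buffer = p$materials$sigma_b,
               cytoplasm = p$materials$sigma_c,
               membrane = p$materials$eps_m_rel * p$materials$eps0,
               plate = p$materials$eps_w_rel * p$materials$eps0)
    recomputed <- ifelse(
      el$kind == "resistor",
      el$geom_length / (const[el$layer] * el$geom_area),
      const[el$layer] * el$geom_area / el$geom_length
    )
    expect_lt(max(abs(recomputed - el$value) / el$value), 1e-12)
  }
})

test_that("geometry pairs match the constitutive formulas", {
  p <- well_parameters()
  ev <- element_values(1, p)
  g <- element_geometry(ev)
  geom <- function(id) unlist(g[g$id == id, c("geom_length", "geom_area")])
  expect_equal(geom("R0n1"), c(geom_length = 0.05,
                               geom_area = 2 * pi * 1e-4 * 2e-4))
  expect_equal(geom("Czin1"), c(geom_length = 0.5e-6,
                                geom_area = 2 * pi * 1e-4 * 2e-4))
  # reduced radial extent of the cytoplasm half-element
  expect_equal(geom("Rrin1")[["geom_length"]], 9.8e-5)
  expect_error(element_geometry(tibble::tibble(
    id = "x", geom_length = NA_real_, geom_area = 1,
    layer = "buffer", orientation = "vertical")), "geometry annotation")
})

test_that("element value scalings with radius hold across segments", {
  p <- well_parameters()
  r <- radial_positions(p)
  vals <- purrr::map_dfr(1:16, element_values, params = p)
  R0 <- vals$value[grepl("^R0n", vals$id)]
  C0 <- vals$value[grepl("^C0n", vals$id)]
  expect_equal(R0 * r, rep(R0[1] * r[1], 16))   # R0n ~ 1/r_n
  expect_equal(C0 / r, rep(C0[1] / r[1], 16))   # C0n ~ r_n
})

test_that("network has the forced element count and topology", {
  p <- well_parameters()
  nw <- build_network(p)
  el <- nw$elements
  # 6 vertical per segment + (n-1) buffer radial + 4 (n-1) cell radial
  expect_equal(nrow(el), 171)
  expect_equal(sum(el$orientation == "vertical"), 96)
  expect_equal(sum(el$layer == "buffer" & el$orientation == "radial"), 15)
  expect_equal(sum(el$layer %in% c("membrane", "cytoplasm") &
                     el$orientation == "radial"), 60)
  # exactly one plate capacitor per segment touches ground
  grounded <- el[el$node_a == "G" | el$node_b == "G", ]
  expect_equal(nrow(grounded), 16)
  expect_true(all(grounded$layer == "plate"))
  expect_true(all(grounded$kind == "capacitor"))

  nw2 <- build_network(well_parameters(n_segments = 2))
  expect_equal(nrow(nw2$elements), 17)  # 12 vertical + 1 + 4
  g2 <- nw2$elements[nw2$elements$node_a == "G" | nw2$elements$node_b == "G", ]
  expect_equal(nrow(g2), 2)

  # general count 11 n - 5
  for (n in c(3, 5, 9)) {
    expect_equal(nrow(build_network(well_parameters(n_segments = n))$elements),
                 11 * n - 5)
  }
})

test_that("ladder stays connected even without the source segment's stack", {
  nw <- build_network(well_parameters())
  el <- nw$elements
  # drop every element incident to the source node; ground must still
  # reach every segment's stack through the remaining ladder
  keep <- el[el$node_a != "B1" & el$node_b != "B1", ]
  reach <- "G"
  repeat {
    hit <- keep$node_a %in% reach | keep$node_b %in% reach
    grew <- union(reach, unique(c(keep$node_a[hit], keep$node_b[hit])))
    if (length(grew) == length(reach)) break
    reach <- grew
  }
  expect_true(all(paste0("M", 1:16) %in% reach))
  expect_true(all(paste0("B", 2:16) %in% reach))
})

test_that("ring areas tile the well bottom under refinement", {
  area <- function(p) sum(2 * pi * radial_positions(p) * p$disc$delta_r)
  p1 <- well_parameters()                                   # 16 x 0.2 mm
  p2 <- well_parameters(n_segments = 8, delta_r = 0.4e-3)   # 8 x 0.4 mm
  expect_equal(area(p1), pi * 3.2e-3^2)
  expect_equal(area(p2), pi * 3.2e-3^2)
})
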