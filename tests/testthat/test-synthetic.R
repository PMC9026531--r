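test_that("generator is deterministic and exact without noise", {
  spec0 <- tensile_spec(yeoh_graft(1), noise_sd = 0)
  d0 <- generate_tensile(spec0)
  expect_equal(d0$samples$stress_mpa,
               uniaxial_stress(yeoh_graft(1), d0$samples$stretch),
               tolerance = 1e-15)

  spec <- tensile_spec(yeoh_graft(1), noise_sd = 0.05, seed = 42)
  d1 <- generate_tensile(spec)
  d2 <- generate_tensile(spec)
  expect_identical(d1$samples, d2$samples)

  d3 <- generate_tensile(tensile_spec(yeoh_graft(1), noise_sd = 0.05,
                                      seed = 43))
  expect_false(identical(d1$samples$stress_mpa, d3$samples$stress_mpa))
})

test_that("generator noise level is reproduced in the samples", {
  spec <- tensile_spec(yeoh_graft(1), n = 100, noise_sd = 0.05,
                       seed = 20220407)
  d <- generate_tensile(spec)
  resid <- d$samples$stress_mpa -
    uniaxial_stress(yeoh_graft(1), d$samples$stretch)
  rmse <- sqrt(mean(resid^2))
  expect_gt(rmse, 0.04)
  expect_lt(rmse, 0.06)
})

test_that("generator validates the rupture point", {
  expect_error(tensile_spec(yeoh_graft(1), rupture = c(1.2, 20)),
               "rupture")
  spec <- tensile_spec(yeoh_graft(1), noise_sd = 0, rupture = c(1.7, 0.01))
  expect_error(generate_tensile(spec), "exceed")
})

test_that("generated data round-trips the fitting loop", {
  d <- generate_tensile(tensile_spec(yeoh_graft(2), noise_sd = 0))
  fit <- fit_material(d, "yeoh3")
  expect_lt(fit$rmse, 1e-8)
})

test_that("inlet waveform matches the stated cycle timing", {
  wf <- default_waveform()
  expect_equal(wf$velocity(0.09), 1.4)
  tt <- seq(0, 0.5, by = 1e-4)
  expect_equal(wf$velocity(tt), wf$velocity(tt + 0.5), tolerance = 1e-12)
  expect_equal(max(wf$velocity(tt)), wf$velocity(0.09), tolerance = 1e-6)
  expect_equal(wf$velocity(0.22), 0, tolerance = 1e-12)
  expect_equal(wf$velocity(0.4), 0)
  # continuity across the periodic seam and at end-systole
  expect_lt(abs(wf$velocity(0.5 - 1e-9) - wf$velocity(0.5 + 1e-9)), 1e-6)
  expect_lt(abs(wf$velocity(0.22 - 1e-9) - wf$velocity(0.22 + 1e-9)), 1e-6)
})

test_that("waveform constructor validates its shape numbers", {
  expect_error(inlet_waveform(t_peak = 0.3, systole = 0.22), "t_peak")
  expect_error(inlet_waveform(v_peak = 0.5, v_base = 1), "v_peak")
  wf <- inlet_waveform(v_base = 0.1)
  expect_equal(wf$velocity(0.45), 0.1)
})

test_that("systemic pressure profile spans the physiologic range", {
  pf <- systemic_pressure_profile()
  tt <- seq(0, 0.5, by = 1e-3)
  p <- pf(tt) / 133.322
  expect_equal(min(p), 80, tolerance = 1e-6)
  expect_equal(max(p), 120, tolerance = 1e-3)
  expect_equal(pf(0.09) / 133.322, 120, tolerance = 1e-6)
})

test_that("networks are built with the stated shunt parents", {
  junction_with <- function(net, seg, side) {
    Filter(function(j) any(j$segment == seg & j$side == side),
           net$junctions)[[1]]
  }
  central <- build_network(network_spec("central"))
  j <- junction_with(central, "shunt", "start")
  expect_true(any(j$segment == "asc_prox" & j$side == "end"))

  right <- build_network(network_spec("right"))
  j <- junction_with(right, "shunt", "start")
  expect_true(any(j$segment == "lsa_prox" & j$side == "end"))

  left <- build_network(network_spec("left"))
  j <- junction_with(left, "shunt", "start")
  expect_true(any(j$segment == "bct_prox" & j$side == "end"))
})

test_that("every placement yields a connected tree feeding the lungs", {
  for (pl in c("central", "right", "left")) {
    net <- build_network(network_spec(pl))
    expect_s3_class(net, "vessel_network")
    down <- shunt_path(net)
    pulm <- names(Filter(function(o) o$type == "pressure", net$outlets))
    expect_true(all(pulm %in% down))
    expect_false(net$inlet %in% down)
    expect_false("desc_aorta" %in% down)
    expect_length(net$outlets[[net$inlet]], 0)
  }
})

test_that("network validation catches broken topologies", {
  net <- build_network(network_spec("central"))
  broken <- net
  broken$junctions[[1]] <- broken$junctions[[1]][-1, ]
  expect_error(shuntflow:::validate_network(broken), "topology|attached")
  orphan <- net
  orphan$junctions[[4]] <- NULL
  expect_error(shuntflow:::validate_network(orphan),
               "attached|disconnected")
})

test_that("dimension overrides and validation work", {
  spec <- network_spec("central",
                       dims = list(shunt = list(radius_mm = 2.0)))
  net <- build_network(spec)
  expect_equal(net$segments$shunt$r0, 2e-3)
  expect_error(build_network(network_spec("central",
    dims = list(shunt = list(length_mm = -2)))), "positive")
})
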