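test_that("invariants follow the standard definitions", {
  iv <- invariants_from_stretches(principal_stretches(1, 1, 1),
                                  fiber_angles = c(0, pi / 3))
  expect_equal(iv$I1bar, 3)
  expect_equal(iv$I2bar, 3)
  expect_equal(iv$I3bar, 1)
  expect_equal(iv$I4, c(1, 1))

  iv2 <- invariants_from_stretches(uniaxial_stretches(1.5))
  expect_equal(iv2$I1bar, 2.25 + 2 / 1.5, tolerance = 1e-12)
  expect_equal(iv2$I3bar, 1, tolerance = 1e-12)

  iv3 <- invariants_from_stretches(principal_stretches(1.2, 1 / 1.2, 1),
                                   fiber_angles = 0)
  expect_equal(iv3$I4, 1.44, tolerance = 1e-12)
})

test_that("deformation state validation rejects bad input", {
  expect_error(principal_stretches(-1, 1, 1), "positive")
  expect_error(principal_stretches(1.5, 1, 1), "incompressibility")
  expect_error(uniaxial_stretches(0), "positive")
})

test_that("strain energy vanishes at the identity for every model", {
  id <- principal_stretches(1, 1, 1)
  for (m in reference_models())
    expect_identical(strain_energy(m, id), 0)
  expect_identical(strain_energy(linear_elastic(10.3, 0.49), id), 0)
})

test_that("Yeoh graft energy matches direct evaluation", {
  W <- strain_energy(yeoh_graft(1), uniaxial_stretches(1.5))
  x <- 2.25 + 2 / 1.5 - 3
  expect_equal(W, 0.11 * x - 4.96e-6 * x^2 + 1.67e-10 * x^3,
               tolerance = 1e-12)
  expect_equal(W, 0.06416, tolerance = 1e-4)
})

test_that("nominal stress is zero at the reference state", {
  for (m in reference_models())
    expect_identical(uniaxial_stress(m, 1), 0)
})

test_that("analytic uniaxial stress matches the energy-derivative oracle", {
  lam <- seq(0.5, 2.5, by = 0.05)
  for (m in reference_models()) {
    P <- uniaxial_stress(m, lam)
    Pn <- numeric_uniaxial_stress(m, lam)
    expect_lt(rel_err(P, Pn), 1e-6)
  }
})

test_that("Cauchy stress is lambda times nominal stress", {
  m <- yeoh_graft(2)
  lam <- c(0.8, 1.3, 1.6)
  expect_equal(uniaxial_stress(m, lam, type = "cauchy"),
               lam * uniaxial_stress(m, lam), tolerance = 1e-14)
})

test_that("one-term Ogden with alpha = 2 is the neo-Hookean solid", {
  mu <- 0.37
  m <- ogden(mu = mu, alpha = 2)
  lam <- seq(0.6, 2, by = 0.1)
  expect_equal(uniaxial_stress(m, lam), mu * (lam - lam^-2),
               tolerance = 1e-12)
})

test_that("two-term Ogden with alpha = (2, -2) equals two-term Mooney-Rivlin", {
  og <- ogden(mu = c(0.8, -0.3), alpha = c(2, -2))
  mr <- mooney_rivlin5(c10 = 0.4, c01 = 0.15, c20 = 0, c11 = 0, c02 = 0)
  lam <- seq(0.7, 1.8, by = 0.02)
  expect_lt(rel_err(uniaxial_stress(og, lam), uniaxial_stress(mr, lam)),
            1e-10)
  Wo <- vapply(lam, function(l) strain_energy(og, uniaxial_stretches(l)), 0)
  Wm <- vapply(lam, function(l) strain_energy(mr, uniaxial_stretches(l)), 0)
  expect_lt(max(abs(Wo - Wm)), 1e-10)
})

test_that("HGO becomes isotropic at kappa = 1/3", {
  lam <- seq(0.7, 1.8, by = 0.05)
  m0 <- hgo(0.3, 0.5, 5, 1 / 3, beta = 0)
  m90 <- hgo(0.3, 0.5, 5, 1 / 3, beta = pi / 2)
  m45 <- hgo(0.3, 0.5, 5, 1 / 3, beta = c(pi / 4, -pi / 4))
  expect_lt(max(abs(uniaxial_stress(m0, lam) - uniaxial_stress(m90, lam))),
            1e-12)
  s45 <- uniaxial_stress(m45, lam)   # two families, double the fiber term
  st <- uniaxial_stress(m0, lam)
  matrix_part <- uniaxial_stress(hgo(0.3, 1e-12, 5, 1 / 3, beta = 0), lam)
  expect_equal(s45 - matrix_part, 2 * (st - matrix_part), tolerance = 1e-9)

  for (l in c(0.9, 1.4)) {
    w0 <- strain_energy(m0, uniaxial_stretches(l))
    w90 <- strain_energy(m90, uniaxial_stretches(l))
    expect_lt(abs(w0 - w90), 1e-12)
  }
})

test_that("HGO fiber strain measure follows its two limits", {
  m <- hgo(0.3, 0.5, 5, kappa = 0, beta = 0)
  iv <- list(I1bar = 3.7, I4 = 1.2)
  expect_equal(hgo_fiber_strain(m, iv, 1), 0.2, tolerance = 1e-12)

  m3 <- hgo(0.3, 0.5, 5, kappa = 1 / 3, beta = 0)
  iv3 <- list(I1bar = 3.5, I4 = 1.4)
  expect_equal(hgo_fiber_strain(m3, iv3, 1), 1 / 6, tolerance = 1e-12)

  id <- invariants_from_stretches(principal_stretches(1, 1, 1),
                                  fiber_angles = 0)
  expect_equal(hgo_fiber_strain(m, id, 1), 0)
  expect_error(hgo_fiber_strain(m, id, 5), "out of range")
})

test_that("the as-printed (1+3k) fiber-strain convention is available", {
  mp <- hgo(0.3, 0.5, 5, kappa = 1 / 3, beta = 0, convention = "plus")
  iv <- list(I1bar = 3.5, I4 = 1.4)
  expect_equal(hgo_fiber_strain(mp, iv, 1), 0.5 / 3 + 2 * 0.4,
               tolerance = 1e-12)
  # with the plus convention kappa = 1/3 is NOT isotropic
  mp90 <- hgo(0.3, 0.5, 5, 1 / 3, beta = pi / 2, convention = "plus")
  expect_gt(abs(uniaxial_stress(mp, 1.4) - uniaxial_stress(mp90, 1.4)),
            1e-6)
})

test_that("small-strain shear modulus matches the numerical tangent", {
  mods <- c(reference_models(),
            list(neo_hookean = ogden(mu = 0.5, alpha = 2)))
  for (m in mods) {
    mu_a <- small_strain_shear_modulus(m)
    mu_n <- uniaxial_tangent(m, 1) / 3
    expect_lt(abs(mu_a - mu_n) / abs(mu_a), 1e-6)
  }
  expect_equal(small_strain_shear_modulus(ogden_aorta()),
               0.5 * (1.274 * 24.074 - 1.211 * 24.073), tolerance = 1e-12)
  expect_equal(small_strain_shear_modulus(ogden_aorta()), 0.759,
               tolerance = 2e-4)
  expect_equal(small_strain_shear_modulus(yeoh_graft(1)), 0.22)
  expect_equal(small_strain_shear_modulus(ogden(mu = 0.31, alpha = 2)), 0.31)
})

test_that("incompressibility holds along every uniaxial path", {
  for (l in seq(0.5, 2.5, by = 0.25))
    expect_lt(abs(prod(uniaxial_stretches(l)) - 1), 1e-12)
})

test_that("Drucker stability report flags non-positive tangents only", {
  nh <- ogden(mu = 0.5, alpha = 2)
  rep1 <- drucker_stability_report(nh, 0.8, 2)
  expect_true(attr(rep1, "all_stable"))

  rep2 <- drucker_stability_report(yeoh_graft(1), 1, 2)
  expect_true(attr(rep2, "all_stable"))

  soft <- mooney_rivlin5(-1, 0.2, 0, 0, 0)  # negative shear modulus
  rep3 <- drucker_stability_report(soft, 0.9, 1.5)
  expect_false(rep3$stable[which.min(abs(rep3$lambda - 1))])
  expect_false(attr(rep3, "all_stable"))
})

test_that("constructors validate parameter ranges", {
  expect_error(yeoh3(-0.1, 0, 0), "positive")
  expect_error(ogden(c(1, -1), c(2, 2)), "shear modulus")
  expect_error(ogden(1:2, 1:3), "equal-length")
  expect_error(hgo(0.3, 0.5, 5, kappa = 0.5), "kappa")
  expect_error(hgo(0.3, -1, 5, kappa = 0.1), "k1")
  expect_error(linear_elastic(10, 0.5), "nu")
  expect_error(linear_elastic(-1, 0.3), "positive")
})

test_that("materials serialize to flat blocks and back", {
  mods <- c(reference_models(), list(lin = elastic_graft()))
  for (m in mods) {
    cfg <- material_to_config(m)
    m2 <- material_from_config(cfg)
    expect_identical(m2$model, m$model)
    lam <- c(0.9, 1.2, 1.5)
    expect_equal(uniaxial_stress(m2, lam), uniaxial_stress(m, lam),
                 tolerance = 1e-12)
  }
  expect_error(material_from_config(list(c10 = 1)), "model")
})
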