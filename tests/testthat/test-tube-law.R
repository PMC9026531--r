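test_that("tube law is stress-free at the reference area", {
  for (m in list(elastic_graft(), ogden_aorta(), hgo_aorta(),
                 yeoh_graft(1))) {
    law <- tube_law(m, A0 = pi * 3e-3^2, h = 0.3e-3)
    expect_equal(law$p(law$A0), 0, tolerance = 1e-9)
  }
})

test_that("linear-elastic law matches the closed thin-shell form", {
  E <- 10.3; nu <- 0.49; h <- 0.35e-3; r0 <- 1.75e-3
  law <- tube_law(linear_elastic(E, nu), A0 = pi * r0^2, h = h)
  lam <- 1.01
  p_expect <- E * 1e6 * h / (1 - nu^2) * (lam - 1) / (lam * r0)
  expect_equal(law$p(law$A0 * lam^2), p_expect, tolerance = 1e-9)
  expect_equal(p_expect, 26840.4, tolerance = 1e-4)
})

test_that("hyperelastic law is the area-derivative of wall strain energy", {
  # energy per unit vessel length: W * (reference wall volume per length)
  for (m in list(ogden(mu = 0.5, alpha = 2), ogden_aorta(), hgo_aorta())) {
    r0 <- 3e-3; h <- 0.3e-3; A0 <- pi * r0^2
    law <- tube_law(m, A0 = A0, h = h)
    psi <- function(A) {
      lam <- sqrt(A / A0)
      2 * pi * r0 * h * 1e6 *
        strain_energy(m, principal_stretches(lam, 1, 1 / lam))
    }
    for (A in A0 * c(0.85, 1.1, 1.44)) {
      dA <- 1e-6 * A0
      p_num <- (psi(A + dA) - psi(A - dA)) / (2 * dA)
      expect_lt(abs(law$p(A) - p_num) / abs(p_num), 1e-6)
    }
  }
})

test_that("tube law construction rejects unstable walls", {
  soft <- mooney_rivlin5(1, 0, -5, 0, 0)
  expect_error(tube_law(soft, A0 = pi * 9e-6, h = 3e-4),
               "unstable.*stretch")
})

test_that("tube law inverse is consistent", {
  law <- tube_law(ogden_aorta(), A0 = pi * 36e-6, h = 6e-4)
  for (p in c(-500, 0, 2666.4, 13332)) {
    expect_equal(law$p(law$area_at(p)), p, tolerance = 1e-6)
  }
})

test_that("thick walls warn and axial stretch is fixed", {
  expect_warning(tube_law(elastic_graft(), A0 = pi * 1e-6, h = 0.9e-3),
                 "thin")
  expect_error(tube_law(elastic_graft(), A0 = pi * 1e-6, h = 1e-4,
                        axial_stretch = 1.1), "axial")
})

test_that("fluid properties validate", {
  f <- fluid_properties()
  expect_equal(f$rho, 1060)
  expect_equal(f$mu, 0.0035)
  expect_error(fluid_properties(-1, 1), "positive")
})
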