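test_that("wall shear stress follows the parabolic closure", {
  r <- 2e-3
  v <- 1                                    # mean velocity 1 m/s
  sol <- fake_solution(Q = v * pi * r^2, r = r)
  w <- wall_shear_stress(sol)
  expect_equal(w$tube[1, 1], 4 * 0.0035 * v / r, tolerance = 1e-12)
  expect_equal(w$tube[1, 1], 7, tolerance = 1e-9)

  sol0 <- fake_solution(Q = 0, r = r)
  expect_true(all(wall_shear_stress(sol0)$tube == 0))

  sol2 <- fake_solution(Q = 2 * v * pi * r^2, r = r)
  expect_equal(wall_shear_stress(sol2)$tube, 2 * w$tube, tolerance = 1e-12)
})

test_that("TAWSS matches closed-form time averages", {
  tt <- seq(0, 1, by = 1e-4)
  expect_equal(tawss(rep(3.2, length(tt)), tt, 1), 3.2, tolerance = 1e-12)
  expect_equal(tawss(sin(2 * pi * tt), tt, 1), 2 / pi, tolerance = 1e-4)
  expect_equal(tawss(numeric(length(tt)), tt, 1), 0)
  # magnitude convention and final-cycle window
  expect_equal(tawss(-rep(1.5, length(tt)), tt, 1), 1.5)
  tt2 <- seq(0, 2, by = 1e-3)
  expect_equal(tawss(c(rep(9, 1000), rep(1, 1001)), tt2, 1), 1,
               tolerance = 1e-6)
  expect_error(tawss(tt, tt, 0.77), "integer number of cycles")
})

test_that("TAWSS of a non-negative series lies between min and max", {
  set.seed(1)
  tt <- seq(0, 0.5, length.out = 400)
  for (i in 1:5) {
    y <- abs(stats::rnorm(400, 2, 1))
    ta <- tawss(y, tt, 0.5)
    expect_gte(ta, min(y)); expect_lte(ta, max(y))
  }
})

test_that("von Mises wall stress is the thin-shell biaxial value", {
  sol <- fake_solution(p = 2666, r = 2e-3, h = 0.35e-3)
  vm <- von_mises_wall_stress(sol)
  st <- 2666 * 2e-3 / 0.35e-3 / 1e3          # sigma_theta in kPa
  expect_equal(st, 15.23, tolerance = 1e-3)
  expect_equal(vm$tube[1, 1], st * sqrt(3) / 2, tolerance = 1e-9)
  expect_equal(vm$tube[1, 1], 13.19, tolerance = 1e-3)

  sol0 <- fake_solution(p = 0)
  expect_true(all(von_mises_wall_stress(sol0)$tube == 0))

  sol_h <- fake_solution(p = 2666, r = 2e-3, h = 0.175e-3)
  expect_equal(von_mises_wall_stress(sol_h)$tube, 2 * vm$tube,
               tolerance = 1e-12)
})

test_that("radial displacement derives from the area change", {
  sol <- fake_solution(r = 2e-3)
  A0 <- sol$network$segments$tube$A0
  sol$A$tube[] <- A0
  expect_true(all(abs(radial_displacement(sol)$tube) < 1e-12))
  sol$A$tube[] <- 4 * A0
  expect_equal(radial_displacement(sol)$tube[1, 1], 2, tolerance = 1e-9)
})

test_that("relative deviation is symmetric and floors at zero", {
  x <- sin(seq(0, 2 * pi, length.out = 50)) + 2
  y <- x * 1.05
  expect_equal(relative_deviation(x, y), relative_deviation(y, x))
  expect_equal(relative_deviation(x, x), 0)
  expect_equal(relative_deviation(numeric(5), numeric(5)), 0)
  expect_error(relative_deviation(x, y[-1]), "lengths differ")
})

test_that("metric report is deterministic and internally consistent", {
  sol <- cached_run("y_junction", {
    solve_pulsatile(y_junction_network(), inlet = steady_waveform(0.05),
                    n_cycles = 12, dx = 5e-3, tol = 1e-10)
  })
  r1 <- metric_report(sol, scenario = "a")
  r2 <- metric_report(sol, scenario = "a")
  expect_identical(r1, r2)
  expect_true(all(r1$tawss_pa <= r1$wss_peak_pa + 1e-12))
  expect_true(all(r1$wss_peak_pa >= 0))
  expect_true(all(r1$vm_peak_kpa >= 0))
  expect_true(all(r1$disp_peak_mm >= 0))
  fake <- sol; fake$converged <- FALSE
  expect_error(metric_report(fake), "converge")
})
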