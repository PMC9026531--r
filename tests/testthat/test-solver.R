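test_that("steady compliant tube reproduces the Hagen-Poiseuille drop", {
  sol <- cached_run("poiseuille", {
    net <- single_tube(material = elastic_graft(), length = 0.05,
                       radius = 1e-3, thickness = 0.2e-3,
                       outlet = list(type = "pressure", p = 1000))
    solve_pulsatile(net, inlet = steady_waveform(0.02), n_cycles = 12,
                    dx = 2.5e-3, tol = 1e-10)
  })
  expect_true(sol$converged)
  nf <- length(sol$time)
  Qs <- sol$Q$tube[nf, ]
  ps <- sol$p$tube[nf, ]
  n <- length(Qs)
  dp_ref <- 8 * sol$fluid$mu * 0.05 * mean(Qs) / (pi * (1e-3)^4)
  expect_lt(abs((ps[1] - ps[n]) - dp_ref) / dp_ref, 0.01)
  # steady mass conservation through the whole tube
  expect_lt(abs(Qs[1] - Qs[n]) / abs(Qs[1]), 1e-6)
  expect_lt(abs(sol$mass_balance$closure_error), 1e-6)
})

test_that("pulse-wave speed matches Moens-Korteweg for an elastic wall", {
  E <- 0.4; nu <- 0.49; r <- 2e-3; h <- 3e-4
  net <- single_tube(material = linear_elastic(E, nu), length = 0.5,
                     radius = r, thickness = h,
                     outlet = list(type = "nonreflecting"))
  wf <- inlet_waveform(period = 1, systole = 0.05, t_peak = 0.02,
                       v_peak = 0.05, v_base = 0)
  sol <- solve_pulsatile(net, inlet = wf, n_cycles = 1, dx = 2.5e-3,
                         out_dt = 5e-4)
  x <- sol$x$tube
  peak_time <- function(i) {
    p <- sol$p$tube[, i]
    k <- which.max(p)
    tt <- sol$time[(k - 1):(k + 1)]
    pp <- p[(k - 1):(k + 1)]
    tt[2] - (pp[3] - pp[1]) / (2 * (pp[3] - 2 * pp[2] + pp[1])) *
      diff(tt)[1]
  }
  i1 <- which.min(abs(x - 0.1)); i2 <- which.min(abs(x - 0.4))
  c_measured <- (x[i2] - x[i1]) / (peak_time(i2) - peak_time(i1))
  c_mk <- sqrt(E * 1e6 * h / (2 * 1060 * r * (1 - nu^2)))
  expect_lt(abs(c_measured - c_mk) / c_mk, 0.03)
})

test_that("junctions conserve mass exactly and split a steady flow", {
  sol <- cached_run("y_junction", {
    solve_pulsatile(y_junction_network(), inlet = steady_waveform(0.05),
                    n_cycles = 12, dx = 5e-3, tol = 1e-10)
  })
  expect_true(sol$converged)
  nf <- length(sol$time)
  qp <- sol$Q$parent[nf, ncol(sol$Q$parent)]
  qc <- sol$Q$c1[nf, 1] + sol$Q$c2[nf, 1]
  expect_lt(abs(qp - qc) / abs(qp), 1e-10)
  # both children carry forward flow; the wider child carries more
  expect_gt(sol$Q$c1[nf, 1], 0)
  expect_gt(sol$Q$c2[nf, 1], 0)
  expect_gt(sol$Q$c1[nf, 1], sol$Q$c2[nf, 1])
  # global steady balance: inflow equals total outflow
  q_in <- sol$Q$parent[nf, 1]
  q_out <- sol$Q$c1[nf, ncol(sol$Q$c1)] + sol$Q$c2[nf, ncol(sol$Q$c2)]
  expect_lt(abs(q_in - q_out) / abs(q_in), 1e-6)
})

test_that("solver runs are deterministic", {
  run <- function() {
    net <- single_tube(material = elastic_graft(), length = 0.05,
                       radius = 1.5e-3, thickness = 0.2e-3,
                       outlet = list(type = "pressure", p = 800))
    solve_pulsatile(net, inlet = inlet_waveform(v_peak = 0.3),
                    n_cycles = 2, dx = 5e-3)
  }
  s1 <- run(); s2 <- run()
  expect_identical(s1$Q, s2$Q)
  expect_identical(s1$A, s2$A)
})

test_that("solution object reports its shape and balance", {
  sol <- cached_run("y_junction", stop("cache miss"))
  expect_s3_class(sol, "flow_solution")
  expect_output(print(sol), "flow_solution")
  s <- summary(sol)
  expect_true(all(c("segment", "p_peak_mmhg") %in% names(s)))
  expect_equal(nrow(s), 3L)
  expect_true(all(vapply(sol$A, function(m) all(m > 0), TRUE)))
})

test_that("shunt flow extraction demands a shunt and convergence", {
  sol <- cached_run("y_junction", stop("cache miss"))
  expect_error(shunt_flow_series(sol), "no shunt")
  fake <- sol
  fake$converged <- FALSE
  expect_error(shunt_flow_series(fake), "converge")
})
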