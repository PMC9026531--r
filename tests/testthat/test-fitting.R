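test_that("noise-free data from a known Yeoh model is recovered in curve space", {
  gen <- yeoh_graft(1)
  d <- generate_tensile(tensile_spec(gen, noise_sd = 0))
  fit <- fit_material(d, "yeoh3")
  expect_true(fit$converged)
  expect_lt(fit$rmse, 1e-8)
  lam <- d$samples$stretch
  expect_lt(max(abs(predict(fit, lam) - uniaxial_stress(gen, lam))), 1e-7)
})

test_that("Yeoh fit of neo-Hookean data collapses to c10 = mu/2", {
  mu <- 0.5
  d <- generate_tensile(tensile_spec(ogden(mu = mu, alpha = 2),
                                     noise_sd = 0))
  fit <- fit_material(d, "yeoh3")
  expect_equal(unname(coef(fit)["c10"]), mu / 2, tolerance = 0.01)
  expect_lt(abs(coef(fit)["c20"]), 1e-4)
  expect_lt(abs(coef(fit)["c30"]), 1e-4)
})

test_that("underdetermined fits are rejected", {
  d2 <- tensile_dataset(c(1, 1.5), c(0, 0.2))
  expect_error(fit_material(d2, "yeoh3"), "8 samples")
  d7 <- tensile_dataset(seq(1, 1.6, length.out = 7),
                        seq(0, 0.3, length.out = 7))
  expect_error(fit_material(d7, "mooney_rivlin5"), "8 samples")
})

test_that("five-parameter Mooney-Rivlin on one uniaxial path is flagged", {
  d <- generate_tensile(tensile_spec(yeoh_graft(1), noise_sd = 0.05,
                                     seed = 11))
  fit <- fit_material(d, "mooney_rivlin5")
  expect_gt(fit$condition_number, fit$cond_threshold)
  expect_true(any(!fit$identifiable))
  # a parsimonious model on the same data stays clean
  fy <- fit_material(d, "yeoh3")
  expect_lt(fy$condition_number, fy$cond_threshold)
  expect_true(all(fy$identifiable))
})

test_that("optimizer residual trace is monotone non-increasing", {
  d <- generate_tensile(tensile_spec(yeoh_graft(2), noise_sd = 0.05,
                                     seed = 3))
  for (m in c("yeoh3", "ogden")) {
    fit <- fit_material(d, m)
    expect_true(all(diff(fit$rss_trace) <= 1e-12))
  }
})

test_that("refitting a fitted curve is idempotent in curve space", {
  d <- generate_tensile(tensile_spec(yeoh_graft(1), noise_sd = 0.05,
                                     seed = 7))
  fit1 <- fit_material(d, "yeoh3")
  d2 <- tensile_dataset(d$samples$stretch, fitted(fit1))
  fit2 <- fit_material(d2, "yeoh3")
  expect_lt(sqrt(mean((fitted(fit2) - fitted(fit1))^2)), 1e-8)
})

test_that("curve recovery under noise stays within twice the noise level", {
  gen <- yeoh_graft(1)
  for (seed in c(1, 2)) {
    d <- generate_tensile(tensile_spec(gen, n = 60, noise_sd = 0.05,
                                       seed = seed))
    fit <- fit_material(d, "yeoh3")
    lam <- d$samples$stretch
    curve_rmse <- sqrt(mean((predict(fit, lam) -
                               uniaxial_stress(gen, lam))^2))
    expect_lt(curve_rmse, 2 * 0.05)
  }
})

test_that("initial modulus recovers a linear law exactly", {
  eps <- seq(0, 0.1, by = 0.01)
  d <- tensile_dataset(1 + eps, 10.3 * eps)
  expect_equal(initial_modulus(d), 10.3, tolerance = 1e-12)
})

test_that("initial modulus approaches 3 mu for an incompressible solid", {
  mu <- 0.4
  lam <- seq(1, 1.01, length.out = 20)
  d <- tensile_dataset(lam, uniaxial_stress(ogden(mu = mu, alpha = 2), lam))
  expect_equal(initial_modulus(d, window = 1.01), 3 * mu, tolerance = 0.01)
  expect_error(initial_modulus(d, window = 1.0004), "at least 3")
})

test_that("ultimate strength finds the planted rupture point", {
  spec <- tensile_spec(yeoh_graft(1), noise_sd = 0,
                       rupture = c(1.7, 13.6), specimen_id = "ruptured")
  d <- generate_tensile(spec)
  us <- ultimate_strength(d)
  expect_equal(us$sigma_y_mpa, 13.6)
  expect_equal(us$stretch_at_failure, 1.7)
  expect_true(us$rupture_detected)

  dm <- generate_tensile(tensile_spec(yeoh_graft(1), noise_sd = 0))
  usm <- ultimate_strength(dm)
  expect_false(usm$rupture_detected)
  expect_equal(usm$sigma_y_mpa,
               max(dm$samples$stress_mpa))

  dz <- tensile_dataset(c(1, 1.2, 1.4), c(0, 0, 0))
  expect_warning(uz <- ultimate_strength(dz), "zero")
  expect_equal(uz$sigma_y_mpa, 0)
})

test_that("fit report compares models on a shared dataset", {
  d <- generate_tensile(tensile_spec(yeoh_graft(1), noise_sd = 0.05,
                                     seed = 5))
  fits <- list(fit_material(d, "yeoh3"), fit_material(d, "mooney_rivlin5"))
  rep <- fit_report(fits, d)
  expect_s3_class(rep, "fit_report")
  expect_equal(nrow(rep), 2L)
  expect_true(rep$n_weak_par[rep$model == "mooney_rivlin5"] > 0)

  other <- generate_tensile(tensile_spec(yeoh_graft(2), noise_sd = 0))
  fits2 <- list(fits[[1]], fit_material(other, "yeoh3"))
  expect_error(fit_report(fits2), "different datasets")
  expect_error(fit_report(list()), "empty")
})

test_that("fit methods behave like a classed model object", {
  d <- generate_tensile(tensile_spec(yeoh_graft(1), noise_sd = 0.02,
                                     seed = 9))
  fit <- fit_material(d, "yeoh3")
  expect_named(coef(fit), c("c10", "c20", "c30"))
  expect_length(residuals(fit), nrow(d$samples))
  expect_equal(fitted(fit) + residuals(fit), d$samples$stress_mpa,
               tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit))
  expect_output(print(fit), "tensile_fit")
  expect_output(print(summary(fit)), "small-strain modulus")
  grDevices::pdf(NULL)
  plot(fit)
  plot(fit_report(list(fit), d))
  grDevices::dev.off()
  expect_s3_class(fit$material, "yeoh3")
})
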