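#' Fit a hyperelastic model to a uniaxial tensile dataset
#'
#' Estimates constitutive constants by bounded nonlinear least squares in
#' stress space: the objective is the sum of squared differences between the
#' analytic nominal stress \code{P(lambda; theta)} and the observed stresses.
#' Optimization uses Levenberg-Marquardt (\code{minpack.lm::nls.lm}) from
#' multiple Latin-hypercube starting points over the parameter bounds, and
#' returns the best converged start.
#'
#' Identifiability is reported, not enforced: the five-parameter
#' Mooney-Rivlin family is rank-deficient on a single uniaxial path, so the
#' fit is assessed in curve space (RMSE of the fitted stress curve), and the
#' condition number of the model Jacobian at the solution drives
#' per-parameter identifiability flags.
#'
#' @param data a \code{\link{tensile_dataset}} with at least 8 samples.
#' @param model model tag: \code{"yeoh3"}, \code{"mooney_rivlin5"},
#'   \code{"ogden"} or \code{"hgo"}.
#' @param n_starts number of Latin-hypercube starts (a deterministic
#'   mid-range start is always added).
#' @param seed RNG seed for the start design.
#' @param n_terms number of Ogden terms (1-3), used when
#'   \code{model = "ogden"}.
#' @param beta fixed HGO fiber-family angles (radians), used when
#'   \code{model = "hgo"}.
#' @param bounds optional named list \code{list(lower =, upper =)} replacing
#'   the default parameter bounds.
#' @param cond_threshold Jacobian condition number above which
#'   identifiability flags are raised.
#' @param control passed to \code{minpack.lm::nls.lm.control}.
#' @return object of class \code{"tensile_fit"} with components
#'   \code{material} (the fitted \code{\link{materials}} object),
#'   \code{par}, \code{rmse}, \code{r_squared}, \code{condition_number},
#'   \code{identifiable} (named logical), \code{converged},
#'   \code{rss_trace}, \code{data}, and methods \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{plot}.
#' @examples
#' gen <- yeoh3(0.11, -4.96e-6, 1.67e-10)
#' d <- generate_tensile(tensile_spec(gen, noise_sd = 0))
#' fit <- fit_material(d, "yeoh3")
#' coef(fit)
#' @export
fit_material <- function(data, model = c("yeoh3", "mooney_rivlin5", "ogden",
                                         "hgo"),
                         n_starts = 16, seed = 20220407, n_terms = 2,
                         beta = c(pi / 4, -pi / 4), bounds = NULL,
                         cond_threshold = 30, control = NULL) {
  model <- match.arg(model)
  if (!inherits(data, "tensile_dataset")) stop("data must be a tensile_dataset")
  lam <- data$samples$stretch
  obs <- data$samples$stress_mpa
  spec <- fit_parameterization(model, n_terms = n_terms, beta = beta)
  if (!is.null(bounds)) {
    spec$lower <- bounds$lower; spec$upper <- bounds$upper
  }
  p <- length(spec$lower)
  if (length(lam) < 8L)
    stop("fit_material: at least 8 samples are required")
  if (length(lam) < p)
    stop("fit_material: fewer samples than parameters (", length(lam),
         " < ", p, ")")

  resid_fn <- function(theta) spec$stress(theta, lam) - obs

  starts <- rbind((spec$lower + spec$upper) / 2,
                  fit_start_design(n_starts, spec$lower, spec$upper, seed))
  ctrl <- do.call(minpack.lm::nls.lm.control,
                  c(list(maxiter = 200), control))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = spec$lower, upper = spec$upper,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best))
    stop("fit_material: no start converged; check data and bounds")

  theta <- best$par
  names(theta) <- spec$names
  pred <- spec$stress(theta, lam)
  rss <- sum((pred - obs)^2)
  rmse <- sqrt(rss / length(obs))
  tss <- sum((obs - mean(obs))^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_

  # collinearity diagnostic: condition number of the column-normalized
  # Jacobian (condition index); parameters whose column is numerically zero
  # have no effect on the curve and are flagged outright
  J <- numeric_jacobian(function(th) spec$stress(th, lam), theta)
  norms <- sqrt(colSums(J^2))
  ident <- rep(TRUE, p)
  names(ident) <- spec$names
  dead <- norms <= max(norms) * 1e-14
  ident[dead] <- FALSE
  Jn <- J[, !dead, drop = FALSE]
  Jn <- sweep(Jn, 2, norms[!dead], "/")
  dec <- svd(Jn)
  sv <- dec$d
  cond <- if (any(dead)) Inf
          else if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (max(sv) / min(sv[sv > 0]) > cond_threshold) {
    live <- which(!dead)
    weak <- which(sv < max(sv) / cond_threshold)
    for (k in weak) ident[live[abs(dec$v[, k]) > 1 / sqrt(p)]] <- FALSE
    if (all(ident)) ident[live[which.max(abs(dec$v[, length(sv)]))]] <- FALSE
  }

  structure(list(
    model = model, par = theta,
    material = spec$build(theta),
    rmse = rmse, r_squared = r2, condition_number = cond,
    identifiable = ident, converged = best$info %in% 1:4,
    optim_info = best$info, rss_trace = best$rsstrace,
    cond_threshold = cond_threshold, data = data,
    stress_fn = function(l) spec$stress(theta, l)),
    class = "tensile_fit")
}

# parameterization table: names, bounds, stress evaluator, material builder
fit_parameterization <- function(model, n_terms = 2,
                                 beta = c(pi / 4, -pi / 4)) {
  switch(model,
    yeoh3 = list(
      names = c("c10", "c20", "c30"),
      lower = c(1e-6, -10, -10), upper = c(10, 10, 10),
      stress = function(th, l)
        (th[1] + 2 * th[2] * (l^2 + 2 / l - 3) +
           3 * th[3] * (l^2 + 2 / l - 3)^2) * (2 * l - 2 / l^2),
      build = function(th) yeoh3(th[1], th[2], th[3])),
    mooney_rivlin5 = list(
      names = c("c10", "c01", "c20", "c11", "c02"),
      lower = rep(-10, 5), upper = rep(10, 5),
      stress = function(th, l) {
        x <- l^2 + 2 / l - 3; y <- 2 * l + 1 / l^2 - 3
        (th[1] + 2 * th[3] * x + th[4] * y) * (2 * l - 2 / l^2) +
          (th[2] + th[4] * x + 2 * th[5] * y) * (2 - 2 / l^3)
      },
      build = function(th) mooney_rivlin5(th[1], th[2], th[3], th[4], th[5])),
    ogden = {
      n <- as.integer(n_terms)
      stopifnot(n >= 1L, n <= 3L)
      list(
        names = c(paste0("mu", seq_len(n)), paste0("alpha", seq_len(n))),
        lower = c(rep(-10, n), rep(-30, n)),
        upper = c(rep(10, n), rep(30, n)),
        stress = function(th, l) {
          out <- 0
          for (p in seq_len(n))
            out <- out + th[p] * (l^(th[n + p] - 1) - l^(-th[n + p] / 2 - 1))
          out
        },
        build = function(th) {
          mu <- th[seq_len(n)]; al <- th[n + seq_len(n)]
          tryCatch(ogden(mu, al), error = function(e) {
            warning("fitted Ogden parameters violate the shear-modulus ",
                    "constraint; returning them unvalidated")
            new_material("ogden", list(mu = unname(mu), alpha = unname(al)))
          })
        })
    },
    hgo = list(
      names = c("c10", "k1", "k2", "kappa"),
      lower = c(1e-6, 0, 1e-6, 0), upper = c(10, 10, 100, 1 / 3),
      stress = function(th, l)
        uniaxial_nominal(hgo(th[1], max(th[2], 0), th[3],
                             min(max(th[4], 0), 1 / 3), beta = beta), l),
      build = function(th) hgo(th[1], max(th[2], 0), th[3],
                               min(max(th[4], 0), 1 / 3), beta = beta)),
    stop("unknown model tag: ", model))
}

fit_start_design <- function(n_starts, lower, upper, seed) {
  p <- length(lower)
  u <- with_preserved_seed(seed, lhs::randomLHS(n_starts, p))
  sweep(sweep(u, 2, upper - lower, "*"), 2, lower, "+")
}

# run code under a fixed seed without disturbing the caller's RNG stream
with_preserved_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

numeric_jacobian <- function(f, x, h = 1e-6) {
  f0 <- f(x)
  J <- matrix(0, length(f0), length(x))
  for (j in seq_along(x)) {
    hj <- h * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + hj
    xm <- x; xm[j] <- x[j] - hj
    J[, j] <- (f(xp) - f(xm)) / (2 * hj)
  }
  J
}

#' @export
print.tensile_fit <- function(x, ...) {
  cat("<tensile_fit>", x$model, "on", x$data$specimen_id, "\n")
  cat("  parameters (MPa / dimensionless):\n")
  print(signif(x$par, 6))
  cat(sprintf("  RMSE = %.4g MPa, R^2 = %.6f, cond(J) = %.3g\n",
              x$rmse, x$r_squared, x$condition_number))
  if (!all(x$identifiable))
    cat("  note: weakly identified parameters:",
        paste(names(x$identifiable)[!x$identifiable], collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.tensile_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.tensile_fit")
}

#' @export
print.summary.tensile_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("  converged:", f$converged, "(nls.lm info", f$optim_info, ")\n")
  cat("  objective trace length:", length(f$rss_trace), "\n")
  E <- tryCatch(3 * small_strain_shear_modulus(f$material),
                error = function(e) NA_real_)
  cat(sprintf("  implied small-strain modulus E = %.4g MPa\n", E))
  invisible(x)
}

#' @export
coef.tensile_fit <- function(object, ...) object$par

#' @export
fitted.tensile_fit <- function(object, ...)
  object$stress_fn(object$data$samples$stretch)

#' @export
residuals.tensile_fit <- function(object, ...)
  object$data$samples$stress_mpa - fitted(object)

#' @export
predict.tensile_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$data$samples$stretch
         else if (is.list(newdata)) newdata$stretch else as.numeric(newdata)
  object$stress_fn(lam)
}

#' @export
plot.tensile_fit <- function(x, ...) {
  s <- x$data$samples
  lam <- seq(min(s$stretch), max(s$stretch), length.out = 200)
  graphics::plot(s$stretch, s$stress_mpa, pch = 1, col = "grey30",
                 xlab = "stretch (-)", ylab = "nominal stress (MPa)",
                 main = paste(x$model, "fit:", x$data$specimen_id), ...)
  graphics::lines(lam, x$stress_fn(lam), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Side-by-side comparison of fits on one dataset
#'
#' @param results list of \code{\link{fit_material}} results fitted on the
#'   same dataset.
#' @param data the shared \code{\link{tensile_dataset}} (defaults to the
#'   dataset of the first result).
#' @return data.frame of class \code{"fit_report"} with one row per model:
#'   RMSE, R^2, condition number, identifiability summary.
#' @export
fit_report <- function(results, data = NULL) {
  if (length(results) == 0L) stop("fit_report: empty result list")
  if (is.null(data)) data <- results[[1]]$data
  for (r in results) {
    if (!inherits(r, "tensile_fit")) stop("all results must be tensile_fit")
    if (!identical(r$data$samples, data$samples))
      stop("fit_report: results were fitted on different datasets")
  }
  out <- data.frame(
    model = vapply(results, function(r) r$model, ""),
    n_par = vapply(results, function(r) length(r$par), 0L),
    rmse_mpa = vapply(results, function(r) r$rmse, 0),
    r_squared = vapply(results, function(r) r$r_squared, 0),
    condition_number = vapply(results, function(r) r$condition_number, 0),
    n_weak_par = vapply(results, function(r) sum(!r$identifiable), 0L))
  attr(out, "fits") <- results
  attr(out, "data") <- data
  class(out) <- c("fit_report", "data.frame")
  out
}

#' @export
plot.fit_report <- function(x, ...) {
  data <- attr(x, "data"); fits <- attr(x, "fits")
  s <- data$samples
  lam <- seq(min(s$stretch), max(s$stretch), length.out = 200)
  graphics::plot(s$stretch, s$stress_mpa, pch = 1, col = "grey30",
                 xlab = "stretch (-)", ylab = "nominal stress (MPa)",
                 main = paste("fits:", data$specimen_id), ...)
  cols <- grDevices::hcl.colors(length(fits), "Dark 3")
  for (i in seq_along(fits))
    graphics::lines(lam, fits[[i]]$stress_fn(lam), col = cols[i], lwd = 2)
  graphics::legend("topleft", legend = x$model, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
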