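#' Hyperelastic and linear-elastic wall materials
#'
#' Constructors for the constitutive models used for vascular grafts and the
#' aortic wall: the five-parameter Mooney-Rivlin model, the three-parameter
#' Yeoh model, the Ogden model in principal stretches, the
#' Holzapfel-Gasser-Ogden (HGO) model with dispersed collagen fiber families,
#' and an isotropic linear-elastic reference. All materials are treated as
#' incompressible (J = 1); the Mooney-Rivlin volumetric penalty coefficient
#' \code{d1} is carried in the parameter record but never evaluated.
#'
#' Units are MPa for all stress-like constants; stretches are dimensionless.
#'
#' @param c10,c01,c20,c11,c02 Mooney-Rivlin coefficients (MPa). Signs are
#'   unconstrained: fits of expanded-PTFE graft data can legitimately return
#'   negative \code{c10} (material stability is then a diagnostic, see
#'   \code{\link{drucker_stability_report}}).
#' @param d1 volumetric penalty coefficient (MPa^-1); stored, not used.
#' @param c20,c30 higher-order Yeoh coefficients (MPa); in the Yeoh model
#'   these multiply (I1bar-3)^2 and (I1bar-3)^3.
#' @param mu,alpha equal-length numeric vectors of Ogden coefficients
#'   (mu_p in MPa, alpha_p dimensionless), 1 to 3 terms. The effective
#'   small-strain shear modulus (1/2) * sum(mu_p * alpha_p) must be positive.
#' @param k1 HGO fiber stiffness (MPa), >= 0.
#' @param k2 HGO fiber exponent (dimensionless), > 0.
#' @param kappa HGO dispersion parameter in [0, 1/3]; 0 = perfectly aligned
#'   fibers, 1/3 = isotropic (randomly dispersed) fibers.
#' @param beta fiber-family mean angles (radians) measured from the
#'   circumferential axis in the wall tangent plane; default two symmetric
#'   families at +/- 45 degrees. At most 3 families.
#' @param convention coefficient convention for the fiber strain measure:
#'   \code{"standard"} uses kappa*(I1bar-3) + (1-3*kappa)*(I4bar-1) so that
#'   kappa = 1/3 is exactly isotropic; \code{"plus"} uses the alternative
#'   (1+3*kappa) coefficient. Default \code{"standard"}.
#' @param E Young modulus (MPa), > 0.
#' @param nu Poisson ratio, in [0, 0.5).
#'
#' @return An object of class \code{c("<model tag>", "material")} with the
#'   parameters as fields and a \code{model} tag, one of
#'   \code{"mooney_rivlin5"}, \code{"yeoh3"}, \code{"ogden"}, \code{"hgo"},
#'   \code{"linear_elastic"}.
#'
#' @examples
#' graft <- yeoh3(c10 = 0.11, c20 = -4.96e-6, c30 = 1.67e-10)
#' uniaxial_stress(graft, lambda = 1.5)
#' aorta <- ogden(mu = c(1.274, -1.211), alpha = c(24.074, 24.073))
#' small_strain_shear_modulus(aorta)
#' @name materials
NULL

new_material <- function(tag, fields) {
  structure(c(fields, list(model = tag)), class = c(tag, "material"))
}

#' @rdname materials
#' @export
mooney_rivlin5 <- function(c10, c01, c20, c11, c02, d1 = 0) {
  stopifnot(is.numeric(c10), is.numeric(c01), is.numeric(c20),
            is.numeric(c11), is.numeric(c02))
  new_material("mooney_rivlin5",
               list(c10 = c10, c01 = c01, c20 = c20, c11 = c11,
                    c02 = c02, d1 = d1))
}

#' @rdname materials
#' @export
yeoh3 <- function(c10, c20, c30) {
  if (!is.numeric(c10) || c10 <= 0)
    stop("yeoh3: c10 must be positive (shear modulus 2*c10 > 0)")
  new_material("yeoh3", list(c10 = c10, c20 = c20, c30 = c30))
}

#' @rdname materials
#' @export
ogden <- function(mu, alpha) {
  if (length(mu) != length(alpha) || length(mu) < 1L || length(mu) > 3L)
    stop("ogden: mu and alpha must be equal-length vectors of 1 to 3 terms")
  if (any(alpha == 0)) stop("ogden: alpha_p must be nonzero")
  if (sum(mu * alpha) / 2 <= 0)
    stop("ogden: effective shear modulus (1/2)*sum(mu_p*alpha_p) must be > 0")
  new_material("ogden", list(mu = as.numeric(mu), alpha = as.numeric(alpha)))
}

#' @rdname materials
#' @export
hgo <- function(c10, k1, k2, kappa, beta = c(pi / 4, -pi / 4),
                convention = c("standard", "plus")) {
  convention <- match.arg(convention)
  if (c10 <= 0) stop("hgo: c10 must be positive")
  if (k1 < 0) stop("hgo: k1 must be >= 0")
  if (k2 <= 0) stop("hgo: k2 must be positive")
  if (kappa < 0 || kappa > 1 / 3)
    stop("hgo: dispersion kappa must lie in [0, 1/3]")
  if (length(beta) < 1L || length(beta) > 3L)
    stop("hgo: at most 3 fiber families")
  new_material("hgo", list(c10 = c10, k1 = k1, k2 = k2, kappa = kappa,
                           beta = as.numeric(beta), convention = convention))
}

#' @rdname materials
#' @export
linear_elastic <- function(E, nu) {
  if (E <= 0) stop("linear_elastic: E must be positive")
  if (nu < 0 || nu >= 0.5) stop("linear_elastic: nu must lie in [0, 0.5)")
  new_material("linear_elastic", list(E = E, nu = nu))
}

#' @export
print.material <- function(x, ...) {
  cat("<material:", x$model, ">\n")
  pars <- x[setdiff(names(x), c("model", "convention"))]
  for (nm in names(pars))
    cat(" ", nm, "=", paste(signif(pars[[nm]], 6), collapse = ", "), "\n")
  if (!is.null(x$convention))
    cat("  fiber-strain convention:", x$convention, "\n")
  invisible(x)
}

# ---- deformation state ------------------------------------------------------

#' Principal stretches of an incompressible deformation
#'
#' @param lambda1,lambda2,lambda3 principal stretch ratios, all > 0. If
#'   \code{lambda3} is omitted it is set to 1/(lambda1*lambda2) so the
#'   deformation is isochoric by construction.
#' @param tol tolerance on |lambda1*lambda2*lambda3 - 1|.
#' @return numeric vector of length 3 with class \code{"principal_stretches"}.
#' @export
principal_stretches <- function(lambda1, lambda2,
                                lambda3 = 1 / (lambda1 * lambda2),
                                tol = 1e-12) {
  l <- c(lambda1, lambda2, lambda3)
  if (any(!is.finite(l)) || any(l <= 0))
    stop("principal stretches must be finite and strictly positive")
  if (abs(prod(l) - 1) > tol)
    stop(sprintf("incompressibility violated: lambda1*lambda2*lambda3 = %.15g",
                 prod(l)))
  structure(l, class = "principal_stretches")
}

#' Incompressible uniaxial deformation state
#'
#' Loading along axis 1 with stress-free lateral contraction:
#' lambda2 = lambda3 = lambda^(-1/2).
#'
#' @param lambda axial stretch, > 0.
#' @return a \code{\link{principal_stretches}} object.
#' @export
uniaxial_stretches <- function(lambda) {
  if (any(lambda <= 0)) stop("lambda must be positive")
  principal_stretches(lambda, 1 / sqrt(lambda), 1 / sqrt(lambda))
}

#' Deviatoric invariants and fiber pseudo-invariants
#'
#' Computes the isochoric invariants I1bar, I2bar, I3bar of the right
#' Cauchy-Green tensor from principal stretches, and the squared fiber
#' stretch I4 for each fiber family lying in the 1-2 plane at angle beta to
#' axis 1 (the loading axis).
#'
#' @param stretches a \code{\link{principal_stretches}} object (or a positive
#'   length-3 numeric with unit product).
#' @param fiber_angles numeric vector of fiber angles (radians) from axis 1;
#'   may be empty.
#' @return list with fields \code{I1bar}, \code{I2bar}, \code{I3bar} and
#'   \code{I4} (numeric vector, one entry per fiber family).
#' @export
invariants_from_stretches <- function(stretches, fiber_angles = numeric()) {
  if (!inherits(stretches, "principal_stretches"))
    stretches <- principal_stretches(stretches[1], stretches[2], stretches[3])
  l <- unclass(stretches)
  l2 <- l^2
  I1 <- sum(l2)
  I2 <- l2[1] * l2[2] + l2[2] * l2[3] + l2[1] * l2[3]
  I3 <- prod(l2)
  I4 <- l2[1] * cos(fiber_angles)^2 + l2[2] * sin(fiber_angles)^2
  list(I1bar = I1, I2bar = I2, I3bar = I3, I4 = I4)
}

# ---- strain energy ----------------------------------------------------------

#' Strain energy density
#'
#' Evaluates the strain energy density W (MPa, energy per unit reference
#' volume) of a material at an incompressible deformation state. For the HGO
#' model the fiber families stored in the material are used, with axis 1 the
#' loading axis and axis 2 the transverse in-plane axis; the fiber term is
#' tension-only (Macaulay bracket on the fiber strain).
#'
#' @param model a \code{\link{materials}} object.
#' @param state a \code{\link{principal_stretches}} object.
#' @return scalar W in MPa; exactly 0 at the identity deformation.
#' @export
strain_energy <- function(model, state) UseMethod("strain_energy")

#' @export
strain_energy.default <- function(model, state)
  stop("unknown material model: ", paste(class(model), collapse = "/"))

#' @export
strain_energy.mooney_rivlin5 <- function(model, state) {
  iv <- invariants_from_stretches(state)
  x <- iv$I1bar - 3; y <- iv$I2bar - 3
  model$c10 * x + model$c01 * y + model$c20 * x^2 + model$c11 * x * y +
    model$c02 * y^2
}

#' @export
strain_energy.yeoh3 <- function(model, state) {
  x <- invariants_from_stretches(state)$I1bar - 3
  model$c10 * x + model$c20 * x^2 + model$c30 * x^3
}

#' @export
strain_energy.ogden <- function(model, state) {
  l <- unclass(if (inherits(state, "principal_stretches")) state
               else principal_stretches(state[1], state[2], state[3]))
  sum(model$mu / model$alpha *
        (l[1]^model$alpha + l[2]^model$alpha + l[3]^model$alpha - 3))
}

#' @export
strain_energy.hgo <- function(model, state) {
  iv <- invariants_from_stretches(state, fiber_angles = model$beta)
  w <- model$c10 * (iv$I1bar - 3)
  for (a in seq_along(model$beta)) {
    e <- hgo_fiber_strain_value(model, iv$I1bar, iv$I4[a])
    ep <- max(e, 0)
    w <- w + model$k1 / (2 * model$k2) * (exp(model$k2 * ep^2) - 1)
  }
  w
}

#' @export
strain_energy.linear_elastic <- function(model, state) {
  # small-strain quadratic form in principal engineering strains, isochoric
  l <- unclass(if (inherits(state, "principal_stretches")) state
               else principal_stretches(state[1], state[2], state[3]))
  eps <- l - 1
  mu <- model$E / (2 * (1 + model$nu))
  mu * sum(eps^2)
}

# fiber strain measure before Macaulay bracketing
hgo_fiber_strain_value <- function(model, I1bar, I4) {
  coef4 <- if (identical(model$convention, "plus")) 1 + 3 * model$kappa
           else 1 - 3 * model$kappa
  model$kappa * (I1bar - 3) + coef4 * (I4 - 1)
}

#' HGO fiber strain measure
#'
#' Returns the fiber strain measure E_alpha of the HGO model (before the
#' tension-only Macaulay bracket): kappa*(I1bar - 3) + (1 - 3*kappa)*(I4 - 1)
#' under the default convention. At kappa = 1/3 the I4 coefficient vanishes
#' and the response is direction-independent (isotropy limit).
#'
#' @param model an \code{\link{hgo}} material.
#' @param invariants output of \code{\link{invariants_from_stretches}} with
#'   one I4 entry per fiber family of the model.
#' @param family fiber family index.
#' @return scalar fiber strain (dimensionless).
#' @export
hgo_fiber_strain <- function(model, invariants, family = 1L) {
  if (!inherits(model, "hgo")) stop("model must be an hgo material")
  if (family < 1L || family > length(invariants$I4))
    stop("fiber family index out of range")
  hgo_fiber_strain_value(model, invariants$I1bar, invariants$I4[family])
}

# ---- uniaxial stress --------------------------------------------------------

#' Uniaxial nominal (first Piola-Kirchhoff) stress
#'
#' Analytic stress along the incompressible uniaxial extension path
#' (lambda, lambda^-1/2, lambda^-1/2), with the transverse stress-free
#' condition eliminated in closed form: P(lambda) = dW/dlambda along the
#' path. P(1) = 0 for every model.
#'
#' @param model a \code{\link{materials}} object.
#' @param lambda axial stretch, vectorized, > 0.
#' @param type \code{"nominal"} (force per undeformed area, the tensile
#'   machine convention) or \code{"cauchy"} (= lambda * nominal under
#'   incompressibility).
#' @return numeric vector of stresses (MPa).
#' @export
uniaxial_stress <- function(model, lambda, type = c("nominal", "cauchy")) {
  type <- match.arg(type)
  if (any(lambda <= 0)) stop("lambda must be positive")
  P <- uniaxial_nominal(model, lambda)
  if (type == "cauchy") lambda * P else P
}

uniaxial_nominal <- function(model, lambda) UseMethod("uniaxial_nominal")

#' @export
uniaxial_nominal.default <- function(model, lambda)
  stop("unknown material model: ", paste(class(model), collapse = "/"))

# uniaxial invariants: I1 = l^2 + 2/l, I2 = 2l + 1/l^2
#' @export
uniaxial_nominal.mooney_rivlin5 <- function(model, lambda) {
  l <- lambda
  x <- l^2 + 2 / l - 3
  y <- 2 * l + 1 / l^2 - 3
  W1 <- model$c10 + 2 * model$c20 * x + model$c11 * y
  W2 <- model$c01 + model$c11 * x + 2 * model$c02 * y
  W1 * (2 * l - 2 / l^2) + W2 * (2 - 2 / l^3)
}

#' @export
uniaxial_nominal.yeoh3 <- function(model, lambda) {
  l <- lambda
  x <- l^2 + 2 / l - 3
  (model$c10 + 2 * model$c20 * x + 3 * model$c30 * x^2) * (2 * l - 2 / l^2)
}

#' @export
uniaxial_nominal.ogden <- function(model, lambda) {
  out <- 0
  for (p in seq_along(model$mu))
    out <- out + model$mu[p] *
      (lambda^(model$alpha[p] - 1) - lambda^(-model$alpha[p] / 2 - 1))
  out
}

#' @export
uniaxial_nominal.hgo <- function(model, lambda) {
  l <- lambda
  P <- model$c10 * (2 * l - 2 / l^2)
  coef4 <- if (identical(model$convention, "plus")) 1 + 3 * model$kappa
           else 1 - 3 * model$kappa
  I1 <- l^2 + 2 / l
  dI1 <- 2 * l - 2 / l^2
  for (b in model$beta) {
    I4 <- l^2 * cos(b)^2 + sin(b)^2 / l
    dI4 <- 2 * l * cos(b)^2 - sin(b)^2 / l^2
    e <- model$kappa * (I1 - 3) + coef4 * (I4 - 1)
    de <- model$kappa * dI1 + coef4 * dI4
    ep <- pmax(e, 0)
    P <- P + model$k1 * exp(model$k2 * ep^2) * ep * de
  }
  P
}

#' @export
uniaxial_nominal.linear_elastic <- function(model, lambda) {
  model$E * (lambda - 1)
}

#' Small-strain shear modulus
#'
#' Analytic shear modulus mu of the linearized material: Ogden
#' mu = (1/2) * sum(mu_p * alpha_p); Mooney-Rivlin 2*(c10 + c01); Yeoh
#' 2*c10; HGO 2*c10 plus the tension-side fiber contribution (the fiber term
#' is tension-only, so the linearized uniaxial tangent is one-sided at
#' lambda = 1); linear elastic E/(2(1+nu)). Consistent with the numerical
#' uniaxial tangent via E = 3*mu for the incompressible models.
#'
#' @param model a \code{\link{materials}} object.
#' @return shear modulus (MPa).
#' @export
small_strain_shear_modulus <- function(model)
  UseMethod("small_strain_shear_modulus")

#' @export
small_strain_shear_modulus.mooney_rivlin5 <- function(model)
  2 * (model$c10 + model$c01)

#' @export
small_strain_shear_modulus.yeoh3 <- function(model) 2 * model$c10

#' @export
small_strain_shear_modulus.ogden <- function(model)
  sum(model$mu * model$alpha) / 2

#' @export
small_strain_shear_modulus.hgo <- function(model) {
  # tension-side Young modulus: 6*c10 from the ground matrix plus
  # k1 * g^2 per fiber family active in tension, g = dE_alpha/dlambda at 1
  coef4 <- if (identical(model$convention, "plus")) 1 + 3 * model$kappa
           else 1 - 3 * model$kappa
  g <- coef4 * (2 * cos(model$beta)^2 - sin(model$beta)^2)
  E <- 6 * model$c10 + model$k1 * sum(ifelse(g > 0, g^2, 0))
  E / 3
}

#' @export
small_strain_shear_modulus.linear_elastic <- function(model)
  model$E / (2 * (1 + model$nu))

#' Numerical uniaxial tangent modulus dP/dlambda
#'
#' Second-order one-sided (tension-side) finite difference of the analytic
#' nominal stress; one-sided because the HGO fiber term makes the tangent
#' discontinuous at lambda = 1.
#'
#' @param model a \code{\link{materials}} object.
#' @param lambda evaluation stretch(es).
#' @param h step size.
#' @return numeric tangent (MPa).
#' @export
uniaxial_tangent <- function(model, lambda, h = 1e-5) {
  (-3 * uniaxial_nominal(model, lambda) +
     4 * uniaxial_nominal(model, lambda + h) -
     uniaxial_nominal(model, lambda + 2 * h)) / (2 * h)
}

#' Drucker-stability diagnostic over a stretch window
#'
#' Flags stretches at which the uniaxial tangent modulus dP/dlambda is
#' non-positive. Fitted graft constants can include negative Mooney-Rivlin
#' coefficients, so material stability over the working stretch range is
#' reported as a diagnostic rather than enforced at construction. Never
#' raises an error.
#'
#' @param model a \code{\link{materials}} object.
#' @param lower,upper stretch window bounds, 0 < lower < upper.
#' @param n number of evaluation points.
#' @return data.frame with columns \code{lambda}, \code{tangent_mpa},
#'   \code{stable}; attribute \code{all_stable}.
#' @export
drucker_stability_report <- function(model, lower = 0.8, upper = 2, n = 101) {
  if (lower <= 0 || upper <= lower)
    stop("window must satisfy 0 < lower < upper")
  lam <- seq(lower, upper, length.out = n)
  tg <- uniaxial_tangent(model, lam)
  out <- data.frame(lambda = lam, tangent_mpa = tg, stable = tg > 0)
  attr(out, "all_stable") <- all(out$stable)
  out
}

# ---- circumferential wall response (used by tube laws) ----------------------

# dW/dlambda_theta and d2W/dlambda_theta^2 (MPa) along the plane-stress,
# incompressible, fixed-axial-stretch path (lambda_theta, 1, 1/lambda_theta).
# With lambda_z = 1 the isochoric invariants coincide: I1 = I2 = s,
# s = l^2 + 1/l^2 + 1.
wall_energy_derivs <- function(model, lam) UseMethod("wall_energy_derivs")

#' @export
wall_energy_derivs.mooney_rivlin5 <- function(model, lam) {
  s <- lam^2 + 1 / lam^2 + 1
  sp <- 2 * lam - 2 / lam^3
  spp <- 2 + 6 / lam^4
  f1 <- (model$c10 + model$c01) +
    2 * (model$c20 + model$c11 + model$c02) * (s - 3)
  f2 <- 2 * (model$c20 + model$c11 + model$c02)
  list(d1 = f1 * sp, d2 = f2 * sp^2 + f1 * spp)
}

#' @export
wall_energy_derivs.yeoh3 <- function(model, lam) {
  s <- lam^2 + 1 / lam^2 + 1
  sp <- 2 * lam - 2 / lam^3
  spp <- 2 + 6 / lam^4
  f1 <- model$c10 + 2 * model$c20 * (s - 3) + 3 * model$c30 * (s - 3)^2
  f2 <- 2 * model$c20 + 6 * model$c30 * (s - 3)
  list(d1 = f1 * sp, d2 = f2 * sp^2 + f1 * spp)
}

#' @export
wall_energy_derivs.ogden <- function(model, lam) {
  d1 <- 0; d2 <- 0
  for (p in seq_along(model$mu)) {
    a <- model$alpha[p]; m <- model$mu[p]
    d1 <- d1 + m * (lam^(a - 1) - lam^(-a - 1))
    d2 <- d2 + m * ((a - 1) * lam^(a - 2) + (a + 1) * lam^(-a - 2))
  }
  list(d1 = d1, d2 = d2)
}

#' @export
wall_energy_derivs.hgo <- function(model, lam) {
  s <- lam^2 + 1 / lam^2 + 1
  sp <- 2 * lam - 2 / lam^3
  spp <- 2 + 6 / lam^4
  d1 <- model$c10 * sp
  d2 <- model$c10 * spp
  coef4 <- if (identical(model$convention, "plus")) 1 + 3 * model$kappa
           else 1 - 3 * model$kappa
  for (b in model$beta) {
    # fibers measured from the circumferential direction; lambda_z = 1
    I4 <- lam^2 * cos(b)^2 + sin(b)^2
    dI4 <- 2 * lam * cos(b)^2
    e <- model$kappa * (s - 3) + coef4 * (I4 - 1)
    de <- model$kappa * sp + coef4 * dI4
    dde <- model$kappa * spp + coef4 * 2 * cos(b)^2
    ep <- pmax(e, 0)
    act <- as.numeric(e > 0)
    ex <- exp(model$k2 * ep^2)
    d1 <- d1 + model$k1 * ex * ep * de
    d2 <- d2 + act * model$k1 * ex *
      ((2 * model$k2 * ep^2 + 1) * de^2 + ep * dde)
  }
  list(d1 = d1, d2 = d2)
}

# ---- serialization ----------------------------------------------------------

#' Serialize / deserialize material parameter blocks
#'
#' Materials are exchanged as flat key-value blocks with a \code{model} tag.
#' Units in files are MPa and degrees (HGO fiber angles as \code{beta_deg}).
#'
#' @param model a \code{\link{materials}} object.
#' @param config a named list as produced by \code{material_to_config} or
#'   read from a YAML configuration.
#' @return \code{material_to_config}: named list; \code{material_from_config}:
#'   a material object.
#' @export
material_to_config <- function(model) {
  switch(model$model,
    mooney_rivlin5 = list(model = "mooney_rivlin5", c10 = model$c10,
                          c01 = model$c01, c20 = model$c20, c11 = model$c11,
                          c02 = model$c02, d1 = model$d1),
    yeoh3 = list(model = "yeoh3", c10 = model$c10, c20 = model$c20,
                 c30 = model$c30),
    ogden = list(model = "ogden", mu_p = model$mu, alpha_p = model$alpha),
    hgo = list(model = "hgo", c10 = model$c10, k1 = model$k1, k2 = model$k2,
               kappa = model$kappa, beta_deg = model$beta * 180 / pi,
               convention = model$convention),
    linear_elastic = list(model = "linear_elastic", E = model$E,
                          nu = model$nu),
    stop("unknown model tag: ", model$model))
}

#' @rdname material_to_config
#' @export
material_from_config <- function(config) {
  tag <- config$model
  if (is.null(tag)) stop("material config needs a 'model' tag")
  switch(tag,
    mooney_rivlin5 = mooney_rivlin5(config$c10, config$c01, config$c20,
                                    config$c11, config$c02,
                                    d1 = config$d1 %||% 0),
    yeoh3 = yeoh3(config$c10, config$c20, config$c30),
    ogden = ogden(unlist(config$mu_p), unlist(config$alpha_p)),
    hgo = hgo(config$c10, config$k1, config$k2, config$kappa,
              beta = unlist(config$beta_deg) * pi / 180,
              convention = config$convention %||% "standard"),
    linear_elastic = linear_elastic(config$E, config$nu),
    stop("unknown model tag: ", tag))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
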