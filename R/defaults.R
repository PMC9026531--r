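#' Reference material parameter sets
#'
#' Constitutive constants used as package defaults: graft constants obtained
#' from uniaxial tensile tests of expanded-PTFE (Gore-Tex) shunt specimens,
#' and aortic constants representative of a pediatric aorta.
#'
#' \code{yeoh_graft} and \code{mooney_rivlin_graft} carry the fitted graft
#' constants for two test specimens (specimen 1: 5 mm diameter, 0.5 mm wall;
#' specimen 2: 3 mm diameter, 0.35 mm wall). \code{ogden_aorta} is the
#' isotropic hyperelastic aorta (two-term Ogden). \code{elastic_graft} is the
#' linear-elastic shunt reference (E = 10.3 MPa, nu = 0.49).
#' \code{hgo_aorta} builds an anisotropic aorta whose tension-side
#' small-strain modulus is matched to a given isotropic target, so that
#' isotropic-versus-anisotropic comparisons isolate the effect of fiber
#' anisotropy rather than of overall stiffness.
#'
#' @param specimen 1 or 2.
#' @return a \code{\link{materials}} object.
#' @examples
#' small_strain_shear_modulus(ogden_aorta())  # ~0.759 MPa
#' @name reference_materials
NULL

#' @rdname reference_materials
#' @export
yeoh_graft <- function(specimen = 1) {
  switch(as.character(specimen),
         "1" = yeoh3(c10 = 0.11, c20 = -4.96e-6, c30 = 1.67e-10),
         "2" = yeoh3(c10 = 0.20, c20 = -6.73e-6, c30 = 1.16e-10),
         stop("specimen must be 1 or 2"))
}

#' @rdname reference_materials
#' @export
mooney_rivlin_graft <- function(specimen = 1) {
  switch(as.character(specimen),
         "1" = mooney_rivlin5(c10 = -1.64, c01 = 2.59, c20 = 4.46e-7,
                              c11 = -2.39e-4, c02 = 0.44),
         "2" = mooney_rivlin5(c10 = -2.2, c01 = 3.26, c20 = 3.86,
                              c11 = -8.6e-4, c02 = 0.62),
         stop("specimen must be 1 or 2"))
}

#' @rdname reference_materials
#' @export
ogden_aorta <- function() {
  ogden(mu = c(1.274, -1.211), alpha = c(24.074, 24.073))
}

#' @rdname reference_materials
#' @export
elastic_graft <- function() linear_elastic(E = 10.3, nu = 0.49)

#' @rdname reference_materials
#' @param target isotropic material whose small-strain shear modulus the HGO
#'   aorta should reproduce (default \code{ogden_aorta()}).
#' @param kappa fiber dispersion, default 0.226 (a typical aortic-media
#'   value; 0 = aligned, 1/3 = isotropic).
#' @param beta symmetric fiber-family angles from the circumferential axis.
#' @param k1,k2 fiber stiffness (MPa) and exponent.
#' @export
hgo_aorta <- function(target = ogden_aorta(), kappa = 0.226,
                      beta = c(pi / 4, -pi / 4), k1 = 0.5, k2 = 5) {
  mu_t <- small_strain_shear_modulus(target)
  coef4 <- 1 - 3 * kappa
  g <- coef4 * (2 * cos(beta)^2 - sin(beta)^2)
  fiber_E <- k1 * sum(ifelse(g > 0, g^2, 0))
  c10 <- (3 * mu_t - fiber_E) / 6
  if (c10 <= 0)
    stop("hgo_aorta: fiber stiffness k1 too large for the target modulus")
  hgo(c10 = c10, k1 = k1, k2 = k2, kappa = kappa, beta = beta)
}

#' Scale the stiffness of a material
#'
#' Multiplies every stress-like constant by \code{factor}, leaving
#' dimensionless shape parameters (Ogden exponents, HGO k2 and kappa, fiber
#' angles, Poisson ratio) unchanged. Used for stiffness-monotonicity checks.
#'
#' @param model a \code{\link{materials}} object.
#' @param factor positive scale factor.
#' @return a material of the same class.
#' @export
scale_stiffness <- function(model, factor) {
  stopifnot(factor > 0)
  switch(model$model,
    mooney_rivlin5 = mooney_rivlin5(model$c10 * factor, model$c01 * factor,
                                    model$c20 * factor, model$c11 * factor,
                                    model$c02 * factor, d1 = model$d1),
    yeoh3 = yeoh3(model$c10 * factor, model$c20 * factor,
                  model$c30 * factor),
    ogden = ogden(model$mu * factor, model$alpha),
    hgo = hgo(model$c10 * factor, model$k1 * factor, model$k2, model$kappa,
              beta = model$beta, convention = model$convention),
    linear_elastic = linear_elastic(model$E * factor, model$nu),
    stop("unknown model tag: ", model$model))
}
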