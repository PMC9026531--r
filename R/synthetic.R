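#' Synthetic uniaxial tensile data generator
#'
#' Generates tensile records that emulate uniaxial tests of expanded-PTFE
#' (Gore-Tex) graft specimens: nominal stress from a generating constitutive
#' model evaluated on a stretch grid, plus i.i.d. Gaussian stress noise, with
#' an optional planted rupture point appended as the terminal sample.
#'
#' @param model generating \code{\link{materials}} object.
#' @param stretch_max terminal stretch of the grid (default 1.6, the working
#'   range of the graft tests).
#' @param n number of samples.
#' @param noise_sd standard deviation of the Gaussian stress noise (MPa).
#' @param rupture optional \code{c(stretch, stress_mpa)} rupture point; its
#'   stress must exceed every pre-rupture stress.
#' @param seed RNG seed.
#' @param diameter_mm,thickness_mm,length_mm,rate_mm_per_min,preload_mpa
#'   specimen metadata; defaults describe a 4.5 mm diameter, 0.35 mm wall,
#'   20 mm gauge specimen loaded at 30 mm/min.
#' @param specimen_id label.
#' @return \code{tensile_spec}: a \code{"tensile_spec"} object;
#'   \code{generate_tensile}: a \code{\link{tensile_dataset}}.
#' @examples
#' spec <- tensile_spec(yeoh3(0.11, -4.96e-6, 1.67e-10), noise_sd = 0)
#' d <- generate_tensile(spec)
#' @export
tensile_spec <- function(model, stretch_max = 1.6, n = 100, noise_sd = 0.05,
                         rupture = NULL, seed = 20220407,
                         diameter_mm = 4.5, thickness_mm = 0.35,
                         length_mm = 20, rate_mm_per_min = 30,
                         preload_mpa = 0, specimen_id = "synthetic") {
  if (!inherits(model, "material")) stop("model must be a material")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (stretch_max <= 1) stop("stretch_max must exceed 1")
  if (n < 2) stop("need at least 2 samples")
  if (!is.null(rupture)) {
    if (length(rupture) != 2L || rupture[1] <= stretch_max)
      stop("rupture must be c(stretch > stretch_max, stress_mpa)")
  }
  structure(list(model = model, stretch_max = stretch_max, n = n,
                 noise_sd = noise_sd, rupture = rupture, seed = seed,
                 diameter_mm = diameter_mm, thickness_mm = thickness_mm,
                 length_mm = length_mm, rate_mm_per_min = rate_mm_per_min,
                 preload_mpa = preload_mpa, specimen_id = specimen_id),
            class = "tensile_spec")
}

#' @rdname tensile_spec
#' @param spec a \code{tensile_spec}.
#' @export
generate_tensile <- function(spec) {
  if (!inherits(spec, "tensile_spec")) stop("spec must be a tensile_spec")
  lam <- seq(1, spec$stretch_max, length.out = spec$n)
  curve <- uniaxial_stress(spec$model, lam)
  noise <- if (spec$noise_sd > 0)
    with_preserved_seed(spec$seed, stats::rnorm(spec$n, sd = spec$noise_sd))
  else rep(0, spec$n)
  stress <- curve + noise
  ruptured <- FALSE
  if (!is.null(spec$rupture)) {
    if (spec$rupture[2] <= max(stress))
      stop("rupture stress must exceed all pre-rupture stresses")
    lam <- c(lam, spec$rupture[1])
    stress <- c(stress, spec$rupture[2])
    ruptured <- TRUE
  }
  tensile_dataset(lam, stress, specimen_id = spec$specimen_id,
                  diameter_mm = spec$diameter_mm,
                  thickness_mm = spec$thickness_mm,
                  length_mm = spec$length_mm,
                  rate_mm_per_min = spec$rate_mm_per_min,
                  preload_mpa = spec$preload_mpa, ruptured = ruptured)
}

#' Aortic-root inlet velocity waveform
#'
#' Piecewise-smooth systolic pulse: quarter-sine rise from the diastolic
#' baseline to the peak velocity at \code{t_peak}, smooth quarter-cosine fall
#' back to baseline at end-systole, constant baseline through diastole;
#' periodic with the cardiac cycle. Defaults describe a pediatric cycle:
#' period 0.5 s, systole 0.22 s, peak 1.4 m/s at t = 0.09 s, zero diastolic
#' baseline.
#'
#' @param period cardiac cycle length (s).
#' @param systole ventricular systole duration (s).
#' @param t_peak time of peak velocity (s), 0 < t_peak < systole.
#' @param v_peak peak velocity (m/s).
#' @param v_base diastolic baseline velocity (m/s), 0 <= v_base <= v_peak.
#' @return object of class \code{"inlet_waveform"} with a vectorized
#'   \code{$velocity(t)} evaluator (m/s).
#' @examples
#' wf <- default_waveform()
#' wf$velocity(0.09)   # 1.4
#' @export
inlet_waveform <- function(period = 0.5, systole = 0.22, t_peak = 0.09,
                           v_peak = 1.4, v_base = 0) {
  if (!(0 < t_peak && t_peak < systole && systole < period))
    stop("need 0 < t_peak < systole < period")
  if (v_base < 0 || v_peak < v_base)
    stop("need v_peak >= v_base >= 0")
  velocity <- function(t) {
    tm <- t %% period
    rise <- tm <= t_peak
    fall <- tm > t_peak & tm <= systole
    v <- rep(v_base, length(tm))
    v[rise] <- v_base + (v_peak - v_base) * sin(pi * tm[rise] / (2 * t_peak))
    v[fall] <- v_base + (v_peak - v_base) *
      cos(pi * (tm[fall] - t_peak) / (2 * (systole - t_peak)))
    v
  }
  structure(list(period = period, systole = systole, t_peak = t_peak,
                 v_peak = v_peak, v_base = v_base, shape = "quarter_wave",
                 velocity = velocity), class = "inlet_waveform")
}

#' @rdname inlet_waveform
#' @export
default_waveform <- function() inlet_waveform()

#' Synthetic systemic outlet pressure profile
#'
#' Physiologic pressure waveform for the aortic (systemic) outlets, for which
#' only the pulmonary value is fixed by the boundary conditions: a pulse
#' between diastolic and systolic pressure phased with the inlet systole,
#' built from the same quarter-wave shape as \code{\link{inlet_waveform}}.
#'
#' @param waveform an \code{\link{inlet_waveform}} giving the timing.
#' @param p_dia_mmhg,p_sys_mmhg diastolic and systolic pressures (mmHg),
#'   default 80 and 120.
#' @return vectorized function \code{p(t)} returning pressure in Pa.
#' @export
systemic_pressure_profile <- function(waveform = default_waveform(),
                                      p_dia_mmhg = 80, p_sys_mmhg = 120) {
  span <- waveform$v_peak - waveform$v_base
  if (span <= 0) span <- 1
  function(t) {
    shape <- (waveform$velocity(t) - waveform$v_base) / span
    (p_dia_mmhg + (p_sys_mmhg - p_dia_mmhg) * shape) * MMHG_PA
  }
}

#' @export
print.inlet_waveform <- function(x, ...) {
  cat("<inlet_waveform> period", x$period, "s, systole", x$systole,
      "s, peak", x$v_peak, "m/s at", x$t_peak, "s, baseline", x$v_base,
      "m/s\n")
  invisible(x)
}

MMHG_PA <- 133.322
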