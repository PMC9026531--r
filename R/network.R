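#' Pressure-area tube law derived from a wall material
#'
#' Reduces the wall momentum balance of a thin-walled vessel to an algebraic
#' pressure-area relation. For a hyperelastic wall under plane stress, fixed
#' axial stretch (= 1) and wall incompressibility, the circumferential Cauchy
#' stress is \code{sigma_theta = lambda * dW/dlambda} along the path
#' \code{(lambda_theta, 1, 1/lambda_theta)}, and membrane equilibrium with
#' the deformed thickness \code{h/lambda} and radius \code{lambda * r0}
#' gives
#' \deqn{p(A) = (h / (r0 * lambda)) * dW/dlambda,  lambda = sqrt(A/A0),}
#' which is exactly the derivative of the wall strain energy per unit vessel
#' length with respect to lumen area (energy-consistent form). For the
#' linear-elastic wall the standard thin-shell form
#' \code{p = (E*h/(1-nu^2)) * (lambda-1) / (lambda*r0)} is used. HGO fiber
#' angles are measured from the circumferential direction.
#'
#' @param material a \code{\link{materials}} object (MPa units).
#' @param A0 reference lumen area (m^2).
#' @param h wall thickness (m), much smaller than sqrt(A0/pi).
#' @param axial_stretch fixed axial stretch (only 1 supported).
#' @param check_range circumferential stretch window over which elastic
#'   stability dp/dA > 0 is verified at construction.
#' @return object of class \code{"tube_law"}: list with vectorized closures
#'   \code{p(A)} (Pa), \code{dpdA(A)} (Pa/m^2), \code{area_at(p)} (inverse
#'   law by Newton iteration), and fields \code{A0}, \code{h}, \code{r0},
#'   \code{material}.
#' @examples
#' law <- tube_law(elastic_graft(), A0 = pi * 1.75e-3^2, h = 0.35e-3)
#' law$p(law$A0)  # 0 at the reference area
#' @export
tube_law <- function(material, A0, h, axial_stretch = 1,
                     check_range = c(0.5, 1.6)) {
  stopifnot(A0 > 0, h > 0)
  if (axial_stretch != 1)
    stop("only a fixed axial stretch of 1 is supported")
  r0 <- sqrt(A0 / pi)
  if (h > 0.5 * r0)
    warning("wall is not thin (h > r0/2); tube law accuracy degrades")
  if (inherits(material, "linear_elastic")) {
    k <- material$E * 1e6 * h / ((1 - material$nu^2) * r0)
    p_of_lam <- function(lam) k * (lam - 1) / lam
    dp_dlam <- function(lam) k / lam^2
  } else {
    K <- h * 1e6 / r0
    p_of_lam <- function(lam) K * wall_energy_derivs(material, lam)$d1 / lam
    dp_dlam <- function(lam) {
      d <- wall_energy_derivs(material, lam)
      K * (d$d2 / lam - d$d1 / lam^2)
    }
  }
  lam_grid <- seq(check_range[1], check_range[2], length.out = 80)
  slope <- dp_dlam(lam_grid)
  if (any(slope <= 0))
    stop(sprintf(
      "tube law unstable: dp/dA <= 0 at circumferential stretch %.4g",
      lam_grid[which(slope <= 0)[1]]))
  p <- function(A) p_of_lam(sqrt(A / A0))
  dpdA <- function(A) {
    lam <- sqrt(A / A0)
    dp_dlam(lam) / (2 * A0 * lam)
  }
  area_at <- function(pressure) {
    lam <- rep(1, length(pressure))
    for (i in 1:60) {
      f <- p_of_lam(lam) - pressure
      lam_new <- lam - f / dp_dlam(lam)
      lam_new <- pmin(pmax(lam_new, 0.3), 3)
      if (max(abs(lam_new - lam)) < 1e-14) { lam <- lam_new; break }
      lam <- lam_new
    }
    A0 * lam^2
  }
  structure(list(p = p, dpdA = dpdA, p_of_lam = p_of_lam,
                 dp_dlam = dp_dlam, area_at = area_at,
                 A0 = A0, h = h, r0 = r0, material = material),
            class = "tube_law")
}

# ---- network specification --------------------------------------------------

default_segment_table <- function() {
  # idealized pediatric dimensions (mm), configurable via network_spec;
  # lengths are multiples of 10 mm so that uniform grid refinement with
  # dx in {10, 5, 2.5, ...} mm halves the spacing of every segment exactly
  rbind(
    data.frame(name = "asc_aorta",  length_mm = 40, radius_mm = 6.0, thickness_mm = 0.60, wall = "aorta"),
    data.frame(name = "asc_prox",   length_mm = 20, radius_mm = 6.0, thickness_mm = 0.60, wall = "aorta"),
    data.frame(name = "asc_dist",   length_mm = 20, radius_mm = 6.0, thickness_mm = 0.60, wall = "aorta"),
    data.frame(name = "arch1",      length_mm = 20, radius_mm = 5.5, thickness_mm = 0.55, wall = "aorta"),
    data.frame(name = "arch2",      length_mm = 20, radius_mm = 5.2, thickness_mm = 0.52, wall = "aorta"),
    data.frame(name = "desc_aorta", length_mm = 60, radius_mm = 4.5, thickness_mm = 0.45, wall = "aorta"),
    data.frame(name = "bct",        length_mm = 20, radius_mm = 3.0, thickness_mm = 0.30, wall = "aorta"),
    data.frame(name = "bct_prox",   length_mm = 10, radius_mm = 3.0, thickness_mm = 0.30, wall = "aorta"),
    data.frame(name = "bct_dist",   length_mm = 10, radius_mm = 3.0, thickness_mm = 0.30, wall = "aorta"),
    data.frame(name = "lcc",        length_mm = 20, radius_mm = 2.0, thickness_mm = 0.20, wall = "aorta"),
    data.frame(name = "lsa",        length_mm = 20, radius_mm = 2.5, thickness_mm = 0.25, wall = "aorta"),
    data.frame(name = "lsa_prox",   length_mm = 10, radius_mm = 2.5, thickness_mm = 0.25, wall = "aorta"),
    data.frame(name = "lsa_dist",   length_mm = 10, radius_mm = 2.5, thickness_mm = 0.25, wall = "aorta"),
    data.frame(name = "shunt",      length_mm = 30, radius_mm = 1.75, thickness_mm = 0.35, wall = "shunt"),
    data.frame(name = "pa_trunk",   length_mm = 20, radius_mm = 4.0, thickness_mm = 0.40, wall = "pulmonary"),
    data.frame(name = "rpa",        length_mm = 30, radius_mm = 3.0, thickness_mm = 0.30, wall = "pulmonary"),
    data.frame(name = "lpa",        length_mm = 30, radius_mm = 3.0, thickness_mm = 0.30, wall = "pulmonary"),
    data.frame(name = "rpa_dist",   length_mm = 20, radius_mm = 3.0, thickness_mm = 0.30, wall = "pulmonary"),
    data.frame(name = "lpa_dist",   length_mm = 20, radius_mm = 3.0, thickness_mm = 0.30, wall = "pulmonary"),
    data.frame(name = "trunk_rpa",  length_mm = 40, radius_mm = 3.5, thickness_mm = 0.35, wall = "pulmonary"),
    data.frame(name = "trunk_lpa",  length_mm = 40, radius_mm = 3.5, thickness_mm = 0.35, wall = "pulmonary"))
}

#' Specification of the aorta-shunt-pulmonary-artery network
#'
#' Describes an idealized pediatric arterial network for one of the three
#' classical shunt placements: \code{"central"} (ascending aorta to pulmonary
#' trunk), \code{"right"} (left subclavian artery to right pulmonary artery)
#' or \code{"left"} (brachiocephalic trunk to left pulmonary artery). Default
#' dimensions are idealized pediatric values (aorta radius 6 mm, shunt
#' diameter 3.5 mm, shunt wall 0.35 mm); every dimension is configurable.
#'
#' @param placement shunt placement tag.
#' @param aorta,shunt,pulmonary wall materials for the three vessel groups.
#' @param dims optional named list of per-segment overrides, each a list with
#'   any of \code{length_mm}, \code{radius_mm}, \code{thickness_mm}.
#' @param p_pulmonary_mmhg constant pulmonary outlet pressure (mmHg).
#' @param systemic_pressure vectorized function p(t) in Pa for the systemic
#'   outlets (default \code{\link{systemic_pressure_profile}()}).
#' @param junction_loss named list of per-segment junction loss coefficients
#'   K in [0, 1]: when a segment end discharges into a junction, K times its
#'   dynamic head (K * rho u^2 / 2) is dissipated there. The default is
#'   K = 1 for every segment (a "mixing plenum" junction: incoming jets lose
#'   their dynamic head, outgoing flow accelerates ideally from the junction
#'   static pressure). This is the unconditionally dissipative closure; with
#'   K = 0 (ideal total-pressure continuity) reverse flow from a
#'   pressure-source outlet into a junction is dynamically unstable.
#' @return object of class \code{"network_spec"}.
#' @export
network_spec <- function(placement = c("central", "right", "left"),
                         aorta = ogden_aorta(), shunt = elastic_graft(),
                         pulmonary = ogden_aorta(), dims = NULL,
                         p_pulmonary_mmhg = 20,
                         systemic_pressure = systemic_pressure_profile(),
                         junction_loss = list()) {
  placement <- match.arg(placement)
  structure(list(placement = placement,
                 materials = list(aorta = aorta, shunt = shunt,
                                  pulmonary = pulmonary),
                 dims = dims, p_pulmonary_mmhg = p_pulmonary_mmhg,
                 systemic_pressure = systemic_pressure,
                 junction_loss = junction_loss),
            class = "network_spec")
}

network_topology <- function(placement) {
  # junctions: list of data.frames (segment, side); side "end" = segment's
  # distal node feeds the junction, "start" = segment is fed by it
  jn <- function(...) {
    v <- list(...)
    data.frame(segment = vapply(v, `[[`, "", 1),
               side = vapply(v, `[[`, "", 2))
  }
  common_arch <- function(first_arch_parent) list(
    jn(c(first_arch_parent, "end"), c("bct", "start"), c("arch1", "start")),
    jn(c("arch1", "end"), c("lcc", "start"), c("arch2", "start")),
    jn(c("arch2", "end"), c("lsa", "start"), c("desc_aorta", "start")))
  switch(placement,
    central = list(
      inlet = "asc_prox",
      segments = c("asc_prox", "asc_dist", "arch1", "arch2", "desc_aorta",
                   "bct", "lcc", "lsa", "shunt", "pa_trunk", "rpa", "lpa"),
      junctions = c(
        list(jn(c("asc_prox", "end"), c("shunt", "start"),
                c("asc_dist", "start"))),
        common_arch("asc_dist"),
        list(jn(c("shunt", "end"), c("pa_trunk", "start")),
             jn(c("pa_trunk", "end"), c("rpa", "start"), c("lpa", "start")))),
      systemic_outlets = c("bct", "lcc", "lsa", "desc_aorta"),
      pulmonary_outlets = c("rpa", "lpa")),
    right = list(
      inlet = "asc_aorta",
      segments = c("asc_aorta", "arch1", "arch2", "desc_aorta", "bct", "lcc",
                   "lsa_prox", "lsa_dist", "shunt", "rpa_dist", "trunk_lpa"),
      junctions = c(
        list(jn(c("asc_aorta", "end"), c("bct", "start"),
                c("arch1", "start")),
             jn(c("arch1", "end"), c("lcc", "start"), c("arch2", "start")),
             jn(c("arch2", "end"), c("lsa_prox", "start"),
                c("desc_aorta", "start")),
             jn(c("lsa_prox", "end"), c("lsa_dist", "start"),
                c("shunt", "start")),
             jn(c("shunt", "end"), c("rpa_dist", "start"),
                c("trunk_lpa", "start")))),
      systemic_outlets = c("bct", "lcc", "lsa_dist", "desc_aorta"),
      pulmonary_outlets = c("rpa_dist", "trunk_lpa")),
    left = list(
      inlet = "asc_aorta",
      segments = c("asc_aorta", "arch1", "arch2", "desc_aorta", "bct_prox",
                   "bct_dist", "lcc", "lsa", "shunt", "lpa_dist",
                   "trunk_rpa"),
      junctions = c(
        list(jn(c("asc_aorta", "end"), c("bct_prox", "start"),
                c("arch1", "start")),
             jn(c("arch1", "end"), c("lcc", "start"), c("arch2", "start")),
             jn(c("arch2", "end"), c("lsa", "start"),
                c("desc_aorta", "start")),
             jn(c("bct_prox", "end"), c("bct_dist", "start"),
                c("shunt", "start")),
             jn(c("shunt", "end"), c("lpa_dist", "start"),
                c("trunk_rpa", "start")))),
      systemic_outlets = c("bct_dist", "lcc", "lsa", "desc_aorta"),
      pulmonary_outlets = c("lpa_dist", "trunk_rpa")),
    stop("unknown placement: ", placement))
}

#' Build a compliant vessel network
#'
#' Realizes a \code{\link{network_spec}} as a \code{vessel_network}: segments
#' with SI geometry and material-derived \code{\link{tube_law}}s, junction
#' topology, the aortic-root inlet and typed outlets (constant 20 mmHg
#' pressure at the pulmonary outlets, a time-varying synthetic physiologic
#' pressure at the systemic outlets).
#'
#' @param spec a \code{\link{network_spec}} (or a placement tag).
#' @return object of class \code{"vessel_network"}.
#' @examples
#' net <- build_network(network_spec("central"))
#' @export
build_network <- function(spec = network_spec("central")) {
  if (is.character(spec)) spec <- network_spec(spec)
  if (!inherits(spec, "network_spec")) stop("spec must be a network_spec")
  topo <- network_topology(spec$placement)
  tab <- default_segment_table()
  segments <- list()
  for (nm in topo$segments) {
    row <- tab[tab$name == nm, ]
    if (nrow(row) != 1L) stop("no default dimensions for segment ", nm)
    ov <- spec$dims[[nm]]
    L <- (ov$length_mm %||% row$length_mm) * 1e-3
    r0 <- (ov$radius_mm %||% row$radius_mm) * 1e-3
    h <- (ov$thickness_mm %||% row$thickness_mm) * 1e-3
    if (L <= 0 || r0 <= 0 || h <= 0)
      stop("segment dimensions must be positive: ", nm)
    material <- spec$materials[[row$wall]]
    segments[[nm]] <- list(name = nm, length = L, r0 = r0, h = h,
                           A0 = pi * r0^2, wall = row$wall,
                           material = material,
                           loss = spec$junction_loss[[nm]] %||% 1,
                           law = tube_law(material, pi * r0^2, h))
  }
  outlets <- list()
  for (nm in topo$systemic_outlets)
    outlets[[nm]] <- list(type = "pressure_fun",
                          p_fun = spec$systemic_pressure)
  for (nm in topo$pulmonary_outlets)
    outlets[[nm]] <- list(type = "pressure",
                          p = spec$p_pulmonary_mmhg * MMHG_PA)
  net <- structure(list(placement = spec$placement, segments = segments,
                        junctions = topo$junctions, inlet = topo$inlet,
                        outlets = outlets, spec = spec),
                   class = "vessel_network")
  validate_network(net)
  net
}

validate_network <- function(net) {
  nms <- names(net$segments)
  attach_count <- matrix(0L, length(nms), 2,
                         dimnames = list(nms, c("start", "end")))
  attach_count[net$inlet, "start"] <- attach_count[net$inlet, "start"] + 1L
  for (o in names(net$outlets))
    attach_count[o, "end"] <- attach_count[o, "end"] + 1L
  for (j in net$junctions)
    for (k in seq_len(nrow(j))) {
      if (!j$segment[k] %in% nms)
        stop("junction references unknown segment ", j$segment[k])
      attach_count[j$segment[k], j$side[k]] <-
        attach_count[j$segment[k], j$side[k]] + 1L
    }
  if (any(attach_count != 1L)) {
    bad <- which(attach_count != 1L, arr.ind = TRUE)
    stop("network topology error: segment '", nms[bad[1, 1]], "' ",
         colnames(attach_count)[bad[1, 2]], " attached ",
         attach_count[bad[1]], " times (must be exactly 1)")
  }
  # connectivity: walk the tree from the inlet
  seen <- net$inlet
  repeat {
    grew <- FALSE
    for (j in net$junctions)
      if (any(j$segment %in% seen) && !all(j$segment %in% seen)) {
        seen <- union(seen, j$segment); grew <- TRUE
      }
    if (!grew) break
  }
  if (!setequal(seen, nms))
    stop("network is disconnected: unreachable segments ",
         paste(setdiff(nms, seen), collapse = ", "))
  invisible(net)
}

#' @export
print.vessel_network <- function(x, ...) {
  cat("<vessel_network>", x$placement, "shunt placement\n")
  cat("  segments:", length(x$segments), " junctions:",
      length(x$junctions), " outlets:", length(x$outlets), "\n")
  for (s in x$segments)
    cat(sprintf("  %-11s L = %4.0f mm  r0 = %4.2f mm  h = %4.2f mm  [%s: %s]\n",
                s$name, s$length * 1e3, s$r0 * 1e3, s$h * 1e3, s$wall,
                s$material$model))
  invisible(x)
}

#' Unique path from the shunt to the pulmonary outlets
#'
#' Walks the tree downstream of the shunt segment; used as a topology check
#' that the shunt is the single feeding conduit of the pulmonary side.
#'
#' @param network a \code{vessel_network}.
#' @return character vector of segment names downstream of the shunt
#'   (including the shunt).
#' @export
shunt_path <- function(network) {
  down <- "shunt"
  repeat {
    grew <- FALSE
    for (j in network$junctions) {
      feeders <- j$segment[j$side == "end"]
      fed <- j$segment[j$side == "start"]
      if (any(feeders %in% down) && !all(fed %in% down)) {
        down <- union(down, fed); grew <- TRUE
      }
    }
    if (!grew) break
  }
  down
}

#' Blood properties
#'
#' @param density_kg_m3 blood density (kg/m^3), default 1060.
#' @param viscosity_pa_s dynamic viscosity (Pa s), default 0.0035 (Newtonian).
#' @return object of class \code{"fluid_properties"}.
#' @export
fluid_properties <- function(density_kg_m3 = 1060, viscosity_pa_s = 0.0035) {
  if (density_kg_m3 <= 0 || viscosity_pa_s <= 0)
    stop("fluid properties must be positive")
  structure(list(rho = density_kg_m3, mu = viscosity_pa_s),
            class = "fluid_properties")
}
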