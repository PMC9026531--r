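#' Wall shear stress series
#'
#' Wall shear stress under the parabolic-profile closure,
#' \code{tau_w = 4 mu Q / (pi R^3)} with \code{R = sqrt(A/pi)}; a
#' lower-fidelity analogue of three-dimensional near-wall velocity gradients.
#' Signed with the flow direction.
#'
#' @param solution a \code{\link{solve_pulsatile}} result.
#' @param fluid fluid properties (defaults to those of the run).
#' @return named list of matrices (frames x nodes) of WSS in Pa.
#' @export
wall_shear_stress <- function(solution, fluid = solution$fluid) {
  lapply(stats::setNames(names(solution$Q), names(solution$Q)), function(nm) {
    R <- sqrt(solution$A[[nm]] / pi)
    4 * fluid$mu * solution$Q[[nm]] / (pi * R^3)
  })
}

#' Time-averaged wall shear stress
#'
#' Mean of |tau_w| over the final whole cycle of a series (magnitude
#' convention), by trapezoidal integration.
#'
#' @param wss numeric vector (or single-node series) of wall shear stress.
#' @param time time grid of the series (s).
#' @param period cycle length (s); the series must span at least one and an
#'   integer number of cycles within 2% of a period.
#' @return scalar TAWSS (Pa).
#' @examples
#' t <- seq(0, 1, by = 1e-4)
#' tawss(sin(2 * pi * t), t, 1)  # 2/pi
#' @export
tawss <- function(wss, time, period) {
  if (length(wss) != length(time)) stop("wss and time lengths differ")
  span <- time[length(time)] - time[1]
  ncyc <- span / period
  if (ncyc < 1 - 1e-9 || abs(ncyc - round(ncyc)) > 0.02)
    stop("series must span an integer number of cycles (got ",
         signif(ncyc, 4), ")")
  keep <- time >= time[length(time)] - period - 1e-12
  tt <- time[keep]; y <- abs(wss[keep])
  sum(diff(tt) * (utils::head(y, -1) + utils::tail(y, -1)) / 2) /
    (tt[length(tt)] - tt[1])
}

#' Von Mises wall stress series
#'
#' Thin-walled biaxial pressure-vessel state: circumferential stress
#' \code{sigma_theta = p R / h}, axial \code{sigma_z = p R / (2h)}, radial
#' ~ 0, giving \code{sigma_vm = sqrt(3)/2 * sigma_theta}. Local bending and
#' anastomosis stress concentrations of a full three-dimensional wall model
#' are not represented.
#'
#' @param solution a \code{\link{solve_pulsatile}} result.
#' @return named list of matrices (frames x nodes) in kPa.
#' @export
von_mises_wall_stress <- function(solution) {
  lapply(stats::setNames(names(solution$p), names(solution$p)), function(nm) {
    h <- solution$network$segments[[nm]]$h
    R <- sqrt(solution$A[[nm]] / pi)
    st <- solution$p[[nm]] * R / h
    sz <- st / 2
    sqrt(st^2 - st * sz + sz^2) / 1e3
  })
}

#' Radial wall displacement series
#'
#' \code{u_r = sqrt(A/pi) - sqrt(A0/pi)} per node, in mm.
#'
#' @param solution a \code{\link{solve_pulsatile}} result.
#' @return named list of matrices (frames x nodes) in mm.
#' @export
radial_displacement <- function(solution) {
  lapply(stats::setNames(names(solution$A), names(solution$A)), function(nm) {
    r0 <- solution$network$segments[[nm]]$r0
    (sqrt(solution$A[[nm]] / pi) - r0) * 1e3
  })
}

#' Per-segment metric report
#'
#' Final-cycle hemodynamic and wall-mechanics summary per segment: peak and
#' mean wall shear stress (Pa), node-maximum TAWSS (Pa), peak von Mises wall
#' stress (kPa), peak radial displacement (mm), and the shunt cycle-mean flow
#' (mL/min) where a shunt exists.
#'
#' @param solution a \code{\link{solve_pulsatile}} result.
#' @param scenario optional label attached to the rows.
#' @param force include unconverged runs.
#' @return data.frame of class \code{"metric_report"}.
#' @export
metric_report <- function(solution, scenario = NA_character_, force = FALSE) {
  if (!solution$converged && !force)
    stop("solution did not converge; pass force = TRUE to report anyway")
  fin <- final_cycle_index(solution)
  wss <- wall_shear_stress(solution)
  vm <- von_mises_wall_stress(solution)
  ur <- radial_displacement(solution)
  tt <- solution$time[fin]
  rows <- lapply(names(solution$A), function(nm) {
    w <- wss[[nm]][fin, , drop = FALSE]
    ta <- max(apply(w, 2, function(col) tawss(col, tt, solution$period)))
    data.frame(scenario = scenario, segment = nm,
               wss_peak_pa = max(abs(w)),
               wss_mean_pa = mean(abs(w)),
               tawss_pa = ta,
               vm_peak_kpa = max(vm[[nm]][fin, ]),
               disp_peak_mm = max(abs(ur[[nm]][fin, ])))
  })
  out <- do.call(rbind, rows)
  if ("shunt" %in% names(solution$Q)) {
    sf <- shunt_flow_series(solution, force = force)
    attr(out, "shunt_mean_ml_min") <- sf$mean_ml_min
    attr(out, "shunt_peak_ml_min") <- sf$peak_ml_min
  }
  class(out) <- c("metric_report", "data.frame")
  out
}

#' Symmetric relative deviation between two cycle series
#'
#' Pointwise |x1 - x2| / max(|x1|, |x2|, eps), maximized over the cycle;
#' invariant (up to the shared normalization) to which series is the
#' baseline.
#'
#' @param x1,x2 numeric series on the same phase grid.
#' @param eps floor preventing division by zero.
#' @return scalar deviation (dimensionless; multiply by 100 for percent).
#' @export
relative_deviation <- function(x1, x2, eps = 1e-12) {
  if (length(x1) != length(x2)) stop("series lengths differ")
  max(abs(x1 - x2) / pmax(abs(x1), abs(x2), eps))
}

#' Structured scenario comparison
#'
#' Solves the pulsatile problem for every cell of the (aorta material) x
#' (shunt material) x (placement) matrix on the same idealized network and
#' forcing, and reports per-cell metrics together with the pairwise
#' deviations of interest: the maximum cycle deviation of shunt flow between
#' the two aorta materials, and the corresponding deviation of
#' descending-aorta wall shear stress, per placement and shunt material.
#'
#' @param aorta named list of aorta wall materials (e.g.
#'   \code{list(isotropic = ogden_aorta(), anisotropic = hgo_aorta())}).
#' @param shunt named list of shunt materials.
#' @param placements character vector of placements to include.
#' @param inlet inlet waveform.
#' @param fluid fluid properties.
#' @param ... further arguments to \code{\link{solve_pulsatile}}.
#' @return object of class \code{"scenario_comparison"}: list with
#'   \code{table} (one metric row per cell and segment), \code{shunt_flow}
#'   (per-cell shunt flow series), \code{deviations} (per placement/shunt
#'   pairwise aorta-material deviations), \code{failed} (labels of
#'   unconverged cells, reported as gaps).
#' @export
compare_scenarios <- function(aorta = list(isotropic = ogden_aorta(),
                                           anisotropic = hgo_aorta()),
                              shunt = list(elastic = elastic_graft()),
                              placements = c("central", "right", "left"),
                              inlet = default_waveform(),
                              fluid = fluid_properties(), ...) {
  cells <- expand.grid(aorta = names(aorta), shunt = names(shunt),
                       placement = placements, stringsAsFactors = FALSE)
  runs <- list(); tables <- list(); failed <- character(0)
  for (i in seq_len(nrow(cells))) {
    lab <- paste(cells$placement[i], cells$aorta[i], cells$shunt[i],
                 sep = "/")
    spec <- network_spec(cells$placement[i],
                         aorta = aorta[[cells$aorta[i]]],
                         shunt = shunt[[cells$shunt[i]]],
                         pulmonary = aorta[[cells$aorta[i]]])
    sol <- tryCatch(
      solve_pulsatile(build_network(spec), fluid = fluid, inlet = inlet,
                      ...),
      error = function(e) e)
    if (inherits(sol, "error") || !sol$converged) {
      failed <- c(failed, lab)
      runs[[lab]] <- NULL
      next
    }
    runs[[lab]] <- sol
    tables[[lab]] <- metric_report(sol, scenario = lab)
  }
  shunt_flow <- lapply(runs, shunt_flow_series)
  # pairwise deviations between aorta materials, per placement and shunt
  deviations <- NULL
  if (length(aorta) >= 2) {
    an <- names(aorta)
    pairs <- utils::combn(an, 2, simplify = FALSE)
    dev_rows <- list()
    for (pl in placements) for (sh in names(shunt)) for (pr in pairs) {
      l1 <- paste(pl, pr[1], sh, sep = "/")
      l2 <- paste(pl, pr[2], sh, sep = "/")
      if (is.null(runs[[l1]]) || is.null(runs[[l2]])) next
      qdev <- relative_deviation(shunt_flow[[l1]]$q_m3_s,
                                 shunt_flow[[l2]]$q_m3_s)
      wss1 <- wall_shear_stress(runs[[l1]])
      wss2 <- wall_shear_stress(runs[[l2]])
      desc <- intersect(c("desc_aorta"), names(wss1))
      wdev <- if (length(desc)) {
        f1 <- final_cycle_index(runs[[l1]])
        f2 <- final_cycle_index(runs[[l2]])
        mid <- ncol(wss1[[desc]]) %/% 2 + 1
        relative_deviation(wss1[[desc]][f1, mid], wss2[[desc]][f2, mid])
      } else NA_real_
      dev_rows[[length(dev_rows) + 1L]] <- data.frame(
        placement = pl, shunt = sh, pair = paste(pr, collapse = " vs "),
        shunt_flow_max_dev = qdev, desc_aorta_wss_max_dev = wdev)
    }
    deviations <- do.call(rbind, dev_rows)
  }
  structure(list(cells = cells,
                 table = do.call(rbind, tables),
                 shunt_flow = shunt_flow,
                 deviations = deviations,
                 failed = failed, runs = runs),
            class = "scenario_comparison")
}

#' @export
print.scenario_comparison <- function(x, ...) {
  cat("<scenario_comparison>", nrow(x$cells), "cells,",
      length(x$failed), "failed\n")
  if (length(x$failed))
    cat("  unconverged cells:", paste(x$failed, collapse = ", "), "\n")
  if (!is.null(x$deviations)) {
    cat("  pairwise aorta-material deviations:\n")
    print(x$deviations, row.names = FALSE)
  }
  invisible(x)
}
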