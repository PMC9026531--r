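#' Pipeline configuration and file round-tripping
#'
#' The pipeline stages (generate -> fit -> simulate -> metrics -> compare)
#' are orchestrated through YAML run configurations and delimited-text data
#' files. Every structured output embeds the package version, the seed and
#' an MD5 hash of the configuration file it was produced from, so a recorded
#' run can be reproduced exactly.
#'
#' @param path configuration file path.
#' @return \code{read_run_config}: named list.
#' @name run_config
NULL

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  yaml::read_yaml(path)
}

#' @rdname run_config
#' @param config named list to serialize.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# resolve a material description: a registry tag or a parameter block
resolve_material <- function(x) {
  if (inherits(x, "material")) return(x)
  if (is.character(x) && length(x) == 1L) {
    return(switch(x,
      ogden_aorta = ogden_aorta(),
      hgo_aorta = hgo_aorta(),
      elastic_graft = elastic_graft(),
      yeoh_graft_1 = yeoh_graft(1),
      yeoh_graft_2 = yeoh_graft(2),
      mooney_rivlin_graft_1 = mooney_rivlin_graft(1),
      mooney_rivlin_graft_2 = mooney_rivlin_graft(2),
      stop("unknown material tag: ", x)))
  }
  material_from_config(x)
}

provenance <- function(config_path = NULL, seed = NA) {
  list(package = "shuntflow",
       version = as.character(utils::packageVersion("shuntflow")),
       seed = seed,
       config_hash = if (!is.null(config_path) && file.exists(config_path))
         unname(tools::md5sum(config_path)) else NA_character_)
}

#' Run the tensile-data generation stage
#'
#' Reads a generator configuration (fields: \code{material} block or tag,
#' \code{stretch_max}, \code{n_samples}, \code{noise_sd}, \code{seed}, optional
#' \code{rupture}, specimen metadata) and writes the generated dataset plus
#' its metadata sidecar.
#'
#' @param config_path YAML configuration path.
#' @param out output data file path.
#' @return the generated \code{\link{tensile_dataset}}, invisibly.
#' @export
run_generate_tensile <- function(config_path, out) {
  cfg <- read_run_config(config_path)
  spec <- tensile_spec(
    model = resolve_material(cfg$material),
    stretch_max = cfg$stretch_max %||% 1.6,
    n = cfg$n_samples %||% 100,
    noise_sd = cfg$noise_sd %||% 0.05,
    rupture = if (!is.null(cfg$rupture)) unlist(cfg$rupture),
    seed = cfg$seed %||% 20220407,
    diameter_mm = cfg$diameter_mm %||% 4.5,
    thickness_mm = cfg$thickness_mm %||% 0.35,
    length_mm = cfg$length_mm %||% 20,
    rate_mm_per_min = cfg$rate_mm_per_min %||% 30,
    preload_mpa = cfg$preload_mpa %||% 0,
    specimen_id = cfg$specimen_id %||% "synthetic")
  d <- generate_tensile(spec)
  write_tensile(d, out)
  prov <- provenance(config_path, seed = spec$seed)
  yaml::write_yaml(c(prov, list(stage = "generate-tensile", data = out)),
                   paste0(out, ".run.yaml"))
  invisible(d)
}

#' Run the fitting stage
#'
#' Fits one or more constitutive models to a tensile data file and writes a
#' comparison table (\code{<out_prefix>_fits.csv}) plus a structured summary
#' (\code{<out_prefix>_summary.yaml}) including per-model parameters,
#' identifiability warnings and provenance.
#'
#' @param data_path tensile data file (see \code{\link{read_tensile}}).
#' @param models character vector of model tags.
#' @param out_prefix output path prefix.
#' @param seed multi-start seed.
#' @param ... further arguments to \code{\link{fit_material}}.
#' @return the \code{\link{fit_report}}, invisibly.
#' @export
run_fit <- function(data_path, models = c("yeoh3", "mooney_rivlin5"),
                    out_prefix = "fit", seed = 20220407, ...) {
  data <- read_tensile(data_path)
  fits <- lapply(models, function(m) fit_material(data, m, seed = seed, ...))
  rep <- fit_report(fits, data)
  utils::write.csv(as.data.frame(rep), paste0(out_prefix, "_fits.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- list(stage = "fit", data = data_path,
               models = lapply(fits, function(f) list(
                 model = f$model,
                 parameters = as.list(f$par),
                 rmse_mpa = f$rmse, r_squared = f$r_squared,
                 condition_number = f$condition_number,
                 weak_parameters = names(f$identifiable)[!f$identifiable],
                 converged = f$converged)))
  for (f in fits)
    if (!all(f$identifiable))
      message("identifiability warning [", f$model, "]: ",
              paste(names(f$identifiable)[!f$identifiable], collapse = ", "))
  yaml::write_yaml(c(provenance(data_path, seed = seed), summ),
                   paste0(out_prefix, "_summary.yaml"))
  invisible(rep)
}

#' Run the simulation stage
#'
#' Builds the network and waveform described by a run configuration, solves
#' the pulsatile problem, and writes one delimited file per segment
#' (time and per-node area, flow, pressure at inlet/mid/outlet nodes) plus a
#' structured summary with the per-segment metric report.
#'
#' @param config_path YAML configuration: optional fields \code{placement},
#'   \code{aorta}, \code{shunt}, \code{pulmonary} (material tags or blocks),
#'   \code{waveform} (see \code{\link{inlet_waveform}}), \code{solver}
#'   (n_cycles, dx, cfl, tol), \code{seed}.
#' @param out_dir output directory (created if missing).
#' @return the \code{\link{solve_pulsatile}} solution, invisibly.
#' @export
run_simulate <- function(config_path, out_dir = "simulation") {
  cfg <- read_run_config(config_path)
  wf_args <- cfg$waveform %||% list()
  wf <- do.call(inlet_waveform, wf_args)
  spec <- network_spec(
    placement = cfg$placement %||% "central",
    aorta = resolve_material(cfg$aorta %||% "ogden_aorta"),
    shunt = resolve_material(cfg$shunt %||% "elastic_graft"),
    pulmonary = resolve_material(cfg$pulmonary %||% cfg$aorta %||%
                                   "ogden_aorta"),
    systemic_pressure = systemic_pressure_profile(wf))
  so <- cfg$solver %||% list()
  sol <- solve_pulsatile(build_network(spec), inlet = wf,
                         n_cycles = so$n_cycles %||% 6,
                         dx = so$dx %||% 5e-3, cfl = so$cfl %||% 0.8,
                         tol = so$tol %||% 1e-3)
  if (!sol$converged)
    stop("simulation did not converge (last residual ",
         signif(utils::tail(sol$cycle_residuals, 1), 3), ")")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(sol$A)) {
    n <- ncol(sol$A[[nm]])
    mid <- n %/% 2 + 1
    tab <- data.frame(time_s = sol$time,
                      a_in_m2 = sol$A[[nm]][, 1],
                      a_mid_m2 = sol$A[[nm]][, mid],
                      a_out_m2 = sol$A[[nm]][, n],
                      q_in_m3_s = sol$Q[[nm]][, 1],
                      q_mid_m3_s = sol$Q[[nm]][, mid],
                      q_out_m3_s = sol$Q[[nm]][, n],
                      p_in_pa = sol$p[[nm]][, 1],
                      p_mid_pa = sol$p[[nm]][, mid],
                      p_out_pa = sol$p[[nm]][, n])
    utils::write.csv(tab, file.path(out_dir, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  mr <- metric_report(sol, scenario = cfg$placement %||% "central")
  utils::write.csv(as.data.frame(mr), file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  summ <- c(provenance(config_path, seed = cfg$seed %||% NA),
            list(stage = "simulate",
                 placement = spec$placement,
                 converged = sol$converged,
                 cycles_run = sol$cycles_run,
                 cycle_residuals = sol$cycle_residuals,
                 inflow_ml = sol$mass_balance$inflow_m3 * 1e6,
                 mass_closure_error = sol$mass_balance$closure_error,
                 shunt_mean_q_ml_min =
                   attr(mr, "shunt_mean_ml_min") %||% NA))
  yaml::write_yaml(summ, file.path(out_dir, "summary.yaml"))
  invisible(sol)
}

#' Run the scenario-comparison stage
#'
#' @param config_path YAML configuration: \code{placements}, named material
#'   blocks/tags under \code{aorta} and \code{shunt}, optional \code{solver}
#'   options.
#' @param out_dir output directory.
#' @return the \code{\link{compare_scenarios}} result, invisibly.
#' @export
run_compare <- function(config_path, out_dir = "comparison") {
  cfg <- read_run_config(config_path)
  if (is.null(cfg$aorta) || is.null(cfg$shunt))
    stop("comparison config needs named 'aorta' and 'shunt' material lists")
  so <- cfg$solver %||% list()
  cmp <- compare_scenarios(
    aorta = lapply(cfg$aorta, resolve_material),
    shunt = lapply(cfg$shunt, resolve_material),
    placements = unlist(cfg$placements %||% c("central", "right", "left")),
    n_cycles = so$n_cycles %||% 6, dx = so$dx %||% 5e-3,
    tol = so$tol %||% 1e-3)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cmp$table, file.path(out_dir, "metrics.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(cmp$deviations))
    utils::write.csv(cmp$deviations, file.path(out_dir, "deviations.csv"),
                     row.names = FALSE, quote = FALSE)
  yaml::write_yaml(c(provenance(config_path, seed = cfg$seed %||% NA),
                     list(stage = "compare",
                          cells = nrow(cmp$cells),
                          failed = as.list(cmp$failed))),
                   file.path(out_dir, "summary.yaml"))
  invisible(cmp)
}
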