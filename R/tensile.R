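#' Uniaxial tensile test dataset
#'
#' Container for a uniaxial tensile record of a tubular graft specimen:
#' specimen geometry plus ordered (stretch, nominal stress) samples. The
#' stress axis is nominal (engineering) stress computed from the undeformed
#' cross-section of the tube wall; see \code{\link{uniaxial_stress}} for the
#' Cauchy conversion.
#'
#' @param stretch numeric vector of axial stretches, non-decreasing, first
#'   value >= 1.
#' @param stress_mpa numeric vector of nominal stresses (MPa), finite.
#' @param specimen_id character label.
#' @param diameter_mm,thickness_mm,length_mm specimen diameter, wall
#'   thickness and gauge length (mm).
#' @param rate_mm_per_min load rate (mm/min); metadata only — graft response
#'   is rate-insensitive over the tested range.
#' @param preload_mpa preload stress (MPa).
#' @param ruptured logical; TRUE when the terminal sample is a planted or
#'   observed rupture point.
#' @return object of class \code{"tensile_dataset"}: a list with a
#'   \code{samples} data.frame and the metadata fields.
#' @export
tensile_dataset <- function(stretch, stress_mpa, specimen_id = "specimen",
                            diameter_mm = NA_real_, thickness_mm = NA_real_,
                            length_mm = NA_real_, rate_mm_per_min = NA_real_,
                            preload_mpa = 0, ruptured = FALSE) {
  stretch <- as.numeric(stretch); stress_mpa <- as.numeric(stress_mpa)
  if (length(stretch) != length(stress_mpa))
    stop("stretch and stress_mpa must have equal length")
  if (length(stretch) < 1L) stop("dataset must contain at least one sample")
  if (any(!is.finite(stretch)) || any(!is.finite(stress_mpa)))
    stop("samples must be finite")
  if (stretch[1] < 1) stop("first sample must be at stretch >= 1")
  if (is.unsorted(stretch)) stop("stretches must be non-decreasing")
  structure(list(
    samples = data.frame(stretch = stretch, stress_mpa = stress_mpa),
    specimen_id = specimen_id, diameter_mm = diameter_mm,
    thickness_mm = thickness_mm, length_mm = length_mm,
    rate_mm_per_min = rate_mm_per_min, preload_mpa = preload_mpa,
    ruptured = isTRUE(ruptured)), class = "tensile_dataset")
}

#' @export
print.tensile_dataset <- function(x, ...) {
  cat("<tensile_dataset>", x$specimen_id, "\n")
  cat(sprintf("  d = %s mm, h = %s mm, L = %s mm, rate = %s mm/min\n",
              x$diameter_mm, x$thickness_mm, x$length_mm, x$rate_mm_per_min))
  cat(sprintf("  %d samples, stretch %.4g .. %.4g, stress %.4g .. %.4g MPa\n",
              nrow(x$samples), min(x$samples$stretch), max(x$samples$stretch),
              min(x$samples$stress_mpa), max(x$samples$stress_mpa)))
  invisible(x)
}

#' Read / write tensile datasets as delimited text
#'
#' The data file is comma-separated with a header row and columns
#' \code{(stretch, stress_mpa)} or \code{(strain_eng, stress_mpa)}; specimen
#' metadata travels in a YAML sidecar \code{<path>.meta.yaml} with keys
#' \code{specimen_id, diameter_mm, thickness_mm, length_mm, rate_mm_per_min,
#' preload_mpa, ruptured}.
#'
#' @param path data file path.
#' @param data a \code{\link{tensile_dataset}}.
#' @return \code{read_tensile}: a \code{tensile_dataset};
#'   \code{write_tensile}: \code{path}, invisibly.
#' @export
read_tensile <- function(path) {
  if (!file.exists(path)) stop("tensile data file not found: ", path)
  tab <- utils::read.csv(path)
  if ("stretch" %in% names(tab)) stretch <- tab$stretch
  else if ("strain_eng" %in% names(tab)) stretch <- 1 + tab$strain_eng
  else stop("expected a 'stretch' or 'strain_eng' column in ", path)
  if (!"stress_mpa" %in% names(tab))
    stop("expected a 'stress_mpa' column in ", path)
  meta_path <- paste0(path, ".meta.yaml")
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  tensile_dataset(stretch, tab$stress_mpa,
                  specimen_id = meta$specimen_id %||% basename(path),
                  diameter_mm = meta$diameter_mm %||% NA_real_,
                  thickness_mm = meta$thickness_mm %||% NA_real_,
                  length_mm = meta$length_mm %||% NA_real_,
                  rate_mm_per_min = meta$rate_mm_per_min %||% NA_real_,
                  preload_mpa = meta$preload_mpa %||% 0,
                  ruptured = meta$ruptured %||% FALSE)
}

#' @rdname read_tensile
#' @export
write_tensile <- function(data, path) {
  utils::write.csv(data$samples, path, row.names = FALSE, quote = FALSE)
  meta <- list(specimen_id = data$specimen_id,
               diameter_mm = data$diameter_mm,
               thickness_mm = data$thickness_mm,
               length_mm = data$length_mm,
               rate_mm_per_min = data$rate_mm_per_min,
               preload_mpa = data$preload_mpa,
               ruptured = data$ruptured)
  yaml::write_yaml(meta, paste0(path, ".meta.yaml"))
  invisible(path)
}

#' Small-strain elastic modulus of a tensile record
#'
#' Slope of nominal stress versus engineering strain over a small-strain
#' window, by ordinary least squares through the preload-corrected origin
#' (stresses reduced by the recorded preload, no intercept).
#'
#' @param data a \code{\link{tensile_dataset}}.
#' @param window upper stretch bound of the small-strain window.
#' @return modulus of elasticity E (MPa).
#' @export
initial_modulus <- function(data, window = 1.05) {
  s <- data$samples
  keep <- s$stretch <= window
  if (sum(keep) < 3L)
    stop("initial_modulus: need at least 3 samples with stretch <= ", window)
  eps <- s$stretch[keep] - 1
  sig <- s$stress_mpa[keep] - data$preload_mpa
  sum(eps * sig) / sum(eps^2)
}

#' Ultimate tensile strength
#'
#' Maximum nominal stress over the record and the stretch at which it
#' occurs. When the dataset does not mark a rupture the terminal maximum is
#' returned with a \code{rupture_detected = FALSE} flag.
#'
#' @param data a \code{\link{tensile_dataset}}.
#' @return list with \code{sigma_y_mpa}, \code{stretch_at_failure},
#'   \code{rupture_detected}.
#' @export
ultimate_strength <- function(data) {
  s <- data$samples
  if (nrow(s) == 0L) stop("ultimate_strength: empty dataset")
  if (all(s$stress_mpa == 0))
    warning("ultimate_strength: all stresses are zero")
  i <- which.max(s$stress_mpa)
  list(sigma_y_mpa = s$stress_mpa[i], stretch_at_failure = s$stretch[i],
       rupture_detected = data$ruptured || i < nrow(s))
}

#' Re-reference a record to its preloaded state
#'
#' Shifts the stress axis so the first sample equals the recorded preload and
#' re-references stretches to the preloaded configuration
#' (lambda -> lambda / lambda_1).
#'
#' @param data a \code{\link{tensile_dataset}}.
#' @return a new \code{tensile_dataset}.
#' @export
rereference_preload <- function(data) {
  s <- data$samples
  shift <- data$preload_mpa - s$stress_mpa[1]
  tensile_dataset(s$stretch / s$stretch[1], s$stress_mpa + shift,
                  specimen_id = data$specimen_id,
                  diameter_mm = data$diameter_mm,
                  thickness_mm = data$thickness_mm,
                  length_mm = data$length_mm,
                  rate_mm_per_min = data$rate_mm_per_min,
                  preload_mpa = data$preload_mpa, ruptured = data$ruptured)
}
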