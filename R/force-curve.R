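#' AFM force curve container
#'
#' One nanoindentation record: piezo position, force and segment labels for
#' the approach/retract cycle, plus the probe and sample metadata needed for
#' contact-model fitting.
#'
#' @param z Piezo positions (increasing toward the sample on approach).
#' @param force Measured force (nN), same length as `z`.
#' @param segment Character/factor per point, `"approach"` or `"retract"`.
#' @param probe_radius_um Colloidal probe radius (um).
#' @param spring_constant Cantilever spring constant (N/m), metadata only.
#' @param region Probed cellular region (`cytoplasm`, `nucleus`, `junction`,
#'   `substrate`).
#' @param substrate Substrate label (e.g. `TCPS`, `NCCI`).
#' @param sample_id Free-text identifier.
#' @param z_unit Unit of `z`: `"um"` (default) or `"nm"`; nm inputs are
#'   converted so that all downstream computation sees um.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(z, force, segment, probe_radius_um,
                        spring_constant = NA_real_,
                        region = "cytoplasm", substrate = "TCPS",
                        sample_id = "", z_unit = c("um", "nm")) {
  z_unit <- match.arg(z_unit)
  if (z_unit == "nm") z <- z / 1000
  n <- length(z)
  if (length(force) != n || length(segment) != n)
    stop("z, force and segment must have equal length")
  if (n < 50) stop("force curve must contain at least 50 points")
  if (!all(is.finite(z)) || !all(is.finite(force)))
    stop("z and force must be finite")
  segment <- as.character(segment)
  if (!all(segment %in% c("approach", "retract")))
    stop("segment labels must be 'approach' or 'retract'")
  if (!is.finite(probe_radius_um) || probe_radius_um <= 0)
    stop("invalid parameter: probe_radius_um must be > 0")
  structure(list(z = as.numeric(z), force = as.numeric(force),
                 segment = segment, probe_radius_um = probe_radius_um,
                 spring_constant = spring_constant, region = region,
                 substrate = substrate, sample_id = sample_id),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "Force curve '%s' (%s on %s): %d approach / %d retract points, R = %.2f um\n",
    x$sample_id, x$region, x$substrate,
    sum(x$segment == "approach"), sum(x$segment == "retract"),
    x$probe_radius_um))
  invisible(x)
}

# segment extractor used by the fitting code
.curve_segment <- function(curve, which) {
  i <- curve$segment == which
  list(z = curve$z[i], force = curve$force[i])
}

#' Read a force curve from CSV + JSON sidecar
#'
#' The CSV must hold columns `z_um` (or `z_nm`), `force_nN` and `segment`;
#' the sidecar (same path with extension `.json`, or given explicitly) holds
#' `probe_radius_um`, `spring_constant_N_per_m`, `region`, `substrate` and
#' `sample_id`.
#'
#' @param csv_path Path to the curve CSV.
#' @param json_path Optional explicit sidecar path.
#' @return A [force_curve].
#' @export
read_force_curve <- function(csv_path, json_path = NULL) {
  if (!file.exists(csv_path)) stop("input missing: ", csv_path)
  if (is.null(json_path))
    json_path <- paste0(tools::file_path_sans_ext(csv_path), ".json")
  if (!file.exists(json_path)) stop("metadata sidecar missing: ", json_path)
  d <- utils::read.csv(csv_path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  if ("z_um" %in% names(d)) { z <- d$z_um; unit <- "um" }
  else if ("z_nm" %in% names(d)) { z <- d$z_nm; unit <- "nm" }
  else stop("curve CSV must contain a z_um or z_nm column")
  force_curve(z, d$force_nN, d$segment,
              probe_radius_um = meta$probe_radius_um,
              spring_constant = meta$spring_constant_N_per_m %||% NA_real_,
              region = meta$region %||% "cytoplasm",
              substrate = meta$substrate %||% "TCPS",
              sample_id = meta$sample_id %||% "", z_unit = unit)
}

#' Write a force curve to CSV + JSON sidecar
#'
#' @param curve A [force_curve].
#' @param csv_path Output CSV path; the sidecar is written next to it.
#' @return Invisibly, the two paths written.
#' @export
write_force_curve <- function(curve, csv_path) {
  stopifnot(inherits(curve, "force_curve"))
  utils::write.csv(data.frame(z_um = curve$z, force_nN = curve$force,
                              segment = curve$segment),
                   csv_path, row.names = FALSE)
  json_path <- paste0(tools::file_path_sans_ext(csv_path), ".json")
  jsonlite::write_json(list(probe_radius_um = curve$probe_radius_um,
                            spring_constant_N_per_m = curve$spring_constant,
                            region = curve$region,
                            substrate = curve$substrate,
                            sample_id = curve$sample_id),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(c(csv_path, json_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
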