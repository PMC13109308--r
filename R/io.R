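## Readers/writers for the package's tabular formats and JSON artifacts.

.scan_columns <- c("wavelength_nm", "holder_scale_deg", "incident_zenith_deg",
                   "incident_azimuth_deg", "view_zenith_deg",
                   "view_azimuth_deg", "flux_sample", "flux_reference")

#' Read an angular-scan CSV
#'
#' Expects a UTF-8 CSV with header columns `wavelength_nm, holder_scale_deg,
#' incident_zenith_deg, incident_azimuth_deg, view_zenith_deg,
#' view_azimuth_deg, flux_sample, flux_reference` (decimal point `.`).
#' Errors name any missing column.
#'
#' @param path CSV file path.
#' @return Data frame of typed scan records.
#' @export
read_scan_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.scan_columns, names(tab))
  if (length(missing)) {
    stop("scan file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (cn in .scan_columns) {
    if (!is.numeric(tab[[cn]])) {
      stop("column '", cn, "' is not numeric", call. = FALSE)
    }
  }
  tab
}

#' Write an angular-scan (or calibrated) table to CSV
#'
#' @param scan Data frame to write.
#' @param path Output path.
#' @export
write_scan_csv <- function(scan, path) {
  utils::write.csv(as.data.frame(scan), path, row.names = FALSE)
  invisible(path)
}

#' Read a canopy-mesh CSV (one triangle per row)
#'
#' Columns: the nine vertex coordinates `v1x..v3z` plus `sigma, k, n, tau`.
#'
#' @param path CSV file path.
#' @return A [canopy_mesh()].
#' @export
read_mesh_csv <- function(path) {
  canopy_mesh(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a canopy mesh to CSV
#' @param mesh A [canopy_mesh()].
#' @param path Output path.
#' @export
write_mesh_csv <- function(mesh, path) {
  cols <- c("v1x", "v1y", "v1z", "v2x", "v2y", "v2z", "v3x", "v3y", "v3z",
            "sigma", "k", "n", "tau")
  utils::write.csv(mesh$triangles[cols], path, row.names = FALSE)
  invisible(path)
}

## Provenance block embedded in JSON artifacts: input hashes, seeds, version.
.provenance <- function(inputs = character(0), seeds = list()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(package = "leafbrdf",
       version = as.character(utils::packageVersion("leafbrdf")),
       input_md5 = hashes, seeds = seeds)
}

#' Write a result object to JSON with a provenance block
#'
#' @param x List to serialize.
#' @param path Output path.
#' @param inputs Paths of input files to hash into the provenance block.
#' @param seeds Named list of seeds used.
#' @export
write_result_json <- function(x, path, inputs = character(0),
                              seeds = list()) {
  x$provenance <- .provenance(inputs, seeds)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
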