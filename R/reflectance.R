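## Calibration of raw sample/reference flux scans to bidirectional
## reflectance, Lambertian whiteboard validation, and wavelength selection.

#' Bidirectional reflectance from sample and reference fluxes
#'
#' The reference whiteboard is an ideal Lambertian surface whose bidirectional
#' reflectance is `1/pi`, so the sample reflectance follows from the flux
#' ratio alone: `f_samp = flux_sample / (pi * flux_reference)`. The solid
#' angle and incident flux cancel because sample and reference are measured
#' under identical geometry.
#'
#' @param flux_sample Non-negative radiant flux from the sample (vectorized).
#' @param flux_reference Positive radiant flux from the reference whiteboard.
#' @return Bidirectional reflectance in 1/steradian.
#' @examples
#' fsamp_from_fluxes(1, 1) # 1/pi: sample identical to the reference
#' @export
fsamp_from_fluxes <- function(flux_sample, flux_reference) {
  if (any(!is.finite(flux_reference)) || any(flux_reference <= 0)) {
    stop("calibration error: reference flux must be positive", call. = FALSE)
  }
  if (any(!is.finite(flux_sample)) || any(flux_sample < 0)) {
    stop("sample flux must be non-negative", call. = FALSE)
  }
  flux_sample / (pi * flux_reference)
}

#' Cosine-law regression check for a Lambertian surface
#'
#' A Lambertian surface reflects intensity proportional to the cosine of the
#' detection angle. Regresses measured intensity on `cos(theta_v)` by ordinary
#' least squares and reports the slope, intercept and R-squared; values of
#' R-squared near 1 validate the angular calibration of the instrument.
#'
#' @param intensities Measured reflected intensities.
#' @param view_zeniths_deg Detection zenith angles in degrees (angle between
#'   viewing direction and the surface normal); at least 3 distinct angles.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
lambertian_check <- function(intensities, view_zeniths_deg) {
  stopifnot(length(intensities) == length(view_zeniths_deg))
  if (length(unique(view_zeniths_deg)) < 3) {
    stop("need at least 3 distinct detection angles", call. = FALSE)
  }
  x <- cos(deg2rad(view_zeniths_deg))
  if (diff(range(x)) < 1e-12) {
    stop("degenerate regression: cos(theta) is constant", call. = FALSE)
  }
  fit <- stats::lm(intensities ~ x)
  sse <- sum(stats::residuals(fit)^2)
  sstot <- sum((intensities - mean(intensities))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = 1 - sse / sstot)
}

#' Representative measurement wavelengths (nm)
#'
#' The five wavelengths used for per-band parameter fitting: blue and red
#' pigment absorption bands, the green reflectance peak, and two
#' near-infrared bands.
#' @export
leaf_wavelengths <- c(468.36, 556.26, 673.46, 819.88, 877.97)

#' Select spectrum samples nearest to target wavelengths
#'
#' Picks, for each target, the nearest sampled wavelength within `tol`
#' nanometers, preserving target order.
#'
#' @param wavelengths_nm Sampled wavelengths (non-empty numeric vector).
#' @param targets Target wavelengths; defaults to [leaf_wavelengths].
#' @param tol Matching tolerance in nm (default 1).
#' @return Named numeric vector: matched sample wavelength per target.
#' @export
select_wavelengths <- function(wavelengths_nm, targets = leaf_wavelengths,
                               tol = 1) {
  if (length(targets) == 0) return(stats::setNames(numeric(0), character(0)))
  if (length(wavelengths_nm) == 0) stop("empty spectrum", call. = FALSE)
  out <- vapply(targets, function(tg) {
    d <- abs(wavelengths_nm - tg)
    i <- which.min(d)
    if (d[i] > tol) NA_real_ else wavelengths_nm[i]
  }, numeric(1))
  if (anyNA(out)) {
    stop("no spectrum sample within ", tol, " nm of target(s): ",
         paste(format(targets[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  stats::setNames(out, format(targets))
}

#' Calibrate an angular scan to bidirectional reflectance
#'
#' Reduces a raw angular-scan table (see [read_scan_csv()] for the schema) to
#' calibrated bidirectional reflectance: computes the geometry frame per row,
#' applies the flux-ratio calibration, and drops rows whose geometry is
#' degenerate (source or detector behind the leaf plane), reporting the count.
#'
#' @param scan Data frame with columns `wavelength_nm, holder_scale_deg,
#'   incident_zenith_deg, incident_azimuth_deg, view_zenith_deg,
#'   view_azimuth_deg, flux_sample, flux_reference`.
#' @param v_form Viewing-vector convention, see [viewing_vector()].
#' @param reference Either `"per_row"` (a reference flux on every row, the
#'   default) or `"per_incidence"` (one reference value per
#'   wavelength-by-incidence group, propagated to all rows in the group).
#' @param quiet Suppress the dropped-row message.
#' @return Data frame: the scan columns plus geometry cosines, `alpha`, and
#'   `f_samp_sr`, with degenerate rows removed. Class `reflectance_dataset`.
#' @export
calibrate_scan <- function(scan, v_form = c("corrected", "as_printed"),
                           reference = c("per_row", "per_incidence"),
                           quiet = FALSE) {
  v_form <- match.arg(v_form)
  reference <- match.arg(reference)
  required <- c("wavelength_nm", "holder_scale_deg", "view_zenith_deg",
                "view_azimuth_deg", "flux_sample", "flux_reference")
  missing <- setdiff(required, names(scan))
  if (length(missing)) {
    stop("scan is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (reference == "per_incidence") {
    grp <- interaction(scan$wavelength_nm, scan$holder_scale_deg, drop = TRUE)
    scan$flux_reference <- stats::ave(scan$flux_reference, grp,
                                      FUN = function(v) {
                                        v[!is.finite(v)] <- NA
                                        m <- mean(v, na.rm = TRUE)
                                        ifelse(is.na(v), m, v)
                                      })
  }
  theta_leaf <- leaf_angle_from_holder(scan$holder_scale_deg)
  ft <- frame_table(theta_leaf, scan$view_zenith_deg, scan$view_azimuth_deg,
                    v_form)
  out <- cbind(scan, ft[c("cos_LN", "cos_NV", "cos_NH", "cos_VH",
                          "cos_theta_h", "alpha", "degenerate")])
  out$f_samp_sr <- fsamp_from_fluxes(scan$flux_sample, scan$flux_reference)
  n_drop <- sum(out$degenerate)
  if (n_drop > 0 && !quiet) {
    message("calibrate_scan: dropped ", n_drop,
            " row(s) with degenerate geometry")
  }
  out <- out[!out$degenerate, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reflectance_dataset", "data.frame")
  out
}
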