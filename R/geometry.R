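## Measurement geometry: instrument scale readings -> unit vectors and angles.
##
## Coordinate convention (right-handed, matching the goniometer platform):
## the illumination beam travels along +Y, so the illumination direction
## vector L (surface -> source) is (0, -1, 0); Z points vertically downward.
## All user-facing angles are degrees; radians are used internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

.unitize <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / nv
}

#' Leaf inclination angle from the holder scale reading
#'
#' The leaf holder's mechanical zero does not coincide with perpendicular
#' illumination; the perpendicular reference sits at a scale reading of 95
#' degrees, so the physical leaf inclination is `95 - holder_scale_deg`.
#'
#' @param holder_scale_deg Numeric vector of holder scale readings (degrees).
#' @return Leaf inclination angle(s) in degrees.
#' @examples
#' leaf_angle_from_holder(95) # 0: perpendicular illumination
#' leaf_angle_from_holder(65) # 30
#' @export
leaf_angle_from_holder <- function(holder_scale_deg) {
  stopifnot(is.numeric(holder_scale_deg), all(is.finite(holder_scale_deg)))
  out <- 95 - holder_scale_deg
  if (any(out < -90 | out > 90)) {
    warning("leaf inclination outside [-90, 90] degrees; passing through")
  }
  out
}

#' Illumination direction vector
#'
#' The source is fixed; light travels along +Y, so the surface-to-source
#' direction is `(0, -1, 0)`.
#'
#' @return Unit 3-vector.
#' @export
illumination_vector <- function() c(0, -1, 0)

#' Leaf normal vector from the inclination angle
#'
#' `N = (sin(theta), -cos(theta), 0)`: at zero inclination the normal points
#' back toward the source (normal incidence, N = L).
#'
#' @param theta_leaf_deg Leaf inclination angle in degrees.
#' @return Unit 3-vector.
#' @export
normal_vector <- function(theta_leaf_deg) {
  stopifnot(is.finite(theta_leaf_deg))
  t <- deg2rad(theta_leaf_deg)
  c(sin(t), -cos(t), 0)
}

#' Viewing direction vector from detection-ring angles
#'
#' The detector slides along a ring; its scale gives the viewing zenith
#' `theta_v` (measured from the illumination axis) and the ring rotation gives
#' the azimuth `phi_v`. The `"corrected"` form,
#' `(sin(theta_v) cos(phi_v), -cos(theta_v), sin(theta_v) sin(phi_v))`,
#' is a unit vector that coincides with L at `theta_v = 0`. The `"as_printed"`
#' form `(sin(theta_v) cos(phi_v), -sin(theta_v), sin(theta_v) sin(phi_v))`
#' is retained for comparison; it is not unit length and degenerates to the
#' zero vector at `theta_v = 0`, where it errors after normalization.
#'
#' @param view_zenith_deg Viewing zenith angle (degrees).
#' @param view_azimuth_deg Viewing azimuth angle (degrees).
#' @param v_form Either `"corrected"` (default) or `"as_printed"`.
#' @return Unit 3-vector.
#' @export
viewing_vector <- function(view_zenith_deg, view_azimuth_deg = 0,
                           v_form = c("corrected", "as_printed")) {
  v_form <- match.arg(v_form)
  stopifnot(is.finite(view_zenith_deg), is.finite(view_azimuth_deg))
  tv <- deg2rad(view_zenith_deg)
  pv <- deg2rad(view_azimuth_deg)
  if (v_form == "corrected") {
    c(sin(tv) * cos(pv), -cos(tv), sin(tv) * sin(pv))
  } else {
    v <- c(sin(tv) * cos(pv), -sin(tv), sin(tv) * sin(pv))
    if (sqrt(sum(v^2)) < 1e-12) {
      stop("'as_printed' viewing vector is the zero vector at theta_v = 0",
           call. = FALSE)
    }
    .unitize(v)
  }
}

#' Half-vector (microfacet bisector) of two directions
#'
#' `H = (L + V) / ||L + V||`, the normalized bisector of the illumination and
#' viewing directions; a microfacet whose normal equals H reflects the source
#' into the detector.
#'
#' @param L,V Unit 3-vectors (surface-to-source and surface-to-detector).
#' @return Unit 3-vector.
#' @export
half_vector <- function(L, V) {
  s <- L + V
  if (sqrt(sum(s^2)) < 1e-9) {
    stop("degenerate geometry: L and V are antiparallel", call. = FALSE)
  }
  .unitize(s)
}

#' Full measurement geometry for one instrument configuration
#'
#' Builds the vector frame (L, N, V, H) and derived angles for one
#' configuration of the goniometer. `theta_leaf_deg` may be given directly or
#' derived from `holder_scale_deg` via [leaf_angle_from_holder()]. The frame
#' is flagged degenerate when the source or the detector lies behind the leaf
#' plane (`L.N <= 0` or `N.V <= 0`); degenerate frames are excluded from
#' fitting rather than clamped.
#'
#' @param theta_leaf_deg Leaf inclination angle (degrees); equals the
#'   illumination zenith angle since the beam is fixed.
#' @param view_zenith_deg,view_azimuth_deg Detection-ring angles (degrees).
#' @param holder_scale_deg Optional holder scale reading used instead of
#'   `theta_leaf_deg`.
#' @param v_form Viewing-vector convention, see [viewing_vector()].
#' @return An object of class `geometry_frame`: list with unit vectors
#'   `L`, `N`, `V`, `H`, the cosines `cos_LN`, `cos_NV`, `cos_NH`, `cos_VH`,
#'   `cos_theta_h` (= L.H), the angles `alpha` (N-to-H) and `theta_h` in
#'   radians, and a logical `degenerate`.
#' @examples
#' fr <- geometry_frame(theta_leaf_deg = 30, view_zenith_deg = 60)
#' fr$alpha # 0: in-plane specular configuration
#' @export
geometry_frame <- function(theta_leaf_deg = NULL, view_zenith_deg,
                           view_azimuth_deg = 0, holder_scale_deg = NULL,
                           v_form = c("corrected", "as_printed")) {
  v_form <- match.arg(v_form)
  if (is.null(theta_leaf_deg)) {
    if (is.null(holder_scale_deg)) {
      stop("supply either theta_leaf_deg or holder_scale_deg", call. = FALSE)
    }
    theta_leaf_deg <- leaf_angle_from_holder(holder_scale_deg)
  }
  L <- illumination_vector()
  N <- normal_vector(theta_leaf_deg)
  V <- viewing_vector(view_zenith_deg, view_azimuth_deg, v_form)
  H <- half_vector(L, V)
  cos_LN <- sum(L * N)
  cos_NV <- sum(N * V)
  cos_NH <- sum(N * H)
  cos_VH <- sum(V * H)
  cos_theta_h <- sum(L * H)
  structure(list(
    L = L, N = N, V = V, H = H,
    cos_LN = cos_LN, cos_NV = cos_NV, cos_NH = cos_NH, cos_VH = cos_VH,
    cos_theta_h = cos_theta_h,
    alpha = acos(pmin(1, pmax(-1, cos_NH))),
    theta_h = acos(pmin(1, pmax(-1, cos_theta_h))),
    degenerate = (cos_LN <= 1e-8 || cos_NV <= 1e-8)
  ), class = "geometry_frame")
}

#' Geometry frame from explicit direction vectors
#'
#' Variant of [geometry_frame()] for arbitrary direction vectors (used by the
#' canopy photon tracer, where facet normals are not instrument-aligned).
#' Inputs are normalized; L and V must not be antiparallel.
#'
#' @param L,N,V 3-vectors: surface-to-source, surface normal,
#'   surface-to-detector.
#' @return A `geometry_frame`, see [geometry_frame()].
#' @export
geometry_frame_from_vectors <- function(L, N, V) {
  L <- .unitize(L); N <- .unitize(N); V <- .unitize(V)
  H <- half_vector(L, V)
  cos_LN <- sum(L * N); cos_NV <- sum(N * V)
  cos_NH <- sum(N * H); cos_VH <- sum(V * H)
  cos_theta_h <- sum(L * H)
  structure(list(
    L = L, N = N, V = V, H = H,
    cos_LN = cos_LN, cos_NV = cos_NV, cos_NH = cos_NH, cos_VH = cos_VH,
    cos_theta_h = cos_theta_h,
    alpha = acos(pmin(1, pmax(-1, cos_NH))),
    theta_h = acos(pmin(1, pmax(-1, cos_theta_h))),
    degenerate = (cos_LN <= 1e-8 || cos_NV <= 1e-8)
  ), class = "geometry_frame")
}

#' @export
print.geometry_frame <- function(x, ...) {
  cat("Measurement geometry frame\n")
  cat(sprintf("  L = (%.4f, %.4f, %.4f)\n", x$L[1], x$L[2], x$L[3]))
  cat(sprintf("  N = (%.4f, %.4f, %.4f)\n", x$N[1], x$N[2], x$N[3]))
  cat(sprintf("  V = (%.4f, %.4f, %.4f)\n", x$V[1], x$V[2], x$V[3]))
  cat(sprintf("  H = (%.4f, %.4f, %.4f)\n", x$H[1], x$H[2], x$H[3]))
  cat(sprintf("  alpha = %.3f deg, theta_h = %.3f deg%s\n",
              rad2deg(x$alpha), rad2deg(x$theta_h),
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

## Vectorized frame table used by calibration/fitting: one row per
## (theta_leaf, theta_v, phi_v) configuration. Columns mirror geometry_frame.
frame_table <- function(theta_leaf_deg, view_zenith_deg, view_azimuth_deg = 0,
                        v_form = c("corrected", "as_printed")) {
  v_form <- match.arg(v_form)
  n <- max(length(theta_leaf_deg), length(view_zenith_deg),
           length(view_azimuth_deg))
  tl <- deg2rad(rep_len(theta_leaf_deg, n))
  tv <- deg2rad(rep_len(view_zenith_deg, n))
  pv <- deg2rad(rep_len(view_azimuth_deg, n))
  Lx <- 0; Ly <- -1; Lz <- 0
  Nx <- sin(tl); Ny <- -cos(tl); Nz <- 0
  if (v_form == "corrected") {
    Vx <- sin(tv) * cos(pv); Vy <- -cos(tv); Vz <- sin(tv) * sin(pv)
  } else {
    Vx <- sin(tv) * cos(pv); Vy <- -sin(tv); Vz <- sin(tv) * sin(pv)
    nv <- sqrt(Vx^2 + Vy^2 + Vz^2)
    if (any(nv < 1e-12)) {
      stop("'as_printed' viewing vector degenerates at theta_v = 0",
           call. = FALSE)
    }
    Vx <- Vx / nv; Vy <- Vy / nv; Vz <- Vz / nv
  }
  Hx <- Lx + Vx; Hy <- Ly + Vy; Hz <- Lz + Vz
  hn <- sqrt(Hx^2 + Hy^2 + Hz^2)
  bad <- hn < 1e-9
  hn[bad] <- NA_real_
  Hx <- Hx / hn; Hy <- Hy / hn; Hz <- Hz / hn
  cos_LN <- Lx * Nx + Ly * Ny + Lz * Nz
  cos_NV <- Nx * Vx + Ny * Vy + Nz * Vz
  cos_NH <- Nx * Hx + Ny * Hy + Nz * Hz
  cos_VH <- Vx * Hx + Vy * Hy + Vz * Hz
  cos_th <- Lx * Hx + Ly * Hy + Lz * Hz
  data.frame(
    theta_leaf_deg = rad2deg(tl),
    view_zenith_deg = rad2deg(tv),
    view_azimuth_deg = rad2deg(pv),
    cos_LN = cos_LN, cos_NV = cos_NV, cos_NH = cos_NH, cos_VH = cos_VH,
    cos_theta_h = cos_th,
    alpha = acos(pmin(1, pmax(-1, cos_NH))),
    degenerate = bad | cos_LN <= 1e-8 | cos_NV <= 1e-8
  )
}
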